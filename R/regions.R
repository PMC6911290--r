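# Region-preference statistics: map nested insertions to regions of their
# original elements, compare observed counts against length-normalized
# expectations with a chi-squared goodness-of-fit test and per-region
# follow-ups under Benjamini-Hochberg FDR control, and build the
# family-by-family autoinsertion matrix plus the superfamily enrichment
# test.

# canonical region orders for aggregated tables
REGION_ORDER_GYPSY <- c("LTR5", "pbs", "5UTR", "GAG", "GAG-AP", "AP",
                        "AP-RT", "RT", "RT-RH", "RH", "RH-INT", "INT",
                        "INT-CHR", "CHR", "3UTR", "ppt", "LTR3")
REGION_ORDER_COPIA <- c("LTR5", "pbs", "5UTR", "GAG", "GAG-AP", "AP",
                        "AP-INT", "INT", "INT-RT", "RT", "RT-RH", "RH",
                        "3UTR", "ppt", "LTR3")

region_order <- function(superfamily) {
  if (superfamily == "gypsy") REGION_ORDER_GYPSY else REGION_ORDER_COPIA
}

#' Assign an insertion offset to a region of the original element
#'
#' The label is the annotated sub-span containing the position; positions in
#' an annotation gap fall to the nearest spanned boundary with a warning.
#' Boundary bases belong to the downstream region by construction of the
#' tiling (regions abut without overlap).
#'
#' @param insertion_offset 1-based bp of the nested element's first base
#'   within the original element.
#' @param original_tiling data.frame `region`, `start`, `end` from
#'   [complete_region_tiling()] (absolute coordinates), or relative with
#'   `element_start = 1`.
#' @param element_start the original element's start coordinate (so that
#'   `element_start + insertion_offset - 1` is the genomic position).
#' @return region label (character).
#' @export
assign_region <- function(insertion_offset, original_tiling,
                          element_start = 1L) {
  pos <- element_start + insertion_offset - 1L
  hit <- which(original_tiling$start <= pos & original_tiling$end >= pos)
  if (length(hit)) return(original_tiling$region[hit[1L]])
  warning("assign_region: offset in annotation gap; using nearest region")
  dists <- pmin(abs(original_tiling$start - pos),
                abs(original_tiling$end - pos))
  original_tiling$region[which.min(dists)]
}

#' Length-normalized expected insertion counts per region
#'
#' `E_r = (mean region length / mean element length) * N`, where `N` is the
#' number of nested elements in the family; expectations sum to `N` exactly.
#'
#' @param schema data.frame `region`, `mean_len` ([family_schema()]).
#' @param N nested-element count for the family (>= 0).
#' @return named numeric vector of expectations.
#' @export
expected_counts <- function(schema, N) {
  stopifnot(N >= 0)
  L <- sum(schema$mean_len)
  if (L <= 0) stop("expected_counts: invalid schema (zero total length)")
  stats::setNames(schema$mean_len / L * N, schema$region)
}

#' Chi-squared goodness-of-fit test with per-region follow-ups
#'
#' Global Pearson statistic `X^2 = sum (O_r - E_r)^2 / E_r` with
#' `#regions - 1` degrees of freedom, then a 1-df region-vs-rest chi-squared
#' follow-up per region, Benjamini-Hochberg adjusted. Regions with
#' expectation below `pool_min` are pooled with the adjacent
#' smaller-expectation region first (chi-squared validity).
#'
#' @param O named observed counts.
#' @param E named expected counts on the same regions (sum equal to
#'   `sum(O)` up to rounding of the input schema).
#' @param pool_min pooling threshold on `E_r` (default 1; 0 disables).
#' @param alpha significance level on adjusted p-values.
#' @return list `table` (data.frame `region`, `observed`, `expected`,
#'   `p_raw`, `p_adj`, `direction`, `significant`), `statistic`, `df`,
#'   `p_global`.
#' @export
gof_test <- function(O, E, pool_min = 1, alpha = 0.05) {
  if (is.null(names(O)) || is.null(names(E)) ||
      !setequal(names(O), names(E))) {
    stop("gof_test: O and E must be named over the same regions")
  }
  E <- E[names(O)]
  if (sum(O) <= 0) stop("gof_test: no observations")
  if (pool_min > 0) {
    pooled <- .pool_low_expected(O, E, pool_min)
    O <- pooled$O; E <- pooled$E
  }
  tot <- sum(O)
  # scale E to the observed total (protects against schema rounding drift)
  E <- E * tot / sum(E)
  stat <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  p_global <- stats::pchisq(stat, df, lower.tail = FALSE)
  p_raw <- vapply(seq_along(O), function(i) {
    suppressWarnings(stats::chisq.test(
      c(O[i], tot - O[i]), p = c(E[i], tot - E[i]) / tot)$p.value)
  }, 0)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  tab <- data.frame(region = names(O), observed = as.numeric(O),
                    expected = as.numeric(E), p_raw = p_raw, p_adj = p_adj,
                    direction = ifelse(O > E, "over",
                                       ifelse(O < E, "under", "equal")),
                    significant = p_adj < alpha, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, statistic = stat, df = df, p_global = p_global)
}

# pool regions with E below the threshold into an adjacent region
.pool_low_expected <- function(O, E, pool_min) {
  while (length(E) > 1L && any(E < pool_min)) {
    i <- which.min(E)
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= length(E)]
    j <- nb[which.min(E[nb])]
    lab <- paste(names(E)[sort(c(i, j))], collapse = "+")
    O[j] <- O[i] + O[j]; E[j] <- E[i] + E[j]
    names(O)[j] <- lab; names(E)[j] <- lab
    O <- O[-i]; E <- E[-i]
  }
  list(O = O, E = E)
}

#' Region-preference table for a set of nested pairs
#'
#' Assigns every pair's insertion to a region of its original element,
#' builds length-normalized expectations from the family panel (per original
#' family, summed within a superfamily) and runs [gof_test()].
#'
#' @param pairs data.frame with `original_id`, `region_label` (if labels are
#'   absent they are computed from `insertion_offset` and the annotation).
#' @param ann `ltr_annotation` holding the originals (used for family and,
#'   if needed, region tilings).
#' @param panel family panel for expectations.
#' @param superfamily `"gypsy"` or `"copia"`: restrict to pairs whose
#'   original belongs to this superfamily.
#' @param ... passed to [gof_test()].
#' @return a [gof_test()] result (with `table` ordered canonically), or
#'   `NULL` if no pairs fall in the superfamily.
#' @export
region_preference <- function(pairs, ann, panel, superfamily, ...) {
  el <- ann$elements
  fam_of <- stats::setNames(el$family, el$id)
  sf_of <- stats::setNames(el$superfamily, el$id)
  use <- pairs[sf_of[pairs$original_id] %in% superfamily, , drop = FALSE]
  if (!nrow(use)) return(NULL)
  if (is.null(use$region_label)) {
    use$region_label <- vapply(seq_len(nrow(use)), function(i) {
      oid <- use$original_id[i]
      tiling <- complete_region_tiling(ann, oid)
      assign_region(use$insertion_offset[i], tiling,
                    element_start = el$start[el$id == oid])
    }, "")
  }
  regs <- region_order(superfamily)
  O <- stats::setNames(numeric(length(regs)), regs)
  oc <- table(use$region_label)
  O[names(oc)] <- as.numeric(oc)
  E <- stats::setNames(numeric(length(regs)), regs)
  for (f in unique(fam_of[use$original_id])) {
    Nf <- sum(fam_of[use$original_id] == f)
    Ef <- expected_counts(family_schema(panel[[f]]), Nf)
    E[names(Ef)] <- E[names(Ef)] + Ef
  }
  keep <- E > 0 | O > 0
  gof_test(O[keep], E[keep], ...)
}

#' Family-by-family autoinsertion matrix
#'
#' Counts of nested-family (rows) by original-family (columns) insertions;
#' the diagonal holds autoinsertions and per-family fractions are
#' diagonal / row sum.
#'
#' @param pairs data.frame `nested_id`, `original_id`.
#' @param elements data.frame with `id`, `family`.
#' @return list `matrix` (counts), `autoinsertion_fraction` (named per
#'   nested family; `NaN` when the family nested nowhere).
#' @export
autoinsertion_matrix <- function(pairs, elements) {
  fam <- stats::setNames(elements$family, elements$id)
  fams <- sort(unique(elements$family))
  M <- matrix(0L, length(fams), length(fams), dimnames = list(fams, fams))
  if (nrow(pairs)) {
    tab <- table(factor(fam[pairs$nested_id], levels = fams),
                 factor(fam[pairs$original_id], levels = fams))
    M <- M + unclass(tab)
  }
  frac <- diag(M) / rowSums(M)
  list(matrix = M, autoinsertion_fraction = frac)
}

#' Superfamily enrichment among nested vs non-nested elements
#'
#' Pearson chi-squared test of independence on the 2x2 table of gypsy/copia
#' counts in the nested and non-nested sets (no continuity correction by
#' default, configurable).
#'
#' @param nested_by_sf length-2 counts `c(gypsy, copia)` among nested.
#' @param nonnested_by_sf length-2 counts among non-nested.
#' @param correct continuity correction flag (default `FALSE`).
#' @return list `statistic`, `df`, `p`.
#' @export
superfamily_enrichment <- function(nested_by_sf, nonnested_by_sf,
                                   correct = FALSE) {
  tab <- rbind(nested = nested_by_sf, non_nested = nonnested_by_sf)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("superfamily_enrichment: zero marginal in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Split pairs into recent and old subsets by LTR identity delta
#'
#' Recent: delta in `[0, 1]` percentage points (nesting soon after the
#' original's own insertion); old: delta `>= 5`. Pairs in between (or with
#' negative delta, an estimation artifact) belong to neither subset.
#'
#' @param pairs data.frame with an `identity_delta` column.
#' @param recent_max upper bound of the recent class (default 1).
#' @param old_min lower bound of the old class (default 5).
#' @return list `recent`, `old` (data.frames).
#' @export
recent_old_split <- function(pairs, recent_max = 1, old_min = 5) {
  stopifnot("identity_delta" %in% names(pairs))
  list(recent = pairs[!is.na(pairs$identity_delta) &
                        pairs$identity_delta >= 0 &
                        pairs$identity_delta <= recent_max, , drop = FALSE],
       old = pairs[!is.na(pairs$identity_delta) &
                     pairs$identity_delta >= old_min, , drop = FALSE])
}
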