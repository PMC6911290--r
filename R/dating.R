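# Molecular dating from LTR divergence. The two LTRs of an element are
# identical at insertion; with substitution rate mu per site per year their
# pairwise divergence d grows as 2*mu*t, so T[Mya] = d / (2*mu) / 1e6.

#' Global-alignment identity between the two LTRs of an element
#'
#' Needleman-Wunsch global alignment with stretcher-like DNA scoring
#' (match +5, mismatch -4, gap open 16, gap extend 4); identity is matches
#' divided by alignment columns (gap columns count in the denominator),
#' in percent.
#'
#' @param ltr5_seq,ltr3_seq non-empty DNA character scalars.
#' @return identity percentage in `[0, 100]`.
#' @export
ltr_identity <- function(ltr5_seq, ltr3_seq) {
  if (!nzchar(ltr5_seq) || !nzchar(ltr3_seq)) {
    stop("ltr_identity: empty sequence")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ltr5_seq), Biostrings::DNAString(ltr3_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = 16, gapExtension = 4)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Convert LTR identity to insertion time
#'
#' @param identity_pct LTR-LTR identity percentage.
#' @param mu substitution rate per site per year (default 1.3e-8).
#' @param correction `"none"` (raw p-distance, default) or `"jc"`
#'   (Jukes-Cantor corrected divergence).
#' @return insertion time in Mya.
#' @export
insertion_time <- function(identity_pct, mu = 1.3e-8, correction = "none") {
  if (any(identity_pct < 0 | identity_pct > 100)) {
    stop("identity_pct must be within [0, 100]")
  }
  stopifnot(mu > 0)
  d <- 1 - identity_pct / 100
  if (correction == "jc") {
    d <- ifelse(d >= 0.75, NA_real_, -0.75 * log(1 - 4 * d / 3))
  }
  d / (2 * mu) / 1e6
}

#' Date every element of an annotation
#'
#' Extracts both LTR sequences per element (from `LTR5`/`LTR3` region spans
#' or from detector `ltr5_start`.. columns), aligns them and reports
#' identity, divergence and insertion time. Elements without two LTR spans
#' are skipped with a message.
#'
#' @param ann `ltr_annotation`, or a detector data.frame carrying
#'   `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`, `id`.
#' @param genome character scalar the coordinates refer to.
#' @param mu substitution rate per site per year.
#' @param elements optional data.frame of all element spans (`id`, `start`,
#'   `end`, `tsd_len`): nested insertions inside an LTR span are stripped
#'   with [extract_feature_seq()] before alignment.
#' @return data.frame `element_id`, `ltr_identity_pct`, `divergence`,
#'   `insertion_time_mya`.
#' @export
date_elements <- function(ann, genome, mu = 1.3e-8, elements = NULL) {
  if (is.null(elements) && inherits(ann, "ltr_annotation")) {
    elements <- ann$elements
  }
  if (is.null(elements) && is.data.frame(ann) && all(c("id", "start", "end")
                                                     %in% names(ann))) {
    elements <- ann
  }
  tab <- .ltr_span_table(ann)
  skipped <- tab$id[is.na(tab$l5s) | is.na(tab$l3s)]
  if (length(skipped)) {
    message("date_elements: skipping ", length(skipped),
            " element(s) without two LTR spans")
  }
  tab <- tab[!(tab$id %in% skipped), , drop = FALSE]
  idp <- vapply(seq_len(nrow(tab)), function(i) {
    l5 <- extract_feature_seq(genome, tab$l5s[i], tab$l5e[i],
                              elements = elements,
                              exclude_id = tab$id[i])
    l3 <- extract_feature_seq(genome, tab$l3s[i], tab$l3e[i],
                              elements = elements,
                              exclude_id = tab$id[i])
    ltr_identity(l5, l3)
  }, 0)
  data.frame(element_id = tab$id, ltr_identity_pct = idp,
             divergence = 1 - idp / 100,
             insertion_time_mya = insertion_time(idp, mu),
             stringsAsFactors = FALSE)
}

.ltr_span_table <- function(ann) {
  if (inherits(ann, "ltr_annotation")) {
    el <- ann$elements
    get_span <- function(id, which) {
      r <- ann$regions[ann$regions$element_id == id &
                         ann$regions$region == which, , drop = FALSE]
      if (nrow(r)) c(r$start[1L], r$end[1L]) else c(NA_integer_, NA_integer_)
    }
    l5 <- t(vapply(el$id, get_span, integer(2L), which = "LTR5"))
    l3 <- t(vapply(el$id, get_span, integer(2L), which = "LTR3"))
    data.frame(id = el$id, l5s = l5[, 1L], l5e = l5[, 2L],
               l3s = l3[, 1L], l3e = l3[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(id = ann$id, l5s = ann$ltr5_start, l5e = ann$ltr5_end,
               l3s = ann$ltr3_start, l3e = ann$ltr3_end,
               stringsAsFactors = FALSE)
  }
}

#' LTR identity delta of nested pairs
#'
#' The difference nested-minus-original in LTR identity percentage points;
#' small deltas mean the nesting happened soon after the original's own
#' insertion. Pairs with a missing identity are dropped with a message.
#'
#' @param pairs data.frame with `nested_id`, `original_id`.
#' @param ages data.frame from [date_elements()].
#' @return `pairs` with an added `identity_delta` column.
#' @export
identity_delta <- function(pairs, ages) {
  idx_n <- match(pairs$nested_id, ages$element_id)
  idx_o <- match(pairs$original_id, ages$element_id)
  miss <- is.na(idx_n) | is.na(idx_o)
  if (any(miss)) {
    message("identity_delta: dropping ", sum(miss), " pair(s) lacking dates")
    pairs <- pairs[!miss, , drop = FALSE]
    idx_n <- idx_n[!miss]; idx_o <- idx_o[!miss]
  }
  pairs$identity_delta <- ages$ltr_identity_pct[idx_n] -
    ages$ltr_identity_pct[idx_o]
  pairs
}

#' Compare insertion-time distributions of nested vs original elements
#'
#' Welch two-sample t-test on Mya values, with group means.
#'
#' @param nested_ages,original_ages numeric vectors (each n >= 2).
#' @return list `t`, `df`, `p`, `mean_nested`, `mean_original`.
#' @export
compare_age_groups <- function(nested_ages, original_ages) {
  stopifnot(length(nested_ages) >= 2L, length(original_ages) >= 2L)
  if (stats::sd(nested_ages) == 0 && stats::sd(original_ages) == 0) {
    eq <- isTRUE(all.equal(mean(nested_ages), mean(original_ages)))
    return(list(t = if (eq) 0 else Inf, df = NA_real_,
                p = if (eq) 1 else 0,
                mean_nested = mean(nested_ages),
                mean_original = mean(original_ages)))
  }
  tt <- stats::t.test(nested_ages, original_ages, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_nested = mean(nested_ages),
       mean_original = mean(original_ages))
}
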