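# Curation and classification: quality filters (RT domain presence, exact
# target site duplications) and superfamily/family assignment, producing the
# curated nested-pair and non-nested element sets.

#' Extract a sub-sequence with nested element insertions removed
#'
#' A feature span (an LTR or protein domain) of an element that hosts nested
#' insertions grows to contain them; the original feature sequence is
#' restored by excising every contained element together with one TSD copy
#' (insertions are substitution-free duplicative events, so removal is
#' exact).
#'
#' @param genome character scalar.
#' @param start,end feature span.
#' @param elements data.frame of all elements (`id`, `start`, `end`,
#'   `tsd_len`); those lying inside the span are stripped.
#' @param exclude_id element id(s) never stripped (the feature's owner).
#' @return character sub-sequence.
#' @export
extract_feature_seq <- function(genome, start, end, elements = NULL,
                                exclude_id = NULL) {
  if (is.null(elements) || !nrow(elements)) {
    return(substr(genome, start, end))
  }
  inner <- elements[elements$start > start & elements$end < end &
                      !(elements$id %in% exclude_id), , drop = FALSE]
  if (!nrow(inner)) return(substr(genome, start, end))
  k <- ifelse(is.na(inner$tsd_len), 0L, inner$tsd_len)
  iv <- cbind(inner$start, pmin(inner$end + k, end))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  # merge overlapping removal intervals (deeper nests sit inside parents)
  merged <- list(iv[1L, ])
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- merged[[length(merged)]]
    if (iv[i, 1L] <= last[2L] + 1L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], iv[i, 2L]))
    } else merged[[length(merged) + 1L]] <- iv[i, ]
  }
  keep <- character(0)
  cursor <- start
  for (m in merged) {
    if (m[1L] > cursor) keep <- c(keep, substr(genome, cursor, m[1L] - 1L))
    cursor <- m[2L] + 1L
  }
  if (cursor <= end) keep <- c(keep, substr(genome, cursor, end))
  paste(keep, collapse = "")
}

#' Keep only elements with an annotated RT domain
#'
#' The reverse transcriptase domain is the annotation-quality criterion: an
#' element without an RT span is dropped. The number removed is reported via
#' a message and the `n_removed` attribute.
#'
#' @param ann an `ltr_annotation`.
#' @return filtered `ltr_annotation`.
#' @export
require_rt_domain <- function(ann) {
  stopifnot(inherits(ann, "ltr_annotation"))
  has_rt <- ann$elements$id %in%
    ann$regions$element_id[ann$regions$region == "RT"]
  n_removed <- sum(!has_rt)
  if (n_removed) {
    message("require_rt_domain: removed ", n_removed,
            " element(s) lacking an RT domain")
  }
  keep <- ann$elements$id[has_rt]
  out <- ann
  out$elements <- ann$elements[has_rt, , drop = FALSE]
  out$regions <- ann$regions[ann$regions$element_id %in% keep, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

#' Detect a target site duplication at the flanks of an element
#'
#' Checks, longest first, whether the `k` bases immediately 5' of the
#' element exactly equal the `k` bases immediately 3' of it (no mismatches
#' tolerated: TSDs are created as perfect duplications).
#'
#' @param genome character scalar.
#' @param start,end element span (1-based inclusive).
#' @param allowed_k lengths tried, in order (default 6, 5, 4).
#' @return list `k`, `seq`, or `NULL` if none (including contig edges where
#'   no flank word can be inspected).
#' @export
detect_tsd <- function(genome, start, end, allowed_k = c(6L, 5L, 4L)) {
  n <- nchar(genome)
  if (start - min(allowed_k) < 1L || end + min(allowed_k) > n) {
    return(NULL)  # contig edge: no flank to inspect
  }
  for (k in allowed_k) {
    if (start - k < 1L || end + k > n) next
    left <- substr(genome, start - k, start - 1L)
    right <- substr(genome, end + 1L, end + k)
    if (left == right && !grepl("N", left, fixed = TRUE)) {
      return(list(k = as.integer(k), seq = left))
    }
  }
  NULL
}

#' Classify superfamily from protein-domain order
#'
#' Ty3/gypsy places integrase (INT) at the 3' end of pol (after RNaseH);
#' Ty1/copia places it 5' of RT. Elements without enough domains are
#' `unknown`; a contradictory order yields `unknown` with a warning.
#'
#' @param regions data.frame of one element's regions (`region`, `start`) or
#'   a character vector of domain names in positional order.
#' @return `"gypsy"`, `"copia"` or `"unknown"`.
#' @export
classify_superfamily <- function(regions) {
  doms <- if (is.character(regions)) regions else {
    regions$region[order(regions$start)]
  }
  doms <- doms[doms %in% c("GAG", "AP", "RT", "RH", "INT", "CHR")]
  i_int <- match("INT", doms)
  i_rt <- match("RT", doms)
  i_rh <- match("RH", doms)
  gypsy <- !is.na(i_int) && !is.na(i_rh) && i_int > i_rh
  copia <- !is.na(i_int) && !is.na(i_rt) && i_int < i_rt
  if (gypsy && copia) {
    warning("classify_superfamily: contradictory domain order")
    return("unknown")
  }
  if (gypsy) return("gypsy")
  if (copia) return("copia")
  "unknown"
}

#' Classify family by RT-domain similarity against the reference panel
#'
#' Global-alignment identity (stretcher-like scoring, as [ltr_identity()])
#' of the element's RT sequence against each panel family's RT consensus;
#' the best hit is reported when it reaches `min_identity`, ties broken by
#' panel order.
#'
#' @param rt_seq the element's RT-domain sequence.
#' @param panel an [build_family_panel()] panel.
#' @param min_identity minimum percent identity (default 60).
#' @return list `family` (name or `"unknown"`), `identity` (best percent),
#'   `superfamily` of the best family (or `"unknown"`).
#' @export
classify_family <- function(rt_seq, panel, min_identity = 60) {
  if (!length(panel)) stop("classify_family: empty panel")
  stopifnot(nzchar(rt_seq))
  ids <- vapply(panel, function(m) {
    ltr_identity(rt_seq, m$consensus[["RT"]])
  }, 0)
  best <- which.max(ids)
  if (ids[best] >= min_identity) {
    list(family = names(panel)[best], identity = unname(ids[best]),
         superfamily = panel[[best]]$superfamily)
  } else {
    list(family = "unknown", identity = unname(ids[best]),
         superfamily = "unknown")
  }
}

#' Curate an annotation into analysis-ready nested-pair and non-nested sets
#'
#' Pipeline: RT-domain filter, containment pair calling, TSD filter (a
#' pair's original element must carry an exact TSD; for motif analyses the
#' nested element must too), then superfamily/family classification.
#' Per-stage attrition is returned.
#'
#' @param ann an `ltr_annotation` whose elements carry region spans.
#' @param genome character scalar.
#' @param panel reference family panel (`NULL` skips family classification).
#' @param min_family_identity threshold for [classify_family()].
#' @param pair_mode passed to [call_nested_pairs()].
#' @return list with `elements` (curated, with `tsd_len`, `tsd_seq`,
#'   `family_called`, `superfamily_called`, `nesting_depth`), `pairs`
#'   (original has TSD), `motif_pairs` (both have TSDs), `non_nested`
#'   (with-TSD non-nested ids), `attrition` (data.frame stage/count).
#' @export
curate <- function(ann, genome, panel = NULL, min_family_identity = 60,
                   pair_mode = "immediate") {
  stopifnot(inherits(ann, "ltr_annotation"))
  n0 <- nrow(ann$elements)
  ann <- require_rt_domain(ann)
  el <- ann$elements
  el <- el[order(el$id), , drop = FALSE]  # order-stable output

  # TSD detection on the (possibly re-detected) spans
  tsd_len <- rep(NA_integer_, nrow(el))
  tsd_seq <- rep(NA_character_, nrow(el))
  for (i in seq_len(nrow(el))) {
    hit <- detect_tsd(genome, el$start[i], el$end[i])
    if (!is.null(hit)) { tsd_len[i] <- hit$k; tsd_seq[i] <- hit$seq }
  }
  el$tsd_len <- tsd_len
  el$tsd_seq <- tsd_seq

  cn <- call_nested_pairs(el, mode = pair_mode)
  el$nesting_depth <- unname(cn$depth[el$id])
  pairs <- cn$pairs
  n_pairs0 <- nrow(pairs)

  has_tsd <- !is.na(el$tsd_len)
  names(has_tsd) <- el$id
  pairs_tsd <- pairs[has_tsd[pairs$original_id], , drop = FALSE]
  motif_pairs <- pairs_tsd[has_tsd[pairs_tsd$nested_id], , drop = FALSE]
  non_nested <- intersect(cn$non_nested, el$id[has_tsd])

  # classification
  el$superfamily_called <- vapply(el$id, function(id) {
    classify_superfamily(ann$regions[ann$regions$element_id == id, ,
                                     drop = FALSE])
  }, "")
  if (!is.null(panel)) {
    el$family_called <- vapply(seq_len(nrow(el)), function(i) {
      r <- ann$regions[ann$regions$element_id == el$id[i] &
                         ann$regions$region == "RT", , drop = FALSE]
      if (!nrow(r)) return("unknown")
      rt_seq <- extract_feature_seq(genome, r$start[1L], r$end[1L],
                                    elements = el,
                                    exclude_id = el$id[i])
      classify_family(rt_seq, panel, min_family_identity)$family
    }, "")
  } else {
    el$family_called <- NA_character_
  }

  attrition <- data.frame(
    stage = c("input", "rt_filter", "pairs_called", "pairs_original_tsd",
              "pairs_both_tsd", "non_nested_tsd"),
    count = c(n0, nrow(el), n_pairs0, nrow(pairs_tsd), nrow(motif_pairs),
              length(non_nested)),
    stringsAsFactors = FALSE)

  list(elements = el, pairs = pairs_tsd, motif_pairs = motif_pairs,
       non_nested = non_nested, attrition = attrition)
}
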