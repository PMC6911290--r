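# TSD and flanking-sequence motif analysis: 50-bp flank extraction,
# position frequency matrices and information-content profiles (sequence
# logo data), and TSD-length distributions by family.

#' Extract the 50-bp flanks of an element
#'
#' Returns `w` bases on each side of the element, outside both TSD copies
#' (the TSD itself is carried separately). Flanks truncated at contig edges
#' are flagged.
#'
#' @param genome character scalar.
#' @param start,end element span.
#' @param tsd_len TSD length (0 if none called).
#' @param w flank width (default 50).
#' @return list `left`, `right` (character), `truncated` (logical).
#' @export
extract_flanks <- function(genome, start, end, tsd_len = 0L, w = 50L) {
  n <- nchar(genome)
  k <- if (is.na(tsd_len)) 0L else as.integer(tsd_len)
  lstart <- max(1L, start - k - w)
  lend <- start - k - 1L
  rstart <- end + k + 1L
  rend <- min(n, end + k + w)
  left <- if (lend >= lstart) substr(genome, lstart, lend) else ""
  right <- if (rend >= rstart) substr(genome, rstart, rend) else ""
  list(left = left, right = right,
       truncated = nchar(left) < w || nchar(right) < w)
}

#' Build sequence-logo data (PFM + information content) per TSD length
#'
#' Records are grouped by TSD length k; each record contributes an aligned
#' window of the last `flank` left-flank bases, the TSD, and the first
#' `flank` right-flank bases. Information content per column is
#' `2 + sum_b p_b log2 p_b` bits (uniform background; Ns excluded per
#' column, no small-sample correction by default).
#'
#' @param records data.frame with `tsd_seq`, `left_flank`, `right_flank`.
#' @param flank flank bases kept on each side of the TSD stripe (default 10).
#' @param small_sample_correction subtract the Miller-Madow style
#'   `(|A|-1) / (2 ln2 n)` bias term (default `FALSE`).
#' @return named list over k (`"4"`, `"5"`, `"6"` as present); each entry a
#'   list `pfm` (4 x width counts), `ic` (bits per column), `n`,
#'   `tsd_cols` (column indices of the TSD stripe). Empty groups are
#'   skipped with a message.
#' @export
build_logo_data <- function(records, flank = 10L,
                            small_sample_correction = FALSE) {
  stopifnot(all(c("tsd_seq", "left_flank", "right_flank") %in%
                  names(records)))
  ks <- nchar(records$tsd_seq)
  out <- list()
  for (k in sort(unique(ks))) {
    grp <- records[ks == k, , drop = FALSE]
    grp <- grp[nchar(grp$left_flank) >= flank &
                 nchar(grp$right_flank) >= flank, , drop = FALSE]
    if (!nrow(grp)) {
      message("build_logo_data: no usable records for k = ", k)
      next
    }
    windows <- paste0(
      substring(grp$left_flank, nchar(grp$left_flank) - flank + 1L),
      grp$tsd_seq, substring(grp$right_flank, 1L, flank))
    width <- 2L * flank + k
    mat <- matrix(unlist(strsplit(windows, "", fixed = TRUE)),
                  nrow = width)
    pfm <- vapply(seq_len(width), function(j) {
      col <- mat[j, ]
      c(A = sum(col == "A"), C = sum(col == "C"),
        G = sum(col == "G"), T = sum(col == "T"))
    }, integer(4L))
    rownames(pfm) <- c("A", "C", "G", "T")
    ic <- apply(pfm, 2L, function(cnt) {
      tot <- sum(cnt)
      if (tot == 0L) return(0)
      p <- cnt[cnt > 0] / tot
      val <- 2 + sum(p * log2(p))
      if (small_sample_correction) val <- val - 3 / (2 * log(2) * tot)
      max(0, val)
    })
    out[[as.character(k)]] <- list(pfm = pfm, ic = ic, n = nrow(grp),
                                   tsd_cols = (flank + 1L):(flank + k))
  }
  out
}

#' TSD length distributions by family
#'
#' @param records data.frame with `family` and `tsd_len`.
#' @return list `by_family` (row-normalized proportions of each k within a
#'   family) and `by_k` (column-normalized contribution of each family to a
#'   k).
#' @export
tsd_length_distribution <- function(records) {
  stopifnot(all(c("family", "tsd_len") %in% names(records)))
  tab <- table(records$family, records$tsd_len)
  by_family <- prop.table(tab, margin = 1L)
  by_k <- prop.table(tab, margin = 2L)
  list(by_family = by_family, by_k = by_k, counts = tab)
}
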