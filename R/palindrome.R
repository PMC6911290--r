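# Approximate-palindrome analysis of insertion-site windows: maximal stem
# detection by dynamic programming (compiled), composition-preserving
# shuffle controls, and paired t-tests per group with Benjamini-Hochberg
# correction across families.

.encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- -1L
  code
}

#' Extract the 20-bp window around an insertion site
#'
#' @param genome character scalar (a genome without the element, or any
#'   sequence whose coordinate `site` marks the insertion cut).
#' @param site 1-based cut coordinate (the TSD's first base).
#' @param half half-window (default 10 -> 20-bp window including the TSD).
#' @return character window of length `2 * half`, or `NULL` when the site
#'   is closer than `half` to a contig edge.
#' @export
extract_site_window <- function(genome, site, half = 10L) {
  n <- nchar(genome)
  if (site - half < 1L || site + half - 1L > n) return(NULL)
  substr(genome, site - half, site + half - 1L)
}

#' Reconstruct the pre-insertion site window of a planted/detected element
#'
#' Splices the sequence the integrase saw: the bases upstream of the left
#' TSD copy, the TSD itself, and the bases downstream of the right TSD copy,
#' giving a `2 * half` window centred on the cut.
#'
#' @param genome character scalar (element still present).
#' @param start,end element span.
#' @param tsd_len TSD length (required, > 0).
#' @param half half-window (default 10).
#' @return character window of length `2 * half`, or `NULL` near contig
#'   edges.
#' @export
window_from_element <- function(genome, start, end, tsd_len, half = 10L) {
  k <- as.integer(tsd_len)
  stopifnot(k > 0L, half >= k)
  n <- nchar(genome)
  lstart <- start - k - half
  rend <- end + k + (half - k)
  if (lstart < 1L || rend > n) return(NULL)
  paste0(substr(genome, lstart, start - 1L),
         substr(genome, end + k + 1L, rend))
}

#' Maximal approximate palindrome of a sequence
#'
#' Finds the longest stem s such that some inverted-repeat configuration
#' (left arm, loop >= 0, right arm) aligns the right arm to the reverse
#' complement of the left arm with at most `floor(max_error_rate * s)`
#' mismatches plus indels, by dynamic programming of the sequence against
#' its reverse complement. Ties are broken by fewer edits, then leftmost.
#'
#' @param seq character scalar (length >= `2 * min_stem` to be useful).
#' @param min_stem minimum reportable stem (default 3).
#' @param max_error_rate maximum error fraction of the stem (default 1/3;
#'   use 0.3 for the stricter 30% variant).
#' @return `NULL` if no stem reaches `min_stem`, else list `stem`, `edits`,
#'   `left_start`, `left_end`, `right_start`, `right_end`, `loop`
#'   (all 1-based).
#' @export
max_approx_palindrome <- function(seq, min_stem = 3L, max_error_rate = 1 / 3) {
  stopifnot(nchar(seq) >= 1L)
  hit <- max_approx_palindrome_cpp(.encode_dna(seq), as.integer(min_stem),
                                   max_error_rate)
  if (hit$stem == 0L) return(NULL)
  hit
}

#' Stem scores for a set of windows
#'
#' Sequences with no qualifying palindrome score `min_stem - 1` so that
#' paired native/shuffled comparisons remain defined.
#'
#' @param seqs character vector.
#' @inheritParams max_approx_palindrome
#' @return numeric vector of stem scores.
#' @export
palindrome_scores <- function(seqs, min_stem = 3L, max_error_rate = 1 / 3) {
  codes <- lapply(seqs, .encode_dna)
  as.numeric(palindrome_stems_cpp(codes, as.integer(min_stem),
                                  max_error_rate))
}

#' Paired shuffle test of palindrome enrichment per group
#'
#' For every sequence the maximal stem is scored natively and on one
#' base-shuffled counterpart; each group is tested with a paired t-test of
#' native minus shuffled scores. Benjamini-Hochberg adjustment is applied
#' across the family-labelled groups (aggregate groups keep their raw p).
#'
#' @param groups named list of character vectors (window sequences); names
#'   are group labels.
#' @param family_groups labels treated as families for the BH correction
#'   (default: every group).
#' @param n_shuffles shuffles per sequence; scores are averaged when > 1
#'   (default 1, the paired design).
#' @inheritParams max_approx_palindrome
#' @return data.frame `group`, `n`, `mean_native`, `mean_random`, `p_raw`,
#'   `p_adj`, `zero_variance`.
#' @export
paired_shuffle_test <- function(groups, family_groups = names(groups),
                                n_shuffles = 1L, min_stem = 3L,
                                max_error_rate = 1 / 3) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  res <- lapply(names(groups), function(lab) {
    seqs <- groups[[lab]]
    stopifnot(length(seqs) >= 2L)
    native <- palindrome_scores(seqs, min_stem, max_error_rate)
    rand <- rowMeans(vapply(seq_len(n_shuffles), function(i) {
      palindrome_scores(vapply(seqs, shuffle_seq, ""), min_stem,
                        max_error_rate)
    }, numeric(length(seqs))))
    diffs <- native - rand
    zv <- stats::sd(diffs) == 0
    p <- if (zv) 1 else stats::t.test(native, rand, paired = TRUE)$p.value
    data.frame(group = lab, n = length(seqs), mean_native = mean(native),
               mean_random = mean(rand), p_raw = p, zero_variance = zv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- out$p_raw
  fam <- out$group %in% family_groups
  out$p_adj[fam] <- stats::p.adjust(out$p_raw[fam], method = "BH")
  attr(out, "max_error_rate") <- max_error_rate
  attr(out, "min_stem") <- min_stem
  out
}
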