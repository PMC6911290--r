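# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over {A,C,G,T,N}; coordinates are 1-based
# inclusive throughout the package (GFF3 convention).

#' Reverse complement of a DNA string
#'
#' @param x character scalar over the alphabet `{A,C,G,T,N}` (case kept upper).
#' @return character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("AACGT")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Generate a random i.i.d. DNA sequence
#'
#' Bases are drawn independently with the given GC fraction split evenly
#' between G and C (and AT evenly between A and T). Uses the current RNG
#' state; callers seed via [set.seed()] or a config seed.
#'
#' @param n integer length in bp.
#' @param gc GC fraction in `[0,1]` (default 0.38, a typical plant genome).
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.38) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Apply random point substitutions to a sequence
#'
#' Each base is substituted with probability `p`, drawing uniformly among the
#' three alternative bases. Indels are never introduced, so coordinates of
#' sub-features stay exact.
#'
#' @param seq character scalar.
#' @param p per-site substitution probability.
#' @return mutated character scalar of identical length.
#' @export
mutate_seq <- function(seq, p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0 || nchar(seq) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < p & chars != "N")
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      alt <- bases[bases != chars[i]]
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(chars, collapse = "")
}

#' GC fraction of one or more sequences
#'
#' @param seqs character vector of DNA sequences; `N`s are excluded from the
#'   denominator.
#' @return single numeric fraction `(G+C)/(A+C+G+T)` over all input combined.
#' @export
gc_content <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  all <- paste(seqs, collapse = "")
  chars <- strsplit(toupper(all), "", fixed = TRUE)[[1L]]
  n_gc <- sum(chars %in% c("G", "C"))
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L) stop("gc_content: no unambiguous bases in input")
  n_gc / n_acgt
}

#' Compare GC content of a sequence set against a background genome
#'
#' @param element_seqs character vector (e.g. element sequences).
#' @param genome background character scalar.
#' @return difference in percentage points (element set minus genome).
#' @export
gc_compare <- function(element_seqs, genome) {
  100 * (gc_content(element_seqs) - gc_content(genome))
}

#' Shuffle the bases of a sequence
#'
#' Uniform random permutation preserving the exact base multiset; the
#' composition-preserving null used for palindrome and nucleosome controls.
#'
#' @param seq character scalar.
#' @return permuted character scalar.
#' @export
shuffle_seq <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(chars[sample.int(length(chars))], collapse = "")
}

# substring by 1-based inclusive span; clamps nothing, callers check bounds
subseq_chr <- function(seq, start, end) {
  substr(seq, start, end)
}

# derive a stage seed from a master seed; keeps results < 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + as.integer(stage) * 7919L) %% 2147483629L
}
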