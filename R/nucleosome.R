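# Nucleosome occupancy prediction from sequence. The scorer is an explicit
# periodic-dinucleotide Boltzmann model: WW (AA/AT/TA/TT) dinucleotides in
# phase with the ~10-bp helical repeat across a 147-bp footprint lower the
# bending energy, SS (CC/CG/GC/GG) dinucleotides in phase raise it;
# footprint-start probabilities follow a Boltzmann distribution over the
# energies, and occupancy at a base is the probability it is covered by a
# footprint.

#' Nucleosome model parameters
#'
#' @param footprint nucleosome footprint F in bp (default 147).
#' @param period dinucleotide period P in bp (default 10.1).
#' @param amplitude dimensionless energy amplitude A (default 0.2).
#' @return list of class `nucleosome_params`.
#' @export
nucleosome_params <- function(footprint = 147L, period = 10.1,
                              amplitude = 0.2) {
  stopifnot(footprint > 1L, period > 0, amplitude >= 0)
  structure(list(footprint = as.integer(footprint), period = period,
                 amplitude = amplitude), class = "nucleosome_params")
}

#' Per-base nucleosome occupancy landscape of a sequence
#'
#' For each footprint start i the energy is
#' `E(i) = sum_j w(dinucleotide at i+j, j)` with
#' `w = +A cos(2 pi j / P)` for WW, `-A cos(2 pi j / P)` for SS and 0
#' otherwise (j = 0..F-2; N-containing dinucleotides weigh 0). Start
#' probabilities are `p(i) = exp(E(i)) / sum_k exp(E(k))` and occupancy
#' `O(x) = sum_{i <= x < i+F} p(i)`.
#'
#' @param seq character scalar, length >= footprint.
#' @param params a [nucleosome_params()] object.
#' @return list `start_prob` (length `L - F + 1`) and `occupancy`
#'   (length `L`, values in `[0, 1]`).
#' @export
occupancy_landscape <- function(seq, params = nucleosome_params()) {
  L <- nchar(seq)
  Fp <- params$footprint
  if (L < Fp) stop("occupancy_landscape: sequence shorter than footprint")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  w_base <- chars %in% c("A", "T")
  s_base <- chars %in% c("C", "G")
  # dinucleotide class at positions 1..L-1
  x <- integer(L - 1L)
  x[w_base[-L] & w_base[-1L]] <- 1L
  x[s_base[-L] & s_base[-1L]] <- -1L

  nstart <- L - Fp + 1L
  kern <- cos(2 * pi * (0:(Fp - 2L)) / params$period)
  E <- numeric(nstart)
  for (j in seq_along(kern)) {
    E <- E + kern[j] * x[(j - 1L) + seq_len(nstart)]
  }
  E <- params$amplitude * E
  p <- exp(E - max(E))
  p <- p / sum(p)
  cp <- c(0, cumsum(p))
  xs <- seq_len(L)
  occupancy <- cp[pmin(xs, nstart) + 1L] - cp[pmax(0L, xs - Fp) + 1L]
  list(start_prob = p, occupancy = occupancy)
}

#' Average occupancy profile over insertion-site windows
#'
#' Computes the occupancy landscape of each window (all the same length,
#' centred on the insertion cut), optionally after base-shuffling each
#' window (the randomized control), and averages positionwise.
#'
#' @param windows character vector of equal-length windows (e.g. 1124 bp
#'   reconstructions from [window_from_element()]).
#' @param params a [nucleosome_params()] object.
#' @param shuffle shuffle each window first (control profile).
#' @param output `"occupancy"` (default) or `"start_prob"`.
#' @return data.frame `position` (relative to the window centre;
#'   `-w/2 .. w/2 - 1`), `mean` and attribute `n`.
#' @export
average_profile <- function(windows, params = nucleosome_params(),
                            shuffle = FALSE, output = "occupancy") {
  windows <- windows[!vapply(windows, is.null, TRUE)]
  if (!length(windows)) stop("average_profile: no usable windows")
  wlen <- unique(nchar(windows))
  stopifnot(length(wlen) == 1L)
  if (shuffle) windows <- vapply(windows, shuffle_seq, "")
  prof <- vapply(windows, function(w) {
    occupancy_landscape(w, params)[[output]]
  }, numeric(if (output == "occupancy") wlen else {
    wlen - params$footprint + 1L
  }))
  m <- rowMeans(prof)
  pos <- if (output == "occupancy") {
    seq_len(wlen) - (wlen %/% 2L) - 1L
  } else {
    seq_len(wlen - params$footprint + 1L)
  }
  out <- data.frame(position = pos, mean = m)
  attr(out, "n") <- length(windows)
  out
}

#' Occupancy over normalized element coordinates, per group
#'
#' Each element's occupancy landscape is rescaled to `bins` normalized
#' positions and averaged within its group (typically superfamily), giving
#' a body profile comparable across element lengths.
#'
#' @param seq_groups named list of character vectors (element sequences).
#' @param params a [nucleosome_params()] object.
#' @param bins number of normalized bins (default 1000).
#' @return named list of data.frames `bin` (1..bins), `mean`, with
#'   attribute `n`.
#' @export
element_body_profile <- function(seq_groups, params = nucleosome_params(),
                                 bins = 1000L) {
  stopifnot(length(seq_groups) >= 1L)
  lapply(seq_groups, function(seqs) {
    seqs <- seqs[nchar(seqs) >= params$footprint]
    stopifnot(length(seqs) >= 1L)
    mat <- vapply(seqs, function(s) {
      occ <- occupancy_landscape(s, params)$occupancy
      idx <- findInterval(seq_along(occ) / length(occ),
                          seq_len(bins) / bins, left.open = TRUE) + 1L
      idx[idx > bins] <- bins
      as.numeric(tapply(occ, factor(idx, levels = seq_len(bins)), mean))
    }, numeric(bins))
    out <- data.frame(bin = seq_len(bins), mean = rowMeans(mat))
    attr(out, "n") <- length(seqs)
    out
  })
}
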