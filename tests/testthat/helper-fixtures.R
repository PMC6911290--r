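# Shared fixtures and independent oracles for the test suite. Simulations
# are cached per configuration so several test files can reuse one genome.

.fixture_env <- new.env(parent = emptyenv())

# a small three-level-nesting simulation reused across files
fixture_sim <- function(seed = 42L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(genome_length_bp = 120000, n_elements = 25,
                      nesting_fraction = 0.5, age_range_mya = c(0.1, 1.5),
                      rng_seed = seed)
    .fixture_env[[key]] <- plant_genome(cfg)
  }
  .fixture_env[[key]]
}

fixture_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- build_family_panel(seed = 1)
  }
  .fixture_env$panel
}

# --- brute-force approximate-palindrome oracle -----------------------------
# Enumerates every (left arm, right arm) substring configuration and scores
# it with utils::adist edit distance against the reverse complement of the
# left arm; independent of the package's dynamic-programming route.
oracle_max_stem <- function(seq, min_stem = 3L, rate = 1 / 3) {
  n <- nchar(seq)
  if (n < 2L * min_stem) return(0L)
  # arms longer than n / (2 - rate) can never satisfy the error bound
  s_cap <- floor(n / (2 - rate))
  for (s in seq(s_cap, min_stem)) {
    allowed <- floor(rate * s + 1e-9)
    for (i in seq_len(n - s + 1L)) {
      if (i + s > n + 1L) next
      # N never matches anything (adist would treat N == N as equal)
      rcL <- chartr("N", "@", revcomp(substr(seq, i, i + s - 1L)))
      # all right arms starting at or after the left arm's end
      rights <- character(0)
      for (j in seq(i + s, n)) {
        tmax <- min(n - j + 1L, s + allowed)
        tmin <- max(1L, s - allowed)
        if (tmax < tmin) next
        rights <- c(rights,
                    chartr("N", "#", substring(seq, j, j + (tmin:tmax) - 1L)))
      }
      if (s <= allowed) return(s)  # empty right arm allowed by deletion
      if (length(rights) && min(utils::adist(rcL, rights)) <= allowed) {
        return(s)
      }
    }
  }
  0L
}

# --- brute-force containment-forest oracle ---------------------------------
# immediate-host pairing by direct O(n^2) scan over all span pairs
oracle_nested_pairs <- function(spans) {
  n <- nrow(spans)
  out <- NULL
  for (i in seq_len(n)) {
    best <- NA_integer_; best_len <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      if (spans$start[j] <= spans$start[i] && spans$end[j] >= spans$end[i] &&
          !(spans$start[j] == spans$start[i] &&
              spans$end[j] == spans$end[i])) {
        len <- spans$end[j] - spans$start[j]
        if (len < best_len) { best <- j; best_len <- len }
      }
    }
    if (!is.na(best)) {
      out <- rbind(out, data.frame(nested_id = spans$id[i],
                                   original_id = spans$id[best],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# random 20-bp windows at a given GC
random_windows <- function(n, gc = 0.4, len = 20L) {
  vapply(seq_len(n), function(i) random_dna(len, gc), "")
}
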