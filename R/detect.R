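# Structural detection of full-length LTR retrotransposons.
#
# Strategy: exact k-mer seeding of direct repeats, grouping of seed pairs by
# diagonal (substitution-only divergence keeps both LTR copies on one
# diagonal), score-based boundary extension, TSD-guided boundary refinement,
# and global-alignment identity filtering. Elements fragmented by nesting
# are recovered by recursively excising detected elements and re-running the
# search; coordinates are mapped back to the original genome, so a
# fragmented host is reported with its full pre-fragmentation span.

#' Detection parameter set
#'
#' @param min_ltr_len minimum LTR length (bp).
#' @param min_ltr_identity minimum LTR-LTR global identity (percent).
#' @param element_span_bounds allowed full element span (bp), ordered pair.
#' @param tsd_lengths TSD lengths tried longest-first at boundary refinement.
#' @param max_rounds maximum detect-and-excise rounds.
#' @param seed_k exact seed k-mer length.
#' @param min_seeds minimum seed pairs on a shared diagonal.
#' @param max_kmer_occ k-mers occurring more often are skipped as repeats.
#' @param max_ltr_len cap on LTR length during extension.
#' @param boundary_slack TSD search slack around extended boundaries (bp).
#' @return list of class `ltr_detection_params`.
#' @export
detection_params <- function(min_ltr_len = 100L, min_ltr_identity = 80,
                             element_span_bounds = c(1000L, 25000L),
                             tsd_lengths = c(6L, 5L, 4L), max_rounds = 8L,
                             seed_k = 13L, min_seeds = 2L,
                             max_kmer_occ = 64L, max_ltr_len = 2500L,
                             boundary_slack = 8L) {
  stopifnot(min_ltr_len > 0, length(element_span_bounds) == 2L,
            element_span_bounds[1L] <= element_span_bounds[2L],
            min_ltr_identity >= 0, min_ltr_identity <= 100)
  structure(list(min_ltr_len = as.integer(min_ltr_len),
                 min_ltr_identity = min_ltr_identity,
                 element_span_bounds = as.integer(element_span_bounds),
                 tsd_lengths = as.integer(tsd_lengths),
                 max_rounds = as.integer(max_rounds),
                 seed_k = as.integer(seed_k),
                 min_seeds = as.integer(min_seeds),
                 max_kmer_occ = as.integer(max_kmer_occ),
                 max_ltr_len = as.integer(max_ltr_len),
                 boundary_slack = as.integer(boundary_slack)),
            class = "ltr_detection_params")
}

#' Find intact (unfragmented) LTR elements in a genome
#'
#' Returns non-overlapping candidates: pairs of direct repeats at least
#' `min_ltr_len` long and at least `min_ltr_identity` percent identical whose
#' outer span lies within `element_span_bounds`. Overlap conflicts are
#' resolved preferring candidates with an exact flanking TSD, then higher
#' identity, then shorter span.
#'
#' @param genome character scalar over `{A,C,G,T,N}`.
#' @param params a [detection_params()] object.
#' @return data.frame sorted by `start` with columns `start`, `end`,
#'   `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`,
#'   `ltr_identity_pct`, `tsd_len`, `tsd_seq`, `detection_round` (NA here).
#' @export
find_intact_elements <- function(genome, params = detection_params()) {
  n <- nchar(genome)
  empty <- data.frame(start = integer(), end = integer(),
                      ltr5_start = integer(), ltr5_end = integer(),
                      ltr3_start = integer(), ltr3_end = integer(),
                      ltr_identity_pct = numeric(), tsd_len = integer(),
                      tsd_seq = character(), termini_ok = logical(),
                      detection_round = integer(), stringsAsFactors = FALSE)
  if (n < params$element_span_bounds[1L]) return(empty)
  chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  seeds <- .seed_pairs(genome, chars, params)
  if (!nrow(seeds)) return(empty)

  cands <- list()
  for (d in unique(seeds$d)) {
    ps <- sort(seeds$p[seeds$d == d])
    # split diagonal into clusters separated by more than one LTR length
    grp <- cumsum(c(0L, diff(ps) > params$max_ltr_len))
    for (g in unique(grp)) {
      pg <- ps[grp == g]
      if (length(pg) < params$min_seeds) next
      cand <- .extend_candidate(chars, n, pg, d, params, genome)
      if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
    }
  }
  if (!length(cands)) return(empty)
  df <- do.call(rbind, cands)
  df <- unique(df)
  # rank: TSD + canonical termini first, then TSD alone, then identity,
  # then shorter span; greedy conflict resolution where strict containment
  # is allowed (nested elements) but partial overlap is a conflict
  ord <- order(-(as.integer(!is.na(df$tsd_seq)) + as.integer(df$termini_ok)),
               -df$ltr_identity_pct, df$end - df$start)
  df <- df[ord, , drop = FALSE]
  keep_rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    clash <- FALSE
    for (j in keep_rows) {
      sj <- df$start[j]; ej <- df$end[j]
      overlap <- s <= ej && e >= sj
      nested <- (s <= sj && e >= ej) || (sj <= s && ej >= e)
      if (overlap && !nested) { clash <- TRUE; break }
    }
    if (!clash) keep_rows <- c(keep_rows, i)
  }
  df <- df[keep_rows, , drop = FALSE]
  # defer outer candidates that contain a kept candidate that will be
  # excised (canonical termini): the inner element goes first and the then
  # intact outer LTR pair is recovered in a later round. Containers of
  # never-excised repeats are not deferred - they would wait forever.
  if (nrow(df) > 1L) {
    len <- df$end - df$start
    outer <- vapply(seq_len(nrow(df)), function(i) {
      any(df$termini_ok & df$start >= df$start[i] & df$end <= df$end[i] &
            len < len[i])
    }, TRUE)
    df <- df[!outer, , drop = FALSE]
  }
  df$detection_round <- NA_integer_
  df[order(df$start), , drop = FALSE]
}

# exact k-mer seed pairs (p, d): direct-repeat hits grouped later by the
# diagonal offset d = downstream copy start - upstream copy start
.seed_pairs <- function(genome, chars, params) {
  sk <- params$seed_k
  n <- length(chars)
  if (n < 2L * sk) return(data.frame(p = integer(), d = integer()))
  starts <- seq_len(n - sk + 1L)
  km <- substring(genome, starts, starts + sk - 1L)
  isN <- cumsum(chars == "N")
  hasN <- (isN[starts + sk - 1L] - c(0L, isN)[starts]) > 0L
  km <- km[!hasN]; starts <- starts[!hasN]
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  km <- km[dup]; starts <- starts[dup]
  if (!length(starts)) return(data.frame(p = integer(), d = integer()))
  groups <- split(starts, km)
  dmin <- max(300L, params$element_span_bounds[1L] - params$max_ltr_len)
  dmax <- params$element_span_bounds[2L]
  ps <- integer(0); ds <- integer(0)
  for (g in groups) {
    if (length(g) > params$max_kmer_occ) next
    g <- sort(g)
    for (i in seq_len(length(g) - 1L)) {
      dd <- g[(i + 1L):length(g)] - g[i]
      ok <- dd >= dmin & dd <= dmax
      if (any(ok)) { ps <- c(ps, rep(g[i], sum(ok))); ds <- c(ds, dd[ok]) }
    }
  }
  unique(data.frame(p = ps, d = ds))
}

# extend a seed cluster along its diagonal into LTR boundaries, refine with
# a TSD search, and score the LTR pair by global-alignment identity
.extend_candidate <- function(chars, n, pg, d, params, genome) {
  sk <- params$seed_k
  a <- min(pg); b <- max(pg) + sk - 1L
  # leftward extension from a-1 (score +1 match / -2 mismatch, take argmax)
  lo <- max(1L, a - params$max_ltr_len)
  s5 <- a
  if (a > lo) {
    xs <- (a - 1L):lo
    sc <- cumsum(ifelse(chars[xs] == chars[xs + d], 1, -3))
    if (max(sc) >= 0) s5 <- xs[which.max(sc)]
  }
  hi <- min(n - d, b + params$max_ltr_len)
  e5 <- b
  if (b < hi) {
    xs <- (b + 1L):hi
    sc <- cumsum(ifelse(chars[xs] == chars[xs + d], 1, -3))
    if (max(sc) >= 0) e5 <- xs[which.max(sc)]
  }
  if (e5 - s5 + 1L > params$max_ltr_len) return(NULL)
  if (e5 >= s5 + d) return(NULL)  # LTR copies must not overlap

  # boundary refinement: search small boundary shifts (nearest first) for
  # an exact duplicated target word; at equal shift, longer TSDs win. A
  # configuration whose implied LTR termini are the canonical TG...CA (on
  # either copy) outranks a TSD-only one - this separates true LTR pairs
  # from spurious direct repeats between homologous element interiors.
  sl <- params$boundary_slack
  shifts <- (-sl:sl)[order(abs(-sl:sl))]
  grid <- expand.grid(b = shifts, a = shifts)
  grid <- grid[order(abs(grid$a) + abs(grid$b)), , drop = FALSE]
  best <- NULL; fallback <- NULL
  for (r in seq_len(nrow(grid))) {
    aa <- grid$a[r]; bb <- grid$b[r]
    for (k in sort(params$tsd_lengths, decreasing = TRUE)) {
      s5n <- s5 + aa; e3n <- e5 + d + bb
      if (s5n - k < 1L || e3n + k > n) next
      left <- substr(genome, s5n - k, s5n - 1L)
      right <- substr(genome, e3n + 1L, e3n + k)
      if (left == right && !grepl("N", left, fixed = TRUE)) {
        e5n <- e5 + bb; s3n <- s5n + d
        tg <- identical(substr(genome, s5n, s5n + 1L), "TG") ||
          identical(substr(genome, s3n, s3n + 1L), "TG")
        ca <- identical(substr(genome, e5n - 1L, e5n), "CA") ||
          identical(substr(genome, e3n - 1L, e3n), "CA")
        hit <- list(k = k, a = aa, b = bb, seq = left, termini = tg && ca)
        if (hit$termini) { best <- hit; break }
        if (is.null(fallback)) fallback <- hit
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) best <- fallback
  if (!is.null(best)) {
    s5 <- s5 + best$a
    e5 <- e5 + best$b
  }
  s3 <- s5 + d; e3 <- e5 + d
  termini <- (identical(substr(genome, s5, s5 + 1L), "TG") ||
                identical(substr(genome, s3, s3 + 1L), "TG")) &&
    (identical(substr(genome, e5 - 1L, e5), "CA") ||
       identical(substr(genome, e3 - 1L, e3), "CA"))
  ltr_len <- e5 - s5 + 1L
  span <- e3 - s5 + 1L
  if (ltr_len < params$min_ltr_len) return(NULL)
  if (span < params$element_span_bounds[1L] ||
      span > params$element_span_bounds[2L]) return(NULL)
  id <- ltr_identity(substr(genome, s5, e5), substr(genome, s3, e3))
  if (id < params$min_ltr_identity) return(NULL)
  data.frame(start = s5, end = e3, ltr5_start = s5, ltr5_end = e5,
             ltr3_start = s3, ltr3_end = e3, ltr_identity_pct = id,
             tsd_len = if (is.null(best)) NA_integer_ else best$k,
             tsd_seq = if (is.null(best)) NA_character_ else best$seq,
             termini_ok = termini,
             detection_round = NA_integer_, stringsAsFactors = FALSE)
}

#' Excise an element (plus one TSD copy) from a genome
#'
#' Removes `[start, end]` and, when a TSD length is given, the downstream
#' TSD copy `[end+1, end+tsd_len]`, restoring the pre-insertion state for a
#' correctly called element. The returned map converts post-excision
#' coordinates back to input coordinates (bijective on retained bases).
#'
#' @param genome character scalar.
#' @param start,end element span (1-based inclusive).
#' @param tsd_len TSD length to remove downstream, or `NA`/0 for none.
#' @return list `genome` (shorter sequence) and `map` (integer vector;
#'   `map[i]` is the input coordinate of post-excision base `i`).
#' @export
excise <- function(genome, start, end, tsd_len = NA_integer_) {
  n <- nchar(genome)
  k <- if (is.na(tsd_len)) 0L else as.integer(tsd_len)
  stopifnot(start >= 1L, end >= start, end + k <= n)
  keep <- rep(TRUE, n)
  keep[start:(end + k)] <- FALSE
  chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  list(genome = paste(chars[keep], collapse = ""),
       map = which(keep))
}

#' Recursive detect-and-excise over a genome
#'
#' Alternates [find_intact_elements()] and excision until a round yields no
#' new candidate or `max_rounds` is reached. All coordinates are reported in
#' the original genome space; an element fragmented by nested insertions is
#' reported with its full pre-fragmentation span via the excision coordinate
#' map. The round in which each element surfaced is recorded
#' (`detection_round`, innermost copies first).
#'
#' @inheritParams find_intact_elements
#' @return data.frame as [find_intact_elements()], plus `detection_round`
#'   and an `id` column, sorted by `start`. A warning is raised if
#'   `max_rounds` was hit with work remaining (result carries attribute
#'   `partial = TRUE`).
#' @export
recursive_detect <- function(genome, params = detection_params()) {
  cur <- genome
  map <- seq_len(nchar(genome))
  out <- list()
  seen <- character(0)  # reported spans in original coordinates
  round <- 1L
  partial <- FALSE
  repeat {
    cands <- find_intact_elements(cur, params)
    if (!nrow(cands)) break
    mapped <- cands
    for (col in c("start", "end", "ltr5_start", "ltr5_end",
                  "ltr3_start", "ltr3_end")) {
      mapped[[col]] <- map[cands[[col]]]
    }
    mapped$detection_round <- round
    key <- paste(mapped$start, mapped$end)
    new_rows <- !(key %in% seen)
    if (any(new_rows)) {
      out[[length(out) + 1L]] <- mapped[new_rows, , drop = FALSE]
      seen <- c(seen, key[new_rows])
    }
    # only candidates with canonical LTR termini are excised: spurious
    # direct repeats (e.g. fragments of an LTR split by a nested insertion
    # pairing with the intact copy) must not delete real sequence
    exc <- which(cands$termini_ok)
    if (!length(exc)) break
    if (round >= params$max_rounds) {
      keep <- rep(TRUE, nchar(cur))
      for (i in exc) {
        k <- if (is.na(cands$tsd_len[i])) 0L else cands$tsd_len[i]
        keep[cands$start[i]:min(cands$end[i] + k, nchar(cur))] <- FALSE
      }
      cur2 <- paste(strsplit(cur, "", fixed = TRUE)[[1L]][keep],
                    collapse = "")
      if (nrow(find_intact_elements(cur2, params))) {
        warning("recursive_detect: max_rounds reached with work remaining; ",
                "partial result")
        partial <- TRUE
      }
      break
    }
    keep <- rep(TRUE, nchar(cur))
    for (i in exc) {
      k <- if (is.na(cands$tsd_len[i])) 0L else cands$tsd_len[i]
      keep[cands$start[i]:min(cands$end[i] + k, nchar(cur))] <- FALSE
    }
    cur <- paste(strsplit(cur, "", fixed = TRUE)[[1L]][keep], collapse = "")
    map <- map[keep]
    round <- round + 1L
  }
  if (!length(out)) {
    res <- find_intact_elements("", params)  # empty frame
    res$id <- character(0)
    return(res)
  }
  res <- .resolve_rounds(do.call(rbind, out))
  res <- res[order(res$start), , drop = FALSE]
  res$id <- sprintf("DET%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  attr(res, "partial") <- partial
  res
}

# cross-round conflict resolution: candidates from different rounds may
# overlap (non-excised repeats resurface once their context is repaired).
# Containment between two termini-backed candidates is genuine nesting and
# allowed; any other overlap is a conflict resolved by rank.
.resolve_rounds <- function(df) {
  ord <- order(-(as.integer(!is.na(df$tsd_seq)) + as.integer(df$termini_ok)),
               -df$ltr_identity_pct, df$end - df$start)
  df <- df[ord, , drop = FALSE]
  keep_rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    clash <- FALSE
    for (j in keep_rows) {
      sj <- df$start[j]; ej <- df$end[j]
      if (s > ej || e < sj) next
      nested <- (s <= sj && e >= ej) || (sj <= s && ej >= e)
      if (!nested || !(df$termini_ok[i] && df$termini_ok[j])) {
        clash <- TRUE; break
      }
    }
    if (!clash) keep_rows <- c(keep_rows, i)
  }
  df[keep_rows, , drop = FALSE]
}

#' Call nested pairs by span containment
#'
#' An element strictly contained in another is paired with its immediate
#' (smallest containing) host; a chain A > B > C yields pairs (B,A) and
#' (C,B), never (C,A). Elements contained in nothing are non-nested.
#'
#' @param elements data.frame with `id`, `start`, `end`.
#' @param mode `"immediate"` (default) pairs every nested element with its
#'   immediate host; `"first_level_only"` keeps only depth-1 pairs (deeper
#'   levels dropped entirely).
#' @return list with `pairs` (data.frame `nested_id`, `original_id`,
#'   `insertion_offset` 1-based bp of the nested start within the original,
#'   `depth`), `depth` (named integer per element; 0 = non-nested) and
#'   `non_nested` (character ids).
#' @export
call_nested_pairs <- function(elements, mode = c("immediate",
                                                 "first_level_only")) {
  mode <- match.arg(mode)
  n <- nrow(elements)
  if (n == 0L) {
    return(list(pairs = data.frame(), depth = integer(0),
                non_nested = character(0)))
  }
  s <- elements$start; e <- elements$end; id <- elements$id
  if (anyDuplicated(cbind(s, e))) {
    stop("call_nested_pairs: elements with identical spans")
  }
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cont <- which(s <= s[i] & e >= e[i] & seq_len(n) != i &
                    !(s == s[i] & e == e[i]))
    if (length(cont)) parent[i] <- cont[which.min(e[cont] - s[cont])]
  }
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(parent[j])) { d <- d + 1L; j <- parent[j] }
    depth[i] <- d
  }
  nested <- which(!is.na(parent))
  pairs <- data.frame(
    nested_id = id[nested], original_id = id[parent[nested]],
    insertion_offset = s[nested] - s[parent[nested]] + 1L,
    depth = depth[nested], stringsAsFactors = FALSE)
  if (mode == "first_level_only") {
    pairs <- pairs[pairs$depth == 1L, , drop = FALSE]
  }
  list(pairs = pairs, depth = stats::setNames(depth, id),
       non_nested = id[is.na(parent)])
}
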