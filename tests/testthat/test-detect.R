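# Structural detection: direct-repeat search, excision, recursion, pairing.

test_that("a plain random genome yields no candidates", {
  params <- detection_params()
  for (sd in 1:5) {
    set.seed(sd)
    g <- random_dna(50000, gc = 0.38)
    expect_equal(nrow(find_intact_elements(g, params)), 0L)
  }
  # brute-force diagonal-scan oracle on a smaller genome: no >=100 bp
  # direct repeat at >=80% identity exists, so the empty result is correct
  set.seed(99)
  g <- strsplit(random_dna(6000, gc = 0.38), "")[[1]]
  n <- length(g)
  found <- FALSE
  for (d in seq(300L, n - 150L)) {
    idx <- seq_len(n - d)
    match_vec <- g[idx] == g[idx + d]
    cs <- cumsum(match_vec)
    w <- 100L
    if (length(match_vec) >= w) {
      frac <- (cs[w:length(cs)] - c(0, cs)[1:(length(cs) - w + 1L)]) / w
      if (any(frac >= 0.8)) { found <- TRUE; break }
    }
  }
  expect_false(found)
})

test_that("a single planted young element is recovered exactly", {
  set.seed(10)
  m <- fixture_panel()$Reina
  el <- synthesize_element(m, age_mya = 0)
  host <- random_dna(30000, gc = 0.38)
  cut <- 12000L; k <- 5L
  tsd <- substr(host, cut, cut + k - 1L)
  g <- paste0(substr(host, 1, cut + k - 1L), el$seq,
              substr(host, cut, nchar(host)))
  start <- cut + k
  cand <- find_intact_elements(g, detection_params())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, start)
  expect_equal(cand$end, start + nchar(el$seq) - 1L)
  expect_equal(cand$ltr_identity_pct, 100)
  expect_identical(cand$tsd_seq, tsd)
  expect_true(cand$termini_ok)

  # excision restores the pre-insertion host byte for byte
  ex <- excise(g, cand$start, cand$end, cand$tsd_len)
  expect_identical(ex$genome, host)
  # coordinate map is a bijection on retained bases
  expect_equal(length(ex$map), nchar(ex$genome))
  expect_true(all(diff(ex$map) >= 1L))
  probe <- c(1L, cand$start - 1L, length(ex$map))
  expect_equal(match(ex$map[probe], ex$map), probe)
  # excision without a TSD call removes the element span only
  ex2 <- excise(g, cand$start, cand$end, NA)
  expect_equal(nchar(ex2$genome), nchar(g) - nchar(el$seq))
})

test_that("the identity threshold separates detection from rejection", {
  set.seed(11)
  m <- fixture_panel()$Angela
  # age chosen so pairwise LTR divergence ~ 15% (identity ~ 85-86%)
  el <- synthesize_element(m, age_mya = 0.15 / (2 * 1.3e-8 * 1e6))
  host <- random_dna(25000, gc = 0.38)
  cut <- 9000L; k <- 5L
  g <- paste0(substr(host, 1, cut + k - 1L), el$seq,
              substr(host, cut, nchar(host)))
  # boundary extension keeps the highest-scoring repeat core, so the
  # reported identity can sit a few points above the planted divergence;
  # the thresholds bracket the reported value
  lo <- find_intact_elements(g, detection_params(min_ltr_identity = 80))
  hi <- find_intact_elements(g, detection_params(min_ltr_identity = 95))
  expect_equal(nrow(lo), 1L)
  expect_equal(nrow(hi), 0L)
  expect_lt(lo$ltr_identity_pct, 95)
  expect_gte(lo$ltr_identity_pct, 80)
})

test_that("recursive detection recovers multi-level nests in original coordinates", {
  sim <- fixture_sim()  # contains nesting levels up to 3
  tr <- sim$annotation$elements
  expect_gte(max(tr$nesting_level), 3L)
  det <- recursive_detect(sim$genome, detection_params())
  err <- vapply(seq_len(nrow(tr)), function(i) {
    min(abs(det$start - tr$start[i]) + abs(det$end - tr$end[i]))
  }, 0)
  expect_gte(mean(err <= 2), 0.95)
  # innermost elements surface in earlier rounds than their hosts
  match_det <- vapply(seq_len(nrow(tr)), function(i) {
    which.min(abs(det$start - tr$start[i]) + abs(det$end - tr$end[i]))
  }, 0L)
  ok <- err <= 2
  for (i in which(ok & !is.na(tr$parent_id))) {
    j <- match(tr$parent_id[i], tr$id)
    if (ok[j]) {
      expect_lte(det$detection_round[match_det[i]],
                 det$detection_round[match_det[j]])
    }
  }
  # no two detected elements partially overlap (containment is allowed)
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(nrow(det))) {
      if (i >= j) next
      ov <- det$start[i] <= det$end[j] && det$end[i] >= det$start[j]
      if (ov) {
        nested <- (det$start[i] <= det$start[j] &&
                     det$end[i] >= det$end[j]) ||
          (det$start[j] <= det$start[i] && det$end[j] >= det$end[i])
        expect_true(nested)
      }
    }
  }
})

test_that("recursion terminates immediately on an element-free genome", {
  set.seed(12)
  g <- random_dna(20000, gc = 0.38)
  det <- recursive_detect(g, detection_params())
  expect_equal(nrow(det), 0L)
})

test_that("nested pair calling matches the brute-force containment oracle", {
  # chain: pairs with immediate host only
  toy <- data.frame(id = c("A", "B", "C"),
                    start = c(1L, 100L, 200L), end = c(1000L, 900L, 700L),
                    stringsAsFactors = FALSE)
  res <- call_nested_pairs(toy)
  expect_equal(res$pairs$nested_id, c("B", "C"))
  expect_equal(res$pairs$original_id, c("A", "B"))
  expect_equal(unname(res$depth), c(0L, 1L, 2L))

  disj <- data.frame(id = c("A", "B"), start = c(1L, 2000L),
                     end = c(1000L, 3000L), stringsAsFactors = FALSE)
  expect_equal(nrow(call_nested_pairs(disj)$pairs), 0L)
  expect_setequal(call_nested_pairs(disj)$non_nested, c("A", "B"))

  two <- data.frame(id = c("H", "X", "Y"), start = c(1L, 100L, 500L),
                    end = c(1000L, 200L, 600L), stringsAsFactors = FALSE)
  p2 <- call_nested_pairs(two)$pairs
  expect_equal(nrow(p2), 2L)
  expect_true(all(p2$original_id == "H"))

  dup <- data.frame(id = c("A", "B"), start = c(1L, 1L), end = c(10L, 10L))
  expect_error(call_nested_pairs(dup), "identical spans")

  # property: equals O(n^2) oracle on random non-partially-overlapping sets
  set.seed(13)
  for (rep in 1:20) {
    spans <- data.frame(id = "R1", start = 1L, end = 10000L,
                        stringsAsFactors = FALSE)
    for (i in 2:12) {
      host <- spans[sample.int(nrow(spans), 1L), ]
      w <- host$end - host$start
      if (w < 40L) next
      s <- host$start + sample.int(w %/% 2L, 1L)
      e <- s + sample.int(max(1L, (host$end - s) %/% 2L), 1L)
      if (any(spans$start == s & spans$end == e)) next
      spans <- rbind(spans, data.frame(id = paste0("R", i), start = s,
                                       end = e, stringsAsFactors = FALSE))
    }
    got <- call_nested_pairs(spans)$pairs
    want <- oracle_nested_pairs(spans)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      got <- got[order(got$nested_id), c("nested_id", "original_id")]
      want <- want[order(want$nested_id), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }

  # first-level-only mode drops deeper pairs entirely
  res1 <- call_nested_pairs(toy, mode = "first_level_only")
  expect_equal(res1$pairs$nested_id, "B")
})
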