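# Region-preference statistics, autoinsertion matrix, enrichment test.

test_that("expected counts follow the length-normalized formula exactly", {
  schema <- data.frame(region = c("A", "3UTR", "B"),
                       mean_len = c(6000L, 1000L, 3000L))
  E <- expected_counts(schema, 50)
  expect_equal(unname(E["3UTR"]), 5.0)
  expect_equal(sum(E), 50)
  expect_equal(unname(expected_counts(schema, 0)), c(0, 0, 0))
  # conservation holds exactly for arbitrary schemas
  set.seed(30)
  for (i in 1:25) {
    sch <- data.frame(region = paste0("r", 1:8),
                      mean_len = sample.int(5000L, 8))
    N <- sample.int(3000L, 1)
    expect_lt(abs(sum(expected_counts(sch, N)) - N), 1e-9 * N)
  }
  expect_error(expected_counts(data.frame(region = "A", mean_len = 0), 5),
               "invalid schema")
})

test_that("the goodness-of-fit test reproduces hand-computed statistics", {
  O <- c(a = 10, b = 10); E <- c(a = 10, b = 10)
  r0 <- gof_test(O, E, pool_min = 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_global, 1)
  expect_false(any(r0$table$significant))

  # hand arithmetic: O=(16,4), E=(10,10) -> X2 = 3.6 + 3.6 = 7.2, df 1
  r1 <- gof_test(c(x = 16, y = 4), c(x = 10, y = 10), pool_min = 0)
  expect_equal(r1$statistic, 7.2)
  expect_equal(r1$df, 1L)

  # BH adjustment equals the textbook step-up on the follow-up p-values
  praw <- r1$table$p_raw
  m <- length(praw)
  o <- order(praw, decreasing = TRUE)
  manual <- pmin(1, cummin(praw[o] * m / (m:1)))[order(o)]
  expect_equal(r1$table$p_adj, manual)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.9), "BH"),
               c(0.03, 0.03, 0.9))

  # regions with expectation below 1 are pooled before testing
  rp <- gof_test(c(a = 30, b = 1, c = 29), c(a = 30, b = 0.5, c = 29.5))
  expect_equal(nrow(rp$table), 2L)
  expect_true(any(grepl("\\+", rp$table$region)))
  expect_error(gof_test(c(a = 1), c(b = 1)), "same regions")
})

test_that("autoinsertion matrix counts and fractions are conserved", {
  el <- data.frame(id = sprintf("E%d", 1:6),
                   family = c("Tekay", "Tekay", "Ogre", "Ogre", "Ale", "Ale"),
                   stringsAsFactors = FALSE)
  pairs <- data.frame(nested_id = c("E1", "E3", "E5"),
                      original_id = c("E2", "E4", "E2"),
                      stringsAsFactors = FALSE)
  am <- autoinsertion_matrix(pairs, el)
  expect_equal(sum(am$matrix), nrow(pairs))
  expect_equal(am$matrix["Tekay", "Tekay"], 1L)
  expect_equal(am$matrix["Ogre", "Ogre"], 1L)
  expect_equal(am$matrix["Ale", "Tekay"], 1L)
  expect_equal(unname(am$autoinsertion_fraction["Ale"]), 0)
  # all-same-family pairs give a purely diagonal matrix, fractions 1
  pairs2 <- data.frame(nested_id = c("E1", "E2"), original_id = c("E2", "E1"))
  am2 <- autoinsertion_matrix(pairs2, el[el$family == "Tekay", ])
  expect_equal(sum(am2$matrix) - sum(diag(am2$matrix)), 0L)
  expect_equal(unname(am2$autoinsertion_fraction["Tekay"]), 1)

  # binomial recovery of a planted autoinsertion probability
  set.seed(31)
  n <- 1000; p_auto <- 0.5
  fams <- c("Tekay", "Ogre", "Ale")
  nested_fam <- rep("Tekay", n)
  orig_fam <- ifelse(stats::runif(n) < p_auto, "Tekay",
                     sample(c("Ogre", "Ale"), n, replace = TRUE))
  elx <- data.frame(id = sprintf("N%d", 1:(2 * n)),
                    family = c(nested_fam, orig_fam),
                    stringsAsFactors = FALSE)
  px <- data.frame(nested_id = sprintf("N%d", 1:n),
                   original_id = sprintf("N%d", (n + 1):(2 * n)))
  amx <- autoinsertion_matrix(px, elx)
  ci <- stats::qnorm(0.995) * sqrt(p_auto * (1 - p_auto) / n)
  expect_lt(abs(amx$autoinsertion_fraction["Tekay"] - p_auto), ci)
})

test_that("superfamily enrichment matches the Pearson formula on printed counts", {
  # the study's gypsy/copia counts among nested and non-nested elements
  tab <- rbind(c(2407, 353), c(8635, 5348))
  res <- superfamily_enrichment(tab[1, ], tab[2, ])
  # independent oracle: Pearson chi-square computed from first principles
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  expect_equal(res$statistic, stat)
  expect_gt(res$statistic, 600)
  expect_lt(res$p, 2.2e-16)
  expect_equal(res$df, 1)

  flat <- superfamily_enrichment(c(10, 10), c(10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # invariance under swapping both rows and both columns
  sw <- superfamily_enrichment(rev(tab[2, ]), rev(tab[1, ]))
  expect_equal(sw$statistic, res$statistic)
  expect_error(superfamily_enrichment(c(0, 0), c(1, 1)), "marginal")
})

test_that("recent/old split uses the delta thresholds with a gap between", {
  pairs <- data.frame(nested_id = 1:5, original_id = 6:10,
                      identity_delta = c(0.5, 5.0, 3.0, 1.0, -0.2))
  sp <- recent_old_split(pairs)
  expect_setequal(sp$recent$identity_delta, c(0.5, 1.0))
  expect_equal(sp$old$identity_delta, 5.0)
  expect_false(3.0 %in% c(sp$recent$identity_delta, sp$old$identity_delta))
})

test_that("offsets map to regions with half-open boundary semantics", {
  tiling <- data.frame(region = c("GAG", "GAG-AP", "AP"),
                       start = c(1L, 101L, 151L), end = c(100L, 150L, 400L))
  expect_equal(assign_region(50L, tiling), "GAG")
  expect_equal(assign_region(101L, tiling), "GAG-AP")  # boundary: downstream
  expect_equal(assign_region(100L, tiling), "GAG")
  expect_warning(r <- assign_region(500L, tiling), "gap")
  expect_equal(r, "AP")
})

test_that("planted region preferences are recovered across replicates", {
  # weights from the study conditions: 3'UTR and RT-RH hot, LTRs/INT cold
  w <- c("3UTR" = 4, "RT-RH" = 3, "GAG-AP" = 2, "5UTR" = 2,
         "LTR5" = 0.3, "LTR3" = 0.3, "INT" = 0.3)
  m <- fixture_panel()$Tekay
  sch <- family_schema(m)
  set.seed(32)
  hits <- logical(20)
  for (r in 1:20) {
    off <- sample_nested_offsets(m, weights = w, n = 2000)
    O <- table(factor(off$region, levels = sch$region))
    Ov <- stats::setNames(as.numeric(O), names(O))
    E <- expected_counts(sch, sum(Ov))
    g <- gof_test(Ov, E)
    tab <- g$table
    over_3utr <- tab$significant[tab$region == "3UTR"] &&
      tab$direction[tab$region == "3UTR"] == "over"
    under_ltr <- all(tab$significant[grepl("LTR", tab$region)] &
                       tab$direction[grepl("LTR", tab$region)] == "under")
    hits[r] <- over_3utr && under_ltr
  }
  expect_gte(sum(hits), 19L)
})

test_that("the global test is calibrated under the length-proportional null", {
  m <- fixture_panel()$Retand
  sch <- family_schema(m)
  set.seed(33)
  p <- replicate(200, {
    off <- sample_nested_offsets(m, weights = NULL, n = 400)
    O <- stats::setNames(as.numeric(table(factor(off$region,
                                                 levels = sch$region))),
                         sch$region)
    E <- expected_counts(sch, sum(O))
    gof_test(O, E)$p_global
  })
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})
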