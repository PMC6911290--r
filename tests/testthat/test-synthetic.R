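# The synthetic-genome module: family panel, element synthesis, planting.

test_that("family panel has 18 families with superfamily-specific layouts", {
  panel <- fixture_panel()
  expect_length(panel, 18L)
  sf <- vapply(panel, `[[`, "", "superfamily")
  expect_equal(sum(sf == "gypsy"), 9L)
  expect_equal(sum(sf == "copia"), 9L)
  for (m in panel) {
    regs <- m$layout$region
    expect_true(all(m$layout$mean_len > 0))
    if (m$superfamily == "gypsy") {
      expect_true(match("INT", regs) > match("RH", regs))
    } else {
      expect_true(match("INT", regs) < match("RT", regs))
    }
    expect_equal(sum(m$tsd_length_probs), 1)
    # canonical LTR termini
    ltr <- m$consensus$LTR
    expect_equal(substr(ltr, 1, 2), "TG")
    expect_equal(substr(ltr, nchar(ltr) - 1, nchar(ltr)), "CA")
  }
  expect_identical(build_family_panel(seed = 7), build_family_panel(seed = 7))
})

test_that("synthesized elements have exact region tables and LTR behaviour", {
  set.seed(1)
  m <- fixture_panel()$Tekay
  el0 <- synthesize_element(m, age_mya = 0)
  r <- el0$regions
  l5 <- r[r$region == "LTR5", ]; l3 <- r[r$region == "LTR3", ]
  expect_identical(substr(el0$seq, l5$start, l5$end),
                   substr(el0$seq, l3$start, l3$end))
  expect_equal(nchar(el0$seq), max(r$end))
  expect_equal(sum(r$end - r$start + 1L), nchar(el0$seq))
  expect_error(synthesize_element(m, age_mya = -1), "age")
})

test_that("realized LTR divergence matches the binomial expectation", {
  # expected pairwise divergence 2*mu*age*1e6 = 0.026 at age 1 Mya;
  # direct base-comparison oracle (no alignment), 200 replicates
  set.seed(2)
  m <- fixture_panel()$Ogre
  mu <- 1.3e-8
  divs <- replicate(200, {
    el <- synthesize_element(m, age_mya = 1, mu = mu)
    r <- el$regions
    a <- strsplit(substr(el$seq, r$start[r$region == "LTR5"],
                         r$end[r$region == "LTR5"]), "")[[1]]
    b <- strsplit(substr(el$seq, r$start[r$region == "LTR3"],
                         r$end[r$region == "LTR3"]), "")[[1]]
    mean(a != b)
  })
  expected <- 2 * mu * 1 * 1e6
  n_sites <- 200 * mean(fixture_panel()$Ogre$layout$mean_len[1])
  se <- sqrt(expected * (1 - expected) / n_sites)
  expect_lt(abs(mean(divs) - expected), 3 * se + 0.001)
})

test_that("plant_genome honours nesting fraction, weights and determinism", {
  cfg0 <- sim_config(genome_length_bp = 60000, n_elements = 8,
                     nesting_fraction = 0, rng_seed = 3)
  sim0 <- plant_genome(cfg0)
  expect_equal(nrow(sim0$pairs), 0L)
  expect_true(all(sim0$annotation$elements$nesting_level == 0L))

  # degenerate weights: all mass on the 3'UTR
  w <- c("3UTR" = 1)
  names(w) <- "3UTR"
  cfg1 <- sim_config(genome_length_bp = 80000, n_elements = 14,
                     nesting_fraction = 0.7,
                     region_preference_weights = w * 1e6, rng_seed = 4)
  # unlisted regions weigh 1, so scale the 3UTR weight up enormously
  sim1 <- plant_genome(cfg1)
  expect_gt(nrow(sim1$pairs), 0L)
  expect_true(all(sim1$pairs$region_label == "3UTR"))

  # byte-identical rerun
  cfg2 <- sim_config(genome_length_bp = 50000, n_elements = 6, rng_seed = 5)
  s1 <- plant_genome(cfg2); s2 <- plant_genome(cfg2)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotation$elements, s2$annotation$elements)
})

test_that("planted TSD copies mirror exactly and ages order parent-child", {
  sim <- fixture_sim()
  el <- sim$annotation$elements
  g <- sim$genome
  for (i in seq_len(nrow(el))) {
    k <- el$tsd_len[i]
    left <- substr(g, el$start[i] - k, el$start[i] - 1L)
    right <- substr(g, el$end[i] + 1L, el$end[i] + k)
    expect_identical(left, el$tsd_seq[i])
    expect_identical(left, right)
  }
  age <- stats::setNames(el$age_mya, el$id)
  nested <- el[!is.na(el$parent_id), ]
  expect_true(all(age[nested$id] < age[nested$parent_id]))
  # every nested span strictly inside its parent
  par <- el[match(nested$parent_id, el$id), ]
  expect_true(all(nested$start > par$start & nested$end < par$end))
})

test_that("excising all planted elements newest-first restores the genome", {
  cfg <- sim_config(genome_length_bp = 60000, n_elements = 10,
                    nesting_fraction = 0.5, palindrome_bias = 0,
                    periodicity_bias = 0, tsd_motif_bias = 0, rng_seed = 6)
  sim <- plant_genome(cfg)
  g <- sim$genome
  el <- sim$annotation$elements
  for (i in rev(seq_len(nrow(el)))) {  # reverse planting order = LIFO
    ex <- excise(g, el$start[i], el$end[i], el$tsd_len[i])
    g <- ex$genome
    removed <- el$end[i] + el$tsd_len[i] - el$start[i] + 1L
    after <- el$start > el$end[i]
    contains <- el$start < el$start[i] & el$end > el$end[i]
    el$start[after] <- el$start[after] - removed
    el$end[after | contains] <- el$end[after | contains] - removed
  }
  expect_identical(g, sim$base_genome)
})

test_that("a genome with no room for a cut raises a capacity error", {
  # edge margins leave no legal non-nested cut position at all
  cfg <- sim_config(genome_length_bp = 25, n_elements = 1,
                    nesting_fraction = 0, rng_seed = 7)
  expect_error(plant_genome(cfg), "capacity")
})

test_that("config validation rejects malformed inputs and fills defaults", {
  expect_error(sim_config(genome_length_bp = -5), "genome_length_bp")
  expect_error(sim_config(nesting_fraction = 1.2), "nesting_fraction")
  expect_error(validate_config(list(bogus_field = 1)), "bogus_field")
  cfg <- validate_config(list(rng_seed = 9))
  expect_s3_class(cfg, "ltr_sim_config")
  expect_equal(cfg$mutation_rate_mu, 1.3e-8)
  # JSON round trip
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(genome_length_bp = 50000, rng_seed = 2), tf,
                       auto_unbox = TRUE)
  cfg2 <- validate_config(tf)
  expect_equal(cfg2$genome_length_bp, 50000L)
})
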