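# Curation filters and classification.

test_that("the RT filter keeps exactly the elements with an RT span", {
  el <- data.frame(id = sprintf("E%02d", 1:10), start = (1:10) * 1000L,
                   end = (1:10) * 1000L + 500L, strand = "+",
                   family = NA, superfamily = NA, age_mya = NA,
                   nesting_level = 0L, parent_id = NA, tsd_len = NA,
                   tsd_seq = NA, site = NA, stringsAsFactors = FALSE)
  rg <- data.frame(element_id = sprintf("E%02d", 1:7), region = "RT",
                   start = (1:7) * 1000L + 10L, end = (1:7) * 1000L + 100L,
                   stringsAsFactors = FALSE)
  ann <- structure(list(elements = el, regions = rg, genome_id = "chr1"),
                   class = "ltr_annotation")
  suppressMessages(out <- require_rt_domain(ann))
  expect_equal(nrow(out$elements), 7L)
  expect_equal(attr(out, "n_removed"), 3L)
  suppressMessages(out2 <- require_rt_domain(out))
  expect_equal(out2$elements, out$elements)  # identity on a clean set
})

test_that("TSD detection is exact-match and longest-first", {
  pad <- strrep("C", 30)
  # 5-bp duplication ATGCA; the flanks otherwise differ
  g <- paste0(pad, "ATGCA", "GGGGGGGGGG", "ATGCA", pad)
  res <- detect_tsd(g, start = 36L, end = 45L)
  expect_equal(res$k, 5L)
  expect_equal(res$seq, "ATGCA")
  # 6-bp duplication must be reported as 6, not its 5-bp suffix
  g6 <- paste0(pad, "GATGCA", "GGGGGGGGGG", "GATGCA", pad)
  res6 <- detect_tsd(g6, start = 37L, end = 46L)
  expect_equal(res6$k, 6L)
  # brute-force check over k: no k in 4..6 shares a flank word here
  gx <- paste0(strrep("A", 30), "GGGGGGGGGG", strrep("T", 30))
  expect_null(detect_tsd(gx, start = 31L, end = 40L))
  # contig edge
  edge <- detect_tsd(paste0("AT", strrep("G", 50)), start = 1L, end = 10L)
  expect_null(edge)
})

test_that("superfamily classification follows integrase position", {
  mk <- function(doms) data.frame(region = doms,
                                  start = seq_along(doms) * 100L,
                                  stringsAsFactors = FALSE)
  expect_equal(classify_superfamily(mk(c("GAG", "AP", "RT", "RH", "INT"))),
               "gypsy")
  expect_equal(classify_superfamily(mk(c("GAG", "AP", "INT", "RT", "RH"))),
               "copia")
  expect_equal(classify_superfamily(mk("GAG")), "unknown")
  expect_equal(classify_superfamily(c("GAG", "AP", "RT", "RH", "INT")),
               "gypsy")
})

test_that("family classification by RT similarity is specific", {
  panel <- fixture_panel()
  # panel consensi are mutually distinguishable: pairwise RT identity well
  # below the 60% call threshold margin
  rts <- vapply(panel, function(m) m$consensus$RT, "")
  ids <- outer(seq_along(rts), seq_along(rts), Vectorize(function(i, j) {
    if (i >= j) return(0)
    ltr_identity(substr(rts[i], 1, 300), substr(rts[j], 1, 300))
  }))
  expect_lt(max(ids), 75)

  expect_equal(classify_family(panel$Tekay$consensus$RT, panel)$family,
               "Tekay")
  expect_equal(classify_family(panel$Tekay$consensus$RT, panel)$identity,
               100)
  set.seed(20)
  mut <- mutate_seq(panel$Ogre$consensus$RT, 0.10)
  expect_equal(classify_family(mut, panel)$family, "Ogre")
  rnd <- random_dna(1000, gc = 0.44)
  expect_equal(classify_family(rnd, panel)$family, "unknown")
  expect_error(classify_family("ACGT", list()), "empty panel")
})

test_that("curation recovers planted families and is order-stable", {
  sim <- fixture_sim()
  suppressMessages(cur <- curate(sim$annotation, sim$genome, sim$panel))
  tr <- sim$annotation$elements
  fam_true <- tr$family[match(cur$elements$id, tr$id)]
  expect_gte(mean(cur$elements$family_called == fam_true), 0.99)
  sf_true <- tr$superfamily[match(cur$elements$id, tr$id)]
  expect_equal(cur$elements$superfamily_called, sf_true)
  # freshly planted TSDs are returned exactly for every non-edge element
  expect_true(all(!is.na(cur$elements$tsd_len)))
  expect_identical(cur$elements$tsd_seq,
                   tr$tsd_seq[match(cur$elements$id, tr$id)])
  # order stability: permuting the input elements leaves the output invariant
  ann2 <- sim$annotation
  set.seed(21)
  perm <- sample.int(nrow(ann2$elements))
  ann2$elements <- ann2$elements[perm, ]
  suppressMessages(cur2 <- curate(ann2, sim$genome, sim$panel))
  rownames(cur$elements) <- rownames(cur2$elements) <- NULL
  expect_equal(cur2$elements, cur$elements)
  expect_equal(cur2$pairs[order(cur2$pairs$nested_id), ],
               cur$pairs[order(cur$pairs$nested_id), ],
               ignore_attr = TRUE)
})

test_that("pairs whose original lacks a TSD are dropped in curation", {
  sim <- fixture_sim()
  ann <- sim$annotation
  # strip the TSD of one original by mutating its right flank copy
  orig_id <- sim$pairs$original_id[1]
  el <- ann$elements[ann$elements$id == orig_id, ]
  g <- sim$genome
  flank <- substr(g, el$end + 1L, el$end + el$tsd_len)
  swapped <- chartr("ACGT", "GTAC", flank)
  substr(g, el$end + 1L, el$end + el$tsd_len) <- swapped
  suppressMessages(cur <- curate(ann, g, panel = NULL))
  expect_false(orig_id %in% cur$pairs$original_id)
  suppressMessages(cur0 <- curate(ann, sim$genome, panel = NULL))
  expect_true(orig_id %in% cur0$pairs$original_id)
})
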