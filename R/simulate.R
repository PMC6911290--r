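# Synthetic-genome simulator: plants LTR retrotransposons with target site
# duplications, age-dependent LTR divergence and nesting events into an
# i.i.d. background genome, keeping exact ground truth for every element.
#
# Biological conventions emulated:
#   * insertion duplicates a k-bp target word (k in {4,5,6}) so the element
#     ends up flanked by two identical TSD copies;
#   * the two LTRs of an element are identical at insertion time and then
#     diverge at 2*mu per site per year;
#   * nested elements are always younger than their hosts (elements are
#     planted oldest-first);
#   * nested insertion offsets follow a configurable region-preference
#     distribution over the host's realized region spans.

# default region preference weights (unlisted regions get weight 1):
# hotspots in the 3'UTR, the RT-RH spacer, the GAG-AP spacer and the 5'UTR;
# LTRs and the integrase domain are cold.
DEFAULT_REGION_WEIGHTS <- c(
  "3UTR" = 4, "RT-RH" = 3, "GAG-AP" = 2, "5UTR" = 2,
  "LTR5" = 0.3, "LTR3" = 0.3, "INT" = 0.3
)

#' Simulation configuration
#'
#' Assembles and validates the parameter set driving [plant_genome()].
#' Defaults describe the study conditions the package's analyses are
#' calibrated against: a 38% GC plant-like background, elements at 44% GC, a
#' grass-calibrated substitution rate of 1.3e-8 per site per year, nesting
#' preference concentrated in the 3'UTR / RT-RH / GAG-AP / 5'UTR regions
#' with cold LTRs and integrase, a moderate autoinsertion bias, and weak
#' palindrome but strong nucleosome-periodicity biases at insertion sites.
#'
#' @param genome_length_bp background genome length in bp.
#' @param gc_fraction background GC fraction.
#' @param n_elements number of elements to plant.
#' @param nesting_fraction probability a new element nests into an existing
#'   one (when at least one element is present).
#' @param region_preference_weights named non-negative weights over region
#'   names; regions not listed get weight 1. Sampling picks a host region
#'   with probability proportional to its weight (not its length), then a
#'   uniform position within the region.
#' @param autoinsertion_bias probability that a nested element targets a host
#'   of its own family when one exists; scalar or named per-family vector.
#' @param palindrome_bias probability an insertion site is seeded with a
#'   planted inverted repeat (stem 5-7 bp) flanking the cut.
#' @param periodicity_bias probability a site carries in-phase WW
#'   dinucleotides every 10 bp over 147 bp centred on the cut.
#' @param tsd_motif_bias probability the duplicated target word is rewritten
#'   with the composition bias seen in real TSDs (AT-rich core for 5/6-bp
#'   words, GC-rich core for 4-bp words).
#' @param age_range_mya numeric length-2 range of element ages (Mya).
#' @param mutation_rate_mu substitutions per site per year.
#' @param rng_seed integer master seed.
#' @param families optional character subset of panel families to plant.
#' @return validated list of class `ltr_sim_config`.
#' @export
sim_config <- function(genome_length_bp = 200000,
                       gc_fraction = 0.38,
                       n_elements = 40,
                       nesting_fraction = 0.35,
                       region_preference_weights = DEFAULT_REGION_WEIGHTS,
                       autoinsertion_bias = 0.2,
                       palindrome_bias = 0.3,
                       periodicity_bias = 0.5,
                       tsd_motif_bias = 0.6,
                       age_range_mya = c(0.1, 4),
                       mutation_rate_mu = 1.3e-8,
                       rng_seed = 1L,
                       families = NULL) {
  cfg <- list(genome_length_bp = as.integer(genome_length_bp),
              gc_fraction = gc_fraction, n_elements = as.integer(n_elements),
              nesting_fraction = nesting_fraction,
              region_preference_weights = region_preference_weights,
              autoinsertion_bias = autoinsertion_bias,
              palindrome_bias = palindrome_bias,
              periodicity_bias = periodicity_bias,
              tsd_motif_bias = tsd_motif_bias,
              age_range_mya = as.numeric(age_range_mya),
              mutation_rate_mu = mutation_rate_mu,
              rng_seed = as.integer(rng_seed), families = families)
  validate_config(cfg)
}

#' Validate (and normalize) a simulation configuration
#'
#' Accepts a config list or a path to a JSON document with the same fields;
#' missing fields are filled with [sim_config()] defaults, unknown fields are
#' rejected, and every probability/range constraint is checked with a
#' per-field message.
#'
#' @param config list of class `ltr_sim_config`, a plain named list, or a
#'   path to a JSON file.
#' @return validated `ltr_sim_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$region_preference_weights)) {
      config$region_preference_weights <-
        unlist(config$region_preference_weights)
    }
  }
  stopifnot(is.list(config))
  defaults <- formals(sim_config)
  known <- names(defaults)
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  }
  for (f in known) {
    if (is.null(config[[f]])) config[f] <- list(eval(defaults[[f]]))
  }
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(is.numeric(config$genome_length_bp) && config$genome_length_bp > 0,
      "genome_length_bp must be positive")
  chk(config$gc_fraction >= 0 && config$gc_fraction <= 1,
      "gc_fraction must be in [0,1]")
  chk(config$n_elements >= 0, "n_elements must be >= 0")
  for (p in c("nesting_fraction", "palindrome_bias", "periodicity_bias",
              "tsd_motif_bias")) {
    chk(all(config[[p]] >= 0 & config[[p]] <= 1),
        paste(p, "must be in [0,1]"))
  }
  chk(all(config$autoinsertion_bias >= 0 & config$autoinsertion_bias <= 1),
      "autoinsertion_bias must be in [0,1]")
  w <- config$region_preference_weights
  chk(is.numeric(w) && all(w >= 0) && !is.null(names(w)),
      "region_preference_weights must be a named non-negative vector")
  chk(length(config$age_range_mya) == 2L &&
        all(config$age_range_mya >= 0) && !is.unsorted(config$age_range_mya),
      "age_range_mya must be an ordered non-negative pair")
  chk(config$mutation_rate_mu > 0, "mutation_rate_mu must be > 0")
  config <- config[known]
  names(config) <- known
  config$genome_length_bp <- as.integer(config$genome_length_bp)
  config$n_elements <- as.integer(config$n_elements)
  config$rng_seed <- as.integer(config$rng_seed)
  class(config) <- "ltr_sim_config"
  config
}

# weight of a region under a preference vector (unlisted regions weigh 1)
region_weight <- function(region, weights) {
  ifelse(region %in% names(weights), unname(weights[region]), 1)
}

#' Synthesize one LTR retrotransposon sequence from a family model
#'
#' Realizes region lengths around the model means, copies the consensus per
#' region (the two LTRs start from one shared consensus and realized length),
#' then applies independent point substitutions at `mu * age * 1e6` per site
#' to every region copy. The expected pairwise divergence between the two
#' LTRs is therefore approximately `2 * mu * age * 1e6`, the quantity the
#' dating module inverts. Substitutions only - no indels - so the realized
#' region table is exact.
#'
#' @param model element model from [build_family_panel()].
#' @param age_mya element age in million years (>= 0).
#' @param mu substitution rate per site per year.
#' @return list with `seq` (character), `regions` (data.frame `region`,
#'   `start`, `end`, 1-based relative to the element), `family`,
#'   `superfamily`, `age_mya`.
#' @export
synthesize_element <- function(model, age_mya, mu = 1.3e-8) {
  stopifnot(inherits(model, "ltr_element_model"))
  if (age_mya < 0) stop("age_mya must be >= 0")
  if (mu <= 0) stop("mu must be > 0")
  m <- mu * age_mya * 1e6  # per-copy substitution probability

  lay <- model$layout
  lens <- integer(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    lens[i] <- if (lay$sd[i] == 0) lay$mean_len[i] else {
      max(10L, as.integer(round(stats::rnorm(1L, lay$mean_len[i], lay$sd[i]))))
    }
  }
  # the two LTRs share one realized length and one pre-mutation sequence
  iltr5 <- which(lay$region == "LTR5"); iltr3 <- which(lay$region == "LTR3")
  lens[iltr3] <- lens[iltr5]
  # keep the canonical TG...CA termini whatever the realized length
  cons_ltr <- model$consensus[["LTR"]]
  ltr_base <- paste0("TG",
                     .realize_region(substr(cons_ltr, 3L, nchar(cons_ltr) - 2L),
                                     lens[iltr5] - 4L),
                     "CA")

  seqs <- character(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    r <- lay$region[i]
    base <- if (r %in% c("LTR5", "LTR3")) ltr_base else {
      .realize_region(model$consensus[[r]], lens[i])
    }
    seqs[i] <- mutate_seq(base, m)
  }
  ends <- cumsum(lens)
  regions <- data.frame(region = lay$region,
                        start = ends - lens + 1L, end = ends,
                        stringsAsFactors = FALSE)
  list(seq = paste(seqs, collapse = ""), regions = regions,
       family = model$family, superfamily = model$superfamily,
       age_mya = age_mya)
}

# fit a consensus to a realized length: truncate, or pad with fresh sequence
.realize_region <- function(consensus, len) {
  cl <- nchar(consensus)
  if (len <= cl) return(substr(consensus, 1L, len))
  paste0(consensus, random_dna(len - cl, gc = 0.44))
}

#' Plant LTR retrotransposons into a synthetic genome
#'
#' Generates an i.i.d. background genome, then inserts `n_elements` elements
#' oldest-first. Each insertion duplicates a sampled 4/5/6-bp target word
#' (TSD) at the cut; a nested insertion draws its host region from
#' `region_preference_weights` applied to the host's realized region spans.
#' Optional per-site biases rewrite the pre-insertion sequence: a TSD
#' composition motif, a planted inverted repeat flanking the cut (stem
#' 5-7 bp), and in-phase WW dinucleotides every 10 bp over a 147-bp span.
#' Biased rewrites never touch previously planted elements or their TSDs,
#' and cuts stay at least 10 bp away from every element boundary, so ground
#' truth remains exact.
#'
#' @param config an [sim_config()] object (or list/JSON path accepted by
#'   [validate_config()]).
#' @param panel optional family panel; defaults to
#'   `build_family_panel(seed = config$rng_seed)`.
#' @return object of class `ltr_simulation`: list with `genome` (character),
#'   `base_genome` (background after bias rewrites are excluded only by
#'   element removal; equals the pre-insertion genome when all biases are 0),
#'   `annotation` (an `ltr_annotation`: `elements` + `regions` data.frames),
#'   `pairs` (ground-truth nested pairs with insertion offsets and true
#'   region labels), `sites` (per-element left-TSD start in final
#'   coordinates), `config`, `panel`.
#' @export
plant_genome <- function(config, panel = NULL) {
  config <- validate_config(config)
  set.seed(derive_seed(config$rng_seed, 2L))
  if (is.null(panel)) panel <- build_family_panel(config$rng_seed)
  fams <- if (is.null(config$families)) names(panel) else {
    stopifnot(all(config$families %in% names(panel)))
    config$families
  }

  n <- config$genome_length_bp
  genome <- random_dna(n, config$gc_fraction)
  base_genome <- genome
  protected <- rep(FALSE, n)

  elements <- data.frame()
  regions <- data.frame()
  pairs <- data.frame()
  nelem <- config$n_elements
  if (nelem == 0L) {
    return(.finish_sim(genome, base_genome, elements, regions, pairs,
                       config, panel))
  }

  ages <- sort(stats::runif(nelem, config$age_range_mya[1L],
                            config$age_range_mya[2L]), decreasing = TRUE)
  fam_draw <- sample(fams, nelem, replace = TRUE)

  for (j in seq_len(nelem)) {
    model <- panel[[fam_draw[j]]]
    el <- synthesize_element(model, ages[j], config$mutation_rate_mu)
    L <- nchar(el$seq)
    k <- as.integer(sample(names(model$tsd_length_probs), 1L,
                           prob = model$tsd_length_probs))

    host_id <- NA_character_; region_label <- NA_character_
    cut <- NA_integer_
    want_nested <- nrow(elements) > 0L &&
      stats::runif(1L) < config$nesting_fraction

    if (want_nested) {
      pick <- .pick_nested_site(elements, regions, el$family, k,
                                config$autoinsertion_bias,
                                config$region_preference_weights)
      if (!is.null(pick)) {
        host_id <- pick$host_id; region_label <- pick$region
        cut <- pick$cut
      }
    }
    if (is.na(cut)) {  # non-nested placement
      cut <- .pick_free_site(n0 = nchar(genome), elements, k)
      if (is.na(cut)) {
        stop("genome too short for requested insertions (capacity exceeded)")
      }
      host_id <- NA_character_; region_label <- NA_character_
    }

    # --- site biases rewrite the pre-insertion sequence (free bases only)
    genome <- .apply_site_biases(genome, protected, cut, k, config)

    tsd_seq <- substr(genome, cut, cut + k - 1L)
    host_row <- if (!is.na(host_id)) elements[elements$id == host_id, ] else NULL

    # --- insert: duplicate [cut, cut+k-1], element sits after the left copy
    ipoint <- cut + k  # first base of the element in new coordinates
    genome <- paste0(substr(genome, 1L, cut + k - 1L), el$seq,
                     substr(genome, cut, nchar(genome)))
    shift <- L + k
    protected <- c(protected[seq_len(cut + k - 1L)], rep(TRUE, L),
                   protected[cut:length(protected)])
    protected[cut:(cut + k - 1L)] <- TRUE
    protected[(ipoint + L):(ipoint + L + k - 1L)] <- TRUE

    if (nrow(elements)) {
      elements <- .shift_features(elements, ipoint, shift)
      regions <- .shift_features(regions, ipoint, shift)
    }

    id <- sprintf("TE%03d", j)
    lvl <- if (is.na(host_id)) 0L else host_row$nesting_level + 1L
    elements <- rbind(elements, data.frame(
      id = id, start = ipoint, end = ipoint + L - 1L, strand = "+",
      family = el$family, superfamily = el$superfamily,
      age_mya = ages[j], nesting_level = lvl,
      parent_id = if (is.na(host_id)) NA_character_ else host_id,
      tsd_len = k, tsd_seq = tsd_seq, site = cut,
      stringsAsFactors = FALSE))
    regions <- rbind(regions, data.frame(
      element_id = id, region = el$regions$region,
      start = el$regions$start + ipoint - 1L,
      end = el$regions$end + ipoint - 1L, stringsAsFactors = FALSE))

    if (!is.na(host_id)) {
      pairs <- rbind(pairs, data.frame(
        nested_id = id, original_id = host_id,
        insertion_offset = ipoint - host_row$start + 1L,
        region_label = region_label,
        same_family = el$family == host_row$family,
        stringsAsFactors = FALSE))
    }
  }
  .finish_sim(genome, base_genome, elements, regions, pairs, config, panel)
}

.finish_sim <- function(genome, base_genome, elements, regions, pairs,
                        config, panel) {
  ann <- structure(list(elements = elements, regions = regions,
                        genome_id = "chr1"), class = "ltr_annotation")
  structure(list(genome = genome, base_genome = base_genome,
                 annotation = ann, pairs = pairs,
                 sites = if (nrow(elements)) {
                   data.frame(element_id = elements$id, site = elements$site,
                              tsd_len = elements$tsd_len,
                              stringsAsFactors = FALSE)
                 } else data.frame(),
                 config = config, panel = panel),
            class = "ltr_simulation")
}

# shift start/end columns of a feature table for an insertion of `shift`
# bases beginning at position `ipoint`; features spanning the point grow.
.shift_features <- function(df, ipoint, shift) {
  grow <- df$start < ipoint & df$end >= ipoint
  after <- df$start >= ipoint
  df$start[after] <- df$start[after] + shift
  df$end[after | grow] <- df$end[after | grow] + shift
  if ("site" %in% names(df)) {
    s_after <- df$site >= ipoint
    df$site[s_after] <- df$site[s_after] + shift
  }
  df
}

# choose host + cut for a nested insertion; NULL if no host has room
.pick_nested_site <- function(elements, regions, family, k, auto_bias,
                              weights) {
  bias <- if (!is.null(names(auto_bias)) && family %in% names(auto_bias)) {
    auto_bias[[family]]
  } else auto_bias[[1L]]
  cand <- elements
  if (stats::runif(1L) < bias && any(elements$family == family)) {
    cand <- elements[elements$family == family, ]
  }
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  for (h in seq_len(nrow(cand))) {
    host <- cand[h, ]
    reg <- regions[regions$element_id == host$id, ]
    # positions blocked by other elements (and their TSD zones) inside host
    inner <- elements[elements$id != host$id &
                        elements$start >= host$start &
                        elements$end <= host$end, , drop = FALSE]
    ok_by_region <- vector("list", nrow(reg))
    for (i in seq_len(nrow(reg))) {
      lo <- max(reg$start[i], host$start + 10L)
      hi <- min(reg$end[i] - k, host$end - 10L - k)
      if (hi < lo) next
      pos <- lo:hi
      if (nrow(inner)) {
        for (e in seq_len(nrow(inner))) {
          pos <- pos[pos > inner$end[e] + 10L |
                       pos < inner$start[e] - 10L - k]
        }
      }
      ok_by_region[[i]] <- pos
    }
    navail <- lengths(ok_by_region)
    if (!any(navail > 0L)) next
    w <- region_weight(reg$region, weights) * (navail > 0L)
    if (sum(w) == 0) next
    ri <- sample.int(nrow(reg), 1L, prob = w)
    pos <- ok_by_region[[ri]]
    cut <- if (length(pos) == 1L) pos else pos[sample.int(length(pos), 1L)]
    return(list(host_id = host$id, region = reg$region[ri], cut = cut))
  }
  NULL
}

# choose a cut for a non-nested insertion, outside all element zones
.pick_free_site <- function(n0, elements, k) {
  free <- rep(TRUE, n0)
  free[seq_len(min(n0, 10L + k))] <- FALSE
  if (n0 > 10L + k) free[(n0 - 10L - k):n0] <- FALSE
  if (nrow(elements)) {
    for (e in seq_len(nrow(elements))) {
      lo <- max(1L, elements$start[e] - 10L - k - elements$tsd_len[e])
      hi <- min(n0, elements$end[e] + 10L + elements$tsd_len[e])
      free[lo:hi] <- FALSE
    }
  }
  pos <- which(free)
  if (!length(pos)) return(NA_integer_)
  pos[sample.int(length(pos), 1L)]
}

# rewrite bases around a cut according to the configured site biases;
# positions inside previously planted elements/TSDs are never touched.
.apply_site_biases <- function(genome, protected, cut, k, config) {
  writes <- list()
  if (stats::runif(1L) < config$tsd_motif_bias) {
    writes <- c(writes, list(list(pos = cut:(cut + k - 1L),
                                  chars = .tsd_motif_word(k))))
  }
  if (stats::runif(1L) < config$palindrome_bias) {
    s <- sample(5:7, 1L)
    arm <- strsplit(random_dna(s, 0.44), "")[[1L]]
    writes <- c(writes,
                list(list(pos = (cut - s):(cut - 1L), chars = arm),
                     list(pos = (cut + k):(cut + k + s - 1L),
                          chars = rev(chartr("ACGT", "TGCA", arm)))))
  }
  if (stats::runif(1L) < config$periodicity_bias) {
    centre <- cut + k %/% 2L
    ww <- c("AA", "AT", "TA", "TT")
    for (j in 0:14) {
      p0 <- centre - 73L + 10L * j
      writes <- c(writes, list(list(
        pos = p0:(p0 + 1L),
        chars = strsplit(ww[sample.int(4L, 1L)], "")[[1L]])))
    }
  }
  if (!length(writes)) return(genome)
  chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  nt <- length(chars)
  for (wr in writes) {
    keep <- wr$pos >= 1L & wr$pos <= nt & !protected[pmin(pmax(wr$pos, 1L), nt)]
    chars[wr$pos[keep]] <- wr$chars[keep]
  }
  paste(chars, collapse = "")
}

# composition-biased TSD words: AT-rich core for 5/6 bp, GC-rich core for 4 bp
.tsd_motif_word <- function(k) {
  at <- c("A", "T"); gcp <- c("G", "C")
  pick <- function(set, n = 1L) sample(set, n, replace = TRUE)
  if (k == 5L) {
    c(pick(c("A", "C", "G")), pick(at, 3L), pick(c("C", "G", "T")))
  } else if (k == 4L) {
    c(pick(at), pick(gcp, 2L), pick(at))
  } else {
    c(pick(c("A", "C", "G")), pick(at, 4L), pick(c("C", "G", "T")))
  }
}

#' Draw nested insertion offsets directly from a family schema
#'
#' Module-scale counterpart of the full simulator: samples insertion offsets
#' within an idealized element (region means from [family_schema()]) with
#' region probability proportional to the preference weight and uniform
#' position within the region. Used to exercise the region-preference
#' statistics without building genomes.
#'
#' @param model an element model.
#' @param weights named region preference weights (unlisted regions weigh 1);
#'   `NULL` means the length-proportional null (uniform per bp).
#' @param n number of offsets.
#' @return data.frame `offset` (1-based bp within the element),
#'   `region` (true label).
#' @export
sample_nested_offsets <- function(model, weights = NULL, n = 1000L) {
  sch <- family_schema(model)
  ends <- cumsum(sch$mean_len)
  starts <- ends - sch$mean_len + 1L
  pw <- if (is.null(weights)) sch$mean_len else {
    region_weight(sch$region, weights) * sch$mean_len /
      sch$mean_len  # weight per region, not per bp
  }
  ri <- sample.int(nrow(sch), n, replace = TRUE, prob = pw)
  off <- starts[ri] + floor(stats::runif(n) * sch$mean_len[ri])
  data.frame(offset = as.integer(off), region = sch$region[ri],
             stringsAsFactors = FALSE)
}

#' @export
print.ltr_simulation <- function(x, ...) {
  cat("ltr_simulation:", nchar(x$genome), "bp genome,",
      nrow(x$annotation$elements), "elements,",
      nrow(x$pairs), "nested pairs\n")
  invisible(x)
}
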