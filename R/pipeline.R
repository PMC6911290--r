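# End-to-end orchestration: simulate -> detect -> curate -> region stats /
# dating / TSD motifs / palindromes / nucleosome profiles, with seeded
# reproducibility, per-stage attrition logging and a JSON summary.

#' Run the full nesting-analysis pipeline on a synthetic genome
#'
#' Simulates a genome from `config`, re-detects the planted elements with
#' the recursive structural detector, transfers region annotations to the
#' detected spans (the external domain-annotator stand-in), curates, and
#' runs every downstream analysis. All tables are written as TSV under
#' `out_dir` together with a `summary.json` of headline numbers and a
#' `manifest.json` (config hash, stage seeds, file list, attrition).
#'
#' @param config an [sim_config()] object, list or JSON path.
#' @param out_dir output directory (created if missing). `NULL` skips all
#'   file output.
#' @param params detection parameters.
#' @param nucleosome nucleosome model parameters.
#' @return (invisibly) list with `simulation`, `detected`, `curated`,
#'   `ages`, `pairs`, `region_tables`, `autoinsertion`, `enrichment`,
#'   `tsd`, `palindrome`, `profiles`, `recovery`, `summary`.
#' @export
run_all <- function(config, out_dir = NULL, params = detection_params(),
                    nucleosome = nucleosome_params()) {
  config <- validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  # --- stage 1: simulate
  sim <- plant_genome(config)
  genome <- sim$genome
  truth <- sim$annotation
  if (!is.null(out_dir)) {
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
    write_gff3(truth, file.path(out_dir, "truth.gff3"))
  }

  # --- stage 2: recursive structural detection
  det <- recursive_detect(genome, params)
  recovery <- .recovery_metrics(det, truth)

  # --- stage 3: transfer region annotation onto detected spans, curate
  ann_det <- .transfer_annotation(det, truth)
  set.seed(derive_seed(config$rng_seed, 3L))
  cur <- curate(ann_det, genome, sim$panel)
  el <- cur$elements

  # --- stage 4: dating and identity deltas
  ages <- date_elements(det[det$id %in% el$id, , drop = FALSE], genome,
                        mu = config$mutation_rate_mu)
  pairs <- identity_delta(cur$pairs, ages)
  age_of <- stats::setNames(ages$insertion_time_mya, ages$element_id)
  age_cmp <- if (nrow(pairs) >= 2L) {
    compare_age_groups(unname(age_of[pairs$nested_id]),
                       unname(age_of[pairs$original_id]))
  } else NULL

  # --- stage 5: region preference (all pairs + recent/old), per superfamily
  sf_of <- stats::setNames(el$superfamily_called, el$id)
  fam_of <- stats::setNames(el$family_called, el$id)
  ann_cls <- ann_det
  ann_cls$elements$superfamily <- sf_of[ann_cls$elements$id]
  ann_cls$elements$family <- fam_of[ann_cls$elements$id]
  splits <- recent_old_split(pairs)
  region_tables <- list()
  for (sf in c("gypsy", "copia")) {
    region_tables[[sf]] <- region_preference(pairs, ann_cls, sim$panel, sf)
    for (cls in c("recent", "old")) {
      sub <- splits[[cls]]
      if (nrow(sub) >= 5L) {
        region_tables[[paste(sf, cls, sep = "_")]] <-
          region_preference(sub, ann_cls, sim$panel, sf)
      }
    }
  }
  for (nm in names(region_tables)) {
    if (!is.null(region_tables[[nm]])) {
      emit(region_tables[[nm]]$table, paste0("regions_", nm, ".tsv"))
    }
  }

  # --- stage 6: autoinsertion matrix and superfamily enrichment
  auto <- autoinsertion_matrix(
    pairs, data.frame(id = el$id, family = el$family_called,
                      stringsAsFactors = FALSE))
  nested_ids <- unique(pairs$nested_id)
  nn_ids <- cur$non_nested
  enrichment <- NULL
  nested_sf <- c(gypsy = sum(sf_of[nested_ids] == "gypsy"),
                 copia = sum(sf_of[nested_ids] == "copia"))
  nn_sf <- c(gypsy = sum(sf_of[nn_ids] == "gypsy"),
             copia = sum(sf_of[nn_ids] == "copia"))
  if (all(nested_sf + nn_sf > 0) && sum(nested_sf) > 0 && sum(nn_sf) > 0) {
    enrichment <- superfamily_enrichment(nested_sf, nn_sf)
  }

  # --- stage 7: TSD motifs, length distribution, GC
  with_tsd <- el[!is.na(el$tsd_len), , drop = FALSE]
  tsd_records <- do.call(rbind, lapply(seq_len(nrow(with_tsd)), function(i) {
    fl <- extract_flanks(genome, with_tsd$start[i], with_tsd$end[i],
                         with_tsd$tsd_len[i])
    data.frame(element_id = with_tsd$id[i], family = with_tsd$family_called[i],
               tsd_len = with_tsd$tsd_len[i], tsd_seq = with_tsd$tsd_seq[i],
               left_flank = fl$left, right_flank = fl$right,
               truncated = fl$truncated, stringsAsFactors = FALSE)
  }))
  tsd <- NULL
  if (!is.null(tsd_records) && nrow(tsd_records)) {
    tsd <- list(records = tsd_records,
                logos = build_logo_data(tsd_records),
                lengths = tsd_length_distribution(tsd_records),
                flank_gc = gc_content(c(tsd_records$left_flank,
                                        tsd_records$right_flank)))
    emit(tsd_records, "tsd_records.tsv")
  }
  el_seqs <- substring(genome, el$start, el$end)
  gc_diff <- gc_compare(el_seqs, genome)

  # --- stage 8: palindromes in 20-bp site windows
  set.seed(derive_seed(config$rng_seed, 8L))
  pal <- NULL
  win20 <- .site_windows(genome, el, half = 10L)
  if (length(win20$ok) >= 4L) {
    grp <- list(ALL = win20$windows)
    isn <- win20$ids %in% nested_ids
    if (sum(isn) >= 2L) grp$nested <- win20$windows[isn]
    if (sum(!isn) >= 2L) grp$non_nested <- win20$windows[!isn]
    fams <- fam_of[win20$ids]
    for (f in unique(fams)) {
      if (!is.na(f) && f != "unknown" && sum(fams == f) >= 5L) {
        grp[[f]] <- win20$windows[fams == f]
      }
    }
    pal <- paired_shuffle_test(grp, family_groups = setdiff(
      names(grp), c("ALL", "nested", "non_nested")))
    emit(pal, "palindrome_summary.tsv")
  }

  # --- stage 9: nucleosome profiles
  set.seed(derive_seed(config$rng_seed, 9L))
  profiles <- NULL
  win_nuc <- .site_windows(genome, el, half = 562L)
  if (length(win_nuc$ok) >= 2L) {
    native <- average_profile(win_nuc$windows, nucleosome)
    control <- average_profile(win_nuc$windows, nucleosome, shuffle = TRUE)
    body <- NULL
    sf_groups <- split(el_seqs, el$superfamily_called)
    sf_groups <- sf_groups[names(sf_groups) %in% c("gypsy", "copia")]
    if (length(sf_groups)) {
      body <- element_body_profile(sf_groups, nucleosome)
    }
    profiles <- list(site_native = native, site_shuffled = control,
                     body = body)
    emit(native, "nucleosome_site_profile.tsv")
    emit(control, "nucleosome_site_profile_shuffled.tsv")
  }

  # --- summary + manifest
  summary <- list(
    genome_length = nchar(genome),
    n_planted = nrow(truth$elements),
    n_detected = nrow(det),
    recovery_pct = recovery$recovered_pct,
    n_curated = nrow(el),
    n_pairs = nrow(pairs),
    n_non_nested = length(nn_ids),
    mean_nested_age = if (nrow(pairs)) mean(age_of[pairs$nested_id]) else NA,
    mean_original_age = if (nrow(pairs)) mean(age_of[pairs$original_id])
      else NA,
    age_ttest_p = if (!is.null(age_cmp)) age_cmp$p else NA,
    gc_diff_points = gc_diff,
    tsd_len_counts = if (!is.null(tsd)) {
      as.list(table(tsd_records$tsd_len))
    } else NULL,
    palindrome = if (!is.null(pal)) {
      pal[pal$group == "ALL", c("mean_native", "mean_random", "p_raw")]
    } else NULL,
    enrichment = enrichment)
  if (!is.null(out_dir)) {
    emit(el[, c("id", "start", "end", "family_called", "superfamily_called",
                "tsd_len", "nesting_depth")], "elements.tsv")
    emit(pairs, "pairs.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    manifest <- list(
      package_version = as.character(utils::packageVersion("ltrnest")),
      config = unclass(config), config_hash = .config_hash(config),
      stage_seeds = list(simulate = derive_seed(config$rng_seed, 2L),
                         curate = derive_seed(config$rng_seed, 3L),
                         palindrome = derive_seed(config$rng_seed, 8L),
                         nucleosome = derive_seed(config$rng_seed, 9L)),
      attrition = cur$attrition,
      files = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(simulation = sim, detected = det, curated = cur,
                 ages = ages, pairs = pairs, region_tables = region_tables,
                 autoinsertion = auto, enrichment = enrichment, tsd = tsd,
                 palindrome = pal, profiles = profiles,
                 recovery = recovery, summary = summary))
}

# match detected spans to ground truth and report recovery
.recovery_metrics <- function(det, truth, tol = 2L) {
  el <- truth$elements
  if (!nrow(el)) {
    return(list(recovered_pct = NA_real_, span_errors = integer(0),
                matched = data.frame()))
  }
  matched <- integer(0)
  errs <- integer(0)
  map <- data.frame()
  for (i in seq_len(nrow(el))) {
    d <- abs(det$start - el$start[i]) + abs(det$end - el$end[i])
    j <- which.min(d)
    if (length(j) && max(abs(det$start[j] - el$start[i]),
                         abs(det$end[j] - el$end[i])) <= tol) {
      matched <- c(matched, i)
      errs <- c(errs, d[j])
      map <- rbind(map, data.frame(truth_id = el$id[i], det_id = det$id[j],
                                   stringsAsFactors = FALSE))
    }
  }
  list(recovered_pct = 100 * length(matched) / nrow(el),
       span_errors = errs, matched = map)
}

# give detected spans the ground-truth sub-annotations of matching planted
# elements (the stand-in for an external protein-domain annotator)
.transfer_annotation <- function(det, truth, tol = 5L) {
  elements <- data.frame(
    id = det$id, start = det$start, end = det$end, strand = "+",
    family = NA_character_, superfamily = NA_character_,
    age_mya = NA_real_, nesting_level = NA_integer_,
    parent_id = NA_character_, tsd_len = det$tsd_len,
    tsd_seq = det$tsd_seq, site = det$start - det$tsd_len,
    detection_round = det$detection_round, stringsAsFactors = FALSE)
  regions <- data.frame()
  tel <- truth$elements
  for (i in seq_len(nrow(det))) {
    if (!nrow(tel)) break
    d <- pmax(abs(tel$start - det$start[i]), abs(tel$end - det$end[i]))
    j <- which.min(d)
    if (d[j] <= tol) {
      rg <- truth$regions[truth$regions$element_id == tel$id[j], ,
                          drop = FALSE]
      if (nrow(rg)) {
        rg$element_id <- det$id[i]
        # clip transferred spans into the detected span
        rg$start <- pmax(rg$start, det$start[i])
        rg$end <- pmin(rg$end, det$end[i])
        regions <- rbind(regions, rg[rg$end >= rg$start, , drop = FALSE])
      }
    }
  }
  structure(list(elements = elements, regions = regions,
                 genome_id = truth$genome_id), class = "ltr_annotation")
}

# pre-insertion 2*half windows for every element with a TSD call
.site_windows <- function(genome, el, half) {
  with_tsd <- el[!is.na(el$tsd_len), , drop = FALSE]
  wins <- list(); ids <- character(0); ok <- integer(0)
  for (i in seq_len(nrow(with_tsd))) {
    w <- window_from_element(genome, with_tsd$start[i], with_tsd$end[i],
                             with_tsd$tsd_len[i], half = half)
    if (!is.null(w)) {
      wins[[length(wins) + 1L]] <- w
      ids <- c(ids, with_tsd$id[i])
      ok <- c(ok, i)
    }
  }
  list(windows = unlist(wins), ids = ids, ok = ok)
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
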