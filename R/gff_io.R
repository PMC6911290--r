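# FASTA and GFF3 interchange. Annotations travel as GFF3 version 3
# (1-based inclusive): LTR_retrotransposon parents with
# long_terminal_repeat, protein_domain (attribute domain=...),
# primer_binding_site, RNA_polypurine_tract and target_site_duplication
# children. Reading goes through rtracklayer; writing is a small formatter
# so the attribute layout is stable across runs.

#' Write a genome sequence as wrapped FASTA
#'
#' @param genome character scalar.
#' @param path output file.
#' @param id sequence name (default `"chr1"`).
#' @export
write_genome_fasta <- function(genome, path, id = "chr1") {
  dss <- Biostrings::DNAStringSet(stats::setNames(genome, id))
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Read the first sequence of a FASTA file
#' @param path FASTA file.
#' @return named character scalar (uppercase).
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(dss[[1L]])), names(dss)[1L])
}

#' Write an element annotation as GFF3
#'
#' Emits one `LTR_retrotransposon` record per element plus child features
#' for LTRs, protein domains, pbs/ppt motifs and both TSD copies. Nested
#' elements carry `Parent=<host id>` in addition to `nesting_level`.
#'
#' @param ann an `ltr_annotation` (as in `plant_genome()$annotation` or
#'   built from detector output).
#' @param path output file.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "ltr_annotation"))
  el <- ann$elements
  rg <- ann$regions
  src <- "ltrnest"
  chrom <- ann$genome_id
  esc <- function(x) gsub("[;=,\t]", "_", x)
  lines <- "##gff-version 3"
  fmt <- function(type, s, e, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, s, e, strand, attrs)
  }
  for (i in seq_len(nrow(el))) {
    x <- el[i, ]
    attrs <- sprintf("ID=%s;family=%s;superfamily=%s;age_mya=%.4f;nesting_level=%d",
                     esc(x$id), esc(x$family), esc(x$superfamily),
                     x$age_mya, x$nesting_level)
    if (!is.na(x$parent_id)) attrs <- paste0(attrs, ";Parent=", esc(x$parent_id))
    if (!is.null(x$detection_round) && !is.na(x$detection_round)) {
      attrs <- paste0(attrs, ";detection_round=", x$detection_round)
    }
    lines <- c(lines, fmt("LTR_retrotransposon", x$start, x$end, x$strand, attrs))
    if (!is.null(rg) && nrow(rg)) {
      sub <- rg[rg$element_id == x$id, , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        r <- sub[j, ]
        type <- switch(r$region,
                       LTR5 = , LTR3 = "long_terminal_repeat",
                       pbs = "primer_binding_site",
                       ppt = "RNA_polypurine_tract",
                       GAG = , AP = , RT = , RH = , INT = , CHR = "protein_domain",
                       NA_character_)
        if (is.na(type)) next  # UTRs/spacers are implied by the gaps
        at <- sprintf("ID=%s_%s;Parent=%s", esc(x$id), r$region, esc(x$id))
        if (type == "protein_domain") at <- paste0(at, ";domain=", r$region)
        if (type == "long_terminal_repeat") at <- paste0(at, ";ltr=", r$region)
        lines <- c(lines, fmt(type, r$start, r$end, x$strand, at))
      }
    }
    if (!is.na(x$tsd_len) && x$tsd_len > 0) {
      lines <- c(lines,
        fmt("target_site_duplication", x$start - x$tsd_len, x$start - 1L,
            x$strand, sprintf("ID=%s_TSD5;Parent=%s", esc(x$id), esc(x$id))),
        fmt("target_site_duplication", x$end + 1L, x$end + x$tsd_len,
            x$strand, sprintf("ID=%s_TSD3;Parent=%s", esc(x$id), esc(x$id))))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an element annotation from GFF3
#'
#' Parses with [rtracklayer::import()] and rebuilds the package's annotation
#' container (elements + named region spans). Interdomain spacers and UTRs,
#' which GFF3 leaves implicit, are reconstructed with
#' [complete_region_tiling()].
#'
#' @param path GFF3 file written by [write_gff3()] (or compatible).
#' @return an `ltr_annotation`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent1 <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p[[1L]]) else NA_character_
  }, "")
  is_el <- df$type == "LTR_retrotransposon"
  el <- df[is_el, , drop = FALSE]
  getnum <- function(x) suppressWarnings(as.numeric(x))
  elements <- data.frame(
    id = as.character(el$ID), start = el$start, end = el$end,
    strand = as.character(el$strand),
    family = if ("family" %in% names(el)) as.character(el$family) else NA,
    superfamily = if ("superfamily" %in% names(el))
      as.character(el$superfamily) else NA,
    age_mya = if ("age_mya" %in% names(el)) getnum(el$age_mya) else NA,
    nesting_level = if ("nesting_level" %in% names(el))
      as.integer(el$nesting_level) else NA,
    parent_id = el$Parent1,
    stringsAsFactors = FALSE)
  elements$strand[elements$strand == "*"] <- "+"

  sub <- df[!is_el, , drop = FALSE]
  regions <- data.frame()
  tsd_len <- rep(NA_integer_, nrow(elements))
  tsd_site <- rep(NA_integer_, nrow(elements))
  if (nrow(sub)) {
    lab <- character(nrow(sub))
    lab[sub$type == "primer_binding_site"] <- "pbs"
    lab[sub$type == "RNA_polypurine_tract"] <- "ppt"
    if ("domain" %in% names(sub)) {
      dd <- sub$type == "protein_domain"
      lab[dd] <- as.character(sub$domain[dd])
    }
    ltr <- which(sub$type == "long_terminal_repeat")
    if (length(ltr)) {
      if ("ltr" %in% names(sub) && !all(is.na(sub$ltr[ltr]))) {
        lab[ltr] <- as.character(sub$ltr[ltr])
      } else {
        # the LTR nearer the element start is the 5' one
        for (id in unique(sub$Parent1[ltr])) {
          ii <- ltr[sub$Parent1[ltr] == id]
          ii <- ii[order(sub$start[ii])]
          lab[ii] <- c("LTR5", rep("LTR3", length(ii) - 1L))
        }
      }
    }
    keep <- lab != "" & sub$type != "target_site_duplication"
    regions <- data.frame(element_id = sub$Parent1[keep], region = lab[keep],
                          start = sub$start[keep], end = sub$end[keep],
                          stringsAsFactors = FALSE)
    tsd <- sub[sub$type == "target_site_duplication", , drop = FALSE]
    if (nrow(tsd)) {
      for (i in seq_len(nrow(elements))) {
        mine <- tsd[tsd$Parent1 == elements$id[i] &
                      tsd$end < elements$start[i], , drop = FALSE]
        if (nrow(mine)) {
          tsd_len[i] <- mine$end[1L] - mine$start[1L] + 1L
          tsd_site[i] <- mine$start[1L]
        }
      }
    }
  }
  elements$tsd_len <- tsd_len
  elements$tsd_seq <- NA_character_
  elements$site <- tsd_site
  if ("detection_round" %in% names(el)) {
    elements$detection_round <- as.integer(el$detection_round)
  }
  structure(list(elements = elements, regions = regions,
                 genome_id = as.character(df$seqnames[1L])),
            class = "ltr_annotation")
}

#' Reconstruct the full region tiling of an element
#'
#' GFF3 carries only named features (LTRs, domains, pbs/ppt); the regions in
#' between are implied. This fills every gap between consecutive named
#' features: after `pbs` comes the `5UTR`, before `ppt` the `3UTR`, and a
#' gap between domains `X` and `Y` is the spacer `X-Y`.
#'
#' @param ann an `ltr_annotation`.
#' @param element_id element whose tiling to build.
#' @return data.frame `region`, `start`, `end` covering the element span.
#' @export
complete_region_tiling <- function(ann, element_id) {
  el <- ann$elements[ann$elements$id == element_id, ]
  stopifnot(nrow(el) == 1L)
  rg <- ann$regions[ann$regions$element_id == element_id, , drop = FALSE]
  rg <- rg[order(rg$start), , drop = FALSE]
  if (!nrow(rg)) return(data.frame(region = "element", start = el$start,
                                   end = el$end, stringsAsFactors = FALSE))
  out <- list()
  cursor <- el$start
  prev <- NA_character_
  for (i in seq_len(nrow(rg))) {
    if (rg$start[i] > cursor) {
      out[[length(out) + 1L]] <- data.frame(
        region = .gap_label(prev, rg$region[i]),
        start = cursor, end = rg$start[i] - 1L, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- rg[i, c("region", "start", "end")]
    cursor <- rg$end[i] + 1L
    prev <- rg$region[i]
  }
  if (cursor <= el$end) {
    out[[length(out) + 1L]] <- data.frame(
      region = .gap_label(prev, NA_character_),
      start = cursor, end = el$end, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.gap_label <- function(prev, nxt) {
  if (!is.na(prev) && prev == "pbs") return("5UTR")
  if (!is.na(nxt) && nxt == "ppt") return("3UTR")
  if (is.na(prev) || prev == "LTR5") return("5UTR")
  if (is.na(nxt) || nxt == "LTR3") return("3UTR")
  paste0(prev, "-", nxt)
}
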