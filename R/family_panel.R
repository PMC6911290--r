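# Bundled reference panel of LTR retrotransposon family models.
#
# Eighteen families are modelled, nine Ty3/gypsy (Athila, CRM, Galadriel,
# Ogre, Phygy, Reina, Retand, Tcn1, Tekay) and nine Ty1/copia (Ale, Angela,
# Bryco, Bianca, Ikeros, Ivana, SIRE, TAR, Tork). A model is a template:
# ordered region layout with mean lengths, a consensus sequence per region,
# and a distribution over target-site-duplication (TSD) lengths {4,5,6}.
# The two superfamilies differ in the position of the integrase (INT) domain
# within pol: gypsy orders GAG-AP-RT-RH-INT(-CHR), copia GAG-AP-INT-RT-RH.

GYPSY_FAMILIES <- c("Athila", "CRM", "Galadriel", "Ogre", "Phygy",
                    "Reina", "Retand", "Tcn1", "Tekay")
COPIA_FAMILIES <- c("Ale", "Angela", "Bryco", "Bianca", "Ikeros",
                    "Ivana", "SIRE", "TAR", "Tork")

# gypsy families modelled with a chromodomain (CHR) after INT
CHR_FAMILIES <- c("Tekay", "CRM", "Tcn1", "Phygy")

# families whose 4-bp TSD is the most common length
TSD4_FAMILIES <- c("Galadriel", "Phygy", "Bryco")
# families with a visible minority of 6-bp TSDs
TSD6_FAMILIES <- c("Ogre", "Tcn1", "Tekay")

#' Build the bundled 18-family reference panel
#'
#' Generates, deterministically for a given seed, one [element
#' model][synthesize_element] per family: region layout (LTR5, primer binding
#' site, 5'UTR, protein domains in superfamily order with interdomain
#' spacers, 3'UTR, polypurine tract, LTR3), per-region consensus sequences at
#' 44% GC, and the family's TSD length distribution. Most families use 5-bp
#' TSDs about 80% of the time; Galadriel, Phygy and Bryco favour 4 bp, and
#' Ogre, Tcn1 and Tekay carry a visible 6-bp minority.
#'
#' @param seed integer seed; the same seed always yields a byte-identical
#'   panel.
#' @return a named list of 18 element models (class `ltr_family_panel`).
#'   Each model is a list with `family`, `superfamily` (`"gypsy"` or
#'   `"copia"`), `layout` (data.frame `region`, `mean_len`, `sd`),
#'   `consensus` (named list of sequences; `LTR` is shared by LTR5/LTR3) and
#'   `tsd_length_probs` (named over `"4","5","6"`, summing to 1).
#' @export
#' @examples
#' panel <- build_family_panel(seed = 1)
#' names(panel)
#' panel$Tekay$layout
build_family_panel <- function(seed = 1L) {
  set.seed(derive_seed(seed, 1L))
  fams <- c(GYPSY_FAMILIES, COPIA_FAMILIES)
  panel <- lapply(fams, function(f) {
    sf <- if (f %in% GYPSY_FAMILIES) "gypsy" else "copia"
    .build_family_model(f, sf)
  })
  names(panel) <- fams
  class(panel) <- "ltr_family_panel"
  panel
}

# one family model; consumes the current RNG stream (seeded by caller)
.build_family_model <- function(family, superfamily) {
  jit <- function(x) round(x * stats::runif(1L, 0.85, 1.15))
  is_gypsy <- superfamily == "gypsy"
  ltr  <- jit(if (is_gypsy) 650 else 420)
  utr5 <- jit(if (is_gypsy) 450 else 350)
  utr3 <- jit(if (is_gypsy) 900 else 500)
  dom <- c(GAG = jit(1200), AP = jit(700), RT = jit(1000),
           RH = jit(550), INT = jit(900), CHR = jit(350))
  sp <- function() jit(150)

  regions <- list(c("LTR5", ltr), c("pbs", 15), c("5UTR", utr5),
                  c("GAG", dom[["GAG"]]))
  if (is_gypsy) {
    regions <- c(regions, list(
      c("GAG-AP", sp()), c("AP", dom[["AP"]]),
      c("AP-RT", sp()),  c("RT", dom[["RT"]]),
      c("RT-RH", sp()),  c("RH", dom[["RH"]]),
      c("RH-INT", sp()), c("INT", dom[["INT"]])))
    if (family %in% CHR_FAMILIES) {
      regions <- c(regions, list(c("INT-CHR", sp()), c("CHR", dom[["CHR"]])))
    }
  } else {
    regions <- c(regions, list(
      c("GAG-AP", sp()),  c("AP", dom[["AP"]]),
      c("AP-INT", sp()),  c("INT", dom[["INT"]]),
      c("INT-RT", sp()),  c("RT", dom[["RT"]]),
      c("RT-RH", sp()),   c("RH", dom[["RH"]])))
  }
  regions <- c(regions, list(c("3UTR", utr3), c("ppt", 15), c("LTR3", ltr)))

  layout <- data.frame(
    region = vapply(regions, `[`, "", 1L),
    mean_len = as.integer(vapply(regions, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  # motif regions have fixed length; others vary a little between copies
  layout$sd <- ifelse(layout$region %in% c("pbs", "ppt"), 0,
                      round(0.03 * layout$mean_len))
  stopifnot(all(layout$mean_len > 0))

  # consensus per region at elevated (44%) GC; LTR5/LTR3 share one consensus
  consensus <- list()
  for (i in seq_len(nrow(layout))) {
    r <- layout$region[i]
    if (r == "LTR3") next
    key <- if (r == "LTR5") "LTR" else r
    consensus[[key]] <- if (key == "LTR") {
      # canonical retroviral LTR termini: 5'-TG ... CA-3'
      paste0("TG", random_dna(layout$mean_len[i] - 4L, gc = 0.44), "CA")
    } else {
      random_dna(layout$mean_len[i], gc = 0.44)
    }
  }

  tsd <- if (family %in% TSD4_FAMILIES) {
    c("4" = 0.60, "5" = 0.35, "6" = 0.05)
  } else if (family %in% TSD6_FAMILIES) {
    c("4" = 0.10, "5" = 0.80, "6" = 0.10)
  } else {
    c("4" = 0.15, "5" = 0.80, "6" = 0.05)
  }

  structure(list(family = family, superfamily = superfamily,
                 layout = layout, consensus = consensus,
                 tsd_length_probs = tsd),
            class = "ltr_element_model")
}

#' Mean region-length schema of a family model
#'
#' Returns the ordered regions with their mean lengths and the element mean
#' length; the length-normalized expectations of the region-preference test
#' are computed from this table.
#'
#' @param model an element model from [build_family_panel()].
#' @return data.frame with columns `region`, `mean_len`, plus attribute
#'   `element_mean_length`.
#' @export
family_schema <- function(model) {
  stopifnot(inherits(model, "ltr_element_model"))
  out <- model$layout[, c("region", "mean_len")]
  attr(out, "element_mean_length") <- sum(out$mean_len)
  out
}

#' @export
print.ltr_family_panel <- function(x, ...) {
  sf <- vapply(x, `[[`, "", "superfamily")
  cat("LTR family panel:", length(x), "families (",
      sum(sf == "gypsy"), "gypsy /", sum(sf == "copia"), "copia )\n")
  invisible(x)
}
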