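---
title: "Methods: simulating and analysing nested LTR retrotransposons"
author: "ltrnest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing nested LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ltrnest` studies *nesting* of long terminal repeat (LTR) retrotransposons:
the insertion of a young element into an older one. The package combines a
synthetic-genome generator with exact ground truth, a structural detector
for full-length and nesting-fragmented elements, curation and
classification filters, and the downstream statistics used to characterise
where elements insert — region preferences within the original element, TSD
sequence motifs, approximate palindromes at insertion sites, and predicted
nucleosome occupancy. Every stage is seeded and reproducible; the generator
is first-class, tested code, not a test fixture.

# The synthetic genome model

## Element templates

Eighteen family models are bundled, nine Ty3/gypsy (Athila, CRM, Galadriel,
Ogre, Phygy, Reina, Retand, Tcn1, Tekay) and nine Ty1/copia (Ale, Angela,
Bryco, Bianca, Ikeros, Ivana, SIRE, TAR, Tork). A model is an ordered region
layout — 5' LTR, primer binding site (pbs), 5'UTR, the protein domains with
interdomain spacers, 3'UTR, polypurine tract (ppt), 3' LTR — with a
consensus sequence per region. The two superfamilies differ in where
integrase sits within *pol*: gypsy orders GAG–AP–RT–RH–INT (with a
chromodomain, CHR, modelled in Tekay, CRM, Tcn1 and Phygy), copia
GAG–AP–INT–RT–RH. LTR consensus sequences carry the canonical `TG ... CA`
termini of retroviral-like LTRs; this biological invariant is also what the
detector uses to tell true LTR pairs from spurious direct repeats (below).

Consensus sequences are generated at 44% GC against a 38% GC background
genome, mirroring the elevated GC of retrotransposons relative to plant
genomes; with the default settings the planted elements run about six
percentage points GC above the background, which is the quantity
`gc_compare()` reports.

Region lengths are realized per element copy around the layout means (3%
standard deviation; motifs fixed), so copies of a family differ slightly in
length while the two LTRs of one element always share a single realized
length and pre-mutation sequence.

## Ages, divergence and dating

Elements are planted oldest-first with ages drawn uniformly from
`age_range_mya` (default 0.1–4 Mya; desk-scale runs in the tests use
0.1–1.5 Mya so that LTR identities stay in the range the detector is
specified for). Each region copy receives independent point substitutions
at `mu * age * 1e6` per site (default `mu` = 1.3e-8 substitutions per site
per year, a common grass calibration; the rate is configurable because
calibrations differ between lineages). Substitutions only — no indels — so
every sub-span coordinate in the ground truth stays exact. The two LTRs
therefore accumulate an expected pairwise divergence of `2 * mu * t`,
and the dating module inverts exactly this relation:
`T = (1 - identity/100) / (2 * mu) / 1e6` Mya. Divergence is the raw
p-distance by default; a Jukes–Cantor option exists but is off, since the
estimator is used on young, weakly diverged pairs where the correction is
negligible relative to its extra variance.

LTR–LTR identity comes from Needleman–Wunsch global alignment with
stretcher-like DNA scoring (match +5, mismatch −4, gap open 16, gap extend
4), counting gap columns in the denominator. Since the simulator introduces
no indels, alignments are effectively diagonal and identity is an unbiased
divergence estimate up to multiple-hit saturation; calibration tests
require the mean estimated age to sit within 10% of truth at 0.5, 1, 2 and
4 Mya (LTR length 1000 bp).

## Insertion mechanics

An insertion duplicates a target word of 4, 5 or 6 bp (the TSD): the word at
the cut is copied so the element ends up flanked by two identical copies.
TSD lengths are drawn per family — most families use 5 bp about 80% of the
time; Galadriel, Phygy and Bryco favour 4 bp; Ogre, Tcn1 and Tekay carry a
6-bp minority — which is the pattern the TSD-length recovery tests check.

A nested insertion chooses its host region with probability proportional to
the configured `region_preference_weights` (default: 3'UTR 4, RT–RH 3,
GAG–AP 2, 5'UTR 2, LTRs and INT 0.3, everything else 1 — hotspots in
untranslated and interdomain sequence, cold regulatory LTRs and integrase),
then a uniform position inside the region. Weights proportional to region
length would make every base equally likely, which is the null the
goodness-of-fit calibration test simulates. With probability
`autoinsertion_bias` (default 0.2) a nested element targets a host of its
own family when one exists.

Three optional site biases rewrite the pre-insertion sequence at the cut:
a composition-biased TSD word (AT-rich core for 5/6-bp words, GC-rich core
for 4-bp words; probability 0.6), a planted inverted repeat with stem 5–7 bp
flanking the cut (probability 0.3 — a weak palindrome preference), and
in-phase WW dinucleotides every 10 bp across 147 bp centred on the cut
(probability 0.5 — a nucleosome-positioning signal). Rewrites never touch
previously planted elements or their TSDs, and cut sites keep 10 bp of
clearance from every element boundary, so ground truth stays exact.

Two deliberate simplifications keep the truth exact and the tests sharp:
elements are planted on the plus strand only, and a sequence stops mutating
once planted (an element's internal divergence reflects its own age; host
sequence is not further mutated after later insertions). Real data violate
both — minus-strand elements are common and hosts keep diverging after
being interrupted — so detector recovery rates measured here are an upper
bound on what identical settings would achieve on real genomes. What the
passing tests do show is that the pipeline's logic (recursion, coordinate
mapping, pairing, filtering, statistics) is correct when its structural
assumptions hold.

# Structural detection

`find_intact_elements()` searches for direct repeats by exact 13-mer
seeding. Because divergence is substitution-only, both copies of an LTR pair
lie on a single diagonal (constant distance `d`), so seed pairs are grouped
by `d`, clustered along the diagonal, and extended outward with a +1/−3
match/mismatch score, taking the score-maximising boundary (score-neutral
extensions are accepted: with ~10% of boundary bases mutated, insisting on
strictly positive evidence systematically truncates boundaries).

Boundaries are then refined by a TSD search: shifts of up to ±8 bp on each
boundary, nearest-first, looking for an exact duplicated 6/5/4-bp word just
outside the implied element. A configuration whose implied LTR termini are
the canonical `TG ... CA` (on either copy, tolerating a mutated terminus on
one) outranks a TSD-only configuration. Candidates are filtered on LTR
length (≥ 100 bp), LTR identity (≥ 80%) and element span (1–25 kb), and
conflicts are resolved greedily in rank order (TSD + termini, then TSD,
then identity, then shorter span), where strict containment — genuine
nesting — is not a conflict but partial overlap is.

Two failure modes shaped this design, both caused by *homologous* spurious
repeats between same-family copies (family copies share a consensus, so
interiors of two nearby copies form long, high-identity direct repeats, and
a nested insertion into an LTR splits it into fragments that still pair
with the intact copy):

* **Excision is gated on canonical termini.** Only candidates with
  `TG ... CA` termini are removed from the working genome during recursion.
  Spurious repeats — which essentially never end on the canonical
  dinucleotides at a register that also matches an exact TSD — are reported
  but never excised, so they cannot delete real LTR sequence out from under
  a host.
* **Outer candidates defer to inner ones.** Within a round, a candidate
  containing another excisable candidate is deferred: the inner element is
  excised first, and the outer LTR pair — now intact — is recovered in a
  later round with its full pre-fragmentation span via the excision
  coordinate map. Containers of never-excisable repeats are not deferred
  (they would wait forever); the cross-round resolution step then keeps the
  termini-backed candidate and discards the spurious one.

`recursive_detect()` iterates detect-and-excise until no excisable
candidate remains (default cap 8 rounds, with a warning if work remains),
reports all coordinates in the original genome space, and records the round
in which each element surfaced (innermost first). On the default study
conditions (120 kb background, 25 elements, nesting fraction 0.5, ages
0.1–1.5 Mya, three nesting levels) the detector recovers planted elements
with ≤ 2 bp span error — the residual ambiguity of a TSD whose flanking
base happens to repeat — at well above the 95% the acceptance suite
requires, with no false positives across the tested seeds.

# Curation and classification

Curation follows the order: RT-domain presence filter → containment pair
calling → TSD filter → classification. TSDs must match exactly: they are
created as perfect duplications, and an exact-match rule (checked longest
first, 6 then 5 then 4, so a 6-bp TSD is never reported as its 5-bp prefix)
keeps the FDR of chance flank matches low. A pair is retained when its
*original* carries a TSD; the motif analyses additionally require the
nested element's TSD, since those analyses read the duplicated word itself.

Pair calling interprets "first level" as *immediate-host pairing*: each
nested element pairs with its smallest container, so a chain A ⊃ B ⊃ C
yields (B, A) and (C, B) but never (C, A). The alternative reading — drop
deeper levels entirely — is available via `mode = "first_level_only"`.

Superfamily is called from domain order (INT after RH → gypsy, INT before
RT → copia). Family is called by aligning the element's RT sequence against
each panel consensus (same scoring as dating) and reporting the best hit at
≥ 60% identity; panel RT consensi are mutually below 75% identity, so the
assignment is unambiguous at the divergences simulated. When a feature span
(RT or LTR) hosts nested insertions, the inserted material (plus one TSD
copy) is excised from the extracted sequence before alignment — without
this, a single nested element inside a host's RT collapses its family call.

# Region-preference statistics

Each pair's insertion offset is mapped to the region of its original
element that contains it (regions tile the element; a boundary base belongs
to the downstream region). Families lacking CHR annotate the region between
INT and ppt as their 3'UTR, so the 3'UTR hotspot aggregates consistently
across families rather than splitting into a separate interdomain label.
Expected counts are length-normalized:
`E_r = (mean region length / mean element length) × N` per family, summed
within a superfamily, so that `ΣE_r = N` exactly.

The test is a global Pearson chi-squared goodness of fit
(`X² = Σ (O_r − E_r)² / E_r`, df = regions − 1) followed by per-region 1-df
region-versus-rest chi-squared tests, Benjamini–Hochberg adjusted, flagged
at adjusted p < 0.05. Regions with expectation below 1 are pooled into the
adjacent smaller-expectation region first (chi-squared validity). Under the
length-proportional null the global p-value is calibrated (the acceptance
suite checks the rejection rate at 0.05 lies in [0.02, 0.09] over 200
replicates), and the planted hotspot/coldspot pattern is recovered in at
least 19 of 20 replicates of 2000 pairs.

The family-by-family matrix counts nested-family × original-family events;
its diagonal divided by row sums gives per-family autoinsertion fractions.
Superfamily enrichment among nested versus non-nested elements is a 2×2
Pearson chi-squared test of independence without continuity correction
(configurable). The recent/old split classifies pairs by the LTR-identity
delta Δ = identity(nested) − identity(original): recent for Δ in [0, 1]
percentage points, old for Δ ≥ 5, with the in-between (and slightly
negative Δ from estimation noise) in neither class.

# TSD motifs

For every curated element with a TSD the package extracts 50-bp flanks
outside both TSD copies and assembles logo windows of the last 10 left-flank
bases + TSD + first 10 right-flank bases, grouped by TSD length. Position
frequency matrices and per-column information content
(`IC = 2 + Σ p log2 p` bits, uniform background, Ns excluded per column,
optional small-sample correction) are the logo data; TSD-length proportions
are reported per family (row-normalized) and per length (column-normalized
family contributions).

# Approximate palindromes

Insertion-site windows are 20 bp centred on the cut, including the TSD; for
a planted or detected element the pre-insertion window is reconstructed by
splicing out the element and one TSD copy. The detector finds the maximal
stem `s` such that some configuration (left arm of length `s`, loop ≥ 0,
right arm) aligns the right arm against the reverse complement of the left
arm with at most `floor(s × rate)` mismatches plus indels (`rate` defaults
to 1/3; the stricter 30% variant is a flag). The dynamic program (compiled
C++) is verified against a brute-force enumeration oracle on hundreds of
random and adversarial windows, including indel-requiring optima and N
handling (N never matches).

The enrichment test is paired by design: each window is scored natively and
after one composition-preserving base shuffle, and each group (family,
nested, non-nested, ALL) gets a paired t-test of the differences;
windows with no qualifying stem score `min_stem − 1` so pairs stay defined,
and zero-variance groups report p = 1 with a flag. BH correction is applied
across family groups only, matching a design in which the family tests are
the multiple-testing family and the aggregates are single pre-specified
comparisons.

A known limitation: this stem definition is generous — the right arm's
length floats freely and deletions are charged like mismatches — so its
absolute random-window baseline (≈ 6.8 at rate 1/3, ≈ 5.9 at 0.30, as the
acceptance script computes) runs higher than published scorers whose
internal constraints (loop limits, symmetric arm handling) are not public.
Paired native-minus-shuffled contrasts, which the analysis actually uses,
are insensitive to this offset: the null calibration test bounds the paired
difference near zero and the planted-stem test recovers the signal.

# Nucleosome occupancy

The external nucleosome predictor used in the original workflow is replaced
by an explicit, fully specified periodic-dinucleotide Boltzmann model — the
single largest substitution in this package, isolated behind
`nucleosome_params()` so an alternative scorer can be plugged in. For each
147-bp footprint start the energy sums `+A cos(2πj/P)` over WW
dinucleotides and `−A cos(2πj/P)` over SS dinucleotides at footprint offset
j (period P = 10.1 bp, amplitude A = 0.2, N-containing dinucleotides weigh
0); start probabilities are the Boltzmann weights normalized over the
window, and occupancy at a base is the summed probability of footprints
covering it. With A = 0 this reduces to the closed-form uniform landscape
(flat interior `F/(L−F+1)`, linear taper within F of the edges), which is
the model's analytic sanity check; a toy sequence is verified against
exhaustive enumeration.

Site profiles average occupancy positionwise over 1124-bp windows centred
on insertion cuts; the shuffled-window control must be flat (central ±75 bp
indistinguishable from the full-coverage interior — comparisons avoid the
edge taper, which would otherwise mimic a central excess). Element-body
profiles rescale each element's landscape to 1000 normalized bins before
averaging per superfamily. Landscapes are computed per extracted window,
not genome-wide, which keeps the energy normalization local — profiles are
comparative, not absolute occupancies.

# Orchestration and problem sizes

`run_all()` wires the stages together: simulate → detect → transfer region
annotations onto detected spans (the stand-in for an external protein-domain
annotator: detected elements inherit the domain sub-spans of the matching
planted element, while family assignment is re-derived independently from
the RT sequence) → curate → date → region statistics (all pairs and
recent/old) → autoinsertion and enrichment → TSD motifs → palindromes →
nucleosome profiles, writing TSV tables, a JSON summary and a manifest with
the config hash and per-stage seeds. Per-stage seeds are derived from the
master seed, so adding a stage never perturbs earlier stages' draws; all
tables are sorted on stable keys; reruns are byte-identical. There is no
shell executable: the package's functions, this vignette and
`scripts/acceptance.R` are the interface, with `validate_config()` accepting
the same JSON config documents a command-line wrapper would.

Default problem sizes were chosen as the smallest at which every
statistical property is comfortably powered: simulations of 100–150 kb with
16–25 elements for end-to-end runs, 2000 pairs × 20 replicates for region
recovery, 10,000 windows for palindrome baselines, 200 replicates for null
calibrations and dating. The full test suite and the acceptance script each
run in a few minutes on one core.

# Known limitations

* Plus-strand planting and frozen post-insertion host sequence (above).
* No solo-LTR formation, illegitimate recombination, truncated elements or
  non-LTR transposon classes; detection is specified for full-length
  elements with ≤ ~15% LTR divergence.
* The palindrome stem definition's absolute scale (above); comparisons
  should stay within one scorer variant.
* The nucleosome model is a mechanistic stand-in: it encodes the canonical
  ~10-bp WW/SS periodicity but is not trained on nucleosome maps, so its
  profiles support relative statements (signal versus shuffled control,
  region versus region) only.
* Family classification relies on the bundled consensus panel; real
  annotations would substitute a curated protein-domain database.
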