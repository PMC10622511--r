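---
title: "Simulating and detecting DSB-induced foldback inversions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting DSB-induced foldback inversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldbackr)
```

## The mechanism being modeled

A site-specific double-strand break (DSB) induced near a natural inverted
repeat (IR) in budding yeast can be repaired by foldback priming: 5'-to-3'
resection exposes the IR in single-stranded DNA, the 3' end anneals back
onto itself at the IR (after trimming of the unpaired "heterologous flap"
between the DSB end and the annealed arm), and fill-in synthesis seals the
chromosome end as a covalent hairpin. Replication through the hairpin
produces a dicentric chromosome that is a perfect palindrome about the
former cap. The dicentric breaks at the next mitosis, typically within a
window measured from one centromere toward the palindrome center, and the
broken product is stabilized either by telomere capture — a non-reciprocal
translocation through a dispersed repeat (a delta element, a PAU-family
gene, occasionally a tRNA gene) — by de novo telomere addition, or by an
interstitial deletion that removes one centromere copy and leaves a
near-full-length monocentric inversion chromosome.

`foldbackr` implements this mechanism as an explicit sequence transform,
together with the assays used to recognise its products: binned read-depth
copy-number calling against a split-parental empirical null,
discordant-read-pair junction reconstruction with a foldback-center finder,
in-silico PCR screening, and efficiency-corrected qPCR copy number.
Competing repair outcomes (NHEJ indels, homeologous gene conversion from a
~61.6%-identity donor, simple interstitial deletion, direct telomere
addition) are simulated alongside so that classifiers can be exercised on
realistic mixed cohorts.

## The synthetic reference

`build_reference()` constructs a miniature genome whose focal locus
reproduces the geometry that drives the biology (all coordinates 0-based,
telomere at 0, centromere at high coordinates):

* a **target IR** of two 11-bp arms with exactly 2 substitution mismatches
  and a 6-bp spacer, inside a CAN1-like gene;
* a **gRNA-17-like protospacer** whose Cas9 cut (3 bp from the
  protospacer's 3' end) falls 20 bp from the target IR, so foldback at the
  target IR requires cleavage of a 20-nt heterologous flap;
* a **gRNA-48-like protospacer** cutting 51 bp from the IR;
* a **5-bp PAM-overlapping IR** with a 35-bp spacer whose telomeric arm
  sits 1 bp from the gRNA-17 cut (a 1-nt flap) and whose spacer straddles
  the whole target IR;
* alternate perfect IRs telomeric and centromeric to the target, giving the
  P11/P12 x P13/P14 screen all three outcomes to distinguish;
* **delta elements**: a cluster of three ~330-bp copies ending ~14 kb from
  the centromere, plus a single truncated 174-bp copy 50 kb from the
  centromere (deltas are otherwise ~300-360 bp);
* **PAU family**: 21 copies of a ~350-bp consensus at >90% identity, two on
  the focal chromosome (one ~90 kb from the centromere, one subtelomeric)
  and the rest subtelomeric on the donor/ballast chromosomes;
* a **homeologous donor gene** on a second chromosome generated by seeded
  per-base substitution. The substitution rate (0.425) was calibrated once
  so that global alignment identity of the emitted pair is 61.6 +/- 1%,
  the identity figure the screen's gene-conversion branch relies on;
* donor-chromosome delta and PAU copies lying between their centromere and
  a telomere, so repeat-mediated telomere capture has a template.

The genome is miniaturized relative to a real yeast genome. The default
build is ~1.2 Mb: a 200-kb focal chromosome, a 100-kb donor, and two
ballast chromosomes (500 kb + 400 kb). Ballast matters because the CNV
procedure normalizes to **total** mapped reads: on a real 12-Mb genome a
rearrangement changes total genome length negligibly, and the ballast keeps
that property at desk scale (a duplication changes total length by < 10%,
so a 2-copy gain stays near ratio 2). A `compact = TRUE` two-chromosome
variant (300 kb) is used where total-length stability is irrelevant, e.g.
junction reconstruction and screening.

`genome_config()` is the single source of these study conditions; the same
config and seed give byte-identical genomes.

## The event engine

Each simulated survivor is one draw from `simulate_cohort()`:

1. **Outcome kind** is drawn from configurable weights over foldback, NHEJ,
   homeologous gene conversion, interstitial deletion, telomere addition,
   and Cas9-inactivated (cassette-inverted) clones, which are flagged and
   excluded from downstream counts as in the screening protocol.
2. **IR choice** for foldback events weights each eligible IR by
   `exp(-flap / lambda)` with `lambda = 10` nt by default: foldback
   frequency falls with DSB-to-IR distance, but no functional form is
   established, so the decay is an explicit, configurable modeling choice.
   IRs centromeric of the essential boundary are lethal and excluded.
3. **Mismatch correction** (default on) rewrites the annealed arm toward
   the centromere-proximal copy, so the replicated palindrome matches the
   reference arm exactly; with correction off the arm carries the
   reverse complement of the telomeric arm instead. Either way the
   dicentric is a perfect palindrome — what distinguishes the two is which
   bases sit at the arm positions relative to the reference, and that is
   what the junction caller's `corrected` flag measures.
4. **Breakage** is uniform in a window measured from a randomly chosen
   centromere toward the palindrome center. The default window is 5-30 kb,
   wider than the classically cited 25-30 kb, because breakage further
   telomeric is plausible and the wider window exercises more geometry;
   `break_window = c(25000, 30000)` restores the narrow preset.
5. **Stabilization** draws among repeat translocation (junction placed at a
   homologous offset inside a repeat element between the break and the
   palindrome center, donor terminal segment appended through its
   telomere), centromere deletion (applied to the un-broken dicentric,
   flank lengths log-uniform on 1-150 kb, clamped to keep the other
   centromere, the telomeres and the essential region), and de novo
   telomere addition. If no repeat element is available between break and
   center the engine falls back to telomere addition.

A second round of foldback priming at the broken dicentric end — the route
to triplications and quadruplications — is available as an opt-in mode
(`refold_prob`, default 0): an IR near the break seeds another hairpin,
replication and breakage repeat, and the product is sealed by telomere
addition. Complex products are flagged in the truth table
(`complex`, `n_foldbacks`); the junction caller detects them only as
additional foldback centers and does not attempt full reconstruction.

Every derivative carries a **block map** — an ordered list of reference
slices (either strand) and novel insertions — which serves as the replay
recipe (`replay_blocks()` reproduces each derivative byte-identically) and
as ground truth for projecting read alignments back onto the reference.

## Reads and alignments

`simulate_reads()` samples fragments uniformly (truncated-normal lengths,
minimum one read length) and emits truth alignments; errors are
substitution-only with uniform quality, because depth and pair orientation,
not base quality, carry the signal the callers use.
`project_to_reference()` maps derivative placements through the block map:
reads in unrearranged blocks map collinearly, junction-spanning reads keep
their majority-block segment and soft-clip the rest, and pairs straddling a
foldback center become same-strand on the reference — the discordant
signature the junction caller keys on. Reads falling wholly inside novel
insertions (the 100-bp telomere seeds) are dropped.

## CNV calling

The procedure is: optional PCR-duplicate removal (`remove_duplicates()`,
fragment-level; a no-op on simulated reads, which carry no duplicates),
per-position depth, normalization to total mapped reads,
fixed windows (5 kb default, 1 kb for fine tracks), per-bin sample/parental
ratio, a 0.0625 pseudocount added to each ratio before log2, an empirical
null built by randomly halving the parental read pairs and running the same
pipeline on the halves, two-sided empirical p-values, BH FDR, and a 0.001
significance threshold. Choices the procedure itself leaves open:

* **Sidedness**: extremeness is measured as absolute deviation from the
  null median, so gains and losses are both detectable.
* **p-value estimator**: the add-one `(1 + r)/(N + 1)` form, so p is never
  zero and masked bins (zero parental signal) are excluded rather than
  infinite.
* **Null pooling**: genome-wide by default; per-chromosome pooling is
  available.
* **Parental depth**: the pipeline sequences the parental at twice the
  per-clone depth. The parental is shared across every clone in a screen,
  so sequencing it deeper is the natural allocation, and it makes the
  half-split null variance-matched to the clone-vs-parental comparison;
  with equal depths the null (half vs half) is roughly twice as variable
  as the observation and fragments segment calls at 1-kb resolution.
* **Segmentation** is simply maximal runs of same-direction significant
  bins.

`full_null_calibration()` measures the false-flagging rate of the whole
pipeline on a signal-free parental set (20x over 500 kb, 1-kb bins, 20
replicate splits by default); the flagged fraction stays at or below the
FDR target.

## Junction reconstruction

Pairs are classified exhaustively (concordant within `mu +/- 4 sigma` of
the insert distribution; inverted same-strand; interchromosomal;
distance-discordant), clustered by single linkage within one fragment
window, and the reads around an inverted cluster are assembled by a greedy
overlap-layout-consensus assembler (exact suffix-prefix overlaps of >= 15
nt by default, both orientations, longest-overlap-first with lexicographic
tie-breaks) — sufficient for error-free synthetic reads, with mismatch
knobs exposed for noisy runs. `find_foldback_center()` anchors both contig
ends in the reference with exact 20-mers and extends them inward; a center
is called where the two ends align to the same locus on opposite strands.
Extension tolerates up to 2 substitutions (so uncorrected arms are
traversed), and the `corrected` flag is set when the *exact* extension
reaches within one spacer of the center — an uncorrected arm stops the
exact match at its outermost mismatch. Center placement is reported to a
tolerance of half the spacer plus one, since the exact center within the
spacer is intrinsically ambiguous. Secondary junctions (translocation
cluster footprint edges, deletion-spanning cluster edges) are annotated
with the repeat family containing the locus within 50 bp, or `none` for
unique sequence.

## Screening and classification

`insilico_pcr()` enumerates all exact convergent primer-site pairs within a
product-length cap, so duplicated loci yield multiple products. Simulated
qPCR derives Cq triplicates from the true amplicon copy number at the
configured efficiencies (`Cq` drops by `log(copies)/log(E)`), plus normal
noise; `qpcr_copy_number()` applies the efficiency-corrected ratio
`E_t^dCq_t / E_r^dCq_r` with parental-control normalization. The survivor
decision tree follows the screening logic: control amplicon required;
P3/P4 product = NHEJ; else P1/P2 plus donor-diagnostic P7/P8 = homeologous
gene conversion; else copy number >= 1.5 = inverted duplication,
sub-classified by P11/P12 x P13/P14 (negative/positive = target IR, both
positive = telomeric IR, both negative = centromeric IR); else terminal
loss. The 1.5 cutoff is a declared choice: the simulated copy-number
clusters sit near 1 and 2 and no operational cutoff is printed for the
assay. Classifier cohorts use the gRNA-48 geometry, where the gap between
cut and target IR leaves room for the alternate telomeric IR and the P11
primer site — with the gRNA-17 geometry the PAM-overlapping IR's center
lies only ~10 bp from the target IR center, which is exactly why that
screen was deployed on the more distal guides.

Fisher's exact test for IR-usage contrasts and two-sample t tests for
survival assays are delegated to `stats::fisher.test()` and
`stats::t.test()`; BH adjustment to `stats::p.adjust()`. The test suite
cross-checks these module surfaces against independent closed-form or
enumeration oracles.

## Problem sizes and what the tests show

The packaged simulations run at desk scale: 500 kb to 1.2 Mb genomes,
20-60x coverage, cohorts of tens to a few hundred clones. At these sizes
the full test suite exercises every pipeline stage end to end in minutes.
The generator emulates uniform coverage, exact or substitution-only reads,
and clean single-event survivors; it does not model GC or mappability bias,
PCR duplicates, indel sequencing errors, multi-mapping ambiguity in repeat
arrays (truth alignments sidestep mapping), or compound rearrangements
(triplications/quadruplications are out of reconstruction scope and would
surface only as multiple foldback centers). Passing tests therefore show
that the *procedures* are implemented faithfully and recover the truth
under their stated assumptions — not that real libraries with those
artefacts would behave as cleanly.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  genome = genome_config(compact = TRUE),
  foldback = foldback_params(
    event_weights = c(foldback = 0.7, nhej = 0.2, homeologous_gc = 0.1),
    ir_candidates = c("IR_target", "IR_alt_tel", "IR_alt_cen"),
    ir_lambda = 200, element_choice = "random"),
  reads = readsim_params(depth = 30),
  cnv = cnv_config(bin_width = 5000L),
  n_clones = 5L, seed = 1L)
run <- run_end_to_end(cfg, tempfile("foldback_run_"))
run$summary$counts
autoplot(run$cnv[[1]])
```
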