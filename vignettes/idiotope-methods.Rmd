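---
title: "Methods: idiotope prediction from IGHV repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: idiotope prediction from IGHV repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idiotope)
```

## The scientific question

B cells can present peptide fragments of their own immunoglobulin variable
regions — *idiotopes* — on HLA class II molecules. If an idiotope-specific
CD4+ T cell recognizes such a complex, it can help the B cell independently
of the B cell's own antigen specificity ("idiotope-driven T–B
collaboration"). For this to happen, three prerequisites must hold
simultaneously for some fragment of the heavy-chain variable (IGHV) region:

1. **Endosomal processing** — cathepsins (S in particular for B cells) must
   cleave the IGHV chain at positions that release the fragment;
2. **HLA class II binding** — the released 15-mer must bind the patient's
   own DRB1 molecule with high affinity;
3. **Escape from tolerance** — the motif the fragment exposes to T-cell
   receptors (its *T cell-exposed motif*, TCEM) must be rare enough in the
   repertoire that circulating T cells are unlikely to be tolerant of it.

This package implements that prediction pipeline for IGHV amino-acid
repertoires: fragment generation indexed on CDR3, cleavage and excision
prediction, affinity prediction and standardization, TCEM frequency
classification, and the composite per-fragment *idiotope score* — together
with a synthetic-repertoire generator with planted ground truth, so every
stage is testable end to end without external data.

## Coordinates and fragment generation

All coordinates are 0-based and half-open. The conserved cysteine opening
CDR3 (IMGT position 104) is position 0; a fragment's index is the position
of its N-terminal residue relative to that cysteine. `cdr3_end` is the
index of the J-region W/F-G-x-G anchor, so `cdr3_end - cdr3_start` is the
CDR3 length including the cysteine and excluding the anchor tryptophan.

On amino-acid-only input, CDR3 anchors are detected heuristically: the
rightmost cysteine followed within 4–32 residues by a W/F-G-x-G motif. This
emulates nucleotide-level junction annotation, which is out of scope;
externally produced coordinates pass through unchanged. Failure is a value,
not an error, so callers can drop unannotated records or supply annotation.

Every overlapping 9-mer and 15-mer is generated per sequence
(`make_fragments()`), one-residue offsets, `L - k + 1` fragments per
length. To avoid end effects in window-based predictors, sequences can be
augmented (`augment_sequences()`) with a 19-residue signal peptide + `DTR`
at the N-terminus and the 26-residue IgG1 constant-region stub
`GTLVTVSSASTKGPSVFPLAPSSKST` at the C-terminus (mode `"full"`), or with
`DTR`/`GTL` only (mode `"short"`). The identity of the signal peptide is
configurable — only its length matters for padding — and the number of
appended residues carried by each fragment is tracked so statistical
subsets can bound it. Fragments containing the ambiguity code `X` are
dropped before prediction: all predictors are defined over the 20-letter
alphabet.

A transcript is *highly transcribed* when its read count is strictly more
than 0.5% of its patient + compartment total; ranks tie-break on sequence
lexicographic order for determinism. Exact amino-acid duplicates within a
patient share a clone identifier.

## Cathepsin cleavage and fuzzy-logic excision

Sequences are decomposed into octamer windows ordered
P4 P3 P2 P1 | P1′ P2′ P3′ P4′, the scissile bond between window residues 4
and 5. A predictor returns a cleavage probability per bond; an ensemble's
prediction is the member median, and a bond is a *site call* when its
median probability is strictly above 0.8.

The original study used proprietary neural-network ensembles; this package
defines the predictor contract and ships a trainable reference model: an
ensemble of ridge-penalized logistic regressions on one-hot octamer
positions, one member per bootstrap resample, with held-out AUROC reported.
The ridge penalty defaults to `1e-3`: strong enough to stabilize 160
coefficients at n ≈ 2000, weak enough not to shrink rare, strongly
predictive residues — important because site calls threshold *calibrated*
probabilities, not ranks.

*Excision* of a fragment follows the fuzzy rule: take the maximum cleavage
probability over the four bonds that can free the N-terminus (N-terminus
minus three residues through the terminus) and likewise for the C-terminus;
the fragment is excised when the larger maximum is ≥ 0.5 and the other is
simultaneously ≥ 0.25. Implied excised peptides therefore span 15–21
residues around a 15-mer core. Bonds without a full octamer (sequence ends,
windows containing `X`) contribute probability 0 — a conservative choice
that never fabricates cleavage beyond the sequence. Thresholds are
strict/non-strict exactly as stated (> 0.8, ≥ 0.5, ≥ 0.25) and are frozen
defaults. Excision is evaluated per enzyme; the idiotope score consumes
cathepsin S specifically, since cathepsin S dominates endosomal processing
in B cells. Whether the two terminal maxima could mix enzymes is left as a
documented interpretation: this implementation keeps them within one
enzyme.

## HLA affinity and Johnson standardization

Affinities are predicted as ln(IC50) (nM; lower = stronger binding) behind
the same pluggable contract. The reference per-allele model is a ridge
regression of ln(IC50) on one-hot 9-mer core positions. Class II 15-mers
are scored as the minimum predicted ln(IC50) over their seven contiguous
9-mer cores — a standard core-scan; the original core model is unstated, so
the minimum over cores is the package's frozen choice.

Predicted values are brought onto an equal scale by a Johnson-family
standardization within patient × compartment (within patient only is
available; the default follows the stated "within patient and compartment").
"Johnson SI" is read as a Johnson-family distributional standardization as
produced by JMP; the family member being unstated, the package fits the
branch (SU, SB or SL) selected by the Slifker–Shapiro quantile criterion at
anchor `s = 0.524` (alternative anchors are tried when a fit is
degenerate), then re-centers and rescales the transformed values to exactly
zero mean and unit variance. The overall map is monotone, so rank order —
and hence any threshold's identity as a group-specific tail — is preserved.
Groups smaller than 8, constant groups, and degenerate fits fall back to a
flagged z-score.

For each fragment, the *patient-specific* DRB1 affinity is the minimum
standardized ln(IC50) over the patient's one or two DRB1 alleles; ties keep
genotype order. The published genotype table of the 11 + 6 study patients
ships in `inst/extdata/patient_hla_genotypes.tsv`.

## TCEMs and frequency classes

A TCEM is the 5-residue subset of a bound peptide facing the T-cell
receptor. TCEM I is residues 4–8 of a 9-mer. For 15-mers the stated
numbering ("−3 to 12") spans 16 positions and cannot fit a 15-mer; the
package freezes the convention *core = central 9-mer at positions 1–9,
N-flank −2, −1, 0 (15-mer residues 1–3), C-flank 10–12*. TCEM IIa is core
positions {2,3,5,7,8} (15-mer residues 5,6,8,10,11); TCEM IIb replaces the
first with the −1 flank residue (residues 2,6,8,10,11). The core used for
TCEM extraction is the *central* 9-mer, not the affinity-selected one,
because motif counting precedes any HLA filtering.

Motif rarity uses a reverse-log2 *frequency class* (FC): a motif occurring
once every `2^f` sequences has FC `f` (FC 0 = every sequence, FC 16 = once
every 65,536, FC 21 ≈ once every 2 million; 21 is the cap). A database
(`build_fc_database()`) computes, per patient/donor × compartment group,
the fraction of distinct *sequences* whose fragments contain the motif
(the once-every-N-*sequences* reading; a per-fragment denominator is
available for sensitivity analysis), averages −log2 frequency over the
groups where the motif occurs (−log2 of zero being undefined), rounds
half-up and caps at 21. A motif is *rare* when FC is strictly above 16.
Motifs absent from the reference database are assigned the cap class and
flagged unobserved by default — querying a 3.2-million-motif space against
any finite reference leaves genuinely novel motifs, and treating them as
maximally rare matches the scale's semantics.

Background motif tables (human proteome / gut microbiome style) are
standardized on log2 frequencies with the same Johnson routine.

## The idiotope score and statistics

A 15-mer fragment *qualifies* when it is (1) predicted excised by cathepsin
S, (2) binds the patient's best DRB1 with standardized ln(IC50) < −1.5, and
(3) carries a TCEM IIa **or** IIb with FC > 16. The three criteria are
evaluated independently per fragment, as stated; whether the rare motif
must lie in the high-affinity register is an open interpretation this
package resolves as independence. A sequence qualifies when at least one of
its fragments does. Group comparisons report per-group rates, the
unadjusted 2×2 odds ratio (Woolf CI; 0.5 continuity correction on zero
cells, flagged), and a patient-stratified Mantel–Haenszel odds ratio as the
stand-in for the original random-effects adjustment — full mixed-model
fitting is deliberately delegated to standard tools (`lme4` et al.) rather
than re-implemented.

Per-position comparisons are Welch two-sample t-tests at each CDR3-relative
position with Benjamini–Hochberg control at FDR 20% over the per-position
p-vector. Statistical subsets mirror the study design: (1) fragments with
roughly half their residues in CDR3 (positions ≥ −7, at most 8 appended
constant-region residues), (2) FW3 vs CDR3 with the CDR3-influence cutoff
at −7 and FW3 taken as the 31 residues preceding the anchor cysteine
(IMGT ~73–104), (3) unaugmented fragments for blood-vs-CSF comparisons.
The per-fragment "at most 8 appended residues" reading of the subset-1
upper bound is an interpretation (the stated rule references a position
that depends on sequence length). Position profiles are trimmed to the
central 99% of fragment positions (quantiles 0.005/0.995).

TCEM occurrence matrices (motif × patient × compartment counts; column sums
equal fragment counts) are compared by Pearson correlation — the
correlation type being unstated, Pearson is the default with Spearman
available — and clustered with average linkage on `1 − r`; columns are
pre-sorted by label so leaf order is deterministic, and the dendrogram is
exported as Newick.

## The synthetic generator and what passing tests mean

`simulate_repertoire()` builds sequences as *family scaffold + CDR3
(conserved C + junction) + J region* with per-compartment hypermutation,
clonal duplication, Pareto read counts and the strict 0.5% rule. Defaults
are the study conditions: 11 case / 6 control patients, 3,500 CSF and
12,000 blood sequences per patient, CDR3 length ~ round(Normal(15.5, 2))
clamped to [5, 26], IGHV3-dominant family usage except a planted IGHV4
bias (60%) in case CSF. Hypermutation rates (blood 0.03, CSF 0.12 per
junction residue; framework 0.005/0.01) are the package's own choice of a
clearly detectable CSF excess, stated nowhere in the source material.

Design choices worth knowing:

* **Scaffolds are synthetic.** The seven family prototypes are hand-written
  VH-like strings, not IMGT germlines. They are cysteine-free except the
  conserved CDR3-opening C and contain no W/F-G-x-G upstream of CDR3, and
  junction substitutions exclude C/W/F — so anchor detection is exact and
  the planted cleavage hotspot at position 0 is unambiguous. Real
  repertoires violate both (e.g. the conserved FW1 cysteine 23), so anchor
  detection and hotspot sharpness on real data will be noisier than the
  tests suggest.
* **A public junction template pool.** Junctions are drawn from a template
  pool shared between patient and reference simulations (then mutated
  compartment-specifically). Without shared junction structure every CDR3
  motif would be a singleton at desk scale and no frequency-class contrast
  could exist. CDR3 length is still drawn per sequence from the Normal
  model, so length statistics are pool-independent.
* **Ground-truth models.** Cleavage truth is a fixed hydropathy-derived
  octamer preference plus a strong cysteine bonus at P1′ (cathepsin S/B)
  or at both P1 and P1′ (cathepsin L) — planting the cleavage peak at the
  CDR3-opening bond. Affinity truth gives the junction-enriched residues
  G/Y/S/R/D a strongly negative (high-affinity) contribution, planting the
  CDR3 affinity dip. Training labels derive from the truth logit plus a
  latent logistic perturbation whose scale is the `noise` parameter: 0
  reproduces deterministic thresholding at probability 0.5, 1 is exact
  Bernoulli sampling at the model probability, and small values mislabel
  only near-boundary octamers.

The end-to-end experiment (`recover_planted_effects()`) simulates 2 + 2
patients with 100 blood / 50 CSF sequences each and a 2 × 300-sequence
reference repertoire, runs the full pipeline, and checks four planted
directions: higher mean CDR3 FC in CSF than blood, the cleavage-site peak
at position 0, lower mean standardized ln(IC50) in CDR3 than FW3, and
over-representation of qualifying fragments at CDR3-influenced positions.
These sizes are the package's demonstration scale — large enough that all
four directions recover in essentially every seeded replicate, small
enough to run in seconds. Passing them shows the pipeline recovers what
the generator plants; it is not evidence about real patients, real
predictor accuracy, or the published effect sizes, which depended on
proprietary trained ensembles and patient data.

## Numerical choices and limitations

* FC binning is round-half-up; `-1.5`, `16` and the excision cutoffs are
  frozen defaults in `idiotope_thresholds()`.
* Identical constant groups in per-position tests are reported as
  `t = 0, p = 1` (a Welch test is undefined there); positions with fewer
  than 2 values per group are skipped and listed.
* Family assignment is global alignment identity against prototypes
  (floor 0.60, ties to the lexicographically smallest name); it is a
  convenience, not a substitute for germline-database annotation.
* Absolute predicted IC50 values are not comparable to any published
  numbers: the reference predictors share only the contract, not the
  weights, of the original models. All affinity consumers therefore work
  on the standardized scale.
* The deposited patient repertoire and the large public healthy reference
  set are accepted as optional external inputs
  (`deposited_repertoire_statistics()`, `options(idiotope.deposited_fasta)`)
  and are not bundled.

## A worked example

```{r example, eval = FALSE}
library(idiotope)

## simulate a small study and a healthy reference sharing junction structure
spec <- repertoire_sim_spec(n_case = 2, n_control = 2,
                            n_blood = 100, n_csf = 50)
sim <- simulate_repertoire(spec, seed = 1)
ref <- simulate_repertoire(
  repertoire_sim_spec(n_case = 2, n_control = 0, n_blood = 300, n_csf = 0,
                      mut_rate_cdr3 = c(blood = 0.02, CSF = 0.02),
                      family_weights = list(case_CSF = NULL)),
  seed = 99)

## frequency-class databases from the reference repertoire
ref_frag <- make_fragments(ref$repertoire, lengths = 15)
db_iia <- build_fc_database(ref_frag, "IIa")
db_iib <- build_fc_database(ref_frag, "IIb")

## train reference predictors on simulated ground-truth data
cd <- simulate_cleavage_data(true_cleavage_model("cathepsin_S"),
                             n = 2000, noise = 0.05, seed = 1)
cath_s <- train_cleavage_model(cd$octamer, cd$cleaved, "cathepsin_S",
                               ensemble_size = 5, seed = 1)
panel <- c("DRB1*S01", "DRB1*S02")
aff <- lapply(panel, function(a) {
  ad <- simulate_affinity_data(true_affinity_model(a), n = 2000, seed = 1)
  train_affinity_model(ad[, c("allele", "peptide", "ic50_nM")], a, seed = 1)
})
names(aff) <- panel

## run the pipeline and summarize
gt <- simulate_genotypes(unique(sim$repertoire$patient_id), panel, seed = 1)
res <- run_idiotope_pipeline(sim$repertoire, cath_s, aff, gt, db_iia, db_iib)
position_proportions(res$calls)
sequence_qualification(res$calls, group = "highly_transcribed")
```
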