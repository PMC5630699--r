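# idiotope

Prediction analysis of idiotope-driven T–B cell collaboration from
immunoglobulin heavy-chain variable (IGHV) amino-acid repertoires.

Memory B cells can present fragments of their own immunoglobulin variable
regions — **idiotopes** — on HLA class II molecules, and idiotope-specific
CD4+ T cells can then help those B cells independently of the B cell's
antigen specificity. For this mechanism to operate, three prerequisites
must coincide for some fragment of the IGHV region: the fragment must be
**excised** by endosomal cathepsins, it must **bind** the patient's HLA-DRB1
molecule with high affinity, and the motif it exposes to T-cell receptors
must be **rare** enough to escape tolerance. This package, aimed at
computational immunologists working with bulk BCR repertoires (blood vs
cerebrospinal fluid, cases vs controls), implements the complete in-silico
pipeline that tests those prerequisites.

## The score at the core

Every IGHV sequence is decomposed into all overlapping 9-mers and 15-mers,
indexed by the position of their N-terminus relative to the conserved
cysteine opening CDR3 (position 0). For each 15-mer fragment *f* of patient
*p*:

* **Excision** — per-bond cathepsin cleavage probabilities are predicted
  from octamer windows (P4…P1 | P1′…P4′); *f* is excised by cathepsin S
  when max(N-terminal, C-terminal cleavage maxima over terminus ± 3 bonds)
  ≥ 0.5 with ≥ 0.25 simultaneously at the other end.
* **High affinity** — predicted ln(IC50) for each of *p*'s DRB1 alleles
  (class II 15-mers scored as the minimum over the seven 9-mer cores) is
  Johnson-standardized within patient × compartment; *f* is high-affinity
  when the best allele's standardized ln(IC50) < −1.5.
* **Rare TCEM** — the T cell-exposed motifs of *f* (TCEM IIa: core
  positions 2,3,5,7,8; IIb: flank −1 and core 3,5,7,8) are looked up in a
  frequency-class (FC) database built from a reference repertoire, where a
  motif occurring once every 2^k sequences has FC k; *f* is rare when
  FC > 16 (rarer than once per 65,536 sequences) for IIa **or** IIb.

The **idiotope score** is the conjunction: a fragment *qualifies* when all
three hold; a sequence qualifies when at least one of its fragments does.
The package adds the surrounding statistics (per-position proportions and
Welch tests with Benjamini–Hochberg control at FDR 20%, odds ratios with
Mantel–Haenszel patient stratification, TCEM occurrence correlation
clustering, Welch ANOVA by IGHV family) and a fully seeded synthetic
repertoire generator with planted ground truth, so the entire chain is
testable offline.

## Worked example

Simulate a small two-group study (2 cases, 2 controls; 100 blood / 50 CSF
sequences each) plus a healthy reference repertoire, train the reference
cleavage and affinity predictors on simulated ground-truth data, and run
the pipeline:

```r
library(idiotope)

spec <- repertoire_sim_spec(n_case = 2, n_control = 2,
                            n_blood = 100, n_csf = 50)
sim <- simulate_repertoire(spec, seed = 1)
ref <- simulate_repertoire(
  repertoire_sim_spec(n_case = 2, n_control = 0, n_blood = 300, n_csf = 0,
                      mut_rate_cdr3 = c(blood = 0.02, CSF = 0.02),
                      family_weights = list(case_CSF = NULL)), seed = 99)

ref_frag <- make_fragments(ref$repertoire, lengths = 15)
db_iia <- build_fc_database(ref_frag, "IIa")
db_iib <- build_fc_database(ref_frag, "IIb")

cd <- simulate_cleavage_data(true_cleavage_model("cathepsin_S"),
                             n = 2000, noise = 0.05, seed = 1)
cath_s <- train_cleavage_model(cd$octamer, cd$cleaved, "cathepsin_S",
                               ensemble_size = 5, seed = 1)
cath_s$holdout_auroc
#> [1] 0.980741

panel <- c("DRB1*S01", "DRB1*S02")
aff <- setNames(lapply(panel, function(a) {
  ad <- simulate_affinity_data(true_affinity_model(a), n = 2000, seed = 1)
  train_affinity_model(ad[, c("allele", "peptide", "ic50_nM")], a, seed = 1)
}), panel)

gt <- simulate_genotypes(unique(sim$repertoire$patient_id), panel, seed = 1)
res <- run_idiotope_pipeline(sim$repertoire, cath_s, aff, gt, db_iia, db_iib)

pp <- position_proportions(res$calls)
pp[pp$cdr3_relative_position %in% -1:3,
   c("cdr3_relative_position", "n", "p_excised", "p_high_affinity",
     "p_rare_tcem", "p_qualifies")]
#>  cdr3_relative_position   n p_excised p_high_affinity p_rare_tcem p_qualifies
#>                      -1 600      0.10            0.30        0.21      0.0017
#>                       0 600      0.19            0.32        0.24      0.0067
#>                       1 600      0.33            0.34        0.27      0.0283
#>                       2 600      0.53            0.33        0.27      0.0433
#>                       3 600      0.71            0.36        0.29      0.0717
```

The per-criterion proportions rise steeply as fragments enter CDR3 and the
composite proportion peaks inside it — only there do excision, affinity and
rarity coincide. At the sequence level, highly transcribed sequences are
more likely to carry at least one qualifying fragment:

```r
sq <- sequence_qualification(res$calls, group = "highly_transcribed")
sq$rates
#>      TRUE     FALSE
#> 0.1835616 0.1148936
round(unlist(sq$or[1:3]), 3)   # unadjusted OR with Woolf 95% CI
#>    or lower upper
#> 1.732 1.071 2.801
sq$mh                          # patient-stratified Mantel-Haenszel OR
#> $or
#> [1] 1.764736
#> $p
#> [1] 0.0210891
```

All numbers above come from the synthetic generator's planted structure;
they demonstrate the pipeline's behavior, not patient biology. See the
methods vignette (`vignettes/idiotope-methods.Rmd`) for the model
descriptions, frozen conventions and limitations.

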