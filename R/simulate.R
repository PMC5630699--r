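## Seeded synthetic-data generation: repertoires with controlled structure,
## cleavage and affinity training data with known ground truth, and
## background motif tables. Every stage of the pipeline can be exercised and
## its planted effects recovered without any external download.
##
## All randomness flows from a single seed through named substreams, so each
## component is reproducible on its own.

## Kyte-Doolittle hydropathy, rescaled to roughly [-1, 1]; used as a fixed,
## deterministic per-residue value scale for the ground-truth models.
AA_VALUE <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
              G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
              M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
              S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3) / 4.5

## residues enriched in CDR3 junctions; the ground-truth affinity tables
## give these high affinity (low ln IC50), planting the CDR3 affinity dip
JUNCTION_ENRICHED <- c("G", "Y", "S", "R", "D")

derive_seed <- function(seed, name) {
  s <- (as.numeric(seed) * 7919 + sum(utf8ToInt(name)) * 104729) %% 2147483647
  as.integer(max(1, s))
}

#' Ground-truth cathepsin cleavage model
#'
#' A fixed position-specific weight model per enzyme, wrapped in the
#' `cleavage_model` contract (single ensemble member). All enzymes share a
#' hydropathy-derived octamer preference producing a continuum of cleavage
#' probabilities; on top of that, a strong cysteine preference is planted at
#' P1' (cathepsin S, B) and at both P1 and P1' (cathepsin L), so sequences
#' whose only cysteine opens CDR3 have their cleavage hotspot exactly at
#' CDR3-relative position 0.
#'
#' @param enzyme One of the three cathepsins.
#' @return A `cleavage_model` usable with [predict_cleavage()].
#' @export
true_cleavage_model <- function(enzyme = CATHEPSINS) {
  enzyme <- match.arg(enzyme)
  pos_scale <- c(0.45, 0.45, 0.60, 0.80, 0.80, 0.60, 0.45, 0.45)
  rot <- switch(enzyme, cathepsin_S = 0L, cathepsin_L = 3L, cathepsin_B = 7L)
  v <- AA_VALUE[((seq_along(AA_VALUE) - 1L + rot) %% 20L) + 1L]
  names(v) <- names(AA_VALUE)
  W <- outer(v, pos_scale)
  rownames(W) <- names(AA_VALUE)
  W <- W[AA_ALPHABET, , drop = FALSE]
  b <- switch(enzyme, cathepsin_S = -0.5, cathepsin_L = -0.6, cathepsin_B = -0.8)
  if (enzyme == "cathepsin_L") {
    W["C", 4L] <- W["C", 4L] + 5.0
    W["C", 5L] <- W["C", 5L] + 5.0
  } else if (enzyme == "cathepsin_S") {
    W["C", 5L] <- W["C", 5L] + 5.5
  } else {
    W["C", 5L] <- W["C", 5L] + 3.0
  }
  structure(list(enzyme = enzyme, members = list(list(W = W, b = b)),
                 holdout_auroc = NA_real_),
            class = "cleavage_model")
}

#' Ground-truth per-allele affinity scoring table
#'
#' A fixed 20 x 9 position-specific ln(IC50) contribution table per allele:
#' a shared hydropathy-derived component, a planted high-affinity (negative)
#' contribution for the junction-enriched residues
#' `r toString(JUNCTION_ENRICHED)`, and a deterministic allele-specific
#' perturbation derived from the allele name, so different alleles rank
#' peptides differently while sharing the CDR3 composition bias.
#'
#' @param allele Allele name.
#' @param hla_class `"I"` or `"II"`.
#' @return An `affinity_model` (see [affinity_model_from_table()]).
#' @export
true_affinity_model <- function(allele, hla_class = c("II", "I")) {
  hla_class <- match.arg(hla_class)
  pos_scale <- c(1, 0.5, 0.5, 0.9, 0.5, 0.9, 0.5, 0.5, 1)
  v <- 0.35 * AA_VALUE[AA_ALPHABET]
  v[JUNCTION_ENRICHED] <- -0.55
  W <- outer(v, pos_scale)
  rownames(W) <- AA_ALPHABET
  old <- .Random.seed_get()
  set.seed(derive_seed(sum(utf8ToInt(allele)), "allele_table"))
  W <- W + matrix(runif(180, -0.15, 0.15), nrow = 20)
  .Random.seed_set(old)
  affinity_model_from_table(W, b = 6.0, allele = allele, hla_class = hla_class)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate labeled octamer cleavage data
#'
#' Octamers are drawn uniformly over the 20-letter alphabet and labeled by
#' thresholding the ground-truth cleavage logit perturbed by latent logistic
#' noise: `cleaved = 1[logit + Logistic(0, noise) > 0]`. `noise = 0` gives
#' deterministic labels at the probability-0.5 threshold; `noise = 1` is
#' exact Bernoulli sampling at the model probability; small values mislabel
#' only near-boundary octamers.
#'
#' @param truth A `cleavage_model` ground truth (see
#'   [true_cleavage_model()]).
#' @param n Number of octamers.
#' @param noise Scale of the latent logistic label perturbation.
#' @param seed RNG seed.
#' @return Data.frame `octamer`, `cleaved` (0/1), `true_probability`.
#' @export
simulate_cleavage_data <- function(truth, n = 2000L, noise = 0.05, seed = 1L) {
  set.seed(derive_seed(seed, "cleavage_data"))
  oct <- random_peptides(n, 8L)
  mem <- truth$members[[1L]]
  logit <- pssm_score(oct, mem$W, mem$b)
  eps <- if (noise > 0) rlogis(n, location = 0, scale = noise) else 0
  data.frame(octamer = oct,
             cleaved = as.integer(logit + eps > 0),
             true_probability = plogis(logit),
             stringsAsFactors = FALSE)
}

#' Simulate a peptide-IC50 training table
#'
#' Random 9-mers with `ic50_nM = exp(true_ln_ic50 + Normal(0, noise_sd))`
#' under a ground-truth allele scoring table; IC50 values are positive by
#' construction.
#'
#' @param truth An `affinity_model` ground truth.
#' @param n Number of peptides.
#' @param noise_sd Gaussian noise sd on the ln(IC50) scale.
#' @param seed RNG seed.
#' @return Data.frame `allele`, `peptide`, `ic50_nM`, `true_ln_ic50`.
#' @export
simulate_affinity_data <- function(truth, n = 2000L, noise_sd = 0.5, seed = 1L) {
  set.seed(derive_seed(seed, "affinity_data"))
  pep <- random_peptides(n, 9L)
  true_ln <- pssm_score(pep, truth$W, truth$b)
  data.frame(allele = truth$allele, peptide = pep,
             ic50_nM = exp(true_ln + rnorm(n, 0, noise_sd)),
             true_ln_ic50 = true_ln, stringsAsFactors = FALSE)
}

random_peptides <- function(n, k, alphabet = AA_ALPHABET, prob = NULL) {
  m <- matrix(sample(alphabet, n * k, replace = TRUE, prob = prob),
              nrow = n, ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a Zipf-distributed background motif table
#'
#' Motif counts following a Zipf-like rank-frequency law, emulating
#' proteome/microbiome motif-occurrence tables.
#'
#' @param tcem_class TCEM class label carried through.
#' @param zipf_exponent Rank-frequency exponent (rank-1 most frequent).
#' @param n_distinct Number of distinct motifs (full enumeration when it
#'   equals `length(alphabet)^5`).
#' @param seed RNG seed.
#' @param alphabet Motif alphabet.
#' @return Data.frame `tcem_class`, `motif`, `count`, ordered by rank.
#' @export
simulate_background <- function(tcem_class = TCEM_CLASSES, zipf_exponent = 1.0,
                                n_distinct = 10000L, seed = 1L,
                                alphabet = AA_ALPHABET) {
  tcem_class <- match.arg(tcem_class)
  space <- length(alphabet)^5
  stopifnot(n_distinct <= space)
  set.seed(derive_seed(seed, "background"))
  if (n_distinct == space) {
    motifs <- enumerate_tcem_motifs(alphabet)
  } else {
    motifs <- unique(random_peptides(ceiling(n_distinct * 1.3), 5L, alphabet))
    while (length(motifs) < n_distinct) {
      motifs <- unique(c(motifs, random_peptides(n_distinct, 5L, alphabet)))
    }
    motifs <- motifs[seq_len(n_distinct)]
  }
  rank <- seq_along(motifs)
  count <- ceiling((n_distinct / rank)^zipf_exponent)
  data.frame(tcem_class = tcem_class, motif = motifs, count = count,
             stringsAsFactors = FALSE)
}

#' Repertoire simulation specification
#'
#' Defaults mirror the study conditions: two patient groups (11 cases, 6
#' controls), compartment sizes of 3,500 CSF and 12,000 blood sequences per
#' patient, CDR3 lengths ~ Normal(15.5, 2) rounded and clamped to [5, 26],
#' IGHV3-dominant family usage everywhere except case CSF where IGHV4 bias
#' is planted, compartment-specific CDR3 hypermutation (CSF higher), a
#' shared pool of public junction templates, power-law read counts, and the
#' strict 0.5% highly-transcribed rule. All probabilities are validated.
#'
#' @param n_case,n_control Patients per group.
#' @param n_blood,n_csf Sequences per patient per compartment.
#' @param family_weights Named list of per-condition IGHV family weight
#'   vectors with entries `default` and optionally `case_CSF`,
#'   `case_blood`, `control_CSF`, `control_blood`.
#' @param cdr3_length_mean,cdr3_length_sd CDR3 length distribution (the
#'   length includes the opening cysteine, excludes the J anchor).
#' @param n_junction_templates Size of the shared public junction pool.
#' @param mut_rate_cdr3 Named per-compartment per-residue CDR3 substitution
#'   rates (`blood`, `CSF`).
#' @param mut_rate_fw Named per-compartment framework substitution rates.
#' @param clone_dup_prob Probability that a record re-emits an existing
#'   sequence of the same patient/compartment (clonal expansion).
#' @param read_alpha Pareto tail exponent for read counts.
#' @param ht_threshold Highly-transcribed read-share threshold.
#' @param seed Default seed used when [simulate_repertoire()] is called
#'   without one.
#' @return Object of class `repertoire_sim_spec`.
#' @export
repertoire_sim_spec <- function(n_case = 11L, n_control = 6L,
                                n_blood = 12000L, n_csf = 3500L,
                                family_weights = NULL,
                                cdr3_length_mean = 15.5, cdr3_length_sd = 2,
                                n_junction_templates = 40L,
                                mut_rate_cdr3 = c(blood = 0.03, CSF = 0.12),
                                mut_rate_fw = c(blood = 0.005, CSF = 0.01),
                                clone_dup_prob = 0.05,
                                read_alpha = 1.2,
                                ht_threshold = 0.005,
                                seed = 1L) {
  default_fam <- c(IGHV1 = 0.12, IGHV2 = 0.04, IGHV3 = 0.40, IGHV4 = 0.22,
                   IGHV5 = 0.10, IGHV6 = 0.06, IGHV7 = 0.06)
  case_csf_fam <- c(IGHV1 = 0.08, IGHV2 = 0.02, IGHV3 = 0.12, IGHV4 = 0.60,
                    IGHV5 = 0.08, IGHV6 = 0.05, IGHV7 = 0.05)
  fw <- list(default = default_fam, case_CSF = case_csf_fam)
  if (!is.null(family_weights)) fw[names(family_weights)] <- family_weights
  fw <- fw[!vapply(fw, is.null, logical(1))]     # NULL entry drops a condition
  for (w in fw) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
      stop("family weights must be non-negative and sum to 1")
    }
  }
  ja <- setdiff(AA_ALPHABET, c("C", "W", "F"))       # keep anchors unambiguous
  jw <- rep(1, length(ja)); names(jw) <- ja
  jw[JUNCTION_ENRICHED] <- 4                         # junction composition bias
  jw <- jw / sum(jw)
  structure(list(
    n_case = n_case, n_control = n_control,
    n_blood = n_blood, n_csf = n_csf,
    family_weights = fw,
    cdr3_length_mean = cdr3_length_mean, cdr3_length_sd = cdr3_length_sd,
    n_junction_templates = n_junction_templates,
    junction_alphabet = ja, junction_weights = jw,
    mut_rate_cdr3 = mut_rate_cdr3, mut_rate_fw = mut_rate_fw,
    clone_dup_prob = clone_dup_prob, read_alpha = read_alpha,
    ht_threshold = ht_threshold, seed = seed
  ), class = "repertoire_sim_spec")
}

mutate_strings <- function(strings, rate, alphabet, protect_first = FALSE) {
  if (rate <= 0 || length(strings) == 0L) return(strings)
  chars <- strsplit(strings, "", fixed = TRUE)
  vapply(chars, function(ch) {
    n <- length(ch)
    from <- if (protect_first) 2L else 1L
    if (from > n) return(paste(ch, collapse = ""))
    hit <- which(runif(n - from + 1L) < rate) + from - 1L
    if (length(hit)) ch[hit] <- sample(alphabet, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
}

J_REGION <- "WGQGTLVTVSS"

#' Simulate an annotated IGHV repertoire
#'
#' Builds sequences as family germline scaffold + CDR3 (conserved cysteine +
#' junction) + J region, with per-compartment hypermutation, clonal
#' duplication, power-law read counts and the strict highly-transcribed
#' rule. Junctions are drawn from a template pool shared across patients
#' (and, for a fixed `pool_seed`, across independent simulations), so motif
#' frequency structure exists at any scale; compartment-specific
#' hypermutation then diversifies CSF junctions more than blood ones.
#' Seeded runs are bit-reproducible.
#'
#' @param spec A [repertoire_sim_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @param pool_seed Seed of the shared junction template pool; keep it fixed
#'   across patient and reference simulations that should share public
#'   junction structure.
#' @return List with `repertoire` (annotated data.frame in the
#'   [parse_repertoire()] layout plus `group` and `ighv_family`) and `truth`
#'   (per-sequence ground-truth sidecar: family, anchors, clone id).
#' @export
simulate_repertoire <- function(spec, seed = spec$seed, pool_seed = 97L) {
  stopifnot(inherits(spec, "repertoire_sim_spec"))
  germ <- ighv_germline_set()
  ## shared public junction template pool
  set.seed(derive_seed(pool_seed, "junction_pool"))
  pool_len <- pmin(26L, pmax(5L, round_half_up(
    rnorm(spec$n_junction_templates, spec$cdr3_length_mean, spec$cdr3_length_sd))))
  pool <- vapply(pool_len, function(l) {
    paste(sample(spec$junction_alphabet, l - 1L, replace = TRUE,
                 prob = spec$junction_weights), collapse = "")
  }, character(1))

  set.seed(derive_seed(seed, "repertoire"))
  conditions <- expand.grid(
    patient = c(if (spec$n_case) paste0("case", seq_len(spec$n_case)),
                if (spec$n_control) paste0("control", seq_len(spec$n_control))),
    compartment = c("blood", "CSF"), stringsAsFactors = FALSE)
  conditions$group <- sub("[0-9]+$", "", conditions$patient)
  out <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    patient <- conditions$patient[ci]
    comp <- conditions$compartment[ci]
    grp <- conditions$group[ci]
    n <- if (comp == "blood") spec$n_blood else spec$n_csf
    if (n == 0L) next
    key <- paste(grp, comp, sep = "_")
    famw <- spec$family_weights[[key]]
    if (is.null(famw)) famw <- spec$family_weights$default
    fam <- sample(names(famw), n, replace = TRUE, prob = famw)
    len <- pmin(26L, pmax(5L, round_half_up(
      rnorm(n, spec$cdr3_length_mean, spec$cdr3_length_sd))))
    tpl <- pool[sample.int(length(pool), n, replace = TRUE)]
    junction <- vapply(seq_len(n), function(i) {
      t <- tpl[i]; want <- len[i] - 1L
      while (nchar(t) < want) t <- paste0(t, tpl[i])
      substr(t, 1L, want)
    }, character(1))
    junction <- mutate_strings(junction, spec$mut_rate_cdr3[[comp]],
                               spec$junction_alphabet)
    scaffold <- mutate_strings(unname(germ[fam]), spec$mut_rate_fw[[comp]],
                               spec$junction_alphabet, protect_first = FALSE)
    ## scaffold ends in the conserved C; never mutate it
    scaffold <- paste0(substr(scaffold, 1L, nchar(scaffold) - 1L),
                       "C")
    seqs <- paste0(scaffold, junction, J_REGION)
    cdr3_start <- nchar(scaffold) - 1L             # 0-based index of the C
    cdr3_end <- cdr3_start + len                   # index of the J anchor W
    ## clonal duplication: re-emit earlier records
    dup <- which(runif(n) < spec$clone_dup_prob & seq_len(n) > 1L)
    for (i in dup) {
      j <- sample.int(i - 1L, 1L)
      seqs[i] <- seqs[j]; fam[i] <- fam[j]
      cdr3_start[i] <- cdr3_start[j]; cdr3_end[i] <- cdr3_end[j]
    }
    reads <- as.integer(ceiling(runif(n)^(-1 / spec$read_alpha)))
    reads <- pmin(reads, 10L * n)                  # cap pathological tails
    ord <- order(-reads, seqs)                     # rank ties: lexicographic
    rank <- integer(n); rank[ord] <- seq_len(n)
    out[[ci]] <- data.frame(
      gi = sprintf("%s_%s_%05d", patient, comp, seq_len(n)),
      patient_id = patient, compartment = comp, group = grp,
      rank = rank, read_count = reads,
      highly_transcribed = reads / sum(reads) > spec$ht_threshold,
      sequence = seqs, ighv_family = fam,
      cdr3_start = cdr3_start, cdr3_end = cdr3_end,
      n_prefix = 0L, n_suffix = 0L, stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  rep$clone_id <- assign_clone_ids(rep$patient_id, rep$sequence)
  truth <- rep[, c("gi", "patient_id", "compartment", "group", "ighv_family",
                   "cdr3_start", "cdr3_end", "clone_id", "read_count")]
  rownames(rep) <- rownames(truth) <- NULL
  list(repertoire = rep, truth = truth)
}

#' Simulate patient DRB1 genotypes over a synthetic allele panel
#'
#' @param patients Character vector of patient codes.
#' @param panel Allele panel (default three synthetic DRB1 alleles).
#' @param seed RNG seed.
#' @return Genotype data.frame (`patient_id`, `locus`, `allele1`, `allele2`).
#' @export
simulate_genotypes <- function(patients,
                               panel = c("DRB1*S01", "DRB1*S02", "DRB1*S03"),
                               seed = 1L) {
  set.seed(derive_seed(seed, "genotypes"))
  a1 <- sample(panel, length(patients), replace = TRUE)
  a2 <- sample(panel, length(patients), replace = TRUE)
  data.frame(patient_id = patients, locus = "DRB1",
             allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
}
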