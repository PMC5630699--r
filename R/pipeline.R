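## End-to-end orchestration: from an annotated repertoire to the idiotope
## call table, and the planted-effect recovery experiment that validates the
## whole chain on synthetic data.

#' Run the idiotope prediction pipeline
#'
#' Fragments an annotated repertoire, predicts cathepsin S cleavage and
#' excision for every 15-mer, predicts per-allele class II affinities,
#' standardizes them within patient and compartment, resolves the
#' patient-specific best DRB1 allele, classifies TCEM IIa/IIb rarity against
#' frequency-class databases, and combines everything into the idiotope call
#' table.
#'
#' @param repertoire Annotated repertoire (CDR3 anchors set).
#' @param cathepsin_s A `cleavage_model` for cathepsin S.
#' @param affinity_models Named list of class II `affinity_model`s, keyed by
#'   allele name; must cover every allele in `genotypes`.
#' @param genotypes DRB1 genotype table (see [read_genotypes()]).
#' @param db_iia,db_iib TCEM IIa/IIb frequency-class databases.
#' @param thresholds See [idiotope_thresholds()].
#' @param lengths Fragment lengths (default `c(9, 15)`; scoring uses the
#'   15-mers).
#' @param standardize_within Standardization grouping (see
#'   [standardize_affinity()]).
#' @return List with `fragments`, `profile` (per-bond cathepsin S
#'   probabilities), `excision`, `affinity` (patient-specific best DRB1 per
#'   fragment), `fc_iia`, `fc_iib`, `calls`.
#' @export
run_idiotope_pipeline <- function(repertoire, cathepsin_s, affinity_models,
                                  genotypes, db_iia, db_iib,
                                  thresholds = idiotope_thresholds(),
                                  lengths = c(9L, 15L),
                                  standardize_within = "patient_compartment") {
  fragments <- make_fragments(repertoire, lengths = lengths)
  frag15 <- fragments[fragments$length == 15L, , drop = FALSE]

  ## cleavage: predict once per unique sequence, then expand to records
  useq <- unique(repertoire$sequence)
  prof_u <- predict_cleavage(cathepsin_s, useq,
                             gi = as.character(seq_along(useq)))
  rows_per_uid <- split(seq_len(nrow(prof_u)),
                        factor(prof_u$parent_gi, levels = as.character(seq_along(useq))))
  idx <- match(repertoire$sequence, useq)
  take <- unlist(rows_per_uid[idx], use.names = FALSE)
  nper <- lengths(rows_per_uid)[idx]
  profile <- prof_u[take, , drop = FALSE]
  profile$parent_gi <- rep(repertoire$gi, nper)
  rownames(profile) <- NULL

  excision <- call_excision(frag15, profile)

  ## affinities: predict once per unique 15-mer per allele
  upep <- unique(frag15$sequence)
  aff_long <- lapply(affinity_models, function(model) {
    pa <- predict_affinity(model, upep)
    data.frame(fragment_id = frag15$fragment_id,
               patient_id = frag15$patient_id,
               compartment = frag15$compartment,
               allele = model$allele,
               ln_ic50 = pa$ln_ic50[match(frag15$sequence, upep)],
               stringsAsFactors = FALSE)
  })
  aff_long <- do.call(rbind, aff_long)
  aff_long <- standardize_affinity(aff_long, within = standardize_within)
  best <- lapply(unique(frag15$patient_id), function(p) {
    alleles <- patient_alleles(genotypes, p, "DRB1")
    best_patient_allele(aff_long[aff_long$patient_id == p, , drop = FALSE],
                        alleles)
  })
  best <- do.call(rbind, best)

  fc_iia <- assign_fc(extract_tcem(frag15$sequence, "IIa"), db_iia,
                      rare_threshold = thresholds$fc)
  fc_iia$fragment_id <- frag15$fragment_id
  fc_iib <- assign_fc(extract_tcem(frag15$sequence, "IIb"), db_iib,
                      rare_threshold = thresholds$fc)
  fc_iib$fragment_id <- frag15$fragment_id

  calls <- score_fragments(frag15, excision, best, fc_iia, fc_iib, thresholds)
  list(fragments = fragments, profile = profile, excision = excision,
       affinity = best, fc_iia = fc_iia, fc_iib = fc_iib, calls = calls)
}

#' Recover planted effects from one simulated study
#'
#' Simulates a patient repertoire with the generator's planted structure
#' (extra CSF junction hypermutation, IGHV4 bias in case CSF, a cleavage
#' hotspot at the CDR3-opening bond, junction residues with planted high
#' HLA affinity), builds TCEM frequency-class databases from an
#' independently simulated healthy reference repertoire sharing the public
#' junction pool, runs the full pipeline, and reports whether each planted
#' direction is recovered:
#' \describe{
#'   \item{`fc_csf_gt_blood`}{mean TCEM IIa frequency class at CDR3
#'     positions higher in CSF than blood (case patients).}
#'   \item{`cleavage_peak_at_zero`}{the cathepsin S cleavage-site proportion
#'     profile peaks at CDR3-relative position 0.}
#'   \item{`cdr3_affinity_lower`}{mean best-allele standardized ln(IC50)
#'     lower (higher affinity) at CDR3 than at FW3 positions.}
#'   \item{`qualifying_concentrated`}{qualifying fragments are
#'     over-represented at CDR3-influenced positions (>= -7) relative to all
#'     fragments.}
#' }
#'
#' @param seed Replicate seed.
#' @param n_case,n_control,n_blood,n_csf Scaled-down study sizes.
#' @param n_reference Reference sequences per healthy donor (2 donors,
#'   blood).
#' @param models Optional list with elements `cathepsin_s` and
#'   `affinity_models` (named list); defaults to the ground-truth models so
#'   the experiment isolates pipeline recovery from trainer recovery.
#' @param cdr3_window,fw3_window Position windows used for the CDR3 and FW3
#'   summaries.
#' @return List of the four logical outcomes plus `details` (the underlying
#'   summary numbers and the sequence-level qualification rates by
#'   highly-transcribed status).
#' @export
recover_planted_effects <- function(seed = 1L, n_case = 2L, n_control = 2L,
                                    n_blood = 100L, n_csf = 50L,
                                    n_reference = 300L, models = NULL,
                                    cdr3_window = c(0L, 7L),
                                    fw3_window = c(-31L, -8L)) {
  spec <- repertoire_sim_spec(n_case = n_case, n_control = n_control,
                              n_blood = n_blood, n_csf = n_csf)
  sim <- simulate_repertoire(spec, seed = seed)
  ref_spec <- repertoire_sim_spec(n_case = 2L, n_control = 0L,
                                  n_blood = n_reference, n_csf = 0L,
                                  mut_rate_cdr3 = c(blood = 0.02, CSF = 0.02),
                                  family_weights = list(case_CSF = NULL))
  ref <- simulate_repertoire(ref_spec, seed = derive_seed(seed, "reference"))
  ref$repertoire$patient_id <- sub("^case", "donor", ref$repertoire$patient_id)
  ref_frag <- make_fragments(ref$repertoire, lengths = 15L)
  db_iia <- build_fc_database(ref_frag, "IIa")
  db_iib <- build_fc_database(ref_frag, "IIb")

  if (is.null(models)) {
    panel <- c("DRB1*S01", "DRB1*S02", "DRB1*S03")
    models <- list(cathepsin_s = true_cleavage_model("cathepsin_S"),
                   affinity_models = setNames(
                     lapply(panel, true_affinity_model), panel))
  }
  genotypes <- simulate_genotypes(unique(sim$repertoire$patient_id),
                                  panel = names(models$affinity_models),
                                  seed = derive_seed(seed, "gt"))
  res <- run_idiotope_pipeline(sim$repertoire, models$cathepsin_s,
                               models$affinity_models, genotypes,
                               db_iia, db_iib)
  frag15 <- res$fragments[res$fragments$length == 15L, , drop = FALSE]
  pos <- frag15$cdr3_relative_position
  in_cdr3 <- pos >= cdr3_window[1] & pos <= cdr3_window[2]
  in_fw3 <- pos >= fw3_window[1] & pos <= fw3_window[2]
  is_case <- frag15$patient_id %in% unique(sim$repertoire$patient_id[sim$repertoire$group == "case"])

  ## (a) TCEM rarity: CSF vs blood at CDR3 positions, case patients
  fc <- res$fc_iia$fc[match(frag15$fragment_id, res$fc_iia$fragment_id)]
  fc_csf <- mean(fc[in_cdr3 & is_case & frag15$compartment == "CSF"])
  fc_blood <- mean(fc[in_cdr3 & is_case & frag15$compartment == "blood"])

  ## (b) cleavage hotspot at position 0
  prof <- cleavage_position_profile(res$profile, sim$repertoire)
  prof <- prof[prof$n >= 0.5 * nrow(sim$repertoire), , drop = FALSE]
  peak <- prof$cdr3_relative_position[which.max(prof$proportion)]

  ## (c) affinity dip in CDR3
  std <- res$affinity$std_ln_ic50[match(frag15$fragment_id,
                                        res$affinity$fragment_id)]
  aff_cdr3 <- mean(std[in_cdr3], na.rm = TRUE)
  aff_fw3 <- mean(std[in_fw3], na.rm = TRUE)

  ## (d) qualifying fragments concentrated at CDR3-influenced positions
  q <- res$calls$qualifies
  share_q <- mean(res$calls$cdr3_relative_position[which(q)] >= -7L)
  share_all <- mean(res$calls$cdr3_relative_position >= -7L)

  rates <- tryCatch(sequence_qualification(res$calls,
                                           group = "highly_transcribed")$rates,
                    error = function(e) NULL)
  list(fc_csf_gt_blood = fc_csf > fc_blood,
       cleavage_peak_at_zero = peak == 0L,
       cdr3_affinity_lower = aff_cdr3 < aff_fw3,
       qualifying_concentrated = sum(q, na.rm = TRUE) > 0L && share_q > share_all,
       details = list(fc_csf = fc_csf, fc_blood = fc_blood,
                      peak_position = peak,
                      aff_cdr3 = aff_cdr3, aff_fw3 = aff_fw3,
                      n_qualifying = sum(q, na.rm = TRUE),
                      share_qualifying_cdr3 = share_q,
                      share_all_cdr3 = share_all,
                      ht_qualification_rates = rates))
}
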