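## HLA affinity prediction behind a pluggable predictor contract, ln(IC50)
## transformation, within-group Johnson standardization, and patient-specific
## best-allele resolution.
##
## A predictor scores a 9-residue core; class I peptides are the core itself,
## class II 15-mers are scored as the minimum predicted ln(IC50) over their
## seven contiguous 9-mer cores (lower ln(IC50) = higher affinity).

#' Train a reference per-allele affinity predictor
#'
#' Ridge regression of ln(IC50) on one-hot 9-mer core positions, with a
#' held-out Pearson correlation reported. Deterministic given the seed. The
#' model implements the same contract as any external affinity predictor:
#' peptide in, predicted ln(IC50) out.
#'
#' @param training Data.frame with columns `allele`, `peptide` (9-mers) and
#'   `ic50_nM` (> 0).
#' @param allele Allele name the model is trained for; must match the
#'   training table.
#' @param hla_class `"I"` (expects 9-mer queries) or `"II"` (expects 15-mer
#'   queries, scored by core scan).
#' @param seed RNG seed.
#' @param lambda Ridge penalty.
#' @param holdout Held-out fraction.
#' @param min_n Minimum number of training pairs (default 200).
#' @return Object of class `affinity_model` with fields `allele`,
#'   `hla_class`, `W` (20 x 9), `b`, `holdout_r`.
#' @export
train_affinity_model <- function(training, allele, hla_class = c("II", "I"),
                                 seed = 1L, lambda = 0.001, holdout = 0.2,
                                 min_n = 200L) {
  hla_class <- match.arg(hla_class)
  stopifnot(all(c("allele", "peptide", "ic50_nM") %in% names(training)))
  if (!all(training$allele == allele)) {
    stop("training table contains alleles other than ", allele)
  }
  if (nrow(training) < min_n) {
    stop(sprintf("insufficient training data for %s: %d < %d pairs",
                 allele, nrow(training), min_n))
  }
  stopifnot(all(nchar(training$peptide) == 9L), all(training$ic50_nM > 0))
  set.seed(seed)
  n <- nrow(training)
  test <- sample.int(n, size = max(1L, round(holdout * n)))
  train <- setdiff(seq_len(n), test)
  X <- onehot_design(training$peptide, 9L)
  y <- log(training$ic50_nM)
  fit <- glmnet::glmnet(X[train, , drop = FALSE], y[train],
                        family = "gaussian", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  pssm <- coef_to_pssm(fit, 9L)
  pred <- pssm_score(training$peptide[test], pssm$W, pssm$b)
  structure(list(allele = allele, hla_class = hla_class,
                 W = pssm$W, b = pssm$b,
                 holdout_r = stats::cor(pred, y[test])),
            class = "affinity_model")
}

#' Build an affinity model directly from a scoring table
#'
#' Wraps a known position-specific scoring table (for instance a simulation
#' ground truth) in the `affinity_model` contract.
#'
#' @param W 20 x 9 matrix of per-position ln(IC50) contributions, rownames
#'   the amino-acid alphabet.
#' @param b Intercept on the ln(IC50) scale.
#' @param allele Allele label.
#' @param hla_class `"I"` or `"II"`.
#' @return An `affinity_model`.
#' @export
affinity_model_from_table <- function(W, b, allele, hla_class = c("II", "I")) {
  hla_class <- match.arg(hla_class)
  stopifnot(identical(dim(W), c(20L, 9L)), identical(rownames(W), AA_ALPHABET))
  structure(list(allele = allele, hla_class = hla_class, W = W, b = b,
                 holdout_r = NA_real_),
            class = "affinity_model")
}

#' Predict peptide-HLA affinity
#'
#' Class I models require 9-mers and score the peptide directly; class II
#' models require 15-mers and report the minimum predicted ln(IC50) over the
#' seven contiguous 9-mer cores. Peptides containing `X` get `NA`.
#'
#' @param model An `affinity_model`.
#' @param peptides Character vector, all of the model's expected length.
#' @return Data.frame `peptide`, `allele`, `ic50`, `ln_ic50` (plus
#'   `core_offset`, 0-based, for class II).
#' @export
predict_affinity <- function(model, peptides) {
  stopifnot(inherits(model, "affinity_model"))
  expected <- if (model$hla_class == "I") 9L else 15L
  if (any(nchar(peptides) != expected)) {
    stop(sprintf("class %s model expects %d-mers", model$hla_class, expected))
  }
  has_x <- grepl("X", peptides, fixed = TRUE)
  n <- length(peptides)
  if (model$hla_class == "I") {
    ln <- rep(NA_real_, n)
    if (any(!has_x)) ln[!has_x] <- pssm_score(peptides[!has_x], model$W, model$b)
    out <- data.frame(peptide = peptides, allele = model$allele,
                      ic50 = exp(ln), ln_ic50 = ln, stringsAsFactors = FALSE)
  } else {
    scores <- matrix(NA_real_, nrow = n, ncol = 7L)
    ok <- !has_x
    for (off in 0:6) {
      cores <- substr(peptides, off + 1L, off + 9L)
      if (any(ok)) scores[ok, off + 1L] <- pssm_score(cores[ok], model$W, model$b)
    }
    ln <- rep(NA_real_, n); best <- rep(NA_integer_, n)
    if (any(ok)) {
      ln[ok] <- do.call(pmin, as.data.frame(scores[ok, , drop = FALSE]))
      best[ok] <- max.col(-scores[ok, , drop = FALSE], ties.method = "first") - 1L
    }
    out <- data.frame(peptide = peptides, allele = model$allele,
                      ic50 = exp(ln), ln_ic50 = ln, core_offset = best,
                      stringsAsFactors = FALSE)
  }
  out
}

#' Standardize predicted affinities within patient (and compartment)
#'
#' Adds a `std_ln_ic50` column: the Johnson-standardized `ln_ic50` within
#' each (patient, compartment) group (default) or within patient only, per
#' allele. Standardization is monotone within each group, so thresholds on
#' the standardized scale select group-specific tails.
#'
#' @param predictions Data.frame with `patient_id`, `compartment`, `allele`,
#'   `ln_ic50`.
#' @param within `"patient_compartment"` (default) or `"patient"`.
#' @return `predictions` with `std_ln_ic50` added; attribute
#'   `"standardization_methods"` records the method per group.
#' @export
standardize_affinity <- function(predictions,
                                 within = c("patient_compartment", "patient")) {
  within <- match.arg(within)
  grp <- if (within == "patient_compartment") {
    paste(predictions$patient_id, predictions$compartment, predictions$allele,
          sep = "\r")
  } else {
    paste(predictions$patient_id, predictions$allele, sep = "\r")
  }
  ok <- !is.na(predictions$ln_ic50)
  std <- rep(NA_real_, nrow(predictions))
  z <- group_standardize(predictions$ln_ic50[ok], grp[ok])
  std[ok] <- z
  predictions$std_ln_ic50 <- std
  attr(predictions, "standardization_methods") <- attr(z, "methods")
  predictions
}

#' Patient-specific best-allele affinity
#'
#' For each fragment, returns the prediction with the minimum standardized
#' ln(IC50) (= highest predicted affinity) among the patient's one or two
#' alleles at the locus. Ties keep the first allele in genotype order, with
#' a message.
#'
#' @param predictions Data.frame with `fragment_id`, `allele`,
#'   `std_ln_ic50` for a single patient.
#' @param genotype Character vector of the patient's allele name(s) at the
#'   locus, in genotype order (length 1 or 2).
#' @return One row per fragment: `fragment_id`, `allele`, `std_ln_ic50`.
#' @export
best_patient_allele <- function(predictions, genotype) {
  genotype <- unique(genotype)
  stopifnot(length(genotype) >= 1L, length(genotype) <= 2L)
  missing_alleles <- setdiff(genotype, unique(predictions$allele))
  if (length(missing_alleles)) {
    stop("missing affinity predictions for allele(s): ",
         paste(missing_alleles, collapse = ", "))
  }
  sub <- predictions[predictions$allele %in% genotype, , drop = FALSE]
  ## order: by fragment, then std value, then genotype order for ties
  sub$.allele_rank <- match(sub$allele, genotype)
  o <- order(sub$fragment_id, sub$std_ln_ic50, sub$.allele_rank)
  sub <- sub[o, , drop = FALSE]
  first <- !duplicated(sub$fragment_id)
  if (length(genotype) == 2L) {
    ties <- tapply(sub$std_ln_ic50, sub$fragment_id,
                   function(v) length(v) == 2L && v[1] == v[2])
    if (any(ties)) {
      message(sprintf("%d fragment(s) tied between alleles; keeping genotype order",
                      sum(ties)))
    }
  }
  res <- sub[first, c("fragment_id", "allele", "std_ln_ic50"), drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-position affinity profile
#'
#' Mean standardized ln(IC50) per CDR3-relative position with a normal
#' approximation 95% confidence interval, trimmed to the central mass of
#' fragment positions (default 99%, the plotting convention for these
#' profiles).
#'
#' @param predictions Data.frame with `cdr3_relative_position` and a value
#'   column.
#' @param value Name of the value column (default `"std_ln_ic50"`).
#' @param trim Two quantiles of the position distribution to keep
#'   (default `c(0.005, 0.995)`); `NULL` keeps everything.
#' @return Data.frame `cdr3_relative_position`, `mean`, `lower`, `upper`,
#'   `n` (CI is `NA` for single-value positions).
#' @export
position_profile <- function(predictions, value = "std_ln_ic50",
                             trim = c(0.005, 0.995)) {
  v <- predictions[[value]]
  pos <- predictions$cdr3_relative_position
  keep <- !is.na(v)
  v <- v[keep]; pos <- pos[keep]
  if (!is.null(trim)) {
    qs <- quantile(pos, trim, type = 1)
    sel <- pos >= qs[1] & pos <= qs[2]
    v <- v[sel]; pos <- pos[sel]
  }
  stats_by <- tapply(v, pos, mean_ci)
  out <- do.call(rbind, stats_by)
  data.frame(cdr3_relative_position = as.integer(names(stats_by)),
             mean = out[, "mean"], lower = out[, "lower"],
             upper = out[, "upper"], n = as.integer(out[, "n"]),
             row.names = NULL)
}

#' Read a patient HLA genotype table
#'
#' Parses a genotype TSV with columns `patient_id`, `locus`, `allele1`,
#' `allele2` (heterodimeric DQ/DP alleles written as alpha-beta pairs, e.g.
#' `DQA1*01:02-DQB1*06:02`). The package ships the published genotype table
#' of the 11 + 6 study patients as
#' `system.file("extdata", "patient_hla_genotypes.tsv", package = "idiotope")`.
#'
#' @param path TSV path.
#' @return Data.frame `patient_id`, `locus`, `allele1`, `allele2`.
#' @export
read_genotypes <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(g))) {
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  }
  g
}

#' Alleles of one patient at one locus
#'
#' @param genotypes Genotype table from [read_genotypes()].
#' @param patient_id Patient code.
#' @param locus Locus name (e.g. `"DRB1"`).
#' @return Character vector of 1-2 allele names in genotype order.
#' @export
patient_alleles <- function(genotypes, patient_id, locus) {
  row <- genotypes[genotypes$patient_id == patient_id & genotypes$locus == locus, ]
  if (nrow(row) == 0L) stop("no genotype for ", patient_id, " at ", locus)
  unique(c(row$allele1[1], row$allele2[1]))
}
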