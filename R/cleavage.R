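## cathepsin S/L/B cleavage prediction over octamer windows, high-probability
## site calls, and the fuzzy-logic peptide excision rule.
##
## Octamer convention: residues ordered P4 P3 P2 P1 P1' P2' P3' P4', the
## scissile bond lying between window residues 4 and 5. A window's
## `bond_index` b is the 0-based index of its P1 residue in the parent
## sequence; cleavage at bond b cuts between residues b and b+1, so the P1'
## residue has index b+1. Bonds without a full octamer (sequence ends,
## windows containing X) have no defined probability and are treated as
## probability 0 wherever a terminal maximum is taken.

CATHEPSINS <- c("cathepsin_S", "cathepsin_L", "cathepsin_B")

#' Enumerate octamer windows of a sequence
#'
#' @param sequence Single amino-acid string.
#' @return Data.frame with `bond_index` (0-based index of P1; the scissile
#'   bond is between `bond_index` and `bond_index + 1`) and `octamer`.
#'   Sequences shorter than 8 residues yield an empty frame.
#' @export
octamer_windows <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 8L) {
    return(data.frame(bond_index = integer(0), octamer = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- seq_len(L - 7L)
  data.frame(bond_index = start + 2L,            # P1 = 4th window residue, 0-based
             octamer = substring(sequence, start, start + 7L),
             stringsAsFactors = FALSE)
}

#' Train a reference cleavage predictor
#'
#' Fits an ensemble of regularized additive position-specific models
#' (ridge-penalized logistic regression on one-hot octamer positions, one
#' member per bootstrap resample) to labeled octamer cleavage data, and
#' evaluates discrimination on a held-out split. The ensemble sits behind the
#' same predictor contract a neural model would: octamer in, median cleavage
#' probability out.
#'
#' @param octamers Character vector of 8-mers over the 20-letter alphabet.
#' @param cleaved Integer/logical labels (both classes must be present).
#' @param enzyme Enzyme label (one of `r toString(CATHEPSINS)`).
#' @param ensemble_size Number of bootstrap members.
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @param lambda Ridge penalty.
#' @param holdout Fraction held out for AUROC evaluation.
#' @return An object of class `cleavage_model` with elements `enzyme`,
#'   `members` (list of 20 x 8 weight matrices plus intercepts),
#'   `holdout_auroc`.
#' @export
train_cleavage_model <- function(octamers, cleaved,
                                 enzyme = CATHEPSINS,
                                 ensemble_size = 5L, seed = 1L,
                                 lambda = 0.001, holdout = 0.2) {
  enzyme <- match.arg(enzyme)
  stopifnot(length(octamers) == length(cleaved), all(nchar(octamers) == 8L))
  y <- as.integer(cleaved)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  set.seed(seed)
  n <- length(octamers)
  test <- sample.int(n, size = max(1L, round(holdout * n)))
  train <- setdiff(seq_len(n), test)
  X <- onehot_design(octamers, 8L)
  members <- vector("list", ensemble_size)
  for (m in seq_len(ensemble_size)) {
    boot <- sample(train, length(train), replace = TRUE)
    if (length(unique(y[boot])) < 2L) boot <- train  # degenerate resample
    fit <- glmnet::glmnet(X[boot, , drop = FALSE], y[boot],
                          family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    members[[m]] <- coef_to_pssm(fit, 8L)
  }
  model <- structure(list(enzyme = enzyme, members = members,
                          n_train = length(train)),
                     class = "cleavage_model")
  ho <- member_median(model, octamers[test])
  model$holdout_auroc <- auroc(ho, y[test])
  model
}

## one-hot sparse design matrix for k equal-length peptide positions
onehot_design <- function(peptides, k) {
  n <- length(peptides)
  i <- rep(seq_len(n), k)
  j <- integer(n * k)
  for (p in seq_len(k)) {
    aa <- match(substr(peptides, p, p), AA_ALPHABET)
    if (anyNA(aa)) stop("peptide contains characters outside the 20-letter alphabet")
    j[((p - 1L) * n + 1L):(p * n)] <- (p - 1L) * 20L + aa
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, k * 20L))
}

coef_to_pssm <- function(fit, k) {
  co <- as.numeric(glmnet::coef.glmnet(fit))
  W <- matrix(co[-1L], nrow = 20L, ncol = k,
              dimnames = list(AA_ALPHABET, NULL))
  list(W = W, b = co[1L])
}

## median over ensemble members of per-peptide probabilities; NA for
## peptides containing non-alphabet characters
member_median <- function(model, peptides) {
  probs <- vapply(model$members, function(mem) {
    plogis(pssm_score(peptides, mem$W, mem$b))
  }, numeric(length(peptides)))
  if (length(peptides) == 1L) probs <- matrix(probs, nrow = 1L)
  apply(probs, 1L, median)
}

#' Predict per-bond cleavage probabilities
#'
#' Scores every octamer window of each sequence with the model ensemble and
#' reports the ensemble-median cleavage probability per scissile bond.
#' Windows containing `X` get `NA`.
#'
#' @param model A `cleavage_model` (trained reference model, or a ground
#'   truth model from [true_cleavage_model()]).
#' @param sequences Character vector of sequences.
#' @param gi Sequence identifiers (defaults to names or indices).
#' @return Data.frame `parent_gi`, `bond_index`, `enzyme`, `probability`.
#' @export
predict_cleavage <- function(model, sequences, gi = NULL) {
  stopifnot(inherits(model, "cleavage_model"))
  if (is.null(model$members) || length(model$members) == 0L) {
    stop("untrained cleavage model")
  }
  if (is.null(gi)) gi <- if (!is.null(names(sequences))) names(sequences) else as.character(seq_along(sequences))
  win <- lapply(seq_along(sequences), function(i) {
    w <- octamer_windows(sequences[i])
    if (nrow(w)) w$parent_gi <- gi[i]
    w
  })
  win <- do.call(rbind, win)
  if (is.null(win) || nrow(win) == 0L) {
    return(data.frame(parent_gi = character(0), bond_index = integer(0),
                      enzyme = character(0), probability = numeric(0)))
  }
  ok <- !grepl("X", win$octamer, fixed = TRUE)
  prob <- rep(NA_real_, nrow(win))
  if (any(ok)) prob[ok] <- member_median(model, win$octamer[ok])
  data.frame(parent_gi = win$parent_gi, bond_index = win$bond_index,
             enzyme = model$enzyme, probability = prob,
             stringsAsFactors = FALSE)
}

#' Call high-probability cleavage sites
#'
#' A bond is called a cleavage site when its ensemble-median probability is
#' strictly above the threshold (default 0.8).
#'
#' @param profile Per-bond probability frame from [predict_cleavage()].
#' @param threshold Strict probability threshold.
#' @return `profile` with a logical `site_call` column (`NA` probabilities
#'   are never calls).
#' @export
call_cleavage_sites <- function(profile, threshold = 0.8) {
  profile$site_call <- !is.na(profile$probability) & profile$probability > threshold
  profile
}

#' Fuzzy-logic excision calls for fragments
#'
#' A fragment is called *excised* when cathepsin cleavage can free it with at
#' most three extra residues at either end: the maximum cleavage probability
#' over the four bonds releasing its N-terminus (N-terminus minus three
#' residues up to the terminus itself) and likewise for the C-terminus are
#' taken, and the call requires the larger to be >= 0.5 with >= 0.25
#' simultaneously at the other end. Implied excised peptides therefore range
#' from k to k+6 residues for a k-mer core. Undefined bonds contribute
#' probability 0.
#'
#' @param fragments Fragment table from [make_fragments()].
#' @param profile Per-bond probabilities for the fragments' parents
#'   (single enzyme).
#' @return `fragments` with `n_term_max_prob`, `c_term_max_prob`, `excised`.
#' @export
call_excision <- function(fragments, profile) {
  stopifnot(length(unique(profile$enzyme)) <= 1L)
  key <- paste(profile$parent_gi, profile$bond_index, sep = "\r")
  p <- ifelse(is.na(profile$probability), 0, profile$probability)
  lookup <- function(gi, bond) {
    v <- p[match(paste(gi, bond, sep = "\r"), key)]
    ifelse(is.na(v), 0, v)
  }
  gi <- fragments$parent_gi
  s <- fragments$start
  e <- s + fragments$length                      # exclusive end
  ## N-terminal cut between residues b and b+1 frees position b+1: bonds s-4..s-1
  nmax <- lookup(gi, s - 4L)
  for (d in -3:-1) nmax <- pmax(nmax, lookup(gi, s + d))
  ## C-terminal cut after last residue: bonds e-1 .. e+2
  cmax <- lookup(gi, e - 1L)
  for (d in 0:2) cmax <- pmax(cmax, lookup(gi, e + d))
  fragments$n_term_max_prob <- nmax
  fragments$c_term_max_prob <- cmax
  fragments$excised <- excision_rule(nmax, cmax)
  fragments
}

#' The excision decision rule
#'
#' @param n_term_max,c_term_max Terminal maximum cleavage probabilities.
#' @return Logical: `max >= 0.5` at either terminal with `>= 0.25`
#'   simultaneously at the other.
#' @export
excision_rule <- function(n_term_max, c_term_max) {
  pmax(n_term_max, c_term_max) >= 0.5 & pmin(n_term_max, c_term_max) >= 0.25
}

#' Per-position cleavage-site proportions
#'
#' Proportion of covered bonds called as cleavage sites at each CDR3-relative
#' position. Positions are indexed by the P1' residue (the residue freed as a
#' new N-terminus), i.e. `bond_index + 1 - cdr3_start`.
#'
#' @param profile Per-bond probabilities (single enzyme) from
#'   [predict_cleavage()].
#' @param repertoire Repertoire frame supplying `gi` and `cdr3_start`.
#' @param threshold Site-call threshold (strict).
#' @return Data.frame `cdr3_relative_position`, `n`, `proportion`.
#' @export
cleavage_position_profile <- function(profile, repertoire, threshold = 0.8) {
  cs <- repertoire$cdr3_start[match(profile$parent_gi, repertoire$gi)]
  pos <- profile$bond_index + 1L - cs
  call <- !is.na(profile$probability) & profile$probability > threshold
  n <- tapply(call, pos, length)
  prop <- tapply(call, pos, mean)
  data.frame(cdr3_relative_position = as.integer(names(n)),
             n = as.integer(n), proportion = as.numeric(prop))
}
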