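## The composite idiotope score: a 15-mer fragment qualifies when it is
## (1) predicted excised by cathepsin S, (2) binds the patient's best DRB1
## allele with standardized ln(IC50) below -1.5, and (3) carries a rare
## (FC > 16) TCEM IIa or IIb motif. All three prerequisites of
## idiotope-driven T-B collaboration must hold simultaneously.

#' Default idiotope-score thresholds
#'
#' @return List with `affinity` (standardized ln(IC50) strict upper bound,
#'   -1.5), `fc` (strict FC rarity threshold, 16), and the excision rule's
#'   `excision_major` (0.5) and `excision_minor` (0.25).
#' @export
idiotope_thresholds <- function() {
  list(affinity = -1.5, fc = 16L, excision_major = 0.5, excision_minor = 0.25)
}

#' Score fragments for idiotope qualification
#'
#' Joins excision calls, best-allele standardized affinities and TCEM IIa/IIb
#' frequency classes per 15-mer fragment into a call table. A fragment with
#' any missing ingredient is emitted with `qualifies = NA` and counted in a
#' message.
#'
#' @param fragments 15-mer fragment table (columns `fragment_id`,
#'   `patient_id`, `compartment`, `cdr3_relative_position`,
#'   `highly_transcribed`, `parent_gi`).
#' @param excision Data.frame `fragment_id`, `excised` (cathepsin S calls
#'   from [call_excision()]).
#' @param affinity Data.frame `fragment_id`, `std_ln_ic50` (patient-specific
#'   best DRB1, from [best_patient_allele()]).
#' @param fc_iia,fc_iib Data.frames `fragment_id`, `fc` for TCEM IIa and IIb.
#' @param thresholds See [idiotope_thresholds()].
#' @return Call table: the fragment columns plus `excised_S`,
#'   `high_affinity`, `rare_tcem`, `qualifies`.
#' @export
score_fragments <- function(fragments, excision, affinity, fc_iia, fc_iib,
                            thresholds = idiotope_thresholds()) {
  id <- fragments$fragment_id
  exc <- excision$excised[match(id, excision$fragment_id)]
  aff <- affinity$std_ln_ic50[match(id, affinity$fragment_id)]
  f_a <- fc_iia$fc[match(id, fc_iia$fragment_id)]
  f_b <- fc_iib$fc[match(id, fc_iib$fragment_id)]
  out <- fragments[, intersect(c("fragment_id", "parent_gi", "patient_id",
                                 "compartment", "cdr3_relative_position",
                                 "highly_transcribed", "ighv_family"),
                               names(fragments)), drop = FALSE]
  out$excised_S <- exc
  out$high_affinity <- !is.na(aff) & aff < thresholds$affinity
  out$high_affinity[is.na(aff)] <- NA
  rare <- function(f) !is.na(f) & f > thresholds$fc
  ## rare if either class II motif is rare; NA only when both are missing
  r <- rare(f_a) | rare(f_b)
  r[is.na(f_a) & is.na(f_b)] <- NA
  out$rare_tcem <- r
  out$qualifies <- out$excised_S & out$high_affinity & out$rare_tcem
  n_missing <- sum(is.na(out$qualifies))
  if (n_missing > 0L) {
    message(sprintf("%d fragment(s) with missing inputs: qualifies undefined",
                    n_missing))
  }
  out
}

#' Per-position criterion proportions
#'
#' Proportion of fragments fulfilling each criterion, and all criteria
#' jointly, at every CDR3-relative position, optionally stratified. The
#' composite proportion is bounded above by each per-criterion proportion at
#' every position (conjunction bound).
#'
#' @param calls Call table from [score_fragments()].
#' @param strata Character vector of stratification column names (optional).
#' @return Data.frame with position, stratum columns, `n`, and per-criterion
#'   and composite proportions with normal-approximation 95% CIs for the
#'   composite.
#' @export
position_proportions <- function(calls, strata = NULL) {
  calls <- calls[!is.na(calls$qualifies), , drop = FALSE]
  keyparts <- list(position = calls$cdr3_relative_position)
  for (s in strata) keyparts[[s]] <- calls[[s]]
  key <- do.call(paste, c(keyparts, sep = "\r"))
  split_idx <- split(seq_len(nrow(calls)), key)
  rows <- lapply(split_idx, function(ii) {
    sub <- calls[ii, , drop = FALSE]
    n <- nrow(sub)
    p <- mean(sub$qualifies)
    se <- sqrt(p * (1 - p) / n)
    row <- data.frame(cdr3_relative_position = sub$cdr3_relative_position[1],
                      n = n,
                      p_excised = mean(sub$excised_S),
                      p_high_affinity = mean(sub$high_affinity),
                      p_rare_tcem = mean(sub$rare_tcem),
                      p_qualifies = p,
                      lower = max(0, p - 1.96 * se),
                      upper = min(1, p + 1.96 * se))
    for (s in strata) row[[s]] <- sub[[s]][1]
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cdr3_relative_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Odds ratio from a 2x2 qualification table
#'
#' @param a,b Qualifying / non-qualifying counts in group 1.
#' @param c,d Qualifying / non-qualifying counts in group 2.
#' @param continuity Add 0.5 to every cell when any cell is zero (flagged).
#' @return List `or`, `lower`, `upper` (Woolf 95% CI on the log scale),
#'   `continuity_corrected`.
#' @export
odds_ratio <- function(a, b, c, d, continuity = TRUE) {
  corrected <- FALSE
  if (continuity && any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       lower = exp(log(or) - 1.96 * se),
       upper = exp(log(or) + 1.96 * se),
       continuity_corrected = corrected)
}

#' Sequence-level qualification and group comparison
#'
#' A sequence qualifies when at least one of its fragments qualifies.
#' Reports per-group qualification rates, the unadjusted odds ratio from the
#' 2x2 table, and a patient-stratified Mantel-Haenszel odds ratio as the
#' stand-in for a random-effects adjustment.
#'
#' @param calls Call table from [score_fragments()].
#' @param group Name of the column in `calls` defining the two groups
#'   (logical or two-level).
#' @return List with `sequences` (per-sequence data.frame), `rates`
#'   (per-group qualification rates), `or` (unadjusted, see [odds_ratio()]),
#'   and `mh` (Mantel-Haenszel estimate, `NULL` when inestimable).
#' @export
sequence_qualification <- function(calls, group = "highly_transcribed") {
  calls <- calls[!is.na(calls$qualifies), , drop = FALSE]
  agg <- aggregate(calls$qualifies,
                   by = list(parent_gi = calls$parent_gi,
                             patient_id = calls$patient_id,
                             grp = calls[[group]]),
                   FUN = any)
  names(agg)[4] <- "qualifies"
  lv <- sort(unique(agg$grp), decreasing = TRUE)   # TRUE / first level = group 1
  if (length(lv) != 2L) stop("grouping column must have exactly two levels")
  g1 <- agg$grp == lv[1]
  a <- sum(agg$qualifies[g1]);  b <- sum(!agg$qualifies[g1])
  c <- sum(agg$qualifies[!g1]); d <- sum(!agg$qualifies[!g1])
  rates <- c(a / (a + b), c / (c + d))
  names(rates) <- as.character(lv)
  mh <- NULL
  if (length(unique(agg$patient_id)) > 1L) {
    tab <- table(factor(agg$grp, levels = lv),
                 factor(agg$qualifies, levels = c(TRUE, FALSE)),
                 agg$patient_id)
    ok <- apply(tab, 3L, function(t2) all(rowSums(t2) > 0))
    tab <- tab[, , ok, drop = FALSE]
    mh <- tryCatch(
      suppressWarnings(mantelhaen.test(tab, correct = FALSE)),
      error = function(e) NULL)
  }
  list(sequences = agg, rates = rates,
       or = odds_ratio(a, b, c, d),
       mh = if (!is.null(mh)) list(or = unname(mh$estimate),
                                   p = mh$p.value) else NULL)
}
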