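## Statistical subset construction, per-position two-group comparisons with
## Benjamini-Hochberg control, TCEM-occurrence correlation clustering, and
## per-family heterogeneity summaries.

## FW3 spans roughly 32 residues immediately preceding the CDR3-opening
## cysteine (IMGT amino acids ~73-104, the anchor cysteine being 104).
FW3_SPAN <- 31L

#' Build a statistical fragment subset
#'
#' Three subsets mirror the comparisons the pipeline supports:
#' \describe{
#'   \item{`cdr3_overlap`}{fragments with roughly half their residues inside
#'     CDR3: N-terminus position >= -7, and at most 8 appended
#'     constant-region residues (requires full augmentation).}
#'   \item{`fw3_vs_cdr3`}{fragments spanning FW3 and CDR3 (position >=
#'     `-FW3_SPAN`), at most `max_added` appended residues, labeled by
#'     region with the CDR3-influence cutoff at -7 (intended for short
#'     DTR/GTL augmentation).}
#'   \item{`blood_vs_csf`}{unaugmented fragments only (no appended
#'     residues), labeled by region as above, for blood-CSF comparisons.}
#' }
#'
#' @param fragments Fragment table from [make_fragments()].
#' @param subset Subset name.
#' @param cdr3_cutoff Position at and above which a fragment is considered
#'   CDR3-influenced (default -7).
#' @param max_added Maximum appended residues tolerated (default 8).
#' @return Filtered fragment table; subsets 2 and 3 gain a `region` column
#'   (`"FW3"` / `"CDR3"`). Counts of included/excluded fragments are
#'   reported in a message.
#' @export
build_subset <- function(fragments,
                         subset = c("cdr3_overlap", "fw3_vs_cdr3", "blood_vs_csf"),
                         cdr3_cutoff = -7L, max_added = 8L) {
  subset <- match.arg(subset)
  pos <- fragments$cdr3_relative_position
  keep <- switch(subset,
    cdr3_overlap = pos >= cdr3_cutoff & fragments$n_added_residues <= max_added,
    fw3_vs_cdr3  = pos >= -FW3_SPAN & fragments$n_added_residues <= max_added,
    blood_vs_csf = pos >= -FW3_SPAN & fragments$n_added_residues == 0L)
  out <- fragments[keep, , drop = FALSE]
  if (subset %in% c("fw3_vs_cdr3", "blood_vs_csf")) {
    out$region <- ifelse(out$cdr3_relative_position >= cdr3_cutoff, "CDR3", "FW3")
  }
  message(sprintf("subset %s: %d fragments kept, %d excluded",
                  subset, nrow(out), sum(!keep)))
  out
}

#' Per-position two-group comparisons with FDR control
#'
#' Welch two-sample t-test of the value between the two groups at every
#' CDR3-relative position, with Benjamini-Hochberg adjustment over the
#' vector of per-position p-values and decisions at FDR `q` (default 20%).
#' Positions where both groups are constant and equal are reported with
#' `t = 0, p = 1`; positions with fewer than `min_n` values in either group
#' are skipped and listed in the `skipped` attribute.
#'
#' @param data Data.frame with `cdr3_relative_position`, a value column and
#'   a two-level group column.
#' @param value,group Column names.
#' @param q FDR level (default 0.2).
#' @param min_n Minimum per-group size per position (default 2).
#' @return Data.frame per position: group means, `diff` (group1 - group2),
#'   CI of the difference, `t`, `p`, `p_adj`, `significant`.
#' @export
per_position_tests <- function(data, value, group, q = 0.2, min_n = 2L) {
  g <- data[[group]]
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("grouping column must have exactly two levels")
  v <- data[[value]]
  pos <- data$cdr3_relative_position
  skipped <- integer(0)
  rows <- list()
  for (p0 in sort(unique(pos))) {
    x <- v[pos == p0 & g == lev[1]]
    y <- v[pos == p0 & g == lev[2]]
    if (length(x) < min_n || length(y) < min_n) {
      skipped <- c(skipped, p0)
      next
    }
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = 0, p.value = 1, conf.int = c(0, 0))
    } else if (sd(x) == 0 && sd(y) == 0) {
      ## distinct constants: certain difference under this test's model
      tt <- list(statistic = Inf, p.value = 0,
                 conf.int = rep(mean(x) - mean(y), 2))
    } else {
      t0 <- t.test(x, y, var.equal = FALSE)
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value,
                 conf.int = as.numeric(t0$conf.int))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cdr3_relative_position = p0,
      mean_1 = mean(x), mean_2 = mean(y),
      n_1 = length(x), n_2 = length(y),
      diff = mean(x) - mean(y),
      ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
      t = tt$statistic, p = tt$p.value)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cdr3_relative_position = integer(0))
  } else {
    out$p_adj <- p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj <= q
  }
  attr(out, "groups") <- as.character(lev)
  attr(out, "skipped") <- skipped
  out
}

#' Correlation clustering of TCEM occurrence profiles
#'
#' Pearson (or Spearman) correlations between the motif-count columns of a
#' motif x group matrix, clustered agglomeratively with average linkage on
#' `1 - r`. Columns are pre-sorted by label so the leaf order is
#' deterministic; zero-variance columns are excluded with a warning.
#'
#' @param mat Motif x group matrix from [motif_occurrence_matrix()].
#' @param method Correlation type (default `"pearson"`).
#' @return List with `correlation` (symmetric matrix), `hclust`,
#'   `leaf_order` (labels), `newick` (dendrogram as a Newick string).
#' @export
cluster_tcem_occurrences <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  v <- apply(mat, 2L, sd)
  if (any(v == 0)) {
    warning("excluding zero-variance group column(s): ",
            paste(colnames(mat)[v == 0], collapse = ", "))
    mat <- mat[, v > 0, drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need at least 2 groups with nonzero variance")
  r <- cor(mat, method = method)
  hc <- hclust(as.dist(1 - r), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(correlation = r, hclust = hc,
       leaf_order = hc$labels[hc$order], newick = newick)
}

#' Per-family summaries with a Welch heterogeneity test
#'
#' Mean, 95% CI and n of a value per IGHV family, plus the Welch ANOVA
#' statistic and p-value across families (delegated to
#' [stats::oneway.test()]). With fewer than two usable families the
#' statistic is reported as `NA`.
#'
#' @param data Data.frame with an `ighv_family` column and a value column.
#' @param value Value column name.
#' @return List `summary` (per-family data.frame) and `welch`
#'   (`statistic`, `df`, `df_denom`, `p`; `NA` when undefined).
#' @export
family_summary <- function(data, value) {
  v <- data[[value]]
  fam <- data$ighv_family
  per <- do.call(rbind, tapply(v, fam, mean_ci))
  summary <- data.frame(ighv_family = rownames(per), per, row.names = NULL)
  usable <- names(which(tapply(v, fam, function(x) length(x) >= 2L && sd(x) > 0)))
  welch <- list(statistic = NA_real_, df = NA_real_, df_denom = NA_real_,
                p = NA_real_)
  if (length(usable) >= 2L) {
    sub <- data[fam %in% usable, , drop = FALSE]
    w <- tryCatch(oneway.test(sub[[value]] ~ factor(sub$ighv_family),
                              var.equal = FALSE),
                  error = function(e) NULL)
    if (!is.null(w)) {
      welch <- list(statistic = unname(w$statistic),
                    df = unname(w$parameter[1]),
                    df_denom = unname(w$parameter[2]),
                    p = w$p.value)
    }
  }
  list(summary = summary, welch = welch)
}
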