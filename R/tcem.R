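## T cell-exposed motifs (TCEMs) and their frequency classification.
##
## A TCEM is the 5-residue subset of an HLA-bound peptide contacting the
## T-cell receptor. Three patterns are used: TCEM I on 9-mers (HLA class I)
## and TCEM IIa/IIb on 15-mers (HLA class II). For 15-mers the binding core
## is taken as the central 9-mer, numbered 1-9, with N-flank positions
## -2, -1, 0 (15-mer residues 1, 2, 3) and C-flank 10, 11, 12. TCEM IIa uses
## core positions {2,3,5,7,8}; TCEM IIb replaces the first of these with the
## -1 flank residue: {flank -1, core 3,5,7,8}. TCEM I uses residues 4-8 of
## the 9-mer. Residues are concatenated in ascending position order.

TCEM_CLASSES <- c("I", "IIa", "IIb")

## 1-based residue indices into the fragment, per class
tcem_residue_indices <- function(tcem_class) {
  switch(tcem_class,
    I   = c(4L, 5L, 6L, 7L, 8L),
    IIa = c(5L, 6L, 8L, 10L, 11L),               # core 2,3,5,7,8
    IIb = c(2L, 6L, 8L, 10L, 11L),               # flank -1, core 3,5,7,8
    stop("unknown TCEM class: ", tcem_class))
}

#' Extract TCEM motifs from fragments
#'
#' @param peptides 9-mers (class `"I"`) or 15-mers (classes `"IIa"`,
#'   `"IIb"`); wrong lengths are an error.
#' @param tcem_class One of `"I"`, `"IIa"`, `"IIb"`.
#' @return Character vector of 5-residue motifs.
#' @export
extract_tcem <- function(peptides, tcem_class = TCEM_CLASSES) {
  tcem_class <- match.arg(tcem_class)
  expected <- if (tcem_class == "I") 9L else 15L
  if (length(peptides) && any(nchar(peptides) != expected)) {
    stop(sprintf("TCEM %s requires %d-mer fragments", tcem_class, expected))
  }
  idx <- tcem_residue_indices(tcem_class)
  out <- substr(peptides, idx[1], idx[1])
  for (i in idx[-1]) out <- paste0(out, substr(peptides, i, i))
  out
}

#' Size of the TCEM motif space
#'
#' @param alphabet_size Number of residues (default 20).
#' @return `alphabet_size ^ 5` (3.2 million for the amino-acid alphabet).
#' @export
tcem_motif_space <- function(alphabet_size = 20L) as.numeric(alphabet_size)^5

#' Enumerate all TCEM motifs over an alphabet
#'
#' Full enumeration of the 5-position motif space; intended for small toy
#' alphabets (the 20-letter space has 3.2 million motifs).
#'
#' @param alphabet Character vector of residues.
#' @return Character vector of all `length(alphabet)^5` motifs.
#' @export
enumerate_tcem_motifs <- function(alphabet = AA_ALPHABET) {
  g <- expand.grid(p5 = alphabet, p4 = alphabet, p3 = alphabet,
                   p2 = alphabet, p1 = alphabet, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
}

#' Frequency-class occurrence denominator
#'
#' The frequency class (FC) is a reverse log2 rarity scale: FC f corresponds
#' to a motif occurring once every `2^f` sequences (FC 0 = every sequence,
#' FC 16 = once every 65,536, FC 21 = once every ~2 million).
#'
#' @param fc Integer frequency class.
#' @return `2^fc`.
#' @export
fc_occurrence_denominator <- function(fc) 2^fc

#' Frequency class from an occurrence frequency
#'
#' @param frequency Occurrence frequency in (0, 1].
#' @param cap Deepest class (default 21).
#' @return Integer FC: `-log2(frequency)` rounded half-up, clamped to
#'   `[0, cap]`.
#' @export
fc_from_frequency <- function(frequency, cap = 21L) {
  stopifnot(all(frequency > 0), all(frequency <= 1))
  pmin(cap, pmax(0, round_half_up(-log2(frequency))))
}

#' Build a TCEM frequency-class database from a repertoire
#'
#' For each motif, the occurrence frequency within every
#' (patient/donor x compartment) group is the number of distinct sequences
#' in the group whose fragments contain the motif, divided by the total
#' number of distinct sequences in the group. The motif's frequency class is
#' the mean of `-log2(frequency)` over the groups where it occurs, rounded
#' half-up and capped at 21.
#'
#' @param fragments Fragment table (9-mers for class I, 15-mers for IIa/IIb)
#'   carrying `parent_gi`, `patient_id`, `compartment`.
#' @param tcem_class TCEM class.
#' @param denominator `"sequences"` (default; matches the once-every-N-
#'   sequences reading of the scale) or `"fragments"` for sensitivity
#'   analysis.
#' @param cap FC cap (default 21).
#' @return Object of class `tcem_fc_db`: list with `tcem_class`, `table`
#'   (data.frame `motif`, `n_groups`, `mean_neg_log2_freq`, `fc`),
#'   `group_sizes`.
#' @export
build_fc_database <- function(fragments, tcem_class = TCEM_CLASSES,
                              denominator = c("sequences", "fragments"),
                              cap = 21L) {
  tcem_class <- match.arg(tcem_class)
  denominator <- match.arg(denominator)
  expected <- if (tcem_class == "I") 9L else 15L
  fragments <- fragments[fragments$length == expected, , drop = FALSE]
  if (nrow(fragments) == 0L) stop("empty repertoire: no fragments of length ", expected)
  motif <- extract_tcem(fragments$sequence, tcem_class)
  group <- paste(fragments$patient_id, fragments$compartment, sep = "|")
  if (denominator == "sequences") {
    key <- paste(group, motif, fragments$parent_gi, sep = "\r")
    first <- !duplicated(key)
    counts <- table(paste(group[first], motif[first], sep = "\r"))
    sizes <- tapply(fragments$parent_gi, group,
                    function(g) length(unique(g)))
  } else {
    counts <- table(paste(group, motif, sep = "\r"))
    sizes <- table(group)
  }
  gm <- strsplit(names(counts), "\r", fixed = TRUE)
  g <- vapply(gm, `[`, character(1), 1L)
  m <- vapply(gm, `[`, character(1), 2L)
  freq <- as.numeric(counts) / as.numeric(sizes[g])
  neg_log2 <- -log2(freq)
  mean_nl2 <- tapply(neg_log2, m, mean)
  n_groups <- tapply(neg_log2, m, length)
  tab <- data.frame(motif = names(mean_nl2),
                    n_groups = as.integer(n_groups),
                    mean_neg_log2_freq = as.numeric(mean_nl2),
                    fc = as.integer(pmin(cap, pmax(0, round_half_up(as.numeric(mean_nl2))))),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(tcem_class = tcem_class, table = tab,
                 group_sizes = sizes, denominator = denominator, cap = cap),
            class = "tcem_fc_db")
}

#' Look up frequency classes and rarity for query motifs
#'
#' A motif is *rare* when its FC is strictly above the rarity threshold
#' (default 16, i.e. occurring less than once every 65,536 sequences).
#' Motifs absent from the database are handled per `missing_policy`:
#' `"cap"` (default) assigns the cap class (21) and flags them unobserved;
#' `"na"` leaves them `NA`.
#'
#' @param motifs Character vector of 5-residue motifs.
#' @param db A `tcem_fc_db`.
#' @param rare_threshold Strict FC threshold for rarity (default 16).
#' @param missing_policy `"cap"` or `"na"`.
#' @return Data.frame `motif`, `fc`, `rare`, `unobserved`.
#' @export
assign_fc <- function(motifs, db, rare_threshold = 16L,
                      missing_policy = c("cap", "na")) {
  stopifnot(inherits(db, "tcem_fc_db"))
  missing_policy <- match.arg(missing_policy)
  i <- match(motifs, db$table$motif)
  fc <- db$table$fc[i]
  unobserved <- is.na(i)
  if (missing_policy == "cap") fc[unobserved] <- db$cap
  data.frame(motif = motifs, fc = fc,
             rare = !is.na(fc) & fc > rare_threshold,
             unobserved = unobserved, stringsAsFactors = FALSE)
}

#' Motif-by-group occurrence matrix
#'
#' Counts every fragment occurrence of every motif per
#' (patient x compartment) group; in counting mode column sums equal the
#' per-group fragment counts. Optionally z-standardizes each column.
#'
#' @param fragments Fragment table of the class-appropriate length.
#' @param tcem_class TCEM class.
#' @param standardize Z-standardize columns (default `FALSE`).
#' @return Numeric matrix, rows = motifs, columns = groups
#'   (`patient|compartment`).
#' @export
motif_occurrence_matrix <- function(fragments, tcem_class = TCEM_CLASSES,
                                    standardize = FALSE) {
  tcem_class <- match.arg(tcem_class)
  expected <- if (tcem_class == "I") 9L else 15L
  fragments <- fragments[fragments$length == expected, , drop = FALSE]
  motif <- extract_tcem(fragments$sequence, tcem_class)
  group <- paste(fragments$patient_id, fragments$compartment, sep = "|")
  mat <- table(motif, group)
  mat <- matrix(as.numeric(mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  if (standardize) {
    mat <- apply(mat, 2L, function(col) {
      if (sd(col) == 0) rep(0, length(col)) else (col - mean(col)) / sd(col)
    })
  }
  mat
}

#' Standardize background motif frequencies
#'
#' Converts raw motif counts from a background corpus (human proteome or gut
#' microbiome style) to log2 frequencies and brings them onto a zero-mean
#' unit-variance scale with the same Johnson-family standardization used for
#' affinities. Fewer than 8 distinct motifs fall back to a z-score.
#'
#' @param counts Data.frame with columns `motif` and `count` (> 0 counts of
#'   motifs present in the corpus).
#' @param source Label, e.g. `"human_proteome"` or `"gut_microbiome"`.
#' @return Data.frame `source`, `motif`, `log2_freq`, `std_log2_freq`, with
#'   attribute `"method"`.
#' @export
background_standardize <- function(counts, source = c("human_proteome",
                                                      "gut_microbiome")) {
  source <- match.arg(source)
  stopifnot(all(c("motif", "count") %in% names(counts)), all(counts$count > 0))
  log2f <- log2(counts$count / sum(counts$count))
  z <- johnson_standardize(log2f)
  out <- data.frame(source = source, motif = counts$motif,
                    log2_freq = log2f, std_log2_freq = as.numeric(z),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- attr(z, "method")
  out
}
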