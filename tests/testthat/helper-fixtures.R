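# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

AA20 <- aa_alphabet()

# A small hand-annotated repertoire: two patients, both compartments,
# including an exact within-patient duplicate pair (a clone).
toy_repertoire <- function() {
  g <- ighv_germline_set()
  mk <- function(fam, junction) paste0(g[[fam]], junction, "WGQGTLVTVSS")
  seqs <- c(
    mk("IGHV3", "ARDLGYSSGYDY"),
    mk("IGHV3", "ARDLGYSSGYDY"),      # duplicate of the first (same patient)
    mk("IGHV4", "ARGGYRDSSPLDY"),
    mk("IGHV1", "AKDRSYYGSGSY"),
    mk("IGHV4", "ARGYSDYRRGSSDY")
  )
  cs <- nchar(ighv_germline_set()[c("IGHV3", "IGHV3", "IGHV4", "IGHV1", "IGHV4")]) - 1L
  junclen <- c(13L, 13L, 14L, 13L, 15L)  # junction + the opening C
  data.frame(
    gi = paste0("g", 1:5),
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    compartment = c("blood", "blood", "CSF", "blood", "CSF"),
    rank = c(1L, 2L, 1L, 1L, 1L),
    read_count = c(900L, 60L, 40L, 980L, 20L),
    highly_transcribed = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    sequence = seqs,
    clone_id = NA_character_,
    cdr3_start = as.integer(cs),
    cdr3_end = as.integer(cs + junclen),
    n_prefix = 0L, n_suffix = 0L,
    stringsAsFactors = FALSE
  )
}

# write a FASTA in the package dialect from raw pieces
write_dialect_fasta <- function(headers, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(rbind(paste0(">", headers), seqs), path)
  path
}

# a cleavage model whose members output fixed constant probabilities
constant_cleavage_model <- function(probs, enzyme = "cathepsin_S") {
  members <- lapply(probs, function(p) {
    list(W = matrix(0, 20, 8, dimnames = list(AA20, NULL)), b = qlogis(p))
  })
  structure(list(enzyme = enzyme, members = members, holdout_auroc = NA_real_),
            class = "cleavage_model")
}

# brute-force Benjamini-Hochberg step-up: reject the k smallest p-values
# where k = max { i : p_(i) <= i * q / m }
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  reject <- rep(FALSE, m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  reject
}
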