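## repertoire ingestion, CDR3 anchoring, terminal augmentation and
## fragment generation.
##
## Coordinates are 0-based and half-open throughout: cdr3_start is the index
## of the conserved cysteine opening CDR3 (the field's "cysteine 104"), and
## cdr3_end is the exclusive end of CDR3, i.e. the index of the J-region
## W/F-G-x-G anchor residue.

## Default FASTA header dialect:
##   >{gi}|{patient}|{compartment}|rank={n}|reads={n}|HT={0/1}
## with the reads field optional.
DEFAULT_HEADER_REGEX <-
  "^([^|]+)\\|([^|]+)\\|([^|]+)\\|rank=([0-9]+)(?:\\|reads=([0-9]+))?\\|HT=([01])$"

#' Default heavy-chain signal peptide used for terminal augmentation
#'
#' A canonical 19-residue immunoglobulin heavy-chain signal peptide. Only its
#' length matters for end-effect padding; it is configurable in
#' [augmentation_scheme()].
#' @return A single string.
#' @export
ig_signal_peptide <- function() "MGWSCIILFLVATATGVHS"

## 26-residue IgG1 constant-region stub appended in full augmentation mode.
IG_CONSTANT_SUFFIX <- "GTLVTVSSASTKGPSVFPLAPSSKST"

#' Terminal augmentation scheme
#'
#' Sequences are padded at both termini before prediction to avoid end
#' effects in the octamer- and 15-mer-window algorithms. Mode `"full"`
#' prepends a signal peptide plus `"DTR"` and appends a 26-residue IgG1
#' constant-region stub; mode `"short"` uses only `"DTR"` / `"GTL"`; mode
#' `"none"` leaves sequences untouched. The number of added residues is
#' tracked so downstream subset rules can exclude fragments that contain
#' too many non-germline-encoded positions.
#'
#' @param mode One of `"full"`, `"short"`, `"none"`.
#' @param signal_peptide Signal peptide used in mode `"full"`.
#' @return A list with elements `mode`, `prefix`, `suffix`.
#' @export
augmentation_scheme <- function(mode = c("full", "short", "none"),
                                signal_peptide = ig_signal_peptide()) {
  mode <- match.arg(mode)
  prefix <- switch(mode,
    full  = paste0(signal_peptide, "DTR"),
    short = "DTR",
    none  = "")
  suffix <- switch(mode,
    full  = IG_CONSTANT_SUFFIX,
    short = "GTL",
    none  = "")
  structure(list(mode = mode, prefix = prefix, suffix = suffix),
            class = "augmentation_scheme")
}

#' Parse an IGHV amino-acid repertoire from FASTA
#'
#' Reads a repertoire FASTA whose headers carry patient code, compartment
#' (blood/CSF), frequency rank, optional read count and a highly-transcribed
#' tag. Records with malformed headers or characters outside the 20-letter
#' amino-acid alphabet (plus the ambiguity code `X`) are dropped with a
#' warning naming the record numbers. Exact-duplicate amino-acid sequences
#' within a patient share a `clone_id`. When read counts are present the
#' highly-transcribed flag is recomputed as read share strictly above 0.5%
#' of the patient+compartment total; otherwise the header tag is used.
#'
#' @param fasta Path to a FASTA file, or a `Biostrings::AAStringSet`.
#' @param header_regex Regular expression with six capture groups
#'   (gi, patient, compartment, rank, reads, HT tag); the reads group may be
#'   unmatched.
#' @param ht_threshold Read-share threshold above which a transcript is
#'   highly transcribed (strict inequality; default 0.005).
#' @return A data.frame with one row per record and columns `gi`,
#'   `patient_id`, `compartment`, `rank`, `read_count`, `highly_transcribed`,
#'   `sequence`, `clone_id`, `cdr3_start`, `cdr3_end` (anchors `NA` until
#'   [annotate_cdr3()] is applied), `n_prefix`, `n_suffix`.
#' @export
parse_repertoire <- function(fasta, header_regex = DEFAULT_HEADER_REGEX,
                             ht_threshold = 0.005) {
  if (inherits(fasta, "AAStringSet")) {
    seqs <- as.character(fasta)
    headers <- names(fasta)
  } else {
    ss <- tryCatch(Biostrings::readAAStringSet(fasta),
                   error = function(e) NULL)
    if (is.null(ss) || length(ss) == 0L) {
      warning("empty repertoire: no FASTA records found")
      return(empty_repertoire())
    }
    seqs <- as.character(ss)
    headers <- names(ss)
  }
  n <- length(seqs)
  m <- regmatches(headers, regexec(header_regex, headers, perl = TRUE))
  ok_header <- lengths(m) == 7L
  if (any(!ok_header)) {
    warning(sprintf("dropping %d record(s) with malformed headers (records %s)",
                    sum(!ok_header),
                    paste(utils::head(which(!ok_header), 10L), collapse = ", ")))
  }
  ok_seq <- !grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(!ok_seq & ok_header)) {
    warning(sprintf(
      "rejecting %d record(s) with non-amino-acid characters (records %s)",
      sum(!ok_seq & ok_header),
      paste(utils::head(which(!ok_seq & ok_header), 10L), collapse = ", ")))
  }
  keep <- ok_header & ok_seq
  if (!any(keep)) {
    warning("no valid records after header/sequence filtering")
    return(empty_repertoire())
  }
  m <- m[keep]
  fields <- function(i) vapply(m, `[`, character(1), i + 1L)
  reads_chr <- fields(4L)
  df <- data.frame(
    gi = fields(1L),
    patient_id = fields(2L),
    compartment = fields(3L),
    rank = as.integer(fields(4L)),
    read_count = ifelse(nzchar(fields(5L)), suppressWarnings(as.integer(fields(5L))), NA_integer_),
    highly_transcribed = fields(6L) == "1",
    sequence = seqs[keep],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gi)) {
    stop("duplicate gi identifier(s): ",
         paste(unique(df$gi[duplicated(df$gi)]), collapse = ", "))
  }
  if (all(!is.na(df$read_count))) {
    totals <- tapply(df$read_count,
                     paste(df$patient_id, df$compartment, sep = "\r"), sum)
    tot <- totals[paste(df$patient_id, df$compartment, sep = "\r")]
    df$highly_transcribed <- df$read_count / as.numeric(tot) > ht_threshold
  }
  df$clone_id <- assign_clone_ids(df$patient_id, df$sequence)
  df$cdr3_start <- NA_integer_
  df$cdr3_end <- NA_integer_
  df$n_prefix <- 0L
  df$n_suffix <- 0L
  rownames(df) <- NULL
  df
}

empty_repertoire <- function() {
  data.frame(gi = character(0), patient_id = character(0),
             compartment = character(0), rank = integer(0),
             read_count = integer(0), highly_transcribed = logical(0),
             sequence = character(0), clone_id = character(0),
             cdr3_start = integer(0), cdr3_end = integer(0),
             n_prefix = integer(0), n_suffix = integer(0),
             stringsAsFactors = FALSE)
}

## clone = exact amino-acid sequence identity within one patient
assign_clone_ids <- function(patient_id, sequence) {
  key <- paste(patient_id, sequence, sep = "\r")
  idx <- match(key, unique(key))
  paste0(patient_id, "_cl", ave(idx, patient_id, FUN = function(v) match(v, unique(v))))
}

#' Write a repertoire back to FASTA in the package header dialect
#'
#' The dialect is lossless: re-parsing a written repertoire round-trips all
#' fields, and writing it again reproduces the file byte for byte.
#'
#' @param repertoire Data.frame as returned by [parse_repertoire()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(repertoire, path) {
  reads <- ifelse(is.na(repertoire$read_count), "",
                  sprintf("|reads=%d", repertoire$read_count))
  hdr <- sprintf(">%s|%s|%s|rank=%d%s|HT=%d",
                 repertoire$gi, repertoire$patient_id, repertoire$compartment,
                 repertoire$rank, reads,
                 as.integer(repertoire$highly_transcribed))
  writeLines(rbind(hdr, repertoire$sequence), path)
  invisible(path)
}

#' Read an AIRR-style rearrangement table as a repertoire
#'
#' Minimal support for AIRR rearrangement TSVs with columns `sequence_aa`,
#' `junction_aa`, `v_call` and `duplicate_count`. Patient and compartment
#' labels are supplied by the caller (AIRR files are usually per sample).
#'
#' @param path TSV path.
#' @param patient_id,compartment Labels applied to every record.
#' @param ht_threshold Highly-transcribed read-share threshold.
#' @return A repertoire data.frame (see [parse_repertoire()]).
#' @export
parse_airr_rearrangement <- function(path, patient_id, compartment,
                                     ht_threshold = 0.005) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_aa", "junction_aa", "v_call", "duplicate_count")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("AIRR table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ord <- order(-tab$duplicate_count, tab$sequence_aa)  # rank ties: lexicographic
  tab <- tab[ord, , drop = FALSE]
  df <- data.frame(
    gi = sprintf("%s_%s_%06d", patient_id, compartment, seq_len(nrow(tab))),
    patient_id = patient_id,
    compartment = compartment,
    rank = seq_len(nrow(tab)),
    read_count = as.integer(tab$duplicate_count),
    highly_transcribed = tab$duplicate_count / sum(tab$duplicate_count) > ht_threshold,
    sequence = tab$sequence_aa,
    stringsAsFactors = FALSE
  )
  df$clone_id <- assign_clone_ids(df$patient_id, df$sequence)
  df$cdr3_start <- NA_integer_
  df$cdr3_end <- NA_integer_
  df$n_prefix <- 0L
  df$n_suffix <- 0L
  df$v_call <- tab$v_call
  df
}

#' Detect CDR3 anchors on an amino-acid sequence
#'
#' Heuristic stand-in for nucleotide-level junction annotation: the CDR3
#' opening anchor is the rightmost cysteine that is followed, within 4 to 32
#' residues, by a J-region W/F-G-x-G anchor; the end anchor is the nearest
#' such W/F. Failure is returned as a value (`NA` coordinates), never raised,
#' so callers can fall back to externally supplied annotation.
#'
#' @param sequence A single amino-acid string.
#' @return Integer vector `c(cdr3_start, cdr3_end)`, 0-based, `cdr3_end`
#'   exclusive (the index of the anchor W/F); both `NA` on failure.
#' @export
detect_cdr3_anchors <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cys <- which(chars == "C")                      # 1-based
  anchors <- gregexpr("(?=[WF]G.G)", sequence, perl = TRUE)[[1]]
  if (length(cys) == 0L || anchors[1] == -1L) {
    return(c(cdr3_start = NA_integer_, cdr3_end = NA_integer_))
  }
  for (i in rev(cys)) {
    d <- anchors - i
    valid <- anchors[d >= 4L & d <= 32L]
    if (length(valid)) {
      return(c(cdr3_start = i - 1L, cdr3_end = min(valid) - 1L))
    }
  }
  c(cdr3_start = NA_integer_, cdr3_end = NA_integer_)
}

#' Annotate CDR3 anchors on a repertoire
#'
#' Applies [detect_cdr3_anchors()] to every sequence whose anchors are not
#' already set; pre-annotated coordinates pass through unchanged. Sequences
#' for which detection fails keep `NA` anchors; use `drop_failures = TRUE`
#' to remove them (with a message).
#'
#' @param repertoire Repertoire data.frame.
#' @param drop_failures Drop records without a consistent anchor pair.
#' @return The repertoire with `cdr3_start`/`cdr3_end` filled in.
#' @export
annotate_cdr3 <- function(repertoire, drop_failures = FALSE) {
  todo <- is.na(repertoire$cdr3_start) | is.na(repertoire$cdr3_end)
  if (any(todo)) {
    uniq <- unique(repertoire$sequence[todo])
    anch <- vapply(uniq, detect_cdr3_anchors, integer(2))
    i <- match(repertoire$sequence[todo], uniq)
    repertoire$cdr3_start[todo] <- anch[1L, i]
    repertoire$cdr3_end[todo] <- anch[2L, i]
  }
  fail <- is.na(repertoire$cdr3_start)
  if (drop_failures && any(fail)) {
    message(sprintf("dropping %d sequence(s) without CDR3 anchors", sum(fail)))
    repertoire <- repertoire[!fail, , drop = FALSE]
  }
  repertoire
}

#' Augment sequence termini
#'
#' Pads each sequence with the scheme's prefix and suffix, shifting the CDR3
#' anchors accordingly and recording the number of added residues at each
#' terminus so downstream fragment filters can count non-native positions.
#'
#' @param repertoire Repertoire data.frame with CDR3 anchors.
#' @param scheme An [augmentation_scheme()].
#' @return The augmented repertoire.
#' @export
augment_sequences <- function(repertoire, scheme = augmentation_scheme("full")) {
  stopifnot(inherits(scheme, "augmentation_scheme"))
  if (scheme$mode == "none") return(repertoire)
  np <- nchar(scheme$prefix)
  ns <- nchar(scheme$suffix)
  repertoire$sequence <- paste0(scheme$prefix, repertoire$sequence, scheme$suffix)
  repertoire$cdr3_start <- repertoire$cdr3_start + np
  repertoire$cdr3_end <- repertoire$cdr3_end + np
  repertoire$n_prefix <- repertoire$n_prefix + np
  repertoire$n_suffix <- repertoire$n_suffix + ns
  repertoire
}

#' Generate overlapping CDR3-indexed fragments
#'
#' Derives every possible 9-mer and 15-mer (by default) from each sequence,
#' offset by a single residue, and indexes each fragment by its N-terminus
#' position relative to the CDR3-opening cysteine (position 0). Fragments
#' containing the ambiguity code `X` are dropped with a message, since the
#' predictors are defined over the 20-letter alphabet only.
#'
#' @param repertoire Repertoire data.frame with CDR3 anchors.
#' @param lengths Fragment lengths to generate (default `c(9, 15)`).
#' @param drop_x Drop fragments containing `X` (default `TRUE`).
#' @return A data.frame of fragments with columns `fragment_id`, `parent_gi`,
#'   `patient_id`, `compartment`, `length`, `start`,
#'   `cdr3_relative_position`, `sequence`, `n_added_residues`,
#'   `highly_transcribed` (plus `ighv_family` and `clone_id` when present on
#'   the input).
#' @export
make_fragments <- function(repertoire, lengths = c(9L, 15L), drop_x = TRUE) {
  stopifnot(nrow(repertoire) == 0L || !any(is.na(repertoire$cdr3_start)))
  L <- nchar(repertoire$sequence)
  out <- vector("list", length(lengths))
  for (li in seq_along(lengths)) {
    k <- lengths[li]
    nfrag <- pmax(0L, L - k + 1L)
    idx <- rep.int(seq_len(nrow(repertoire)), nfrag)
    start <- sequence(nfrag) - 1L            # 0-based N-terminus offsets
    frag_seq <- substring(repertoire$sequence[idx], start + 1L, start + k)
    npre <- repertoire$n_prefix[idx]
    nsuf <- repertoire$n_suffix[idx]
    Lp <- L[idx]
    n_added <- pmax(0L, npre - start) +
      pmax(0L, (start + k) - (Lp - nsuf))
    frg <- data.frame(
      parent_gi = repertoire$gi[idx],
      patient_id = repertoire$patient_id[idx],
      compartment = repertoire$compartment[idx],
      length = rep.int(k, length(idx)),
      start = start,
      cdr3_relative_position = start - repertoire$cdr3_start[idx],
      sequence = frag_seq,
      n_added_residues = as.integer(n_added),
      highly_transcribed = repertoire$highly_transcribed[idx],
      stringsAsFactors = FALSE
    )
    if (!is.null(repertoire$ighv_family)) frg$ighv_family <- repertoire$ighv_family[idx]
    if (!is.null(repertoire$clone_id)) frg$clone_id <- repertoire$clone_id[idx]
    out[[li]] <- frg
  }
  frg <- do.call(rbind, out)
  if (nrow(frg)) {
    frg$fragment_id <- sprintf("%s:%d:%d", frg$parent_gi, frg$length, frg$start)
  } else {
    frg$fragment_id <- character(0)
  }
  if (drop_x && nrow(frg)) {
    has_x <- grepl("X", frg$sequence, fixed = TRUE)
    if (any(has_x)) {
      message(sprintf("dropped %d fragment(s) containing X", sum(has_x)))
      frg <- frg[!has_x, , drop = FALSE]
    }
  }
  rownames(frg) <- NULL
  frg
}

#' Synthetic IGHV family germline scaffolds
#'
#' Seven hand-written VH-like framework scaffolds (FW1 through FW3, ending at
#' the conserved CDR3-opening cysteine), one per IGHV family. These are
#' synthetic stand-ins, not IMGT germline sequences: each is cysteine-free
#' except the terminal C and contains no W/F-G-x-G motif, so CDR3 anchor
#' detection on sequences built from them is exact. Real germline FASTA can
#' be supplied to [assign_family()] instead.
#'
#' @return Named character vector `IGHV1` .. `IGHV7`.
#' @export
ighv_germline_set <- function() {
  c(
    IGHV1 = "QVQLVQSGAEVKKPGASVKVSATKASGYTFTSYAMHAVRQAPGQRLEAMGAINAGNGNTKYSQKFQGRVTITRDTSASTAYMELSSLRSEDTAVYYC",
    IGHV2 = "QITLKESGPTLVKPTQTLTLTATFSGASLSTSGMGVGAIRQPPGKALEALAHIYANDEKSYRTSLKSRLTISKDTSKNQVVLTMTNMDPVDTATYYC",
    IGHV3 = "EVQLVESGGGLVQPGGSLRLSAAGASGFTFSSYAMSAVRQAPGKGLEAVSAISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC",
    IGHV4 = "QVQLQESGPGLVKPSETLSLTATGVSVSGGSISSYYASAIRQPPGKGLEAIGYIYYSGSTNYNPSLKSRVTISVDTSKNQFSLKLSSVTAADTAVYYC",
    IGHV5 = "EVQLVQSGAEVKKPGESLKISAKGSGYSFTSYAISAVRQMPGKGLEAMGIIYPGDSDTRYSPSFQGQVTISADKSISTAYLQASSLKASDTAMYYC",
    IGHV6 = "QVQLQQSGPGLVKPSQTLSLTAAISGDSVSSNSAAANIRQSPSRGLEALGRTYYRSKAYNDYAVSVKSRITINPDTSKNQFSLQLNSVTPEDTAVYYC",
    IGHV7 = "QVQLVQSGSELKKPGASVKVSAKASGYTFTTYAMNAVRQAPGQGLEAMGAINTNTGNPTYAQGFTGRFVFSLDTSVSTAYLQIASLKAEDTAVYYC"
  )
}

#' Assign IGHV family by best prototype identity
#'
#' Aligns each pre-CDR3 region (FW1 through FW3) globally against a set of
#' family prototypes and assigns the family of the highest-identity
#' prototype, or `"unknown"` when the best identity falls below `floor`.
#' Ties are broken toward the lexicographically smallest family name, with a
#' message.
#'
#' @param sequences Character vector of amino-acid sequences (pre-CDR3
#'   regions, or full sequences together with `cdr3_start`).
#' @param germline_set Named character vector of family prototypes; defaults
#'   to the packaged synthetic scaffolds.
#' @param floor Minimum identity (0-1) below which the family is `"unknown"`.
#' @param cdr3_start Optional 0-based CDR3 anchor per sequence; when given,
#'   only the prefix up to the anchor is compared.
#' @return Character vector of family assignments.
#' @export
assign_family <- function(sequences, germline_set = ighv_germline_set(),
                          floor = 0.60, cdr3_start = NULL) {
  if (length(germline_set) == 0L) stop("empty germline set")
  if (is.null(names(germline_set)) || any(!nzchar(names(germline_set)))) {
    stop("germline set must be named by family")
  }
  germline_set <- germline_set[order(names(germline_set))]
  if (!is.null(cdr3_start)) {
    sequences <- substr(sequences, 1L, cdr3_start)   # up to (excluding) the C
  }
  uniq <- unique(sequences)
  letters_all <- c(AA_ALPHABET, "X")
  submat <- diag(1, length(letters_all))
  dimnames(submat) <- list(letters_all, letters_all)
  ids <- matrix(0, nrow = length(uniq), ncol = length(germline_set))
  pat <- Biostrings::AAStringSet(uniq)
  for (j in seq_along(germline_set)) {
    aln <- Biostrings::pairwiseAlignment(
      pat, germline_set[[j]], type = "global",
      substitutionMatrix = submat, gapOpening = 2, gapExtension = 0.5)
    ids[, j] <- Biostrings::pid(aln, type = "PID1") / 100
  }
  best <- max.col(ids, ties.method = "first")
  is_tie <- vapply(seq_len(nrow(ids)), function(i) {
    sum(abs(ids[i, ] - ids[i, best[i]]) < 1e-9) > 1L
  }, logical(1))
  if (any(is_tie)) {
    message(sprintf(
      "%d sequence(s) tied between prototypes; using lexicographically smallest family",
      sum(is_tie)))
  }
  fam <- names(germline_set)[best]
  fam[ids[cbind(seq_len(nrow(ids)), best)] < floor] <- "unknown"
  fam[match(sequences, uniq)]
}

#' Summary statistics of a deposited repertoire FASTA
#'
#' Recomputes, with the package's own CDR3 annotation, the record count after
#' parsing/filtering and the mean CDR3 length (`cdr3_end - cdr3_start`) per
#' patient group and compartment from a repertoire FASTA in the package
#' header dialect. Intended for the publicly deposited patient repertoire,
#' which must be downloaded separately (path via
#' `options(idiotope.deposited_fasta = ...)`).
#'
#' @param fasta Path to the repertoire FASTA.
#' @param group_fun Function mapping patient codes to group labels; the
#'   default takes the leading alphabetic prefix (e.g. `"MS"`, `"OIND"`).
#' @return A list with `n_records`, `n_annotated` and a data.frame
#'   `cdr3_length` of per group x compartment means.
#' @export
deposited_repertoire_statistics <- function(fasta,
                                            group_fun = function(p) sub("[^A-Za-z].*$", "", p)) {
  rep <- parse_repertoire(fasta)
  n_records <- nrow(rep)
  rep <- annotate_cdr3(rep, drop_failures = TRUE)
  rep$group <- group_fun(rep$patient_id)
  len <- rep$cdr3_end - rep$cdr3_start
  agg <- aggregate(len, by = list(group = rep$group, compartment = rep$compartment),
                   FUN = mean)
  names(agg)[3] <- "mean_cdr3_length"
  agg$n <- aggregate(len, by = list(rep$group, rep$compartment), FUN = length)$x
  list(n_records = n_records, n_annotated = nrow(rep), cdr3_length = agg)
}
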