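test_that("the header dialect is parsed, clones assigned, and the strict 0.5% rule applied", {
  seqA <- "QVQLVESGGGLVQYYCARDFDYWGQGTLVTVSS"
  seqB <- "EVQLVESGGDLVQYYCARSGYWFDPWGQGTLVTVSS"
  path <- write_dialect_fasta(
    c("s1|P1|blood|rank=1|reads=989|HT=1",
      "s2|P1|blood|rank=2|reads=6|HT=0",     # 0.6% -> recomputed TRUE
      "s3|P1|blood|rank=3|reads=5|HT=1",     # exactly 0.5% -> FALSE (strict)
      "s4|P2|CSF|rank=1|reads=10|HT=1"),
    c(seqA, seqA, seqB, seqA))
  rep <- parse_repertoire(path)
  expect_equal(nrow(rep), 4L)
  # identical sequences within a patient share a clone, distinct gi
  expect_equal(rep$clone_id[1], rep$clone_id[2])
  expect_false(rep$gi[1] == rep$gi[2])
  expect_false(rep$clone_id[3] == rep$clone_id[1])
  # same sequence in a different patient is a different clone
  expect_false(rep$clone_id[4] == rep$clone_id[1])
  # HT recomputed from read counts: strictly more than 0.5%
  expect_true(rep$highly_transcribed[2])
  expect_false(rep$highly_transcribed[3])
  expect_true(rep$highly_transcribed[1])
})

test_that("malformed records are dropped, duplicates are fatal, empty input warns", {
  seqA <- "QVQLVESGGGLVQYYCARDFDYWGQGTLVTVSS"
  p1 <- write_dialect_fasta(
    c("ok|P1|blood|rank=1|reads=10|HT=1", "broken-header-no-fields"),
    c(seqA, seqA))
  expect_warning(rep <- parse_repertoire(p1), "malformed")
  expect_equal(rep$gi, "ok")

  p2 <- write_dialect_fasta(
    c("a|P1|blood|rank=1|reads=10|HT=1", "b|P1|blood|rank=2|reads=5|HT=0"),
    c(seqA, "QVQLZZ123"))
  w2 <- capture_warnings(rep2 <- parse_repertoire(p2))
  expect_true(any(grepl("non-amino-acid", w2)))
  expect_equal(rep2$gi, "a")

  p3 <- write_dialect_fasta(
    c("dup|P1|blood|rank=1|reads=10|HT=1", "dup|P1|blood|rank=2|reads=5|HT=0"),
    c(seqA, seqA))
  expect_error(parse_repertoire(p3), "duplicate gi")

  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  w <- capture_warnings(rep3 <- parse_repertoire(empty))
  expect_true(any(grepl("empty", w)))
  expect_equal(nrow(rep3), 0L)
})

test_that("a written repertoire round-trips byte for byte", {
  rep <- toy_repertoire()
  f1 <- tempfile(fileext = ".fasta")
  write_repertoire(rep, f1)
  back <- parse_repertoire(f1)
  expect_equal(back$gi, rep$gi)
  expect_equal(back$sequence, rep$sequence)
  expect_equal(back$read_count, rep$read_count)
  f2 <- tempfile(fileext = ".fasta")
  write_repertoire(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("CDR3 anchors are found at the conserved Cys and the J-region W", {
  s <- "EVQLVESGGGYYCARDLWSGYFDYWGQGTLVTVSS"
  a <- detect_cdr3_anchors(s)
  expect_equal(substr(s, a["cdr3_start"] + 1, a["cdr3_start"] + 1), "C")
  # cdr3_start is the C of "YYC" (rightmost C), cdr3_end the W of "WGQG"
  expect_equal(unname(a["cdr3_start"]), as.integer(regexpr("YYC", s)) + 1L)
  expect_equal(substr(s, a["cdr3_end"] + 1, a["cdr3_end"] + 4), "WGQG")
  # failure is a value, not an error
  expect_true(all(is.na(detect_cdr3_anchors("QVQLVESGGGCARDLDY"))))
  expect_true(all(is.na(detect_cdr3_anchors("AAAAAAAA"))))
})

test_that("pre-annotated coordinates pass through annotate_cdr3 unchanged", {
  rep <- toy_repertoire()
  rep$cdr3_start[1] <- 5L; rep$cdr3_end[1] <- 15L   # deliberately wrong
  out <- annotate_cdr3(rep)
  expect_equal(out$cdr3_start[1], 5L)
  expect_equal(out$cdr3_end[1], 15L)
  # detection on the simulated layout agrees with the generator's truth
  rep2 <- toy_repertoire()
  det <- annotate_cdr3(transform(rep2, cdr3_start = NA_integer_,
                                 cdr3_end = NA_integer_))
  expect_equal(det$cdr3_start, rep2$cdr3_start)
  expect_equal(det$cdr3_end, rep2$cdr3_end)
})

test_that("augmentation shifts anchors and uses the exact constant-region strings", {
  rep <- toy_repertoire()
  sh <- augment_sequences(rep, augmentation_scheme("short"))
  expect_equal(sh$sequence, paste0("DTR", rep$sequence, "GTL"))
  expect_equal(sh$cdr3_start, rep$cdr3_start + 3L)
  expect_equal(sh$n_prefix, rep$n_prefix + 3L)

  fu <- augment_sequences(rep, augmentation_scheme("full"))
  expect_true(all(endsWith(fu$sequence, "GTLVTVSSASTKGPSVFPLAPSSKST")))
  expect_equal(fu$cdr3_start, rep$cdr3_start + nchar(ig_signal_peptide()) + 3L)

  no <- augment_sequences(rep, augmentation_scheme("none"))
  expect_identical(no, rep)
})

test_that("fragment generation is exhaustive, CDR3-indexed, and conserves counts", {
  rep <- toy_repertoire()[1, , drop = FALSE]
  rep$sequence <- paste(rep(aa_alphabet()[-c(2, 19)], length.out = 130), collapse = "")
  rep$cdr3_start <- 100L; rep$cdr3_end <- 113L
  fr <- make_fragments(rep, lengths = 15L)
  expect_equal(nrow(fr), 130L - 15L + 1L)
  expect_equal(fr$cdr3_relative_position, fr$start - 100L)
  expect_equal(fr$sequence,
               substring(rep$sequence, fr$start + 1L, fr$start + 15L))
  # fragment starting at the conserved C has position 0
  both <- make_fragments(toy_repertoire())
  at0 <- both[both$cdr3_relative_position == 0L, ]
  rep0 <- toy_repertoire()
  expect_true(all(substr(at0$sequence, 1, 1) == "C"))
  # 9-mer count minus 15-mer count is 6 per sequence when L >= 15
  n9 <- table(both$parent_gi[both$length == 9])
  n15 <- table(both$parent_gi[both$length == 15])
  expect_true(all(as.integer(n9) - as.integer(n15) == 6L))
  # degenerate: too-short sequence yields nothing
  short <- rep; short$sequence <- "ACDEFGHK"; short$cdr3_start <- 2L; short$cdr3_end <- 7L
  expect_equal(nrow(make_fragments(short, lengths = 9L)), 0L)
})

test_that("fragments containing X are dropped with a count", {
  rep <- toy_repertoire()[1, , drop = FALSE]
  rep$sequence <- paste0("AAAAAAAAAAXAAAAAAAAAA")
  rep$cdr3_start <- 3L; rep$cdr3_end <- 10L
  expect_message(fr <- make_fragments(rep, lengths = 9L), "containing X")
  expect_false(any(grepl("X", fr$sequence)))
  expect_equal(nrow(fr), (21 - 9 + 1) - 9)  # 9 windows overlap the X
})

test_that("excluding fragments with any added residue equals fragmenting the unaugmented sequence", {
  set.seed(42)
  g <- ighv_germline_set()
  for (i in 1:100) {
    fam <- sample(names(g), 1)
    junc <- paste(sample(setdiff(aa_alphabet(), c("C", "W", "F")), 12,
                         replace = TRUE), collapse = "")
    rep <- toy_repertoire()[1, , drop = FALSE]
    rep$sequence <- paste0(g[[fam]], junc, "WGQGTLVTVSS")
    rep$cdr3_start <- nchar(g[[fam]]) - 1L
    rep$cdr3_end <- rep$cdr3_start + 13L
    plain <- make_fragments(rep, lengths = 15L)
    aug <- make_fragments(augment_sequences(rep, augmentation_scheme("short")),
                          lengths = 15L)
    aug <- aug[aug$n_added_residues == 0L, ]
    expect_equal(aug$sequence, plain$sequence)
    expect_equal(aug$cdr3_relative_position, plain$cdr3_relative_position)
  }
})

test_that("family assignment matches prototypes, floors to unknown, and breaks ties by name", {
  g <- ighv_germline_set()
  expect_equal(assign_family(unname(g)), names(g))
  # a heavily scrambled sequence matches nothing above the floor
  set.seed(7)
  rand <- paste(sample(aa_alphabet(), 90, replace = TRUE), collapse = "")
  expect_equal(assign_family(rand), "unknown")
  # mild mutation keeps the family call
  mut <- g[["IGHV4"]]
  pos <- sample(nchar(mut) - 1L, 10)
  for (p in pos) substr(mut, p, p) <- sample(setdiff(aa_alphabet(), "C"), 1)
  expect_equal(assign_family(mut), "IGHV4")
  # tie between two identical prototypes resolves to the smaller name
  twins <- c(Z = g[["IGHV1"]], A = g[["IGHV1"]])
  expect_message(fam <- assign_family(g[["IGHV1"]], germline_set = twins),
                 "tied")
  expect_equal(fam, "A")
  expect_error(assign_family("ACDEF", germline_set = character(0)), "empty")
})
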