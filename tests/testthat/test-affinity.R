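test_that("affinity predictions live on the ln(IC50) scale with class-specific lengths", {
  W0 <- matrix(0, 20, 9, dimnames = list(AA20, NULL))
  mI <- affinity_model_from_table(W0, b = log(50), allele = "A*TEST",
                                  hla_class = "I")
  p <- predict_affinity(mI, "ACDEFGHIK")
  expect_equal(p$ln_ic50, 3.912, tolerance = 1e-3)
  expect_equal(p$ic50, 50)
  expect_error(predict_affinity(mI, "ACDEFGHIKLMNPQR"), "9-mers")
  mII <- affinity_model_from_table(W0, b = log(50), allele = "DRB1*TEST",
                                   hla_class = "II")
  expect_error(predict_affinity(mII, "ACDEFGHIK"), "15-mers")
  expect_true(is.na(predict_affinity(mII, "ACDEFGHIKLMNPQX")$ln_ic50))
})

test_that("class II scoring is the minimum over the seven 9-mer cores", {
  set.seed(14)
  W <- matrix(rnorm(180), 20, 9, dimnames = list(AA20, NULL))
  m <- affinity_model_from_table(W, b = 5, allele = "DRB1*TEST")
  peps <- vapply(1:25, function(i)
    paste(sample(AA20, 15, replace = TRUE), collapse = ""), character(1))
  got <- predict_affinity(m, peps)
  # independent oracle: loop over the 7 cores and 9 positions
  for (i in seq_along(peps)) {
    cores <- vapply(0:6, function(off) substr(peps[i], off + 1, off + 9),
                    character(1))
    core_scores <- vapply(cores, function(cc) {
      5 + sum(vapply(1:9, function(j) W[substr(cc, j, j), j], numeric(1)))
    }, numeric(1))
    expect_equal(got$ln_ic50[i], min(core_scores), tolerance = 1e-10)
    expect_equal(got$core_offset[i], unname(which.min(core_scores)) - 1L)
    # the reported score is <= every individual core score
    expect_true(all(got$ln_ic50[i] <= core_scores + 1e-12))
  }
})

test_that("Johnson standardization meets the zero-mean unit-variance contract", {
  set.seed(31)
  samples <- list(normal = rnorm(1000, 5, 2),
                  lognormal = exp(rnorm(1000, 0, 0.8)),
                  uniform = runif(1000),
                  heavy = rt(1000, df = 4))
  for (x in samples) {
    z <- johnson_standardize(x)
    expect_lt(abs(mean(z)), 0.05)
    expect_lt(abs(sd(z) - 1), 0.05)
    # monotone: rank order preserved
    expect_equal(rank(z), rank(x))
  }
  # right-skewed input is made more symmetric
  x <- samples$lognormal
  z <- johnson_standardize(x)
  skew <- function(v) mean(((v - mean(v)) / sd(v))^3)
  expect_lt(abs(skew(as.numeric(z))), abs(skew(x)))
  # degenerate and small-group behavior
  zc <- johnson_standardize(rep(3, 20))
  expect_true(all(zc == 0))
  expect_equal(attr(zc, "method"), "degenerate")
  zs <- johnson_standardize(c(1, 2, 3, 10))
  expect_equal(attr(zs, "method"), "zscore")
})

test_that("a standardized threshold of -1.5 selects a bounded lower tail", {
  set.seed(77)
  gens <- list(function(n) rnorm(n), function(n) exp(rnorm(n)),
               function(n) runif(n), function(n) rt(n, 5))
  for (g in gens) {
    for (rep in 1:3) {
      x <- g(800)
      z <- johnson_standardize(x)
      frac <- mean(z < -1.5)
      expect_gte(frac, 0)
      expect_lte(frac, 0.12)
    }
  }
})

test_that("group standardization is applied within patient and compartment", {
  set.seed(9)
  df <- data.frame(
    patient_id = rep(c("P1", "P2"), each = 200),
    compartment = rep(c("blood", "CSF"), times = 200),
    allele = "DRB1*S01",
    ln_ic50 = c(rnorm(200, 8, 1), rnorm(200, 3, 2)))
  out <- standardize_affinity(df)
  for (p in c("P1", "P2")) for (co in c("blood", "CSF")) {
    z <- out$std_ln_ic50[out$patient_id == p & out$compartment == co]
    expect_lt(abs(mean(z)), 1e-8)
    expect_lt(abs(sd(z) - 1), 1e-8)
  }
})

test_that("best-allele resolution takes the minimum and honors genotype order on ties", {
  preds <- data.frame(fragment_id = rep(c("f1", "f2"), each = 2),
                      allele = rep(c("DRB1*A", "DRB1*B"), 2),
                      std_ln_ic50 = c(-1.7, -0.2, 0.5, 0.5))
  expect_message(best <- best_patient_allele(preds, c("DRB1*A", "DRB1*B")),
                 "tied")
  expect_equal(best$std_ln_ic50[best$fragment_id == "f1"], -1.7)
  expect_equal(best$allele[best$fragment_id == "f2"], "DRB1*A")
  # never larger than either allele's value
  expect_true(all(best$std_ln_ic50 <=
                    tapply(preds$std_ln_ic50, preds$fragment_id, min) + 1e-12))
  # homozygous patient
  hom <- best_patient_allele(preds[preds$allele == "DRB1*B", ], "DRB1*B")
  expect_equal(hom$std_ln_ic50, c(-0.2, 0.5))
  expect_error(best_patient_allele(preds, c("DRB1*A", "DRB1*C")), "DRB1\\*C")
})

test_that("position profiles average per position and flag undefined CIs", {
  df <- data.frame(cdr3_relative_position = c(0, 0, 0, 5),
                   std_ln_ic50 = c(-1, 0, 1, 2))
  pr <- position_profile(df, trim = NULL)
  expect_equal(pr$mean[pr$cdr3_relative_position == 0], 0)
  expect_true(is.na(pr$lower[pr$cdr3_relative_position == 5]))
  # a planted low-affinity block inside CDR3 puts the profile minimum there
  set.seed(4)
  big <- data.frame(
    cdr3_relative_position = rep(-20:20, each = 30),
    std_ln_ic50 = rnorm(41 * 30, 0, 0.3))
  inside <- big$cdr3_relative_position >= 0 & big$cdr3_relative_position <= 10
  big$std_ln_ic50[inside] <- big$std_ln_ic50[inside] - 2
  pr2 <- position_profile(big, trim = NULL)
  argmin <- pr2$cdr3_relative_position[which.min(pr2$mean)]
  expect_true(argmin >= 0 && argmin <= 10)
})

test_that("the reference affinity trainer recovers a planted scoring table", {
  truth <- true_affinity_model("DRB1*S01")
  d <- simulate_affinity_data(truth, n = 2000L, noise_sd = 0.5, seed = 12L)
  m <- train_affinity_model(d[, c("allele", "peptide", "ic50_nM")],
                            "DRB1*S01", seed = 2L)
  pred <- idiotope:::pssm_score(d$peptide, m$W, m$b)
  expect_gte(cor(pred, d$true_ln_ic50), 0.9)
  m2 <- train_affinity_model(d[, c("allele", "peptide", "ic50_nM")],
                             "DRB1*S01", seed = 2L)
  expect_identical(m$W, m2$W)
  expect_error(train_affinity_model(d[, c("allele", "peptide", "ic50_nM")],
                                    "DRB1*S02"), "alleles other than")
  expect_error(train_affinity_model(d[1:50, c("allele", "peptide", "ic50_nM")],
                                    "DRB1*S01"), "insufficient")
})
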