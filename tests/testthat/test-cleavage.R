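test_that("octamer windows follow the P4-P4' convention", {
  w <- octamer_windows("ABCDEFGHIJ")
  expect_equal(nrow(w), 3L)
  expect_equal(w$octamer[1], "ABCDEFGH")
  expect_equal(w$bond_index[1], 3L)          # scissile bond D-E
  expect_equal(nrow(octamer_windows(strrep("A", 130))), 123L)
  expect_equal(nrow(octamer_windows("ABCDEFGH")), 1L)
  expect_equal(nrow(octamer_windows("ABCDEFG")), 0L)
})

test_that("ensemble prediction is the member median and X voids a bond", {
  m3 <- constant_cleavage_model(c(0.7, 0.9, 0.85))
  p <- predict_cleavage(m3, "AAAAAAAAA")       # 2 windows
  expect_equal(p$probability, c(0.85, 0.85), tolerance = 1e-12)
  m1 <- constant_cleavage_model(0.7)
  expect_equal(predict_cleavage(m1, "AAAAAAAA")$probability, 0.7,
               tolerance = 1e-12)
  # window containing X is undefined
  px <- predict_cleavage(m3, "AAAAXAAAAAAAA")
  expect_true(any(is.na(px$probability)))
  expect_false(is.na(px$probability[nrow(px)]))  # trailing X-free window defined
  # untrained model is a hard error
  broken <- structure(list(enzyme = "cathepsin_S", members = list()),
                      class = "cleavage_model")
  expect_error(predict_cleavage(broken, "AAAAAAAA"), "untrained")
})

test_that("median aggregation is invariant to member order", {
  set.seed(3)
  probs <- runif(9)
  seqs <- vapply(1:20, function(i)
    paste(sample(AA20, 12, replace = TRUE), collapse = ""), character(1))
  m <- constant_cleavage_model(probs)
  mshuf <- m; mshuf$members <- m$members[sample(9)]
  expect_equal(predict_cleavage(m, seqs)$probability,
               predict_cleavage(mshuf, seqs)$probability)
})

test_that("site calls are strictly above threshold", {
  prof <- data.frame(parent_gi = "g", bond_index = 3:5, enzyme = "cathepsin_S",
                     probability = c(0.85, 0.8, 0.1))
  out <- call_cleavage_sites(prof, threshold = 0.8)
  expect_equal(out$site_call, c(TRUE, FALSE, FALSE))
  expect_equal(call_cleavage_sites(prof, threshold = 0)$site_call,
               c(TRUE, TRUE, TRUE))
  prof$probability <- 0
  expect_false(any(call_cleavage_sites(prof)$site_call))
})

test_that("the excision rule reproduces its truth table and is monotone", {
  expect_true(excision_rule(0.6, 0.3))
  expect_false(excision_rule(0.6, 0.2))
  expect_true(excision_rule(0.45, 0.9))       # either terminal may carry >= 0.5
  expect_true(excision_rule(0.5, 0.25))       # boundary: both inclusive
  expect_true(excision_rule(0.9, 0.49))
  expect_false(excision_rule(0.4, 0.4))       # no terminal reaches 0.5
  # monotonicity: raising either terminal never flips TRUE -> FALSE
  grid <- expand.grid(n = seq(0, 1, 0.05), c = seq(0, 1, 0.05))
  base <- excision_rule(grid$n, grid$c)
  for (eps in c(0.05, 0.2)) {
    up_n <- excision_rule(pmin(1, grid$n + eps), grid$c)
    up_c <- excision_rule(grid$n, pmin(1, grid$c + eps))
    expect_true(all(up_n[base]))
    expect_true(all(up_c[base]))
  }
})

test_that("excision wiring picks terminal windows and zero-fills missing bonds", {
  # 20-residue parent, one 15-mer fragment at start 2 (bonds -2..1 undefined)
  frag <- data.frame(fragment_id = "f", parent_gi = "g", length = 15L,
                     start = 2L, stringsAsFactors = FALSE)
  prof <- data.frame(parent_gi = "g", bond_index = 3:12,
                     enzyme = "cathepsin_S",
                     probability = c(0.3, rep(0.1, 9)))
  out <- call_excision(frag, prof)
  # N-terminal bonds are -2..1: all undefined except none -> 0... bond 1? undefined
  expect_equal(out$n_term_max_prob, 0)
  expect_false(out$excised)
  # C-terminal bonds are 16..19, also undefined here
  expect_equal(out$c_term_max_prob, 0)
  # now give the fragment reachable cut sites at both ends
  frag2 <- data.frame(fragment_id = "f2", parent_gi = "g", length = 15L,
                      start = 7L, stringsAsFactors = FALSE)
  prof2 <- data.frame(parent_gi = "g",
                      bond_index = c(4L, 21L),
                      enzyme = "cathepsin_S",
                      probability = c(0.55, 0.3))
  out2 <- call_excision(frag2, prof2)
  expect_equal(out2$n_term_max_prob, 0.55)    # bond 4 in 3..6
  expect_equal(out2$c_term_max_prob, 0.3)     # bond 21 in 21..24
  expect_true(out2$excised)
})

test_that("the reference trainer recovers a planted specificity model", {
  truth <- true_cleavage_model("cathepsin_S")
  d <- simulate_cleavage_data(truth, n = 2000L, noise = 0.05, seed = 11L)
  m <- train_cleavage_model(d$octamer, d$cleaved, "cathepsin_S",
                            ensemble_size = 5L, seed = 2L)
  expect_gte(m$holdout_auroc, 0.95)
  # predictions correlate with the generating probabilities
  set.seed(5)
  fresh <- simulate_cleavage_data(truth, n = 500L, noise = 0, seed = 99L)
  pred <- predict_cleavage(m, fresh$octamer, gi = as.character(1:500))
  expect_gt(cor(pred$probability, fresh$true_probability), 0.9)
  # same data, same seed -> identical ensemble
  m2 <- train_cleavage_model(d$octamer, d$cleaved, "cathepsin_S",
                             ensemble_size = 5L, seed = 2L)
  expect_identical(m$members, m2$members)
  # ensemble of 1 and of 9 agree closely on clean data
  m1 <- train_cleavage_model(d$octamer, d$cleaved, "cathepsin_S",
                             ensemble_size = 1L, seed = 2L)
  m9 <- train_cleavage_model(d$octamer, d$cleaved, "cathepsin_S",
                             ensemble_size = 9L, seed = 2L)
  p1 <- predict_cleavage(m1, fresh$octamer, gi = as.character(1:500))$probability
  p9 <- predict_cleavage(m9, fresh$octamer, gi = as.character(1:500))$probability
  expect_lt(mean(abs(p1 - p9)), 0.1)
  # single-class data are rejected
  expect_error(train_cleavage_model(d$octamer, rep(1L, nrow(d)), "cathepsin_S"),
               "single class")
})

test_that("the rank AUROC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(300, 1, 0.4)
  s <- y + rnorm(300)
  ours <- idiotope:::auroc(s, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("a planted cleavage hotspot at the CDR3-opening bond is recovered", {
  spec <- repertoire_sim_spec(n_case = 1L, n_control = 0L,
                              n_blood = 40L, n_csf = 0L)
  sim <- simulate_repertoire(spec, seed = 21L)
  model <- true_cleavage_model("cathepsin_S")
  prof <- predict_cleavage(model, sim$repertoire$sequence, gi = sim$repertoire$gi)
  pp <- cleavage_position_profile(prof, sim$repertoire)
  pp <- pp[pp$n >= 20L, ]
  expect_equal(pp$cdr3_relative_position[which.max(pp$proportion)], 0L)
  # cathepsin L is planted to cleave both before and after the cysteine
  profL <- predict_cleavage(true_cleavage_model("cathepsin_L"),
                            sim$repertoire$sequence, gi = sim$repertoire$gi)
  ppL <- cleavage_position_profile(profL, sim$repertoire)
  top2 <- ppL$cdr3_relative_position[order(-ppL$proportion)][1:2]
  expect_setequal(top2, c(0L, 1L))
})
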