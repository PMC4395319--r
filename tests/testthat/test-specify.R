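test_that("Markov test rejects when the sojourn time drives post-progression risk", {
  cfg <- idm_sim_config(n = 1000)           # beta_t010 = -0.028 by default
  d <- idm_adjust_ties(idm_simulate(cfg, seed = 31))
  mt <- idm_markov_test(d)
  expect_lt(mt$coef, 0)
  expect_lt(mt$wald_p, 0.01)
  expect_lt(mt$lr_p, 0.01)
  expect_error(idm_markov_test(d, idm_structure_full(t010 = FALSE)),
               "must include t010")
})

test_that("Markov test keeps its level when the sojourn effect is absent", {
  cfg <- idm_sim_config(n = 500, beta_t010 = 0)
  reps <- 80
  rej <- 0L
  for (r in seq_len(reps)) {
    d <- idm_adjust_ties(idm_simulate(cfg, seed = 4000 + r))
    p <- idm_markov_test(d)$wald_p
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / reps, 0.13)
})

test_that("Markov test has power against a sojourn-time slope", {
  cfg <- idm_sim_config(n = 1000, beta_t010 = -0.03)
  hits <- 0L
  reps <- 25
  for (r in seq_len(reps)) {
    d <- idm_adjust_ties(idm_simulate(cfg, seed = 5000 + r))
    hits <- hits + (idm_markov_test(d)$wald_p < 0.01)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("pairwise baseline tests accept truly proportional death baselines", {
  # shared Weibull death baseline (gamma shift only): proportionality holds
  cfg <- idm_sim_config(n = 800)
  non_rej <- 0L
  reps <- 40
  for (r in seq_len(reps)) {
    d <- idm_adjust_ties(idm_simulate(cfg, seed = 6000 + r))
    bt <- idm_baseline_tests(d)
    p <- bt$tests$p[bt$tests$pair == "02 vs 12"]
    non_rej <- non_rej + (p >= 0.05)
  }
  expect_gte(non_rej / reps, 0.85)
})

test_that("baseline tests return all three pairs and log-log data", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 434), seed = 7))
  bt <- idm_baseline_tests(d)
  expect_setequal(bt$tests$pair, c("01 vs 02", "01 vs 12", "02 vs 12"))
  expect_true(all(bt$tests$p >= 0 & bt$tests$p <= 1))
  expect_setequal(unique(bt$loglog$stratum), c("01", "02", "12"))
})

test_that("a fully shared, significant structure is a reduction fixed point", {
  cfg <- idm_sim_config(
    n = 800,
    beta01 = c(residual_tumor = 0.6, figo_high = 1.5),
    beta02 = c(residual_tumor = 0.6),
    beta12 = c(residual_tumor = 0.6),
    beta_t010 = -0.03)
  d <- idm_adjust_ties(idm_simulate(cfg, seed = 41))
  start <- idm_structure(
    effects = list(
      list(covariate = "residual_tumor", transitions = c("01", "02", "12")),
      list(covariate = "figo_high", transitions = "01"),
      list(covariate = "t010", transitions = "12")),
    strata = list("01", c("02", "12")), prop_terms = "12")
  red <- idm_reduce(d, start)
  expect_length(red$steps, 0L)
  expect_equal(red$final$df, start$df)
  expect_equal(red$final$loglik, red$start$loglik)
})

test_that("accepted steps keep the LR and AIC guards and df bookkeeping", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 434), seed = 17))
  red <- idm_reduce(d, idm_structure_ph())
  tr <- red$trace
  expect_gte(nrow(tr), 2)                   # at least one accepted move
  expect_true(all(diff(tr$aic) <= 1e-9))    # AIC never increases
  expect_true(all(tr$lr_p[-1] >= red$alpha))
  expect_true(all(diff(tr$df) < 0))
  removed <- vapply(red$steps, function(s)
    if (s$accepted) s$lr$df else 0L, 0L)
  expect_equal(red$start$df - red$final$df, sum(removed))
  # t010 and the gamma term survive the reduction
  expect_true(any(grepl("^t010", names(red$final$coefficients))))
  expect_true("prog.12" %in% names(red$final$coefficients))
})

test_that("a prespecified move list is applied in order with the same guards", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 600), seed = 19))
  moves <- list(
    idm_move("merge", "residual_tumor", c("01", "02", "12")),
    idm_move("merge", "figo_high", c("02", "12")),
    idm_move("drop", "age", "01"))
  red <- idm_reduce(d, idm_structure_ph(), moves = moves)
  labs <- vapply(red$steps, function(s) idmspec:::.move_label(s$move), "")
  expect_equal(labs, vapply(moves, idmspec:::.move_label, ""))
  acc <- vapply(red$steps, `[[`, NA, "accepted")
  # every accepted step satisfied both guards
  for (s in red$steps[acc]) {
    expect_gte(s$lr$p, red$alpha)
    expect_lte(s$aic_delta, 1e-9)
  }
  # df path consistent with accepted moves
  expect_equal(red$final$df,
               11L - sum(vapply(red$steps[acc], function(s) s$lr$df, 0L)))
})

test_that("merge moves are accepted under equal effects and rejected under unequal", {
  eq <- idm_sim_config(n = 2000,
                       beta01 = c(residual_tumor = 0.6, figo_high = 1.5),
                       beta02 = c(residual_tumor = 0.6, age = 0.05),
                       beta12 = c(residual_tumor = 0.6, age = 0.015),
                       beta_t010 = -0.028)
  uneq <- idm_sim_config(n = 2000,
                         beta01 = c(residual_tumor = 0.2, figo_high = 1.5),
                         beta02 = c(residual_tumor = 0.9, age = 0.05),
                         beta12 = c(residual_tumor = 0.9, age = 0.015),
                         beta_t010 = -0.028)
  start <- idm_structure(
    effects = list(
      list(covariate = "residual_tumor", transitions = "01"),
      list(covariate = "residual_tumor", transitions = "02"),
      list(covariate = "residual_tumor", transitions = "12"),
      list(covariate = "figo_high", transitions = "01"),
      list(covariate = "age", transitions = "02"),
      list(covariate = "age", transitions = "12"),
      list(covariate = "t010", transitions = "12")),
    strata = list("01", c("02", "12")), prop_terms = "12")
  mv <- list(idm_move("merge", "residual_tumor", c("01", "02", "12")))
  accepted <- function(cfg, seed) {
    d <- idm_adjust_ties(idm_simulate(cfg, seed = seed))
    red <- idm_reduce(d, start, moves = mv)
    length(red$steps) == 1 && red$steps[[1]]$accepted
  }
  reps <- 12
  acc_eq <- sum(vapply(seq_len(reps), function(r) accepted(eq, 7000 + r), NA))
  acc_uneq <- sum(vapply(seq_len(reps), function(r) accepted(uneq, 8000 + r), NA))
  expect_gte(acc_eq, 9)       # usually accepted when truly equal
  expect_lte(acc_uneq, 1)     # virtually never with a 0.7 log-HR gap
})
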