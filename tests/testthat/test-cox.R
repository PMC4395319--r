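test_that("three-subject partial likelihood has the analytic maximizer", {
  # events at t = 1 (x=1), 2 (x=0), 3 (x=1): the score equation reduces to
  # 2 exp(2 beta) = 1, so beta-hat = -log(2)/2
  st <- surv01(c(1, 2, 3), c(1, 1, 1), c(1, 0, 1))
  fit <- idm_fit(st, struct01())
  expect_equal(unname(fit$coefficients), -0.5 * log(2), tolerance = 1e-7)
  expect_equal(fit$loglik,
               pl_bruteforce(st$tstop, st$status, cbind(st$x),
                             fit$coefficients),
               tolerance = 1e-10)
})

test_that("engine log-likelihood matches risk-set enumeration on tiny data", {
  grid <- seq(-1.5, 1.5, by = 0.5)
  for (seed in 1:4) {
    rs <- random_surv_data(n = 8, p = 2, seed = seed)
    st <- as_stacked(data.frame(id = 1:8,
                                transition = rep(c("01", "02"), each = 4),
                                tstop = rs$tstop, status = rs$status,
                                x = rs$X[, 1], z = rs$X[, 2]),
                     covs = c("x", "z"))
    struct <- idm_structure(
      list(list(covariate = "x", transitions = c("01", "02")),
           list(covariate = "z", transitions = "01")),
      strata = list("01", "02"))
    X <- idm_design(st, struct)
    stratum <- ifelse(st$transition == "01", 1, 2)
    for (b1 in grid) for (b2 in c(-0.7, 0.3)) {
      beta <- c(b1, b2)
      expect_equal(idm_loglik(st, struct, beta),
                   pl_bruteforce(st$tstop, st$status, X, beta, stratum),
                   tolerance = 1e-10)
    }
  }
})

test_that("score at the optimum vanishes", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 200), seed = 4))
  st <- idm_stack(d)
  struct <- idm_structure_reduced()
  fit <- idm_fit(st, struct, tol = 1e-9)
  X <- idm_design(st, struct)
  stratum <- vapply(st$transition, function(tr)
    idmspec:::.stratum_of(struct$strata, tr), "")
  sc <- score_bruteforce(st$tstop, st$status, X, fit$coefficients, stratum,
                         h = 1e-5)
  expect_lt(max(abs(sc)), 1e-4)
})

test_that("zero-effect structures return the null likelihood", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 100), seed = 6))
  st <- idm_stack(d)
  null_struct <- idm_structure(list(), strata = as.list(IDM_TRANSITIONS))
  fit <- idm_fit(st, null_struct)
  expect_length(fit$coefficients, 0)
  expect_equal(fit$loglik, fit$loglik_null)
  expect_equal(fit$aic, -2 * fit$loglik_null)
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta = 0", {
  st <- surv01(c(1, 2, 3), c(1, 1, 1), c(0, 0, 0))
  fit <- idm_fit(st, idm_structure(list(), strata = list("01")))
  b <- fit$baselines[["01"]]
  expect_equal(b$time, c(1, 2, 3))
  expect_equal(b$dhaz, c(1 / 3, 1 / 2, 1))
  expect_equal(b$cumhaz, cumsum(c(1 / 3, 1 / 2, 1)))
})

test_that("baselines are nondecreasing step functions; eventless strata are zero", {
  d <- idm_simulate(idm_sim_config(n = 300), seed = 8)
  # remove direct deaths so stratum 02 has rows but no events
  d$s_death[d$s_prog == 0] <- 0
  st <- idm_stack(idm_adjust_ties(d))
  struct <- idm_structure(
    list(list(covariate = "residual_tumor", transitions = "01"),
         list(covariate = "age", transitions = "12"),
         list(covariate = "t010", transitions = "12")),
    strata = as.list(IDM_TRANSITIONS))
  fit <- idm_fit(st, struct)
  for (b in fit$baselines) {
    expect_true(all(diff(c(0, b$cumhaz)) >= 0))
  }
  expect_equal(nrow(fit$baselines[["02"]]), 0L)
})

test_that("hazard ratios and fit criteria are invariant to covariate centering", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 300), seed = 10))
  d2 <- d; d2$age <- d2$age - mean(d2$age)
  f1 <- idm_fit(d, idm_structure_full(), tol = 1e-10)
  f2 <- idm_fit(d2, idm_structure_full(), tol = 1e-10)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("joint stratified fit equals per-transition fits", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 300), seed = 12))
  st <- idm_stack(d)
  joint <- idm_fit(st, idm_structure_full(), tol = 1e-10)
  covs <- c("age", "residual_tumor", "figo_high")
  parts <- lapply(IDM_TRANSITIONS, function(tr) {
    sub <- st[st$transition == tr, , drop = FALSE]
    attr(sub, "covariates") <- attr(st, "covariates")
    class(sub) <- class(st)
    eff <- lapply(covs, function(cv) list(covariate = cv, transitions = tr))
    if (tr == "12") eff <- c(eff, list(list(covariate = "t010",
                                            transitions = "12")))
    idm_fit(sub, idm_structure(eff, strata = list(tr)), tol = 1e-10)
  })
  sep_beta <- unlist(lapply(parts, function(f) f$coefficients))
  expect_equal(sort(names(sep_beta)), sort(names(joint$coefficients)))
  expect_equal(sep_beta[names(joint$coefficients)], joint$coefficients,
               tolerance = 1e-8)
  expect_equal(sum(vapply(parts, `[[`, 0, "loglik")), joint$loglik,
               tolerance = 1e-8)
})

test_that("Breslow and Efron agree when event times are untied", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 250), seed = 14))
  fb <- idm_fit(d, idm_structure_ph(), ties = "breslow", tol = 1e-10)
  fe <- idm_fit(d, idm_structure_ph(), ties = "efron", tol = 1e-10)
  expect_equal(fb$coefficients, fe$coefficients, tolerance = 1e-8)
  expect_equal(fb$loglik, fe$loglik, tolerance = 1e-8)
})

test_that("monotone likelihood is reported, naming the coefficient", {
  st <- surv01(tstop = c(1, 2, 10, 11, 12, 13),
               status = c(1, 1, 0, 0, 1, 1),
               x = c(1, 1, 1, 0, 0, 0))
  # x = 1 subjects fail first or are censored: likelihood increases in beta
  expect_error(suppressWarnings(idm_fit(st, struct01())), "x.01")
})

test_that("Schoenfeld test keeps its level under a proportional effect", {
  reps <- 150
  rej <- 0L
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n <- 300
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.05 * exp(0.7 * x))     # truly proportional effect
    cens <- runif(n, 0, 40)
    st <- surv01(pmin(tt, cens), as.integer(tt <= cens), x)
    fit <- idm_fit(st, struct01())
    p <- idm_ph_test(fit, "x.01")$p
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / reps, 0.005)
  expect_lte(rej / reps, 0.12)
})

test_that("Schoenfeld test detects a strong proportionality violation", {
  set.seed(77)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  # crossing hazards: increasing Weibull for x = 1, decreasing for x = 0
  tt <- ifelse(x == 1, rweibull(n, shape = 3, scale = 12),
               rweibull(n, shape = 0.7, scale = 12))
  st <- surv01(tt, rep(1, n), x)
  fit <- idm_fit(st, struct01())
  expect_lt(idm_ph_test(fit, "x.01")$p, 0.01)
})

test_that("log-log curves report log cumulative baselines with offsets preserved", {
  grid <- c(2)
  st <- idm_structure(list(), strata = list("01", "02", "12"))
  m <- idm_model(st, setNames(numeric(0), character(0)),
                 list(`01` = data.frame(time = 2, dhaz = 0.5),
                      `02` = data.frame(time = numeric(0), dhaz = numeric(0)),
                      `12` = data.frame(time = numeric(0), dhaz = numeric(0))))
  ll <- idm_loglog(m)
  expect_equal(nrow(ll), 1L)
  expect_equal(ll$log_time, log(2))
  expect_equal(ll$log_cumhaz, log(0.5))

  # exactly proportional baselines differ by a constant vertical offset
  tgrid <- c(1, 3, 7, 12)
  dh <- c(0.05, 0.1, 0.02, 0.2)
  k <- 2.5
  m2 <- idm_model(st, setNames(numeric(0), character(0)),
                  list(`01` = data.frame(time = tgrid, dhaz = dh),
                       `02` = data.frame(time = tgrid, dhaz = k * dh),
                       `12` = data.frame(time = numeric(0), dhaz = numeric(0))))
  ll2 <- idm_loglog(m2)
  off <- ll2$log_cumhaz[ll2$stratum == "02"] -
    ll2$log_cumhaz[ll2$stratum == "01"]
  expect_equal(off, rep(log(k), length(tgrid)))
})

test_that("fitted Weibull data yield log-log curves with slope near the shape", {
  set.seed(5)
  n <- 3000
  shape <- 1.6
  tt <- rweibull(n, shape = shape, scale = 30)
  st <- surv01(tt, rep(1, n), rep(0, n))
  fit <- idm_fit(st, idm_structure(list(), strata = list("01")))
  ll <- idm_loglog(fit)
  mid <- ll[ll$time > quantile(tt, 0.2) & ll$time < quantile(tt, 0.9), ]
  slope <- coef(lm(log_cumhaz ~ log_time, data = mid))[2]
  expect_equal(unname(slope), shape, tolerance = 0.1)
})

test_that("fit serialization round-trips to identical predictions", {
  d <- idm_adjust_ties(idm_simulate(idm_sim_config(n = 200), seed = 21))
  fit <- idm_fit(d, idm_structure_reduced())
  f <- withr::local_tempfile(fileext = ".json")
  idm_fit_to_json(fit, f)
  model <- idm_model_from_json(f)
  prof <- list(age = 55, residual_tumor = 1, figo_high = 1)
  expect_equal(
    idm_overall_survival(model, prof, times = c(6, 12, 24)),
    idm_overall_survival(fit, prof, times = c(6, 12, 24)),
    tolerance = 1e-12)
})
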