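# Independent oracles and tiny fixture builders used across the suite.

# Stratified Cox log partial likelihood by explicit risk-set enumeration
# (Breslow tie handling).  Deliberately naive: loops over event times and
# enumerates each risk set {tstop >= u} afresh.
pl_bruteforce <- function(tstop, status, X, beta, stratum = rep(1, length(tstop))) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (s in unique(stratum)) {
    in_s <- stratum == s
    for (u in sort(unique(tstop[in_s & status == 1]))) {
      ev <- in_s & status == 1 & tstop == u
      risk <- in_s & tstop >= u
      ll <- ll + sum(eta[ev]) - sum(ev) * log(sum(exp(eta[risk])))
    }
  }
  ll
}

# Central-difference score of the brute-force partial likelihood.
score_bruteforce <- function(tstop, status, X, beta, stratum = rep(1, length(tstop)),
                             h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    bp <- bm <- beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    (pl_bruteforce(tstop, status, X, bp, stratum) -
       pl_bruteforce(tstop, status, X, bm, stratum)) / (2 * h)
  }, 0)
}

# Plain (unweighted) Brier score oracle: mean squared difference between
# being-alive status at t and predicted survival.  Valid without censoring.
brier_plain <- function(surv, time, status, times) {
  vapply(seq_along(times), function(k) {
    alive <- time > times[k]
    mean((as.numeric(alive) - surv[, k])^2)
  }, 0)
}

# A fitted-model object with constant transition hazards, built from dense
# baseline jump grids; closed-form state probabilities are available for it.
const_hazard_model <- function(l01, l02, l12, bt = 0, tmax = 20, dt = 0.002) {
  grid <- seq(dt, tmax, by = dt)
  bl <- function(rate) data.frame(time = grid, dhaz = rate * dt)
  eff <- if (bt != 0) list(list(covariate = "t010", transitions = "12")) else list()
  st <- idm_structure(eff, strata = list("01", "02", "12"))
  beta <- if (bt != 0) c(t010.12 = bt) else setNames(numeric(0), character(0))
  idm_model(st, beta, list(`01` = bl(l01), `02` = bl(l02), `12` = bl(l12)))
}

# Closed-form illness-death state probabilities under constant hazards
# (no sojourn effect).
const_hazard_truth <- function(l01, l02, l12, t) {
  P00 <- exp(-(l01 + l02) * t)
  P01 <- l01 / (l01 + l02 - l12) * (exp(-l12 * t) - exp(-(l01 + l02) * t))
  list(P00 = P00, P01 = P01, P02 = 1 - P00 - P01)
}

# Small wide-format cohort with hand-set values.
tiny_cohort <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    t_prog = c(10, 5, 25, 8),
    s_prog = c(1, 0, 0, 1),
    t_death = c(25, 5, 25, 12),
    s_death = c(1, 0, 0, 0),
    age = c(60, 55, 70, 48),
    residual_tumor = c(1, 0, 1, 0),
    figo_high = c(1, 1, 0, 0),
    stringsAsFactors = FALSE
  )
}

# Random small stacked-style single-stratum survival data for property tests.
random_surv_data <- function(n, p = 2, seed = 1) {
  set.seed(seed)
  list(tstop = round(rexp(n, 0.2) + 0.1, 2),
       status = rbinom(n, 1, 0.7),
       X = matrix(rnorm(n * p), n, p))
}

# Coerce a plain data frame of counting-process rows into the stacked class
# (single- or few-transition fixtures for engine tests).
as_stacked <- function(df, covs = character()) {
  if (is.null(df$tstart)) df$tstart <- 0
  if (is.null(df$t010)) df$t010 <- 0
  attr(df, "covariates") <- covs
  class(df) <- c("idm_stacked", "data.frame")
  df
}

# Single-stratum fixture on transition 01 with one covariate x.
surv01 <- function(tstop, status, x) {
  as_stacked(data.frame(id = seq_along(tstop), transition = "01",
                        tstart = 0, tstop = tstop, status = status,
                        t010 = 0, x = x), covs = "x")
}

struct01 <- function() idm_structure(list(list(covariate = "x", transitions = "01")),
                                     strata = list("01"))
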