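# Linear predictor of `profiles` (data frame, one row per subject) on one
# transition; t010 contributes separately in the convolution and is excluded
# here unless `t010` values are supplied.
.idm_lp <- function(fit, profiles, transition, t010 = NULL) {
  st <- fit$structure
  lp <- rep(0, nrow(profiles))
  for (i in seq_len(nrow(st$effects))) {
    e <- st$effects[i, ]
    if (!transition %in% e$transitions[[1]]) next
    if (e$covariate == "t010") {
      if (!is.null(t010)) lp <- lp + fit$coefficients[[e$term]] * t010
      next
    }
    if (is.null(profiles[[e$covariate]]))
      stop("profile is missing covariate: ", e$covariate)
    lp <- lp + fit$coefficients[[e$term]] * as.numeric(profiles[[e$covariate]])
  }
  if (transition %in% st$prop_terms)
    lp <- lp + fit$coefficients[[.prop_term_name(transition)]]
  lp
}

.idm_t010_coef <- function(fit) {
  st <- fit$structure
  hit <- st$effects$term[st$effects$covariate == "t010"]
  if (length(hit)) fit$coefficients[[hit]] else 0
}

.baseline_for <- function(fit, transition) {
  fit$baselines[[.stratum_of(fit$structure$strata, transition)]]
}

# State-occupation probabilities from the healthy state for a matrix of
# profiles.  Returns list of n x length(times) matrices P00, P01, P02.
# P00(t) = exp(-L01(t) - L02(t)); P01(t) sums, over baseline jumps u <= t of
# the progression stratum, P00(u-) dL01(u) S12(t - u | t010 = u), with
# S12(s|u) = exp(-L12_0(s) exp(lp12 + beta_t010 u)); P02 is the complement.
.state_probs <- function(fit, profiles, times) {
  n <- nrow(profiles)
  b01 <- .baseline_for(fit, "01")
  b02 <- .baseline_for(fit, "02")
  b12 <- .baseline_for(fit, "12")
  e01 <- exp(.idm_lp(fit, profiles, "01"))
  e02 <- exp(.idm_lp(fit, profiles, "02"))
  lp12 <- .idm_lp(fit, profiles, "12")
  bt <- .idm_t010_coef(fit)

  L01_t <- outer(e01, .cumhaz_at(b01, times))        # n x T
  L02_t <- outer(e02, .cumhaz_at(b02, times))
  P00 <- exp(-(L01_t + L02_t))

  u <- b01$time                                       # progression jump grid
  P01 <- matrix(0, n, length(times))
  if (length(u)) {
    dL01 <- outer(e01, b01$dhaz)                      # n x U
    P00m <- exp(-(outer(e01, .cumhaz_at(b01, u, left = TRUE)) +
                    outer(e02, .cumhaz_at(b02, u, left = TRUE))))
    w12 <- exp(outer(rep(1, n), bt * u) + lp12)       # exp(lp12 + bt*u), n x U
    core <- P00m * dL01                               # n x U
    for (k in seq_along(times)) {
      tk <- times[k]
      ok <- u <= tk
      if (!any(ok)) next
      L12s <- .cumhaz_at(b12, tk - u[ok])             # length sum(ok)
      S12 <- exp(-sweep(w12[, ok, drop = FALSE], 2, L12s, `*`))
      P01[, k] <- rowSums(core[, ok, drop = FALSE] * S12)
    }
  }
  P02 <- 1 - P00 - P01
  list(P00 = P00, P01 = P01, P02 = P02)
}

#' Predict state-occupation probabilities for a covariate profile
#'
#' Computes, for one covariate profile under a fitted clock-reset model, the
#' probability of being healthy, progressed, or dead at each time since
#' origin (when starting healthy at time 0), or of being alive vs dead at
#' each time since progression (when starting from the progression state,
#' which requires the observed healthy-state sojourn `t010`).  Probabilities
#' from the healthy state are obtained by convolution over the Breslow jump
#' times of the progression baseline, with the post-progression survival
#' evaluated at the sojourn time reached at each jump.
#'
#' @param fit An `idm_fit` (or [idm_model()]).
#' @param profile One-row data frame (or named list) of covariate values.
#' @param times Evaluation grid in months (default monthly 0 to 120).
#' @param from Starting state.
#' @param t010 Healthy-state sojourn in months (required when
#'   `from = "progression"`).
#' @return Data frame of class `idm_probs`: `time` plus `p_healthy`,
#'   `p_progression`, `p_death` (from healthy) or `p_progression`, `p_death`
#'   (from progression).
#' @examples
#' cohort <- idm_simulate(idm_sim_config(n = 300), seed = 1)
#' fit <- idm_fit(cohort, idm_structure_reduced())
#' pr <- idm_predict(fit, list(age = 50, residual_tumor = 0, figo_high = 0),
#'                   times = 0:60)
#' head(pr)
#' @export
idm_predict <- function(fit, profile, times = 0:120,
                        from = c("healthy", "progression"), t010 = NULL) {
  from <- match.arg(from)
  profile <- as.data.frame(profile)
  if (nrow(profile) != 1) stop("'profile' must describe one subject")
  if (any(times < 0)) stop("'times' must be nonnegative")
  last <- max(unlist(lapply(fit$baselines, function(b)
    if (nrow(b)) max(b$time) else 0)))
  if (max(times) > last)
    warning("prediction grid extends beyond the last event time (",
            signif(last, 4), " months); baselines carried forward")
  if (from == "healthy") {
    ps <- .state_probs(fit, profile, times)
    out <- data.frame(time = times, p_healthy = drop(ps$P00),
                      p_progression = drop(ps$P01), p_death = drop(ps$P02))
  } else {
    if (is.null(t010)) stop("'t010' is required for prediction from progression")
    lp <- .idm_lp(fit, profile, "12") + .idm_t010_coef(fit) * t010
    b12 <- .baseline_for(fit, "12")
    P11 <- exp(-.cumhaz_at(b12, times) * exp(lp))
    out <- data.frame(time = times, p_progression = P11, p_death = 1 - P11)
  }
  attr(out, "from") <- from
  class(out) <- c("idm_probs", "data.frame")
  out
}

#' Model-based overall survival from time 0
#'
#' `S(t) = P00(t) + P01(t)`: the probability of being alive (healthy or
#' progressed) at `t` when starting healthy, the quantity scored by the
#' prediction-error machinery.
#'
#' @inheritParams idm_predict
#' @return Numeric vector `S(times)`.
#' @export
idm_overall_survival <- function(fit, profile, times) {
  pr <- idm_predict(fit, profile, times, from = "healthy")
  pr$p_healthy + pr$p_progression
}

#' Overall-survival predictions for many subjects
#'
#' Vectorized form of [idm_overall_survival()] used by the evaluation module.
#'
#' @param fit An `idm_fit`.
#' @param newdata Data frame of covariate profiles (one row per subject).
#' @param times Evaluation grid.
#' @return Matrix, `nrow(newdata)` rows by `length(times)` columns.
#' @export
idm_surv_matrix <- function(fit, newdata, times) {
  ps <- .state_probs(fit, as.data.frame(newdata), times)
  ps$P00 + ps$P01
}

#' Microsimulation cross-check of the state probabilities
#'
#' Samples individual illness-death paths from the fitted hazards (first-event
#' time and type by inversion of the subject-specific cumulative hazards over
#' the Breslow jump grid; post-progression survival from the sojourn-dependent
#' 1->2 hazard) and tabulates empirical state frequencies.  Serves as an
#' independent check of the convolution in [idm_predict()].
#'
#' @inheritParams idm_predict
#' @param n_paths Number of simulated paths.
#' @param seed Integer seed (local RNG; the global seed is untouched).
#' @return Data frame of class `idm_probs` with empirical `p_healthy`,
#'   `p_progression`, `p_death`; attribute `n_paths`.
#' @export
idm_microsimulate <- function(fit, profile, n_paths, times = 0:120, seed = 1) {
  profile <- as.data.frame(profile)
  stopifnot(n_paths >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  b01 <- .baseline_for(fit, "01"); b02 <- .baseline_for(fit, "02")
  b12 <- .baseline_for(fit, "12")
  e01 <- exp(.idm_lp(fit, profile, "01"))
  e02 <- exp(.idm_lp(fit, profile, "02"))
  lp12 <- .idm_lp(fit, profile, "12")
  bt <- .idm_t010_coef(fit)

  grid0 <- sort(unique(c(b01$time, b02$time)))
  d01 <- numeric(length(grid0)); d02 <- numeric(length(grid0))
  d01[match(b01$time, grid0)] <- b01$dhaz * e01
  d02[match(b02$time, grid0)] <- b02$dhaz * e02
  cumtot <- cumsum(d01 + d02)

  E <- stats::rexp(n_paths)
  j <- findInterval(E, cumtot) + 1L          # first jump with cumtot >= E
  exits <- j <= length(grid0)
  t_exit <- rep(Inf, n_paths)
  t_exit[exits] <- grid0[j[exits]]
  p01 <- ifelse(exits, d01[pmin(j, length(grid0))] /
                  (d01[pmin(j, length(grid0))] + d02[pmin(j, length(grid0))]), 0)
  prog <- exits & stats::runif(n_paths) < p01

  t_death <- rep(Inf, n_paths)
  t_death[exits & !prog] <- t_exit[exits & !prog]
  if (any(prog) && nrow(b12)) {
    u <- t_exit[prog]
    scale12 <- exp(lp12 + bt * u)
    E2 <- stats::rexp(sum(prog))
    # residual death time: first s with cumhaz12(s) >= E2 / scale
    k <- findInterval(E2 / scale12, b12$cumhaz) + 1L
    got <- k <= nrow(b12)
    s <- rep(Inf, sum(prog))
    s[got] <- b12$time[k[got]]
    t_death[prog] <- u + s
  }

  n <- n_paths
  P00 <- vapply(times, function(t) sum(t_exit > t) / n, 0)
  P01 <- vapply(times, function(t) sum(t_exit <= t & prog & t_death > t) / n, 0)
  out <- data.frame(time = times, p_healthy = P00, p_progression = P01,
                    p_death = 1 - P00 - P01)
  attr(out, "from") <- "healthy"
  attr(out, "n_paths") <- n_paths
  class(out) <- c("idm_probs", "data.frame")
  out
}

#' Stacked-band plot of state probabilities
#'
#' @param x An `idm_probs` object.
#' @param main Plot title.
#' @param cols Band colours (severity order).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.idm_probs <- function(x, main = NULL,
                           cols = c("grey85", "grey60", "grey30"), ...) {
  from <- attr(x, "from")
  t <- x$time
  if (identical(from, "progression")) {
    bands <- cbind(x$p_progression, x$p_progression + x$p_death)
    labs <- c("progression", "death")
    cols <- cols[-1]
  } else {
    bands <- cbind(x$p_healthy, x$p_healthy + x$p_progression,
                   x$p_healthy + x$p_progression + x$p_death)
    labs <- c("healthy", "progression", "death")
  }
  graphics::plot(range(t), c(0, 1), type = "n", xlab = "months",
                 ylab = "state probability", main = main, ...)
  lower <- rep(0, length(t))
  for (i in seq_len(ncol(bands))) {
    graphics::polygon(c(t, rev(t)), c(lower, rev(bands[, i])),
                      col = cols[i], border = NA)
    lower <- bands[, i]
  }
  graphics::legend("topright", legend = labs, fill = cols, bty = "n")
  invisible(x)
}
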