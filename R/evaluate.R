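#' Kaplan-Meier estimate of the censoring distribution
#'
#' Reverse Kaplan-Meier: the event indicator is flipped so that censorings are
#' the "events", giving the estimate `G(t)` of the probability of remaining
#' uncensored, the weight denominator of the IPCW Brier score.
#'
#' @param time Follow-up times (overall survival scale).
#' @param status Death indicators (1 = death, 0 = censored).
#' @return An object of class `idm_censkm` with functions `G(t)` and
#'   `Gminus(t)` (left limit).
#' @export
idm_censoring_km <- function(time, status) {
  stopifnot(length(time) == length(status), all(status %in% c(0, 1)))
  if (all(status == 1)) {
    ev <- function(t) rep(1, length(t))
    out <- list(G = ev, Gminus = ev, times = numeric(0), surv = numeric(0))
  } else {
    sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
    tt <- sf$time; ss <- sf$surv
    evalG <- function(t, left = FALSE) {
      idx <- findInterval(if (left) t - 1e-12 else t, tt)
      c(1, ss)[idx + 1L]
    }
    out <- list(G = function(t) evalG(t),
                Gminus = function(t) evalG(t, left = TRUE),
                times = tt, surv = ss)
  }
  class(out) <- "idm_censkm"
  out
}

#' IPCW Brier score curve
#'
#' Time-dependent Brier score with inverse-probability-of-censoring weights:
#' at each grid time `t`, deaths by `t` contribute
#' `(0 - S_i(t))^2 / G(T_i-)` and subjects still under observation past `t`
#' contribute `(1 - S_i(t))^2 / G(t)`; censored-before-`t` subjects get
#' weight 0.  With no censoring this reduces exactly to the plain mean squared
#' difference between survival status and prediction.
#'
#' @param surv Matrix of predicted survival, one row per subject, one column
#'   per element of `times` (a vector is recycled across subjects).
#' @param time,status Observed follow-up and death indicator per subject.
#' @param times Evaluation grid.
#' @param cens Optional [idm_censoring_km()] object (estimated from
#'   `time`/`status` when absent).
#' @return Numeric vector: Brier score at each grid time.
#' @export
idm_brier <- function(surv, time, status, times, cens = NULL) {
  n <- length(time)
  if (is.vector(surv)) surv <- matrix(surv, n, length(times), byrow = TRUE)
  stopifnot(nrow(surv) == n, ncol(surv) == length(times))
  if (is.null(cens)) cens <- idm_censoring_km(time, status)
  Gm <- cens$Gminus(time)
  bs <- numeric(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    dead <- time <= t & status == 1
    alive <- time > t
    Gt <- cens$G(t)
    if (any(alive) && Gt <= 0)
      stop("censoring survival G(t) is zero at t = ", t,
           "; restrict the grid to the censoring support")
    if (any(dead & Gm <= 0))
      stop("censoring survival G(T-) is zero for an observed death; ",
           "restrict the grid")
    contrib <- numeric(n)
    contrib[dead] <- (surv[dead, k])^2 / Gm[dead]
    contrib[alive] <- (1 - surv[alive, k])^2 / Gt
    bs[k] <- mean(contrib)
  }
  bs
}

# All-pairs no-information error: every prediction scored against every
# subject's status.  Equivalent to averaging the IPCW Brier over all
# (prediction j, subject i) pairs.
.idm_noinf <- function(surv, time, status, times, cens) {
  n <- length(time)
  Gm <- cens$Gminus(time)
  out <- numeric(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    dead <- time <= t & status == 1
    alive <- time > t
    Gt <- cens$G(t)
    s <- surv[, k]
    # mean over subjects i of mean over predictions j
    per_i <- numeric(n)
    per_i[dead] <- mean(s^2) / Gm[dead]
    per_i[alive] <- mean((1 - s)^2) / Gt
    out[k] <- mean(per_i)
  }
  out
}

#' Kaplan-Meier null-model survival predictions
#'
#' The covariate-free benchmark: the overall-survival Kaplan-Meier curve,
#' used as every subject's prediction.
#'
#' @inheritParams idm_brier
#' @return Numeric vector `S(times)` (recycled across subjects by the
#'   scoring functions).
#' @export
idm_km_null <- function(time, status, times) {
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  idx <- findInterval(times, sf$time)
  c(1, sf$surv)[idx + 1L]
}

#' The 0.632+ combination of apparent and cross-validated error
#'
#' Combines the downward-biased apparent (resubstitution) error with the
#' upward-biased bootstrap cross-validation error: the relative overfit
#' `R(t) = (err_cv - err_app) / (err_noinf - err_app)` (clipped to `[0, 1]`,
#' and set to 0 with a warning where the no-information error does not exceed
#' the apparent error) drives the weight `w(t) = 0.632 / (1 - 0.368 R(t))`,
#' and the estimate is `(1 - w) err_app + w err_cv`.
#'
#' @param err_app,err_cv,err_noinf Error curves on a common grid.
#' @return List with `R`, `w`, `err632plus` (vectors on the grid).
#' @export
idm_err632plus <- function(err_app, err_cv, err_noinf) {
  stopifnot(length(err_app) == length(err_cv),
            length(err_app) == length(err_noinf))
  err_cv1 <- pmin(err_cv, err_noinf)   # standard guard of the 0.632+ estimator
  R <- (err_cv1 - err_app) / (err_noinf - err_app)
  degenerate <- !(err_noinf > err_app) | !(err_cv1 > err_app)
  bad <- degenerate & err_noinf < err_app - 1e-12 & err_cv > err_app
  if (any(bad))
    warning("no-information error falls below the apparent error at ",
            sum(bad), " grid point(s); R set to 0")
  R[degenerate] <- 0
  R <- pmin(pmax(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  list(R = R, w = w, err632plus = (1 - w) * err_app + w * err_cv1)
}

#' Bootstrap cross-validated prediction error
#'
#' Repeatedly draws training subsamples without replacement, refits the whole
#' modelling pipeline on each, and scores the held-out subjects with the IPCW
#' Brier score; the cross-validated error is the average over replicates.
#' Replicates whose training fit fails are dropped (with a count reported via
#' attribute `failed`).
#'
#' @param data Wide-format records.
#' @param pipeline Function `(train_data) -> function(newdata, times) ->
#'   survival matrix`; see [idm_pipeline()].
#' @param times Evaluation grid.
#' @param B Number of training subsamples.
#' @param train_n Training-set size (must leave at least 10 validation
#'   subjects).
#' @param seed Integer seed.
#' @return Numeric vector `err_cv(times)` with attribute `failed`.
#' @export
idm_bootstrap_cv <- function(data, pipeline, times, B = 300, train_n = 300,
                             seed = 1) {
  n <- nrow(data)
  if (train_n >= n - 9)
    stop("'train_n' must leave at least 10 validation subjects")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  acc <- matrix(NA_real_, B, length(times))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, train_n)
    val <- data[-idx, , drop = FALSE]
    predictor <- tryCatch(suppressWarnings(pipeline(data[idx, , drop = FALSE])),
                          error = function(e) NULL)
    if (is.null(predictor)) { failed <- failed + 1L; next }
    S <- predictor(val, times)
    acc[b, ] <- idm_brier(S, val$t_death, val$s_death, times)
  }
  if (failed == B) stop("every training fit failed")
  out <- colMeans(acc, na.rm = TRUE)
  attr(out, "failed") <- failed
  out
}

#' Fit-and-predict pipelines for the evaluation module
#'
#' `idm_pipeline(structure)` refits the given effect structure on each
#' training set; `idm_pipeline_reduce(start, ...)` re-runs the step-down
#' specification procedure on each training set before predicting (so model
#' selection is cross-validated together with estimation).  `"null"` gives
#' the Kaplan-Meier null model.
#'
#' @param structure An [idm_structure()].
#' @param start Starting structure for the reduction.
#' @param alpha Significance level of the reduction.
#' @param moves Candidate-move specification, see [idm_reduce()].
#' @return A pipeline function for [idm_bootstrap_cv()] / [idm_pec()].
#' @export
idm_pipeline <- function(structure) {
  force(structure)
  function(train) {
    fit <- idm_fit(train, structure)
    function(newdata, times) idm_surv_matrix(fit, newdata, times)
  }
}

#' @rdname idm_pipeline
#' @export
idm_pipeline_reduce <- function(start, alpha = 0.05, moves = "auto") {
  force(start); force(alpha); force(moves)
  function(train) {
    red <- idm_reduce(train, start, alpha = alpha, moves = moves)
    fit <- red$final
    function(newdata, times) idm_surv_matrix(fit, newdata, times)
  }
}

#' @rdname idm_pipeline
#' @export
idm_pipeline_null <- function() {
  function(train) {
    t_tr <- train$t_death; s_tr <- train$s_death
    function(newdata, times) {
      s <- idm_km_null(t_tr, s_tr, times)
      matrix(s, nrow(newdata), length(times), byrow = TRUE)
    }
  }
}

#' Prediction error curves with the 0.632+ estimator
#'
#' For each candidate model: the apparent IPCW Brier curve (fit on all data,
#' scored on all data), the bootstrap cross-validated curve
#' ([idm_bootstrap_cv()]), the all-pairs no-information curve, and their
#' 0.632+ combination.  The default grid runs over event times up to the 95th
#' percentile of follow-up so the censoring weights stay bounded.
#'
#' @param data Wide-format records.
#' @param pipelines Named list of pipeline functions (see [idm_pipeline()]);
#'   a Kaplan-Meier null model is added when `include_null = TRUE`.
#' @param times Evaluation grid (default as above).
#' @param B,train_n,seed Passed to [idm_bootstrap_cv()].
#' @param include_null Add the null-model curve?
#' @return Object of class `idm_pec`: per model a list with `err_app`,
#'   `err_cv`, `err_noinf`, `R`, `w`, `err632plus`; plus `times`.
#' @export
idm_pec <- function(data, pipelines, times = NULL, B = 300, train_n = 300,
                    seed = 1, include_null = TRUE) {
  if (is.null(times)) {
    cutoff <- stats::quantile(data$t_death, 0.95)
    ev <- sort(unique(data$t_death[data$s_death == 1]))
    times <- c(0, ev[ev <= cutoff])
  }
  if (include_null && !"null" %in% names(pipelines))
    pipelines <- c(pipelines, list(null = idm_pipeline_null()))
  cens <- idm_censoring_km(data$t_death, data$s_death)
  out <- list(times = times, models = list())
  for (nm in names(pipelines)) {
    pl <- pipelines[[nm]]
    predictor <- pl(data)
    S <- predictor(data, times)
    if (is.vector(S)) S <- matrix(S, nrow(data), length(times), byrow = TRUE)
    err_app <- idm_brier(S, data$t_death, data$s_death, times, cens)
    err_noinf <- .idm_noinf(S, data$t_death, data$s_death, times, cens)
    err_cv <- idm_bootstrap_cv(data, pl, times, B = B, train_n = train_n,
                               seed = seed)
    comb <- idm_err632plus(err_app, err_cv, err_noinf)
    out$models[[nm]] <- list(err_app = err_app, err_cv = as.numeric(err_cv),
                             err_noinf = err_noinf, R = comb$R, w = comb$w,
                             err632plus = comb$err632plus,
                             failed = attr(err_cv, "failed"))
  }
  class(out) <- "idm_pec"
  out
}

#' @export
print.idm_pec <- function(x, ...) {
  cat("Prediction error curves (0.632+), grid of", length(x$times),
      "time points\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-10s mean err632+ = %.4f (apparent %.4f, cv %.4f)\n", nm,
                mean(m$err632plus), mean(m$err_app), mean(m$err_cv)))
  }
  invisible(x)
}

#' Plot prediction error curves
#'
#' @param x An `idm_pec` object.
#' @param which Curve to draw per model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.idm_pec <- function(x, which = "err632plus", ...) {
  Y <- vapply(x$models, function(m) m[[which]], numeric(length(x$times)))
  graphics::matplot(x$times, Y, type = "l", lty = 1, lwd = 2,
                    xlab = "months", ylab = paste0("prediction error (", which, ")"),
                    ...)
  graphics::legend("topleft", legend = colnames(Y), lty = 1, lwd = 2,
                   col = seq_len(ncol(Y)), bty = "n")
  invisible(x)
}
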