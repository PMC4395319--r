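#' Fit a stratified Cox model under an effect structure
#'
#' Maximizes the stratified Cox partial likelihood on the stacked
#' counting-process table, with one nonparametric baseline hazard per baseline
#' stratum of the structure and one coefficient per declared effect (shared
#' effects are single columns populated across their transitions, so equality
#' restrictions are imposed by construction).  Baseline cumulative hazards are
#' extracted per stratum as Breslow step functions.
#'
#' @param data Wide-format records or an `idm_stacked` table.
#' @param structure An [idm_structure()].
#' @param ties Tie-handling method for the partial likelihood.
#' @param tol Convergence tolerance (relative change in log partial
#'   likelihood).
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `idm_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `loglik_null`, `df`, `aic`, `baselines` (per-stratum data
#'   frames `time`/`dhaz`/`cumhaz`), `structure`, `n`, `nevent`, `ties`.
#' @examples
#' cohort <- idm_simulate(idm_sim_config(n = 200), seed = 1)
#' fit <- idm_fit(cohort, idm_structure_reduced())
#' summary(fit)
#' @export
idm_fit <- function(data, structure, ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 100) {
  ties <- match.arg(ties)
  stacked <- if (inherits(data, "idm_stacked")) data else idm_stack(data)
  X <- idm_design(stacked, structure)
  stratum <- vapply(stacked$transition, function(tr)
    .stratum_of(structure$strata, tr), "")
  for (s in names(structure$strata))
    if (!any(stratum == s))
      stop("empty stratum: ", s)

  dd <- data.frame(.tstop = stacked$tstop, .status = stacked$status,
                   .stratum = stratum, check.names = FALSE)
  dd <- cbind(dd, as.data.frame(X))
  terms <- colnames(X)

  if (length(terms)) {
    fml <- stats::as.formula(paste(
      "survival::Surv(.tstop, .status) ~",
      paste(c(terms, "survival::strata(.stratum)"), collapse = " + ")))
    cfit <- survival::coxph(fml, data = dd, ties = ties, x = TRUE, y = TRUE,
                            control = survival::coxph.control(
                              eps = tol, iter.max = max_iter))
    beta <- stats::setNames(as.numeric(cfit$coefficients), terms)
    if (anyNA(beta))
      stop("coefficient(s) inestimable (collinear or no events): ",
           paste(terms[is.na(beta)], collapse = ", "))
    if (any(abs(beta) > 15))
      stop("monotone likelihood: coefficient diverging for ",
           paste(terms[abs(beta) > 15], collapse = ", "))
    vc <- cfit$var
    dimnames(vc) <- list(terms, terms)
    loglik <- cfit$loglik[2]
    loglik_null <- cfit$loglik[1]
  } else {
    fml <- stats::as.formula(
      "survival::Surv(.tstop, .status) ~ survival::strata(.stratum)")
    cfit <- survival::coxph(fml, data = dd, ties = ties, x = TRUE, y = TRUE)
    beta <- stats::setNames(numeric(0), character(0))
    vc <- matrix(0, 0, 0)
    loglik <- loglik_null <- cfit$loglik[1]
  }

  lp <- if (length(beta)) drop(X %*% beta) else rep(0, nrow(X))
  baselines <- lapply(names(structure$strata), function(s)
    .breslow_stratum(stacked$tstop[stratum == s],
                     stacked$status[stratum == s], lp[stratum == s]))
  names(baselines) <- names(structure$strata)

  out <- list(coefficients = beta, se = sqrt(diag(vc))[seq_along(beta)],
              vcov = vc, loglik = loglik, loglik_null = loglik_null,
              df = length(beta), aic = -2 * loglik + 2 * length(beta),
              baselines = baselines, structure = structure,
              n = length(unique(stacked$id)), nrow = nrow(stacked),
              nevent = sum(stacked$status), ties = ties,
              coxph = cfit)
  class(out) <- "idm_fit"
  out
}

# Breslow cumulative baseline hazard for one stratum: increment at each event
# time u is (events at u) / sum of exp(lp) over the risk set {tstop >= u}.
.breslow_stratum <- function(tstop, status, lp) {
  if (!length(tstop))
    return(data.frame(time = numeric(0), dhaz = numeric(0),
                      cumhaz = numeric(0)))
  ut <- sort(unique(tstop[status == 1]))
  if (!length(ut))
    return(data.frame(time = numeric(0), dhaz = numeric(0),
                      cumhaz = numeric(0)))
  w <- exp(lp)
  # risk-set denominators by cumulative sums over sorted exit times
  o <- order(tstop)
  ts <- tstop[o]; ws <- w[o]
  revcum <- rev(cumsum(rev(ws)))            # sum of w over {tstop >= ts[k]}
  first_ge <- findInterval(ut - 1e-12, ts) + 1L
  denom <- revcum[first_ge]
  dvec <- vapply(ut, function(u) sum(status[tstop == u]), 0)
  dh <- dvec / denom
  data.frame(time = ut, dhaz = dh, cumhaz = cumsum(dh))
}

# Evaluate a cumulative baseline (data.frame time/cumhaz) at times t,
# carrying the last value forward; left = TRUE gives the left limit.
.cumhaz_at <- function(baseline, t, left = FALSE) {
  if (!nrow(baseline)) return(rep(0, length(t)))
  tt <- if (left) t - 1e-12 else t
  idx <- findInterval(tt, baseline$time)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' @export
print.idm_fit <- function(x, ...) {
  cat("Clock-reset illness-death Cox fit (", x$ties, " ties)\n", sep = "")
  cat(sprintf("  n = %d subjects, %d rows, %d events\n", x$n, x$nrow, x$nevent))
  cat(sprintf("  log partial likelihood = %.3f (null %.3f), df = %d, AIC = %.1f\n",
              x$loglik, x$loglik_null, x$df, x$aic))
  if (x$df) print(summary(x), ...)
  invisible(x)
}

#' Summarize an illness-death model fit
#'
#' @param object An `idm_fit`.
#' @param conf_level Confidence level of the Wald intervals.
#' @param ... Unused.
#' @return Data frame with one row per coefficient: `term`, `beta`, `se`,
#'   `hr`, `lower`, `upper`, `p` (two-sided Wald).
#' @export
summary.idm_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- object$coefficients; se <- object$se
  data.frame(term = names(b), beta = unname(b), se = unname(se),
             hr = exp(unname(b)),
             lower = exp(unname(b) - z * se), upper = exp(unname(b) + z * se),
             p = 2 * stats::pnorm(-abs(unname(b) / se)),
             stringsAsFactors = FALSE)
}

#' Evaluate the stratified log partial likelihood at fixed coefficients
#'
#' Evaluates (without maximizing) the same stratified partial likelihood that
#' [idm_fit()] maximizes, at a supplied coefficient vector — the hook for
#' checking the engine against independent risk-set enumeration.
#'
#' @param data Wide-format records or an `idm_stacked` table.
#' @param structure An [idm_structure()].
#' @param beta Coefficient vector in [idm_terms()] order (names optional).
#' @param ties Tie-handling method.
#' @return The log partial likelihood at `beta`.
#' @export
idm_loglik <- function(data, structure, beta, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stacked <- if (inherits(data, "idm_stacked")) data else idm_stack(data)
  X <- idm_design(stacked, structure)
  if (length(beta) != ncol(X))
    stop("beta must have length ", ncol(X))
  if (!is.null(names(beta))) beta <- beta[colnames(X)]
  stratum <- vapply(stacked$transition, function(tr)
    .stratum_of(structure$strata, tr), "")
  dd <- data.frame(.tstop = stacked$tstop, .status = stacked$status,
                   .stratum = stratum, check.names = FALSE)
  dd <- cbind(dd, as.data.frame(X))
  fml <- stats::as.formula(paste(
    "survival::Surv(.tstop, .status) ~",
    paste(c(colnames(X), "survival::strata(.stratum)"), collapse = " + ")))
  cfit <- suppressWarnings(survival::coxph(
    fml, data = dd, ties = ties, init = as.numeric(beta),
    control = survival::coxph.control(iter.max = 0)))
  unname(cfit$loglik[2])
}

#' Likelihood-ratio test of nested effect structures
#'
#' @param nested,full `idm_fit` objects on the same data; `nested$structure`
#'   must be a restriction of `full$structure`.
#' @return List `statistic` (`2 * (loglik_full - loglik_nested)`), `df`
#'   (difference in free coefficients) and `p` (upper chi-square tail).
#' @export
idm_lr_test <- function(nested, full) {
  if (!.is_restriction_of(nested$structure, full$structure))
    stop("'nested' structure is not a restriction of 'full'")
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6)
    stop("nested model has larger likelihood; models are not nested as fitted")
  stat <- max(stat, 0)
  df <- full$df - nested$df
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Schoenfeld test of proportional hazards for one coefficient
#'
#' Correlates the scaled Schoenfeld residuals of a coefficient with a
#' transform of event time (score-type chi-square test on 1 df), the standard
#' check that a hazard ratio is time-constant.
#'
#' @param fit An `idm_fit`.
#' @param term Coefficient name (see [idm_terms()]); a bare covariate name is
#'   accepted when it maps to a single coefficient.
#' @param transform Time transform: analysis time (`"identity"`, default),
#'   ranks, or the Kaplan-Meier transform.
#' @return List `statistic`, `df`, `p`.
#' @export
idm_ph_test <- function(fit, term, transform = c("identity", "rank", "km")) {
  transform <- match.arg(transform)
  if (fit$nevent < 2) stop("fewer than 2 events")
  terms <- names(fit$coefficients)
  if (!term %in% terms) {
    hit <- terms[fit$structure$effects$covariate == term]
    if (length(hit) == 1) term <- hit
    else stop("'term' must name one coefficient; candidates: ",
              paste(terms, collapse = ", "))
  }
  zp <- survival::cox.zph(fit$coxph, transform = transform, terms = FALSE,
                          global = FALSE)
  tab <- zp$table
  row <- match(term, rownames(tab))
  if (is.na(row)) stop("no Schoenfeld residuals for ", term)
  list(statistic = unname(tab[row, "chisq"]), df = unname(tab[row, "df"]),
       p = unname(tab[row, "p"]))
}

#' Log-log cumulative baseline hazard curves
#'
#' Returns `ln(cumulative baseline hazard)` against `ln(analysis time)` per
#' baseline stratum; parallel curves support proportional baseline hazards.
#'
#' @param fit An `idm_fit`.
#' @return Data frame `stratum`, `time`, `log_time`, `log_cumhaz` (rows with
#'   positive time and positive cumulative hazard only).
#' @export
idm_loglog <- function(fit) {
  out <- lapply(names(fit$baselines), function(s) {
    b <- fit$baselines[[s]]
    b <- b[b$time > 0 & b$cumhaz > 0, , drop = FALSE]
    if (!nrow(b)) return(NULL)
    data.frame(stratum = s, time = b$time, log_time = log(b$time),
               log_cumhaz = log(b$cumhaz), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Serialize a fit to JSON
#'
#' Coefficient table, likelihoods and per-stratum baseline jump tables; the
#' result can be rebuilt into a predictable model with
#' [idm_model_from_json()].
#'
#' @param fit An `idm_fit`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
idm_fit_to_json <- function(fit, path = NULL) {
  st <- fit$structure
  obj <- list(
    coefficients = summary(fit),
    loglik = fit$loglik, loglik_null = fit$loglik_null,
    df = fit$df, aic = fit$aic, ties = fit$ties,
    structure = list(
      effects = lapply(seq_len(nrow(st$effects)), function(i)
        list(covariate = st$effects$covariate[i],
             transitions = st$effects$transitions[[i]])),
      strata = unname(st$strata), prop_terms = st$prop_terms),
    baselines = lapply(fit$baselines, function(b)
      list(time = b$time, dhaz = b$dhaz))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Rebuild a predictable model from JSON
#'
#' @param path File written by [idm_fit_to_json()] (or a JSON string).
#' @return An [idm_model()] usable with the prediction functions.
#' @export
idm_model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  st <- idm_structure(
    effects = lapply(seq_len(nrow(obj$structure$effects)), function(i)
      list(covariate = obj$structure$effects$covariate[i],
           transitions = obj$structure$effects$transitions[[i]])),
    strata = as.list(obj$structure$strata),
    prop_terms = obj$structure$prop_terms %||% character())
  beta <- stats::setNames(obj$coefficients$beta, obj$coefficients$term)
  baselines <- lapply(obj$baselines, function(b)
    data.frame(time = b$time, dhaz = b$dhaz, cumhaz = cumsum(b$dhaz)))
  idm_model(st, beta, baselines)
}

#' Assemble an illness-death model from explicit parameters
#'
#' Builds a predictable model object directly from an effect structure, a
#' coefficient vector and per-stratum baseline jump tables — e.g. published
#' coefficients, or analytic baselines for validation against closed forms.
#'
#' @param structure An [idm_structure()].
#' @param coefficients Named vector covering [idm_terms()] of `structure`.
#' @param baselines Named list (one per stratum of `structure`) of data frames
#'   with columns `time` and `dhaz` (jump increments); `cumhaz` is completed
#'   if absent.
#' @return An object of class `idm_fit` (without likelihood information).
#' @export
idm_model <- function(structure, coefficients, baselines) {
  terms <- idm_terms(structure)
  if (!setequal(names(coefficients), terms))
    stop("coefficients must be named exactly: ", paste(terms, collapse = ", "))
  coefficients <- coefficients[terms]
  if (!setequal(names(baselines), names(structure$strata)))
    stop("baselines must be named exactly: ",
         paste(names(structure$strata), collapse = ", "))
  baselines <- lapply(baselines[names(structure$strata)], function(b) {
    b <- as.data.frame(b)
    if (is.null(b$cumhaz)) b$cumhaz <- cumsum(b$dhaz)
    if (is.unsorted(b$time, strictly = TRUE))
      stop("baseline jump times must be strictly increasing")
    if (any(b$dhaz < 0)) stop("baseline increments must be nonnegative")
    b[c("time", "dhaz", "cumhaz")]
  })
  out <- list(coefficients = coefficients,
              se = rep(NA_real_, length(coefficients)),
              vcov = NULL, loglik = NA_real_, loglik_null = NA_real_,
              df = length(coefficients),
              aic = NA_real_, baselines = baselines, structure = structure,
              n = NA_integer_, nrow = NA_integer_, nevent = NA_integer_,
              ties = "none", coxph = NULL)
  class(out) <- "idm_fit"
  out
}
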