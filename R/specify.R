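#' Test the Markov assumption via the healthy-state sojourn time
#'
#' Under a clock-reset formulation the process is Markov only if the time
#' spent healthy before progression carries no information about survival
#' after progression.  The test fits the model with and without `t010` on the
#' 1->2 transition and reports the Wald and likelihood-ratio evidence; a
#' significant `t010` rejects the (homogeneous) Markov/semi-Markov assumption
#' in favour of the non-homogeneous semi-Markov model.
#'
#' @param data Wide-format records or an `idm_stacked` table.
#' @param structure Structure *including* `t010` (default the full model).
#' @return List `coef`, `se`, `wald_p`, `lr_statistic`, `lr_p`.
#' @export
idm_markov_test <- function(data, structure = idm_structure_full()) {
  t010_term <- structure$effects$term[structure$effects$covariate == "t010"]
  if (!length(t010_term))
    stop("'structure' must include t010 on transition 12")
  stacked <- if (inherits(data, "idm_stacked")) data else idm_stack(data)
  if (!sum(stacked$status[stacked$transition == "12"]))
    stop("no progression-to-death events; Markov test undefined")
  with_t <- idm_fit(stacked, structure)
  without <- idm_fit(stacked, idm_drop_effect(structure, "t010", "12"))
  lr <- idm_lr_test(without, with_t)
  b <- with_t$coefficients[[t010_term]]
  se <- with_t$se[[match(t010_term, names(with_t$coefficients))]]
  list(coef = b, se = se, wald_p = 2 * stats::pnorm(-abs(b / se)),
       lr_statistic = lr$statistic, lr_p = lr$p)
}

#' Pairwise tests of proportional baseline hazards
#'
#' For each pair of transitions, their rows are pooled into a single stratum
#' with a 0/1 indicator distinguishing the second transition (plus all
#' transition-specific covariate effects of the full model); the Schoenfeld
#' test on that indicator checks whether the two baseline hazards are
#' proportional on their (reset) clocks.  Log-log curve data of the full
#' transition-specific fit are returned alongside for graphical assessment.
#'
#' @param data Wide-format records or an `idm_stacked` table.
#' @param structure Full transition-specific structure used for the adjusting
#'   covariate effects.
#' @param transform Schoenfeld time transform, see [idm_ph_test()].
#' @return List with `tests` (data frame `pair`, `statistic`, `p`) and
#'   `loglog` (see [idm_loglog()]).
#' @export
idm_baseline_tests <- function(data, structure = idm_structure_full(),
                               transform = "identity") {
  stacked <- if (inherits(data, "idm_stacked")) data else idm_stack(data)
  pairs <- list(c("01", "02"), c("01", "12"), c("02", "12"))
  res <- lapply(pairs, function(pr) {
    sub <- stacked[stacked$transition %in% pr, , drop = FALSE]
    attr(sub, "covariates") <- attr(stacked, "covariates")
    class(sub) <- class(stacked)
    eff <- .df_to_effects(structure$effects[
      vapply(structure$effects$transitions,
             function(t) any(t %in% pr), NA), , drop = FALSE])
    # restrict shared effects to the pair's transitions
    eff <- lapply(eff, function(e) {
      e$transitions <- intersect(e$transitions, pr)
      e
    })
    st <- idm_structure(eff, strata = list(pr), prop_terms = pr[2])
    fit <- idm_fit(sub, st)
    pht <- idm_ph_test(fit, .prop_term_name(pr[2]), transform = transform)
    data.frame(pair = paste(pr, collapse = " vs "),
               statistic = pht$statistic, p = pht$p,
               stringsAsFactors = FALSE)
  })
  full_fit <- idm_fit(stacked, structure)
  list(tests = do.call(rbind, res), loglog = idm_loglog(full_fit))
}

# ---- step-down reduction ---------------------------------------------------

#' Describe a candidate reduction move
#'
#' @param type `"merge"` (equality restriction) or `"drop"` (remove effect).
#' @param covariate Covariate name.
#' @param transitions Transition set of the move.
#' @return A move descriptor for [idm_reduce()].
#' @export
idm_move <- function(type = c("merge", "drop"), covariate, transitions) {
  type <- match.arg(type)
  list(type = type, covariate = covariate,
       transitions = .check_transitions(transitions))
}

.apply_move <- function(structure, move) {
  switch(move$type,
         merge = idm_merge_effect(structure, move$covariate, move$transitions),
         drop = idm_drop_effect(structure, move$covariate, move$transitions))
}

.move_label <- function(move) {
  paste0(move$type, "(", move$covariate, "; ",
         paste(move$transitions, collapse = ","), ")")
}

# Auto candidate moves for the current structure/fit: per covariate
# (lexicographic) the all-transitions merge, then the death-pair merge, then
# drops of effects with Wald p > alpha.  t010 and exp(gamma) terms are never
# candidates.
.auto_moves <- function(structure, fit, alpha) {
  ef <- structure$effects
  covs <- sort(setdiff(unique(ef$covariate), "t010"))
  moves <- list()
  for (cv in covs) {
    rows <- which(ef$covariate == cv)
    if (length(rows) >= 2) {
      all_tr <- sort(unlist(ef$transitions[rows]))
      moves[[length(moves) + 1L]] <- idm_move("merge", cv, all_tr)
    }
    has02 <- any(vapply(ef$transitions[rows], function(t) identical(t, "02"), NA))
    has12 <- any(vapply(ef$transitions[rows], function(t) identical(t, "12"), NA))
    if (has02 && has12)
      moves[[length(moves) + 1L]] <- idm_move("merge", cv, c("02", "12"))
  }
  if (!is.null(fit)) {
    sm <- summary(fit)
    for (cv in covs) {
      rows <- which(ef$covariate == cv)
      for (r in rows) {
        p <- sm$p[match(ef$term[r], sm$term)]
        if (is.finite(p) && p > alpha)
          moves[[length(moves) + 1L]] <-
            idm_move("drop", cv, ef$transitions[[r]])
      }
    }
  }
  moves
}

#' Step-down reduction of an illness-death effect structure
#'
#' Greedy specification search: at each step, candidate moves (equality
#' restrictions merging a covariate's coefficients across transitions, then
#' drops of main effects whose Wald p-value exceeds `alpha`) are evaluated
#' against the current model.  A move is acceptable when the likelihood-ratio
#' test against the current model is non-significant (`p >= alpha`) *and* the
#' AIC does not increase; among acceptable moves the one with the lowest AIC
#' wins, ties broken by the larger df reduction, then lexicographic covariate
#' order.  The loop stops when no move is acceptable.  The sojourn-time
#' covariate `t010` and `exp(gamma)` proportionality terms are never
#' candidates.
#'
#' Supplying `moves` as a list of [idm_move()] descriptors replaces the
#' automatic candidate generation: the moves are tried in the given order and
#' each is accepted only if it passes the same LR/AIC guard, which reproduces
#' a prespecified reduction path.
#'
#' @param data Wide-format records or an `idm_stacked` table.
#' @param start Starting [idm_structure()] (typically [idm_structure_ph()]).
#' @param alpha Significance level for the LR guard and the Wald screen of
#'   droppable effects.
#' @param moves `"auto"` or an ordered list of [idm_move()]s.
#' @param ties,tol,max_iter Passed to [idm_fit()].
#' @return Object of class `idm_reduction`: `steps` (list; each with `name`,
#'   `move`, `fit`, `lr`, `aic_delta`, `accepted`), `final` (`idm_fit`),
#'   `trace` (data frame, one row per model in the accepted path).
#' @export
idm_reduce <- function(data, start, alpha = 0.05, moves = "auto",
                       ties = "breslow", tol = 1e-9, max_iter = 100) {
  stacked <- if (inherits(data, "idm_stacked")) data else idm_stack(data)
  fit0 <- idm_fit(stacked, start, ties = ties, tol = tol, max_iter = max_iter)
  cur <- list(structure = start, fit = fit0)
  steps <- list()
  trace <- data.frame(model = "start", move = "", loglik = fit0$loglik,
                      aic = fit0$aic, df = fit0$df, lr_stat = NA_real_,
                      lr_df = NA_integer_, lr_p = NA_real_,
                      stringsAsFactors = FALSE)
  nm_i <- 0L
  next_name <- function() {
    nm_i <<- nm_i + 1L
    LETTERS[1 + nm_i]  # B, C, D, ...
  }
  eval_move <- function(move) {
    st <- tryCatch(.apply_move(cur$structure, move), error = function(e) NULL)
    if (is.null(st)) return(NULL)
    fit <- tryCatch(idm_fit(stacked, st, ties = ties, tol = tol,
                            max_iter = max_iter), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    lr <- idm_lr_test(fit, cur$fit)
    list(move = move, structure = st, fit = fit, lr = lr,
         aic_delta = fit$aic - cur$fit$aic)
  }
  accept <- function(cand, name) {
    steps[[length(steps) + 1L]] <<- list(
      name = name, move = cand$move, fit = cand$fit, lr = cand$lr,
      aic_delta = cand$aic_delta, accepted = TRUE)
    trace <<- rbind(trace, data.frame(
      model = name, move = .move_label(cand$move), loglik = cand$fit$loglik,
      aic = cand$fit$aic, df = cand$fit$df, lr_stat = cand$lr$statistic,
      lr_df = cand$lr$df, lr_p = cand$lr$p, stringsAsFactors = FALSE))
    cur <<- list(structure = cand$structure, fit = cand$fit)
  }

  if (is.list(moves)) {
    for (mv in moves) {
      cand <- eval_move(mv)
      if (is.null(cand)) {
        warning("move ", .move_label(mv), " could not be evaluated; skipped")
        next
      }
      if (cand$lr$p >= alpha && cand$aic_delta <= 1e-9) {
        accept(cand, next_name())
      } else {
        steps[[length(steps) + 1L]] <- list(
          name = NA_character_, move = mv, fit = cand$fit, lr = cand$lr,
          aic_delta = cand$aic_delta, accepted = FALSE)
      }
    }
  } else {
    repeat {
      cands <- .auto_moves(cur$structure, cur$fit, alpha)
      evaled <- Filter(Negate(is.null), lapply(cands, eval_move))
      ok <- Filter(function(cand)
        cand$lr$p >= alpha && cand$aic_delta <= 1e-9, evaled)
      if (!length(ok)) break
      aics <- vapply(ok, function(cand) cand$fit$aic, 0)
      dfs <- vapply(ok, function(cand) cand$fit$df, 0L)
      cvs <- vapply(ok, function(cand) cand$move$covariate, "")
      o <- order(round(aics, 6), dfs, cvs)
      accept(ok[[o[1]]], next_name())
    }
  }
  out <- list(steps = steps, final = cur$fit, start = fit0, trace = trace,
              alpha = alpha)
  class(out) <- "idm_reduction"
  out
}

#' @export
print.idm_reduction <- function(x, digits = 4, ...) {
  cat("Step-down specification (alpha =", x$alpha, ")\n")
  tr <- x$trace
  tr$loglik <- round(tr$loglik, 1); tr$aic <- round(tr$aic, 1)
  tr$lr_stat <- round(tr$lr_stat, 3); tr$lr_p <- round(tr$lr_p, digits)
  print(tr, row.names = FALSE)
  invisible(x)
}
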