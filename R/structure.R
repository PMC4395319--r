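#' @importFrom stats pchisq pnorm qnorm rbinom rexp rnorm runif setNames
#'   approx aggregate
NULL

# Canonical transition codes of the illness-death model without recovery:
# 0 = healthy, 1 = progression, 2 = death (absorbing).
IDM_TRANSITIONS <- c("01", "02", "12")

.check_transitions <- function(trans) {
  trans <- as.character(trans)
  bad <- setdiff(trans, IDM_TRANSITIONS)
  if (length(bad))
    stop("unknown transition(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(IDM_TRANSITIONS, collapse = ", "), ")")
  sort(unique(trans))
}

.effect_term <- function(covariate, transitions) {
  paste(c(covariate, sort(transitions)), collapse = ".")
}

#' Declare an effect structure for an illness-death model
#'
#' An effect structure declares, for a clock-reset illness-death model, which
#' regression coefficients exist: each *effect* is one free coefficient for a
#' covariate acting on a set of transitions (a singleton set gives a
#' transition-specific coefficient, a larger set a coefficient shared across
#' those transitions).  It also declares how the three transition baseline
#' hazards are partitioned into strata, and whether transitions sharing a
#' stratum are distinguished by a proportionality factor `exp(gamma)`
#' (an indicator of arriving in the death state from progression).
#'
#' The sojourn time in the healthy state enters as the covariate `"t010"`,
#' allowed only on transition `"12"`; its presence makes the model
#' non-homogeneous semi-Markov.
#'
#' @param effects A list; each element is a list or vector with elements
#'   `covariate` (name) and `transitions` (character subset of
#'   `c("01","02","12")`).
#' @param strata A list of character vectors partitioning `c("01","02","12")`;
#'   transitions in one element share a (nonparametric) baseline hazard.
#' @param prop_terms Character vector of transitions that receive an
#'   `exp(gamma)` proportionality indicator within their (shared) stratum;
#'   usually `"12"` or empty.
#' @return An object of class `idm_structure` with elements `effects`
#'   (data frame: `term`, `covariate`, `transitions` list-column), `strata`,
#'   `prop_terms`, and `df` (number of free coefficients).
#' @examples
#' # transition-specific age everywhere, residual tumour shared across all three
#' idm_structure(
#'   effects = list(
#'     list(covariate = "age", transitions = "01"),
#'     list(covariate = "age", transitions = "02"),
#'     list(covariate = "residual_tumor", transitions = c("01", "02", "12"))
#'   ),
#'   strata = list("01", c("02", "12")), prop_terms = "12"
#' )
#' @export
idm_structure <- function(effects = list(), strata = as.list(IDM_TRANSITIONS),
                          prop_terms = character()) {
  eff <- lapply(effects, function(e) {
    e <- as.list(e)
    if (is.null(e$covariate) || is.null(e$transitions))
      stop("each effect needs 'covariate' and 'transitions'")
    trs <- .check_transitions(e$transitions)
    if (e$covariate == "t010" && !identical(trs, "12"))
      stop("t010 is defined only on transition 12")
    list(term = .effect_term(e$covariate, trs),
         covariate = as.character(e$covariate), transitions = trs)
  })
  terms <- vapply(eff, `[[`, "", "term")
  if (anyDuplicated(terms))
    stop("duplicated effect: ", terms[duplicated(terms)][1])
  # no covariate twice on the same transition
  inc <- unlist(lapply(eff, function(e)
    paste(e$covariate, e$transitions, sep = "@")), use.names = FALSE)
  if (anyDuplicated(inc))
    stop("covariate appears twice on one transition: ",
         inc[duplicated(inc)][1])

  # strata must partition a (sub)set of the transitions; structures over a
  # transition subset arise in pairwise baseline-proportionality tests
  strata <- lapply(strata, .check_transitions)
  flat <- unlist(strata, use.names = FALSE)
  if (!length(flat) || anyDuplicated(flat))
    stop("'strata' must partition a subset of the transitions ",
         paste(IDM_TRANSITIONS, collapse = ", "))
  covered <- unlist(lapply(eff, `[[`, "transitions"))
  if (!all(covered %in% flat))
    stop("effect transitions outside the strata: ",
         paste(setdiff(covered, flat), collapse = ", "))
  names(strata) <- vapply(strata, paste, "", collapse = "+")

  prop_terms <- .check_transitions(prop_terms)
  for (tr in prop_terms) {
    s <- .stratum_of(strata, tr)
    if (length(strata[[s]]) < 2)
      stop("proportional term on ", tr,
           " requires it to share a stratum with another transition")
  }

  ef <- data.frame(term = terms %||% character(),
                   covariate = vapply(eff, `[[`, "", "covariate") %||% character(),
                   stringsAsFactors = FALSE)
  ef$transitions <- lapply(eff, `[[`, "transitions")

  out <- structure(list(effects = ef, strata = strata,
                        prop_terms = prop_terms), class = "idm_structure")
  out$df <- nrow(ef) + length(prop_terms)
  out
}

`%||%` <- function(a, b) if (length(a)) a else b

.stratum_of <- function(strata, transition) {
  for (nm in names(strata)) if (transition %in% strata[[nm]]) return(nm)
  stop("transition ", transition, " not in any stratum")
}

.prop_term_name <- function(transition) paste0("prog.", transition)

#' @export
print.idm_structure <- function(x, ...) {
  cat("Illness-death effect structure (", x$df, " free coefficients)\n", sep = "")
  cat("  baseline strata:", paste(names(x$strata), collapse = " | "), "\n")
  if (length(x$prop_terms))
    cat("  proportional exp(gamma) term on:",
        paste(x$prop_terms, collapse = ", "), "\n")
  if (nrow(x$effects)) {
    cat("  effects:\n")
    for (i in seq_len(nrow(x$effects)))
      cat("    ", x$effects$term[i], "\n", sep = "")
  } else cat("  effects: (none)\n")
  invisible(x)
}

#' Coefficient names of an effect structure
#' @param structure An [idm_structure()].
#' @return Character vector: effect terms, then any `exp(gamma)` indicator
#'   terms (`prog.<transition>`).
#' @export
idm_terms <- function(structure) {
  c(structure$effects$term,
    vapply(structure$prop_terms, .prop_term_name, ""))
}

#' Full transition-specific semi-Markov structure
#'
#' Every covariate gets its own coefficient on each of the three transitions,
#' each transition keeps its own baseline hazard, and the healthy-state
#' sojourn time `t010` acts on the progression-to-death transition.  With the
#' default three covariates this is a 10-coefficient model.
#'
#' @param covariates Covariate names (each placed on all three transitions).
#' @param t010 Include the sojourn-time covariate on transition 1->2?
#' @return An [idm_structure()].
#' @export
idm_structure_full <- function(covariates = c("age", "residual_tumor", "figo_high"),
                               t010 = TRUE) {
  eff <- list()
  for (tr in IDM_TRANSITIONS)
    for (cv in covariates)
      eff[[length(eff) + 1L]] <- list(covariate = cv, transitions = tr)
  if (t010)
    eff[[length(eff) + 1L]] <- list(covariate = "t010", transitions = "12")
  idm_structure(eff, strata = as.list(IDM_TRANSITIONS))
}

#' Proportional-baseline (PH) structure
#'
#' Same effects as [idm_structure_full()], but the two transitions into death
#' share one baseline hazard, distinguished by a proportionality factor
#' `exp(gamma)` (the mortality shift caused by progression).  With the default
#' covariates this has 11 free coefficients.
#'
#' @inheritParams idm_structure_full
#' @return An [idm_structure()].
#' @export
idm_structure_ph <- function(covariates = c("age", "residual_tumor", "figo_high"),
                             t010 = TRUE) {
  idm_share_baseline(idm_structure_full(covariates, t010 = t010),
                     transitions = c("02", "12"), prop = TRUE)
}

#' Reduced proportional-baseline structure
#'
#' The parsimonious six-coefficient model: residual tumour shared across all
#' three transitions, high stage acting on progression only, age acting on the
#' two death transitions (separately), the sojourn time `t010` on 1->2, and a
#' shared death baseline with `exp(gamma)`.
#'
#' @return An [idm_structure()].
#' @export
idm_structure_reduced <- function() {
  idm_structure(
    effects = list(
      list(covariate = "residual_tumor", transitions = c("01", "02", "12")),
      list(covariate = "figo_high", transitions = "01"),
      list(covariate = "age", transitions = "02"),
      list(covariate = "age", transitions = "12"),
      list(covariate = "t010", transitions = "12")
    ),
    strata = list("01", c("02", "12")), prop_terms = "12"
  )
}

#' Merge a covariate's coefficients into one shared coefficient
#'
#' Replaces the separate effects of `covariate` on `transitions` by a single
#' coefficient shared across their union (an equality restriction; removes
#' `k - 1` degrees of freedom when `k` effects are merged).
#'
#' @param structure An [idm_structure()].
#' @param covariate Covariate name.
#' @param transitions Transitions over which the effect becomes shared; the
#'   existing effects of the covariate must tile this set exactly.
#' @return The restricted [idm_structure()].
#' @export
idm_merge_effect <- function(structure, covariate, transitions) {
  transitions <- .check_transitions(transitions)
  ef <- structure$effects
  hit <- which(ef$covariate == covariate &
                 vapply(ef$transitions, function(t) all(t %in% transitions), NA))
  if (length(hit) < 2)
    stop("no merge possible: ", covariate, " has ", length(hit),
         " effect(s) within {", paste(transitions, collapse = ","), "}")
  covered <- sort(unlist(ef$transitions[hit]))
  if (!identical(covered, transitions))
    stop("existing effects of ", covariate, " do not tile {",
         paste(transitions, collapse = ","), "}")
  keep <- ef[-hit, , drop = FALSE]
  eff <- c(.df_to_effects(keep),
           list(list(covariate = covariate, transitions = transitions)))
  idm_structure(eff, structure$strata, structure$prop_terms)
}

#' Drop a covariate effect
#'
#' Removes the coefficient of `covariate` acting on exactly `transitions`
#' (whether transition-specific or shared).
#'
#' @inheritParams idm_merge_effect
#' @return The restricted [idm_structure()].
#' @export
idm_drop_effect <- function(structure, covariate, transitions) {
  transitions <- .check_transitions(transitions)
  ef <- structure$effects
  hit <- which(ef$term == .effect_term(covariate, transitions))
  if (!length(hit))
    stop("no effect ", .effect_term(covariate, transitions), " in structure")
  idm_structure(.df_to_effects(ef[-hit, , drop = FALSE]),
                structure$strata, structure$prop_terms)
}

#' Share a baseline hazard across transitions
#'
#' Merges the named transitions into one baseline stratum.  With
#' `prop = TRUE`, transitions after the first (in `01 < 02 < 12` order) get an
#' `exp(gamma)` proportionality indicator, so merging the two death
#' transitions adds one coefficient while removing one nonparametric baseline
#' (the full 10-coefficient model becomes the 11-coefficient PH model).
#'
#' @param structure An [idm_structure()].
#' @param transitions Transitions to pool into one stratum (currently in
#'   separate strata).
#' @param prop Add proportionality terms distinguishing the pooled
#'   transitions?
#' @return The restricted [idm_structure()].
#' @export
idm_share_baseline <- function(structure, transitions = c("02", "12"),
                               prop = TRUE) {
  transitions <- .check_transitions(transitions)
  cur <- vapply(transitions, function(tr) .stratum_of(structure$strata, tr), "")
  if (anyDuplicated(cur))
    stop("transitions ", paste(transitions, collapse = ","),
         " already share a stratum")
  if (any(vapply(structure$strata[unique(cur)], length, 0L) > 1))
    stop("can only merge singleton strata")
  strata <- structure$strata[setdiff(names(structure$strata), unique(cur))]
  strata <- c(strata, list(transitions))
  prop_terms <- structure$prop_terms
  if (prop) prop_terms <- sort(unique(c(prop_terms, transitions[-1])))
  idm_structure(.df_to_effects(structure$effects), strata, prop_terms)
}

.df_to_effects <- function(ef) {
  lapply(seq_len(nrow(ef)), function(i)
    list(covariate = ef$covariate[i], transitions = ef$transitions[[i]]))
}

#' @export
format.idm_structure <- function(x, ...) {
  paste0("idm_structure(df=", x$df, ")")
}

# Is `nested` a restriction of `full`?  True when every covariate incidence
# (covariate acting on a transition) of `nested` also occurs in `full`, each
# nested effect's transition set is a union of full-effect transition sets,
# nested strata are coarsenings, and df strictly decreases or stays equal.
.is_restriction_of <- function(nested, full) {
  if (nested$df > full$df) return(FALSE)
  inc <- function(s) unlist(lapply(seq_len(nrow(s$effects)), function(i)
    paste(s$effects$covariate[i], s$effects$transitions[[i]], sep = "@")))
  if (!all(inc(nested) %in% inc(full))) return(FALSE)
  # every full stratum must sit inside one nested stratum
  for (fs in full$strata) {
    host <- vapply(nested$strata, function(ns) all(fs %in% ns), NA)
    if (!any(host)) return(FALSE)
  }
  TRUE
}
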