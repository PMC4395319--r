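#' Validate wide-format illness-death records
#'
#' One record per subject: months from origin (e.g. surgery) to progression or
#' to censoring on that endpoint (`t_prog`, indicator `s_prog`), months to
#' death or censoring (`t_death`, `s_death`), and baseline covariates.  The
#' checks enforce the observable structure of the illness-death process
#' without recovery: nonnegative times, binary statuses, progression not after
#' death, unique ids.  A record with `t_prog == t_death` and `s_prog = 0` is
#' permitted (shared censoring or direct death with no progression observed).
#'
#' @param data Data frame with columns `id`, `t_prog`, `s_prog`, `t_death`,
#'   `s_death` plus covariate columns.
#' @return Data frame with one row per record: `id`, `valid`, and a `reasons`
#'   string (empty when valid).
#' @export
idm_validate <- function(data) {
  req <- c("id", "t_prog", "s_prog", "t_death", "s_death")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  n <- nrow(data)
  reasons <- vector("list", n)
  add <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  add(duplicated(data$id) | duplicated(data$id, fromLast = TRUE),
      "duplicate id")
  add(!is.finite(data$t_prog) | data$t_prog < 0, "negative or missing t_prog")
  add(!is.finite(data$t_death) | data$t_death < 0, "negative or missing t_death")
  add(!data$s_prog %in% c(0, 1), "non-binary status (s_prog)")
  add(!data$s_death %in% c(0, 1), "non-binary status (s_death)")
  ok_so_far <- lengths(reasons) == 0
  add(ok_so_far & data$s_prog == 1 & data$t_prog > data$t_death,
      "progression after death")
  add(ok_so_far & data$s_prog == 0 & data$t_prog != data$t_death,
      "censored progression time differs from last-contact time")
  covs <- setdiff(names(data), req)
  for (cv in covs)
    add(!is.finite(as.numeric(data[[cv]])), paste0("missing covariate ", cv))
  data.frame(id = data$id, valid = lengths(reasons) == 0,
             reasons = vapply(reasons, paste, "", collapse = "; "),
             stringsAsFactors = FALSE)
}

.assert_valid <- function(data) {
  rep <- idm_validate(data)
  if (!all(rep$valid)) {
    bad <- rep[!rep$valid, , drop = FALSE]
    stop("invalid records: ",
         paste(utils::head(paste0(bad$id, " (", bad$reasons, ")"), 5),
               collapse = "; "),
         if (nrow(bad) > 5) sprintf(" ... and %d more", nrow(bad) - 5) else "")
  }
  invisible(data)
}

#' Separate coincident progression and death times
#'
#' When progression and death are recorded at the same time (both observed),
#' the counting-process expansion would produce a zero-length sojourn in the
#' progression state.  The adjustment subtracts `delta` (default half a month)
#' from the progression time of such records, leaving all others untouched.
#'
#' @param data Validated wide-format records.
#' @param delta Months subtracted from coincident progression times.
#' @return The records with adjusted `t_prog`.
#' @export
idm_adjust_ties <- function(data, delta = 0.5) {
  .assert_valid(data)
  tie <- data$s_prog == 1 & data$s_death == 1 & data$t_prog == data$t_death
  if (any(tie & data$t_prog <= delta))
    stop("tie adjustment would produce non-positive progression time for id(s): ",
         paste(data$id[tie & data$t_prog <= delta], collapse = ", "))
  data$t_prog[tie] <- data$t_prog[tie] - delta
  data
}

#' Expand wide records to the stacked counting-process table
#'
#' Each subject contributes one row per at-risk transition, on that
#' transition's reset clock.  The `(0,1)` and `(0,2)` rows span
#' `(0, min(t_prog, t_death)]` with event indicators `s_prog` and
#' `s_death & !s_prog`; a subject with observed progression additionally
#' contributes a `(1,2)` row spanning `(0, t_death - t_prog]` whose `t010`
#' column records the healthy-state sojourn time (making the sojourn available
#' as a covariate for the post-progression death hazard).  Raw covariates are
#' carried onto every row; if an effect structure is supplied, the expanded
#' design columns (one per free coefficient) are appended as well.
#'
#' @param data Validated, tie-adjusted wide-format records.
#' @param structure Optional [idm_structure()]; adds its design columns.
#' @return A data frame of class `idm_stacked` with columns `id`,
#'   `transition`, `tstart`, `tstop`, `status`, `t010`, the covariates, and
#'   (optionally) design columns; attribute `covariates` lists the covariate
#'   names.
#' @export
idm_stack <- function(data, structure = NULL) {
  .assert_valid(data)
  reserved <- c("id", "t_prog", "s_prog", "t_death", "s_death")
  covs <- setdiff(names(data), reserved)
  t0stop <- pmin(data$t_prog, data$t_death)
  if (any(t0stop <= 0))
    stop("zero-length healthy-state interval for id(s): ",
         paste(data$id[t0stop <= 0], collapse = ", "))
  tie <- data$s_prog == 1 & data$s_death == 1 & data$t_prog == data$t_death
  if (any(tie))
    stop("coincident progression and death times for id(s): ",
         paste(data$id[tie], collapse = ", "),
         "; run idm_adjust_ties() first")

  base <- data[covs]
  mk <- function(trans, tstop, status, t010, sel = rep(TRUE, nrow(data))) {
    cbind(data.frame(id = data$id[sel], transition = trans, tstart = 0,
                     tstop = tstop[sel], status = as.integer(status[sel]),
                     t010 = t010[sel], stringsAsFactors = FALSE),
          base[sel, , drop = FALSE])
  }
  zero <- rep(0, nrow(data))
  out <- rbind(
    mk("01", t0stop, data$s_prog, zero),
    mk("02", t0stop, data$s_death * (1 - data$s_prog), zero),
    mk("12", data$t_death - data$t_prog, data$s_death, data$t_prog,
       sel = data$s_prog == 1)
  )
  if (any(out$tstop <= out$tstart))
    stop("internal error: non-positive interval in stacked table")
  rownames(out) <- NULL
  attr(out, "covariates") <- covs
  class(out) <- c("idm_stacked", "data.frame")
  if (!is.null(structure)) {
    X <- idm_design(out, structure)
    out[colnames(X)] <- as.data.frame(X)
  }
  out
}

#' Design matrix of an effect structure on a stacked table
#'
#' One column per free coefficient: a covariate's column carries its value on
#' rows of the transitions the effect acts on and 0 elsewhere (shared effects
#' populate a single column across their transitions); `exp(gamma)`
#' proportionality terms are 0/1 indicators of the marked transition.
#'
#' @param stacked An `idm_stacked` table (see [idm_stack()]).
#' @param structure An [idm_structure()].
#' @return Numeric matrix with `nrow(stacked)` rows, one column per term.
#' @export
idm_design <- function(stacked, structure) {
  covs <- c(attr(stacked, "covariates"), "t010")
  need <- setdiff(unique(structure$effects$covariate), covs)
  if (length(need))
    stop("structure references unknown covariate(s): ",
         paste(need, collapse = ", "))
  terms <- idm_terms(structure)
  X <- matrix(0, nrow(stacked), length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_len(nrow(structure$effects))) {
    e <- structure$effects[i, ]
    on <- stacked$transition %in% e$transitions[[1]]
    X[on, e$term] <- as.numeric(stacked[[e$covariate]][on])
  }
  for (tr in structure$prop_terms)
    X[stacked$transition == tr, .prop_term_name(tr)] <- 1
  X
}

#' Collapse a stacked table back to wide format
#'
#' Inverse of [idm_stack()] (up to column order); useful as a round-trip
#' check.
#'
#' @param stacked An `idm_stacked` table.
#' @return Wide-format data frame (`id`, `t_prog`, `s_prog`, `t_death`,
#'   `s_death`, covariates).
#' @export
idm_unstack <- function(stacked) {
  covs <- attr(stacked, "covariates")
  r01 <- stacked[stacked$transition == "01", , drop = FALSE]
  r02 <- stacked[stacked$transition == "02", , drop = FALSE]
  r12 <- stacked[stacked$transition == "12", , drop = FALSE]
  out <- data.frame(id = r01$id, t_prog = r01$tstop, s_prog = r01$status,
                    stringsAsFactors = FALSE)
  i02 <- match(out$id, r02$id)
  out$t_death <- r02$tstop[i02]
  out$s_death <- r02$status[i02]
  i12 <- match(out$id, r12$id)
  got12 <- !is.na(i12)
  out$t_death[got12] <- r12$tstop[i12[got12]] + out$t_prog[got12]
  out$s_death[got12] <- r12$status[i12[got12]]
  out[covs] <- r01[covs]
  out
}

#' Read wide-format records from a delimited file
#'
#' Expects a header with `id`, `t_prog`, `s_prog`, `t_death`, `s_death` and
#' covariate columns; missing values are not permitted.
#'
#' @param path CSV file path.
#' @param validate Stop on invalid records?
#' @return Wide-format data frame.
#' @export
idm_read <- function(path, validate = TRUE) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (validate) .assert_valid(data)
  data
}
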