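#' Read or write an effect structure as YAML
#'
#' The YAML schema mirrors [idm_structure()]:
#' ```yaml
#' effects:
#'   - {covariate: age, transitions: ["02"]}
#'   - {covariate: residual_tumor, transitions: ["01", "02", "12"]}
#' strata: [["01"], ["02", "12"]]
#' prop_terms: ["12"]
#' ```
#'
#' @param path YAML file path.
#' @return An [idm_structure()].
#' @export
idm_structure_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  idm_structure(effects = obj$effects %||% list(),
                strata = obj$strata %||% as.list(IDM_TRANSITIONS),
                prop_terms = unlist(obj$prop_terms) %||% character())
}

#' @rdname idm_structure_from_yaml
#' @param structure An [idm_structure()].
#' @export
idm_structure_to_yaml <- function(structure, path) {
  obj <- list(
    effects = lapply(seq_len(nrow(structure$effects)), function(i)
      list(covariate = structure$effects$covariate[i],
           transitions = structure$effects$transitions[[i]])),
    strata = unname(structure$strata),
    prop_terms = structure$prop_terms)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a simulator configuration from YAML
#'
#' Top-level keys mirror the arguments of [idm_sim_config()]; absent keys
#' keep their defaults.  The cohort size is spelled `n_subjects` (a bare `n`
#' is a YAML 1.1 boolean and would be mangled by conforming parsers).
#'
#' @param path YAML file path.
#' @return An [idm_sim_config()].
#' @export
idm_sim_config_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$n_subjects)) obj$n <- obj$n_subjects
  args <- list()
  for (nm in intersect(names(obj), names(formals(idm_sim_config)))) {
    v <- obj[[nm]]
    if (nm %in% c("beta01", "beta02", "beta12")) v <- unlist(v)
    if (nm %in% c("baseline01", "baseline_death", "baseline12")) v <- unlist(v)
    args[[nm]] <- v
  }
  do.call(idm_sim_config, args)
}
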