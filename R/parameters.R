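# Model parameter handling: the full input table (transition probabilities,
# state costs, state utilities per arm), analysis settings, validation, and
# probabilistic description of every uncertain input.

ARMS <- c("ICD", "PHARM")
ICD_STATES <- c("WELL", "HOSPITALIZATION", "COMPLICATION", "REJECTION", "DEATH")
PHARM_STATES <- c("WELL", "HOSPITALIZATION", "DEATH")

# Free (unpublished) transition probabilities out of WELL, recovered by
# calibration against the reported lifetime outputs. Defaults below are the
# package's own calibrated values; a parameter file may override them.
FREE_IDS <- c("tp_well_compl_icd", "tp_well_hosp_icd", "tp_well_death_icd",
              "tp_well_hosp_pharm", "tp_well_death_pharm")

# Exit-probability row groups sharing a source state; used for validation and
# for renormalisation when one member is sampled or varied.
ROW_GROUPS <- list(
  list(members = c("tp_hosp_well_icd", "tp_hosp_death_icd")),
  list(members = c("tp_compl_well_icd", "tp_compl_rej_icd", "tp_compl_death_icd")),
  list(members = c("tp_rej_well_icd", "tp_rej_death_icd")),
  list(members = c("tp_hosp_well_pharm", "tp_hosp_death_pharm"))
)

param_row <- function(parameter_id, arm, category, source_state, target_state,
                      mean, sd = NA_real_, distribution = "fixed") {
  data.frame(parameter_id = parameter_id, arm = arm, category = category,
             source_state = source_state, target_state = target_state,
             mean = mean, sd = sd, distribution = distribution,
             stringsAsFactors = FALSE)
}

#' Default model input table
#'
#' The published inputs for the two-arm cardiac-arrhythmia Markov model:
#' transition probabilities, annual state costs (USD, 2021, converted at
#' 42,000 Rial/USD), and state utilities, each with its SD and sampling
#' distribution where one was reported. Rows out of the WELL state are not
#' published; their defaults are this package's calibrated values (see
#' [calibrate()]) and are flagged by `is_free_parameter()`.
#'
#' @return A data.frame with columns `parameter_id, arm, category,
#'   source_state, target_state, mean, sd, distribution`.
#' @export
default_parameter_table <- function() {
  rbind(
    # transition probabilities
    param_row("tp_hosp_well_icd",    "ICD",   "transition", "HOSPITALIZATION", "WELL",  0.822),
    param_row("tp_hosp_death_icd",   "ICD",   "transition", "HOSPITALIZATION", "DEATH", 0.178, 0.008, "beta"),
    param_row("tp_hosp_well_pharm",  "PHARM", "transition", "HOSPITALIZATION", "WELL",  0.716),
    param_row("tp_hosp_death_pharm", "PHARM", "transition", "HOSPITALIZATION", "DEATH", 0.284, 0.009, "beta"),
    param_row("tp_compl_well_icd",   "ICD",   "transition", "COMPLICATION",    "WELL",  0.768),
    param_row("tp_compl_rej_icd",    "ICD",   "transition", "COMPLICATION",    "REJECTION", 0.022),
    param_row("tp_compl_death_icd",  "ICD",   "transition", "COMPLICATION",    "DEATH", 0.210, 0.109, "beta"),
    param_row("tp_rej_well_icd",     "ICD",   "transition", "REJECTION",       "WELL",  0.822),
    param_row("tp_rej_death_icd",    "ICD",   "transition", "REJECTION",       "DEATH", 0.178, 0.008, "beta"),
    # free (calibrated) transitions out of WELL
    param_row("tp_well_compl_icd",   "ICD",   "transition", "WELL", "COMPLICATION",    CALIBRATED_DEFAULTS[["tp_well_compl_icd"]]),
    param_row("tp_well_hosp_icd",    "ICD",   "transition", "WELL", "HOSPITALIZATION", CALIBRATED_DEFAULTS[["tp_well_hosp_icd"]]),
    param_row("tp_well_death_icd",   "ICD",   "transition", "WELL", "DEATH",           CALIBRATED_DEFAULTS[["tp_well_death_icd"]]),
    param_row("tp_well_hosp_pharm",  "PHARM", "transition", "WELL", "HOSPITALIZATION", CALIBRATED_DEFAULTS[["tp_well_hosp_pharm"]]),
    param_row("tp_well_death_pharm", "PHARM", "transition", "WELL", "DEATH",           CALIBRATED_DEFAULTS[["tp_well_death_pharm"]]),
    # annual state costs (USD); death cost is a one-time transition reward
    param_row("cost_well_icd",    "ICD",   "cost", "WELL",            NA, 3398, 1105, "gamma"),
    param_row("cost_well_pharm",  "PHARM", "cost", "WELL",            NA,  741, 1246, "gamma"),
    param_row("cost_compl_icd",   "ICD",   "cost", "COMPLICATION",    NA, 3221,  933, "gamma"),
    param_row("cost_hosp_icd",    "ICD",   "cost", "HOSPITALIZATION", NA, 2925, 1247, "gamma"),
    param_row("cost_hosp_pharm",  "PHARM", "cost", "HOSPITALIZATION", NA, 1465, 2024, "gamma"),
    param_row("cost_death_icd",   "ICD",   "cost", "DEATH",           NA, 2777),
    param_row("cost_death_pharm", "PHARM", "cost", "DEATH",           NA,  467),
    # state utilities
    param_row("u_well_icd",    "ICD",   "utility", "WELL",            NA, 0.845, 0.124, "beta"),
    param_row("u_well_pharm",  "PHARM", "utility", "WELL",            NA, 0.880, 0.100, "beta"),
    param_row("u_compl_icd",   "ICD",   "utility", "COMPLICATION",    NA, 0.750),
    param_row("u_hosp_icd",    "ICD",   "utility", "HOSPITALIZATION", NA, 0.725),
    param_row("u_hosp_pharm",  "PHARM", "utility", "HOSPITALIZATION", NA, 0.850),
    # settings rows (moved into the settings list by the loader)
    param_row("dr_cost",    "BOTH", "setting", NA, NA, 0.06),
    param_row("dr_outcome", "BOTH", "setting", NA, NA, 0.03)
  )
}

#' Default analysis settings
#'
#' @param ... Named overrides of any default.
#' @return Named list: `dr_cost` (0.06), `dr_outcome` (0.03), `discount_range`
#'   (0.03-0.09, used by the deterministic sensitivity analysis), `wtp`
#'   (13,002 USD/QALY, three times 2021 GDP per capita), `cycle_length`
#'   (1 year), `max_cycles` (100), `absorb_tol` (1e-4), `half_cycle`
#'   (FALSE), `init_state` ("WELL"), `psa_iterations` (1000), `seed`,
#'   `dsa_fallback` (0.25 relative half-width for SD-less parameters).
#' @export
cea_settings <- function(...) {
  s <- list(
    dr_cost = 0.06, dr_outcome = 0.03, discount_range = c(0.03, 0.09),
    wtp = 13002, cycle_length = 1, max_cycles = 100L, absorb_tol = 1e-4,
    half_cycle = FALSE, init_state = "WELL", psa_iterations = 1000L,
    seed = 1L, dsa_fallback = 0.25
  )
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(s))
  if (length(unknown))
    stop("cea_settings: unknown setting(s): ", paste(unknown, collapse = ", "))
  s[names(ov)] <- ov
  s
}

fit_spec_for_row <- function(row) {
  sd <- row$sd
  has_sd <- is.finite(sd) && sd > 0
  fam <- tolower(ifelse(is.na(row$distribution) | row$distribution %in% c("", "-"),
                        "fixed", row$distribution))
  if (!has_sd || fam == "fixed") return(dist_spec("fixed", row$mean))
  switch(fam,
    beta = beta_from_moments(row$mean, sd),
    gamma = gamma_from_moments(row$mean, sd),
    stop("VALIDATION_ERROR: unknown distribution '", fam, "' for ",
         row$parameter_id))
}

#' Validate a model input table
#'
#' Checks schema completeness, domains (probabilities and utilities in
#' [0,1], costs nonnegative), beta-feasibility of every (mean, SD) pair
#' tagged beta, and that the published exit probabilities of each transient
#' state sum to 1.
#'
#' @param tab A data.frame in the [default_parameter_table()] schema.
#' @return Character vector of issues, each prefixed `SCHEMA_ERROR:` or
#'   `VALIDATION_ERROR:`; empty when the table is valid.
#' @export
validate_parameter_table <- function(tab) {
  issues <- character()
  need_cols <- c("parameter_id", "arm", "category", "source_state",
                 "target_state", "mean", "sd", "distribution")
  miss_cols <- setdiff(need_cols, names(tab))
  if (length(miss_cols))
    return(paste0("SCHEMA_ERROR: missing column(s): ",
                  paste(miss_cols, collapse = ", ")))
  mandatory <- setdiff(default_parameter_table()$parameter_id, FREE_IDS)
  miss <- setdiff(mandatory, tab$parameter_id)
  if (length(miss))
    issues <- c(issues, paste0("SCHEMA_ERROR: missing mandatory row: ", miss))
  dup <- unique(tab$parameter_id[duplicated(tab$parameter_id)])
  if (length(dup))
    issues <- c(issues, paste0("SCHEMA_ERROR: duplicated parameter_id: ", dup))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!is.finite(row$mean)) {
      issues <- c(issues, paste0("SCHEMA_ERROR: non-numeric mean for ",
                                 row$parameter_id))
      next
    }
    if (row$category %in% c("transition", "utility") &&
        (row$mean < 0 || row$mean > 1))
      issues <- c(issues, paste0("VALIDATION_ERROR: ", row$parameter_id,
                                 " outside [0,1]: ", row$mean))
    if (row$category == "cost" && row$mean < 0)
      issues <- c(issues, paste0("VALIDATION_ERROR: negative cost for ",
                                 row$parameter_id))
    if (identical(tolower(row$distribution), "beta") &&
        is.finite(row$sd) && row$sd > 0 &&
        row$mean > 0 && row$mean < 1 &&
        row$sd^2 >= row$mean * (1 - row$mean))
      issues <- c(issues, paste0("VALIDATION_ERROR: beta-infeasible sd for ",
                                 row$parameter_id))
  }
  # published exit probabilities of transient states must sum to one
  for (grp in ROW_GROUPS) {
    if (!all(grp$members %in% tab$parameter_id)) next
    tot <- sum(tab$mean[match(grp$members, tab$parameter_id)])
    if (abs(tot - 1) > 1e-9)
      issues <- c(issues, paste0("VALIDATION_ERROR: exit probabilities of ",
                                 tab$source_state[match(grp$members[1], tab$parameter_id)],
                                 " sum to ", format(tot), ", not 1"))
  }
  free <- intersect(FREE_IDS, tab$parameter_id)
  for (arm in ARMS) {
    ids <- free[grepl(paste0("_", tolower(arm), "$"), free)]
    if (length(ids)) {
      tot <- sum(tab$mean[match(ids, tab$parameter_id)])
      if (is.finite(tot) && tot > 1)
        issues <- c(issues, paste0("VALIDATION_ERROR: WELL exit probabilities (",
                                   arm, ") exceed 1"))
    }
  }
  issues
}

new_cea_parameters <- function(tab, settings, free_calibrated) {
  rownames(tab) <- NULL
  specs <- lapply(seq_len(nrow(tab)), function(i) fit_spec_for_row(tab[i, ]))
  names(specs) <- tab$parameter_id
  structure(list(table = tab, specs = specs, settings = settings,
                 free_calibrated = free_calibrated),
            class = "cea_parameters")
}

#' Load and validate a model parameter file
#'
#' Reads a flat CSV in the [default_parameter_table()] schema, fills any
#' omitted row with its published default, fits a beta or gamma distribution
#' to every (mean, SD) pair by the method of moments, and attaches analysis
#' settings. `setting` rows in the file (e.g. `dr_cost`) override the
#' built-in defaults; explicit `settings` overrides take precedence over
#' both. If the file omits the WELL-exit rows the package's calibrated
#' defaults are used and the set is flagged uncalibrated.
#'
#' @param path CSV file; `NULL` loads the bundled default file, which
#'   mirrors the published input table.
#' @param settings Named list of setting overrides (see [cea_settings()]),
#'   or a path to a JSON file holding one.
#' @return A `cea_parameters` object.
#' @export
load_parameter_table <- function(path = NULL, settings = list()) {
  if (is.null(path))
    path <- system.file("extdata", "arrhythmia_parameters.csv",
                        package = "icdcea", mustWork = TRUE)
  if (!file.exists(path)) stop("SCHEMA_ERROR: no such parameter file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(settings) && length(settings) == 1L)
    settings <- jsonlite::read_json(settings, simplifyVector = TRUE)
  need_cols <- c("parameter_id", "arm", "category", "source_state",
                 "target_state", "mean", "sd", "distribution")
  miss_cols <- setdiff(need_cols, names(tab))
  if (length(miss_cols))
    stop("SCHEMA_ERROR: missing column(s): ", paste(miss_cols, collapse = ", "))
  defaults <- default_parameter_table()
  free_calibrated <- all(FREE_IDS %in% tab$parameter_id)
  add <- defaults[!defaults$parameter_id %in% tab$parameter_id, ]
  tab <- rbind(tab[, need_cols], add[, need_cols])
  issues <- validate_parameter_table(tab)
  if (length(issues)) stop(paste(issues, collapse = "\n"))
  # setting rows feed the settings list (below explicit overrides)
  set_rows <- tab[tab$category == "setting", ]
  from_file <- stats::setNames(as.list(set_rows$mean), set_rows$parameter_id)
  tab <- tab[tab$category != "setting", ]
  s <- cea_settings()
  s[names(from_file)] <- from_file
  s[names(settings)] <- settings
  s <- do.call(cea_settings, s)
  new_cea_parameters(tab, s, free_calibrated)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat(sprintf("<cea_parameters> %d parameters, WELL-exit rows %s\n",
              nrow(x$table),
              if (x$free_calibrated) "from file" else "calibrated defaults (uncalibrated flag)"))
  cat(sprintf("  discounting: cost %.0f%%, outcome %.0f%%; WTP $%s/QALY; horizon %d cycles\n",
              100 * x$settings$dr_cost, 100 * x$settings$dr_outcome,
              format(x$settings$wtp, big.mark = ","), x$settings$max_cycles))
  invisible(x)
}

#' Is a parameter one of the calibrated WELL-exit probabilities?
#' @param parameter_id Character vector of ids.
#' @return Logical vector.
#' @export
is_free_parameter <- function(parameter_id) parameter_id %in% FREE_IDS

#' Base-case parameter values
#'
#' @param params A `cea_parameters` object.
#' @return Named numeric vector of all parameter means (the deterministic
#'   base case), suitable for [build_transition_matrix()] and
#'   [accrue_outcomes()].
#' @export
base_values <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  stats::setNames(params$table$mean, params$table$parameter_id)
}

# Renormalise the exit row containing `changed` so it sums to one again:
# all siblings except the largest-mean one keep their base value; the
# largest-mean sibling absorbs the residual (clamped at 0). With the
# published means the smallest sibling is held fixed, as intended.
renormalize_row <- function(values, base, changed) {
  n_clamped <- 0L
  for (grp in ROW_GROUPS) {
    if (!changed %in% grp$members) next
    sibs <- setdiff(grp$members, changed)
    resid_id <- sibs[which.max(base[sibs])]
    keep <- setdiff(sibs, resid_id)
    if (values[changed] > 1 - sum(base[keep])) {
      values[changed] <- 1 - sum(base[keep])
      n_clamped <- n_clamped + 1L
    }
    values[resid_id] <- 1 - values[changed] - sum(base[keep])
  }
  attr(values, "n_clamped") <- n_clamped
  values
}

#' Draw one concrete parameter set for probabilistic sensitivity analysis
#'
#' Every distribution-tagged parameter is drawn independently from its
#' fitted beta or gamma distribution; fixed parameters (including the
#' calibrated WELL-exit probabilities, which carry no published uncertainty)
#' are returned as-is. After sampling, each exit row is renormalised: the
#' sampled probability is kept, the smallest-mean sibling stays at its base
#' value, and the largest-mean sibling takes the residual, clamped at 0.
#' Clamp events are counted in the `n_clamped` attribute.
#'
#' @param params A `cea_parameters` object.
#' @return Named numeric vector like [base_values()], drawn from the
#'   current RNG stream, with attribute `n_clamped`.
#' @export
sample_parameters <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  base <- base_values(params)
  values <- base
  n_clamped <- 0L
  for (id in names(values)) {
    spec <- params$specs[[id]]
    if (spec$family == "fixed") next
    values[id] <- sample_spec(spec, 1)
    if (params$table$category[match(id, params$table$parameter_id)] == "transition") {
      values <- renormalize_row(values, base, id)
      n_clamped <- n_clamped + attr(values, "n_clamped")
    }
  }
  attr(values, "n_clamped") <- n_clamped
  values
}
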