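# Synthetic fixtures: the bundled default parameter file, toy Markov chains
# with closed-form discounted totals (test oracles), and randomized but
# valid parameter sets for property tests.

#' Write the default parameter file
#'
#' Emits the bundled input table as CSV. Output is byte-stable: writing
#' twice yields identical files, and loading round-trips to an identical
#' parameter set.
#'
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_default_parameter_file <- function(path) {
  utils::write.csv(default_parameter_table(), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Two-state toy chain with closed-form discounted totals
#'
#' A single live state with per-cycle survival `p` and an absorbing death
#' state. Counting the t = 0 cycle, the discounted totals are geometric
#' series: QALY `u / (1 - p/(1+r_outcome))` and cost analogously with
#' `r_cost`. Used as an independent oracle for the cohort engine.
#'
#' @param p_survive Per-cycle survival probability in [0, 1).
#' @param utility,cost Per-cycle reward of the live state.
#' @param r_cost,r_outcome Discount rates.
#' @return A `toy_model`: list with the `transition_matrix`, reward
#'   vectors, and `closed_form` (`cost`, `qaly`).
#' @export
make_toy_two_state <- function(p_survive, utility = 1, cost = 0,
                               r_cost = 0, r_outcome = 0) {
  if (p_survive < 0 || p_survive > 1)
    stop("make_toy_two_state: p_survive must be a probability")
  if (p_survive >= 1 && r_cost <= 0 && r_outcome <= 0)
    stop("make_toy_two_state: immortal chain with zero discounting diverges")
  P <- matrix(c(p_survive, 1 - p_survive, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("ALIVE", "DEATH"), c("ALIVE", "DEATH")))
  closed <- c(cost = cost / (1 - p_survive / (1 + r_cost)),
              qaly = utility / (1 - p_survive / (1 + r_outcome)))
  structure(list(tm = transition_matrix(P),
                 costs = c(ALIVE = cost), utilities = c(ALIVE = utility),
                 r_cost = r_cost, r_outcome = r_outcome,
                 closed_form = closed),
            class = "toy_model")
}

#' Run a toy model through the real engine
#'
#' @param toy A `toy_model`.
#' @param max_cycles,absorb_tol Horizon settings (tight defaults so the
#'   truncated sum approaches the closed form).
#' @return An `arm_result`.
#' @export
run_toy <- function(toy, max_cycles = 10000L, absorb_tol = 1e-10) {
  stopifnot(inherits(toy, "toy_model"))
  trace <- run_cohort(toy$tm, "ALIVE", max_cycles = max_cycles,
                      absorb_tol = absorb_tol)
  accrue_outcomes(trace, toy$costs, toy$utilities, death_cost = 0,
                  dr_cost = toy$r_cost, dr_outcome = toy$r_outcome)
}

#' Toy model expressed in the parameter-file schema
#'
#' Maps a two-state toy onto the pharmacotherapy arm structure (the
#' hospitalization state is made unreachable and equivalent to well), so
#' the closed form can be checked through the full file-loading path.
#'
#' @param toy A `toy_model`.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_toy_parameter_file <- function(toy, path) {
  stopifnot(inherits(toy, "toy_model"))
  p_die <- 1 - toy$tm$probs["ALIVE", "ALIVE"]
  tab <- default_parameter_table()
  set_mean <- function(tab, id, mean) {
    tab$mean[tab$parameter_id == id] <- mean
    tab$sd[tab$parameter_id == id] <- NA_real_
    tab$distribution[tab$parameter_id == id] <- "fixed"
    tab
  }
  tab <- set_mean(tab, "tp_well_hosp_pharm", 0)
  tab <- set_mean(tab, "tp_well_death_pharm", p_die)
  tab <- set_mean(tab, "cost_well_pharm", unname(toy$costs[["ALIVE"]]))
  tab <- set_mean(tab, "cost_hosp_pharm", unname(toy$costs[["ALIVE"]]))
  tab <- set_mean(tab, "cost_death_pharm", 0)
  tab <- set_mean(tab, "u_well_pharm", unname(toy$utilities[["ALIVE"]]))
  tab <- set_mean(tab, "u_hosp_pharm", unname(toy$utilities[["ALIVE"]]))
  tab <- set_mean(tab, "dr_cost", toy$r_cost)
  tab <- set_mean(tab, "dr_outcome", toy$r_outcome)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# run with RNG state isolated from (and restored for) the caller
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a randomized but valid parameter set
#'
#' Draws a full model input table that passes every validation check:
#' row-feasible transition probabilities, beta-feasible SDs (capped at
#' 0.8 * sqrt(m(1-m))), positive costs. Deterministic given `seed`; the
#' caller's RNG state is untouched. Intended for property tests (cohort
#' conservation, discount monotonicity, ...) across many generated models.
#'
#' @param seed Integer seed.
#' @return A `cea_parameters` object.
#' @export
random_valid_parameter_set <- function(seed) {
  with_local_seed(seed, {
    tab <- default_parameter_table()
    set_row <- function(tab, id, mean, sd = NA_real_, dist = "fixed") {
      i <- match(id, tab$parameter_id)
      tab$mean[i] <- mean; tab$sd[i] <- sd; tab$distribution[i] <- dist
      tab
    }
    beta_sd <- function(m) stats::runif(1, 0.05, 0.8) * sqrt(m * (1 - m))
    # two-exit rows: death sampled, recovery is the complement
    for (ids in list(c("tp_hosp_death_icd", "tp_hosp_well_icd"),
                     c("tp_hosp_death_pharm", "tp_hosp_well_pharm"),
                     c("tp_rej_death_icd", "tp_rej_well_icd"))) {
      d <- stats::runif(1, 0.05, 0.6)
      tab <- set_row(tab, ids[1], d, beta_sd(d), "beta")
      tab <- set_row(tab, ids[2], 1 - d)
    }
    # three-exit complication row
    d <- stats::runif(1, 0.05, 0.5)
    rej <- stats::runif(1, 0.005, 0.1)
    tab <- set_row(tab, "tp_compl_death_icd", d, beta_sd(d), "beta")
    tab <- set_row(tab, "tp_compl_rej_icd", rej)
    tab <- set_row(tab, "tp_compl_well_icd", 1 - d - rej)
    # free WELL exits, jointly below 1
    icd_free <- stats::runif(3, 0, 0.25)
    tab <- set_row(tab, "tp_well_compl_icd", icd_free[1])
    tab <- set_row(tab, "tp_well_hosp_icd", icd_free[2])
    tab <- set_row(tab, "tp_well_death_icd", icd_free[3])
    ph_free <- stats::runif(2, 0, 0.35)
    tab <- set_row(tab, "tp_well_hosp_pharm", ph_free[1])
    tab <- set_row(tab, "tp_well_death_pharm", ph_free[2])
    # costs: positive means, gamma where an SD is drawn
    for (id in c("cost_well_icd", "cost_well_pharm", "cost_compl_icd",
                 "cost_hosp_icd", "cost_hosp_pharm")) {
      m <- stats::runif(1, 200, 8000)
      tab <- set_row(tab, id, m, m * stats::runif(1, 0.1, 0.7), "gamma")
    }
    for (id in c("cost_death_icd", "cost_death_pharm"))
      tab <- set_row(tab, id, stats::runif(1, 0, 4000))
    # utilities in (0, 1)
    for (id in c("u_well_icd", "u_well_pharm")) {
      m <- stats::runif(1, 0.5, 0.95)
      tab <- set_row(tab, id, m, beta_sd(m), "beta")
    }
    for (id in c("u_compl_icd", "u_hosp_icd", "u_hosp_pharm"))
      tab <- set_row(tab, id, stats::runif(1, 0.3, 0.95))
    issues <- validate_parameter_table(tab)
    if (length(issues))
      stop("random_valid_parameter_set: generated an invalid table:\n",
           paste(issues, collapse = "\n"))
    s <- cea_settings(seed = as.integer(seed %% 2147483647))
    tab <- tab[tab$category != "setting", ]
    new_cea_parameters(tab, s, free_calibrated = TRUE)
  })
}

#' Zero out all parameter uncertainty
#'
#' Replaces every distribution-tagged row with a fixed one, making the PSA
#' degenerate at the base case. Used in tests.
#'
#' @param params A `cea_parameters` object.
#' @return The degenerate parameter set.
#' @export
zero_uncertainty <- function(params) {
  tab <- params$table
  tab$sd <- NA_real_
  tab$distribution <- "fixed"
  new_cea_parameters(tab, params$settings, params$free_calibrated)
}
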