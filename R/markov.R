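# Cohort state-transition engine: transition matrices per treatment arm,
# annual-cycle cohort propagation to a lifetime horizon, and discounted
# cost/QALY accrual.

#' Construct a transition matrix
#'
#' Low-level constructor used both by the arm-specific builder and by toy
#' oracle models. Rows are source states and must be stochastic; the death
#' state, when present, must be absorbing.
#'
#' @param probs Square numeric matrix with identical row/column state names.
#' @param arm Optional arm label (`"ICD"` or `"PHARM"`).
#' @param death_state Name of the absorbing death state, if any.
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(probs, arm = NA_character_,
                              death_state = "DEATH") {
  if (!is.matrix(probs) || nrow(probs) != ncol(probs))
    stop("transition_matrix: probs must be a square matrix")
  if (is.null(rownames(probs)) || !identical(rownames(probs), colnames(probs)))
    stop("transition_matrix: probs must have matching row/column state names")
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12))
    stop("transition_matrix: entries must be probabilities in [0,1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition_matrix: row(s) not stochastic: ",
         paste(rownames(probs)[abs(rs - 1) > 1e-9], collapse = ", "))
  if (death_state %in% rownames(probs) &&
      abs(probs[death_state, death_state] - 1) > 1e-12)
    stop("transition_matrix: ", death_state, " must be absorbing")
  structure(list(arm = arm, states = rownames(probs), probs = probs,
                 death_state = death_state),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> arm=%s, %d states\n", x$arm,
              length(x$states)))
  print(round(x$probs, 4))
  invisible(x)
}

#' Build the transition matrix for one treatment arm
#'
#' The ICD arm has five states (well, hospitalization, complication, device
#' rejection, death); the pharmacotherapy arm has three (well,
#' hospitalization, death) — it carries no mass into or out of the
#' complication and rejection states. WELL retains the residual probability
#' of its exits as a self-loop.
#'
#' @param arm `"ICD"` or `"PHARM"`.
#' @param values Named parameter vector from [base_values()] or
#'   [sample_parameters()].
#' @return A `transition_matrix`.
#' @export
build_transition_matrix <- function(arm, values) {
  arm <- match.arg(arm, ARMS)
  v <- function(id) {
    if (!id %in% names(values)) stop("build_transition_matrix: missing ", id)
    unname(values[[id]])
  }
  if (arm == "ICD") {
    st <- ICD_STATES
    P <- matrix(0, 5, 5, dimnames = list(st, st))
    stay <- 1 - v("tp_well_compl_icd") - v("tp_well_hosp_icd") - v("tp_well_death_icd")
    if (stay < -1e-9)
      stop("build_transition_matrix: WELL exits (ICD) exceed 1; residual ", stay)
    P["WELL", ] <- c(max(stay, 0), v("tp_well_hosp_icd"), v("tp_well_compl_icd"),
                     0, v("tp_well_death_icd"))
    P["HOSPITALIZATION", c("WELL", "DEATH")] <-
      c(v("tp_hosp_well_icd"), v("tp_hosp_death_icd"))
    P["COMPLICATION", c("WELL", "REJECTION", "DEATH")] <-
      c(v("tp_compl_well_icd"), v("tp_compl_rej_icd"), v("tp_compl_death_icd"))
    P["REJECTION", c("WELL", "DEATH")] <-
      c(v("tp_rej_well_icd"), v("tp_rej_death_icd"))
  } else {
    st <- PHARM_STATES
    P <- matrix(0, 3, 3, dimnames = list(st, st))
    stay <- 1 - v("tp_well_hosp_pharm") - v("tp_well_death_pharm")
    if (stay < -1e-9)
      stop("build_transition_matrix: WELL exits (PHARM) exceed 1; residual ", stay)
    P["WELL", ] <- c(max(stay, 0), v("tp_well_hosp_pharm"), v("tp_well_death_pharm"))
    P["HOSPITALIZATION", c("WELL", "DEATH")] <-
      c(v("tp_hosp_well_pharm"), v("tp_hosp_death_pharm"))
  }
  P["DEATH", "DEATH"] <- 1
  transition_matrix(P, arm = arm)
}

#' Run the cohort through the Markov chain
#'
#' Propagates a cohort occupancy vector through annual cycles,
#' `occupancy(t+1) = occupancy(t) %*% P`, recording the fraction newly
#' entering death each cycle. Iteration stops at the first cycle where
#' death occupancy reaches `1 - absorb_tol`, or at `max_cycles`.
#'
#' @param tm A `transition_matrix`.
#' @param initial Named occupancy vector summing to 1; a single state name
#'   puts the whole cohort there.
#' @param max_cycles Maximum number of cycles (default 100).
#' @param absorb_tol Absorption tolerance (default 1e-4).
#' @return A `cohort_trace`: list with `occupancy` (matrix, rows are cycles
#'   t = 0..n_cycles), `entered_death` (fraction newly dead at each cycle; 0
#'   at t = 0), and `n_cycles`.
#' @export
run_cohort <- function(tm, initial, max_cycles = 100L, absorb_tol = 1e-4) {
  stopifnot(inherits(tm, "transition_matrix"), max_cycles >= 1)
  st <- tm$states
  if (is.character(initial) && length(initial) == 1L) {
    occ <- stats::setNames(numeric(length(st)), st)
    if (!initial %in% st) stop("run_cohort: unknown initial state ", initial)
    occ[initial] <- 1
  } else {
    if (is.null(names(initial)) || !setequal(names(initial), st))
      stop("run_cohort: initial must be named over the matrix states")
    occ <- initial[st]
  }
  if (abs(sum(occ) - 1) > 1e-9) stop("run_cohort: initial must sum to 1")
  dstate <- tm$death_state
  has_death <- dstate %in% st
  occ_rows <- list(occ)
  entered <- 0
  t <- 0L
  while (t < max_cycles) {
    if (has_death && occ[dstate] >= 1 - absorb_tol) break
    newocc <- as.vector(occ %*% tm$probs)
    names(newocc) <- st
    entered <- c(entered,
                 if (has_death) newocc[[dstate]] - occ[[dstate]] else 0)
    occ <- newocc
    occ_rows[[length(occ_rows) + 1L]] <- occ
    t <- t + 1L
  }
  occupancy <- do.call(rbind, occ_rows)
  rownames(occupancy) <- 0:t
  structure(list(occupancy = occupancy, entered_death = entered,
                 n_cycles = t, death_state = dstate),
            class = "cohort_trace")
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Cycle-t rewards are discounted by `(1+r)^-t`, t starting at 0 (first
#' cycle undiscounted). Live states accrue their annual cost and
#' `utility * cycle_length`; death contributes no recurring reward but a
#' one-time cost applied to the fraction newly entering it that cycle.
#' The optional half-cycle correction halves the state rewards of the
#' first and last recorded cycle.
#'
#' @param trace A `cohort_trace`.
#' @param costs,utilities Named per-state annual values; the death state may
#'   be omitted (it contributes zero).
#' @param death_cost One-time cost on entering death.
#' @param dr_cost,dr_outcome Annual discount rates for costs and outcomes.
#' @param cycle_length Cycle length in years (default 1).
#' @param half_cycle Apply half-cycle correction (default FALSE).
#' @param arm Optional arm label carried through to the result.
#' @return An `arm_result`: list with `arm`, `discounted_cost`,
#'   `discounted_qaly`, `trace`, and `increments` (per-cycle discounted
#'   cost/QALY increments).
#' @export
accrue_outcomes <- function(trace, costs, utilities, death_cost = 0,
                            dr_cost = 0.06, dr_outcome = 0.03,
                            cycle_length = 1, half_cycle = FALSE,
                            arm = NA_character_) {
  stopifnot(inherits(trace, "cohort_trace"))
  st <- colnames(trace$occupancy)
  live <- setdiff(st, trace$death_state)
  missing <- setdiff(live, names(costs))
  if (length(missing))
    stop("accrue_outcomes: missing cost for state(s): ",
         paste(missing, collapse = ", "))
  missing <- setdiff(live, names(utilities))
  if (length(missing))
    stop("accrue_outcomes: missing utility for state(s): ",
         paste(missing, collapse = ", "))
  cvec <- stats::setNames(numeric(length(st)), st)
  uvec <- cvec
  cvec[live] <- costs[live]
  uvec[live] <- utilities[live]
  tt <- 0:trace$n_cycles
  w <- rep(1, length(tt))
  if (half_cycle) { w[1] <- 0.5; w[length(w)] <- 0.5 }
  disc_c <- (1 + dr_cost)^(-tt)
  disc_o <- (1 + dr_outcome)^(-tt)
  state_cost <- as.vector(trace$occupancy %*% cvec)
  state_qaly <- as.vector(trace$occupancy %*% uvec) * cycle_length
  cost_inc <- w * state_cost * disc_c + trace$entered_death * death_cost * disc_c
  qaly_inc <- w * state_qaly * disc_o
  structure(list(arm = arm,
                 discounted_cost = sum(cost_inc),
                 discounted_qaly = sum(qaly_inc),
                 trace = trace,
                 increments = data.frame(cycle = tt,
                                         entered_death = trace$entered_death,
                                         discounted_cost_increment = cost_inc,
                                         discounted_qaly_increment = qaly_inc)),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost $%.0f, %.3f QALYs over %d cycles\n",
              x$arm, x$discounted_cost, x$discounted_qaly, x$trace$n_cycles))
  invisible(x)
}

# Per-arm state costs/utilities from a parameter value vector. The
# rejection state has no published cost or utility; it reuses the arm's
# hospitalization values unless cost_rej_icd / u_rej_icd are supplied.
arm_state_values <- function(arm, values) {
  g <- function(id, fallback = NULL) {
    if (id %in% names(values)) unname(values[[id]])
    else if (!is.null(fallback)) unname(values[[fallback]])
    else stop("arm_state_values: missing ", id)
  }
  if (arm == "ICD") {
    list(costs = c(WELL = g("cost_well_icd"),
                   HOSPITALIZATION = g("cost_hosp_icd"),
                   COMPLICATION = g("cost_compl_icd"),
                   REJECTION = g("cost_rej_icd", "cost_hosp_icd")),
         utilities = c(WELL = g("u_well_icd"),
                       HOSPITALIZATION = g("u_hosp_icd"),
                       COMPLICATION = g("u_compl_icd"),
                       REJECTION = g("u_rej_icd", "u_hosp_icd")),
         death_cost = g("cost_death_icd"))
  } else {
    list(costs = c(WELL = g("cost_well_pharm"),
                   HOSPITALIZATION = g("cost_hosp_pharm")),
         utilities = c(WELL = g("u_well_pharm"),
                       HOSPITALIZATION = g("u_hosp_pharm")),
         death_cost = g("cost_death_pharm"))
  }
}

#' Run one arm of the model end to end
#'
#' Builds the arm's transition matrix from `values`, runs the cohort to the
#' lifetime horizon, and accrues discounted outcomes under the settings in
#' `params` (any of which `...` may override, e.g. `dr_cost = 0.09`).
#'
#' @param params A `cea_parameters` object.
#' @param arm `"ICD"` or `"PHARM"`.
#' @param values Parameter values; defaults to [base_values()].
#' @param ... Setting overrides (`dr_cost`, `dr_outcome`, `max_cycles`,
#'   `absorb_tol`, `half_cycle`, `init_state`, `cycle_length`).
#' @return An `arm_result`.
#' @export
run_arm <- function(params, arm, values = base_values(params), ...) {
  s <- params$settings
  ov <- list(...)
  s[names(ov)] <- ov
  tm <- build_transition_matrix(arm, values)
  trace <- run_cohort(tm, s$init_state, max_cycles = s$max_cycles,
                      absorb_tol = s$absorb_tol)
  sv <- arm_state_values(arm, values)
  accrue_outcomes(trace, sv$costs, sv$utilities, sv$death_cost,
                  dr_cost = s$dr_cost, dr_outcome = s$dr_outcome,
                  cycle_length = s$cycle_length, half_cycle = s$half_cycle,
                  arm = arm)
}

#' Run both arms and summarise cost-effectiveness
#'
#' @inheritParams run_arm
#' @return List with `icd`, `pharm` (each an `arm_result`) and `cea`
#'   (a `cea_result`, ICD vs pharmacotherapy).
#' @export
run_base_case <- function(params, values = base_values(params), ...) {
  icd <- run_arm(params, "ICD", values, ...)
  pharm <- run_arm(params, "PHARM", values, ...)
  list(icd = icd, pharm = pharm,
       cea = icer(icd, pharm, wtp = params$settings$wtp))
}

#' Export a cohort trace as a per-cycle table
#'
#' @param result An `arm_result`.
#' @return data.frame with one row per cycle: state occupancies,
#'   `entered_death`, and the discounted cost/QALY increments.
#' @export
trace_table <- function(result) {
  stopifnot(inherits(result, "arm_result"))
  occ <- as.data.frame(result$trace$occupancy)
  cbind(cycle = 0:result$trace$n_cycles, occ,
        result$increments[, c("entered_death", "discounted_cost_increment",
                              "discounted_qaly_increment")])
}
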