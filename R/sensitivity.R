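# Deterministic and probabilistic sensitivity analysis: one-way (tornado)
# and two-way analyses over 95%-CI parameter ranges, seeded Monte-Carlo PSA,
# the cost-effectiveness acceptability curve, and CE-plane scatter export.

# Pseudo-parameters that live in the settings list but are varied in the
# DSA over the published 0.03-0.09 range.
DSA_SETTING_IDS <- c("dr_cost", "dr_outcome")

#' Deterministic sensitivity bounds for one parameter
#'
#' Distribution-tagged parameters use mean +/- 1.96*SD clamped to their
#' domain; SD-less parameters (including the calibrated WELL-exit
#' probabilities) use a relative +/- `dsa_fallback` range; the discount
#' rates use the published 0.03-0.09 range.
#'
#' @param params A `cea_parameters` object.
#' @param parameter_id A parameter id, or `"dr_cost"`/`"dr_outcome"`.
#' @return `c(low, high)`.
#' @export
dsa_bounds <- function(params, parameter_id) {
  if (parameter_id %in% DSA_SETTING_IDS)
    return(c(low = params$settings$discount_range[1],
             high = params$settings$discount_range[2]))
  idx <- match(parameter_id, params$table$parameter_id)
  if (is.na(idx)) stop("dsa_bounds: unknown parameter ", parameter_id)
  domain <- switch(params$table$category[idx],
                   transition = "probability", utility = "utility",
                   cost = "cost",
                   stop("dsa_bounds: ", parameter_id, " is not varied"))
  ci95_bounds(params$specs[[parameter_id]], domain,
              fallback = params$settings$dsa_fallback)
}

# Evaluate the two-arm ICER with one parameter overridden. Transition
# overrides renormalise their exit row like sampling does; setting
# pseudo-parameters are passed through to the engine.
evaluate_with_override <- function(params, parameter_id, value) {
  base <- base_values(params)
  ov <- list()
  if (parameter_id %in% DSA_SETTING_IDS) {
    ov[[parameter_id]] <- value
    values <- base
  } else {
    values <- base
    values[parameter_id] <- value
    idx <- match(parameter_id, params$table$parameter_id)
    if (params$table$category[idx] == "transition")
      values <- renormalize_row(values, base, parameter_id)
  }
  icd <- do.call(run_arm, c(list(params, "ICD", values), ov))
  pharm <- do.call(run_arm, c(list(params, "PHARM", values), ov))
  icer(icd, pharm, wtp = params$settings$wtp)
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Runs the full two-arm model at the parameter's low and high bound with
#' everything else at base case and records both ICERs. A bound that
#' produces an invalid model is recorded as `NA` with a warning.
#'
#' @param params A `cea_parameters` object.
#' @param parameter_id Parameter to vary.
#' @param bounds Optional `c(low, high)`; defaults to [dsa_bounds()].
#' @return One-row data.frame: `parameter_id, low, high, low_icer,
#'   high_icer, range_width`.
#' @export
one_way_dsa <- function(params, parameter_id, bounds = NULL) {
  if (is.null(bounds)) bounds <- dsa_bounds(params, parameter_id)
  eval_side <- function(value) {
    out <- tryCatch(evaluate_with_override(params, parameter_id, value)$icer,
                    error = function(e) {
                      warning("one_way_dsa: ", parameter_id, " at ", value,
                              " undefined: ", conditionMessage(e))
                      NA_real_
                    })
    out
  }
  lo <- eval_side(bounds[[1]])
  hi <- eval_side(bounds[[2]])
  data.frame(parameter_id = parameter_id,
             low = bounds[[1]], high = bounds[[2]],
             low_icer = lo, high_icer = hi,
             range_width = abs(hi - lo),
             stringsAsFactors = FALSE)
}

#' Tornado analysis
#'
#' One-way DSA over a set of parameters, sorted by the width of the ICER
#' swing (descending; ties broken by parameter id). The base-case ICER is
#' attached as the `base_icer` attribute (the tornado pivot line).
#'
#' @param params A `cea_parameters` object.
#' @param parameter_ids Parameters to vary; defaults to every model
#'   parameter plus the two discount rates.
#' @return data.frame of [one_way_dsa()] rows, class `tornado_result`.
#' @export
tornado <- function(params, parameter_ids = NULL) {
  if (is.null(parameter_ids))
    parameter_ids <- c(params$table$parameter_id, DSA_SETTING_IDS)
  entries <- do.call(rbind, lapply(parameter_ids, one_way_dsa, params = params))
  ord <- order(-entries$range_width, entries$parameter_id)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  attr(entries, "base_icer") <- run_base_case(params)$cea$icer
  class(entries) <- c("tornado_result", class(entries))
  entries
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates the model on a `grid_n x grid_n` lattice over two parameter
#' ranges and records which strategy has the higher net monetary benefit at
#' the given willingness-to-pay in each cell.
#'
#' @param params A `cea_parameters` object.
#' @param param_a,param_b Parameter ids.
#' @param range_a,range_b `c(low, high)` ranges. Defaults are the published
#'   two-way ranges for the well-state costs (ICD $563-$9,096,
#'   pharmacotherapy $42-$9,195) when those parameters are chosen,
#'   otherwise [dsa_bounds()].
#' @param grid_n Grid resolution per axis (default 20).
#' @param wtp Willingness-to-pay; defaults to the configured threshold.
#' @return data.frame `value_a, value_b, nmb_icd, nmb_pharm, preferred`,
#'   class `twoway_result`.
#' @export
two_way_dsa <- function(params, param_a = "cost_well_icd",
                        param_b = "cost_well_pharm",
                        range_a = NULL, range_b = NULL,
                        grid_n = 20, wtp = NULL) {
  published <- list(cost_well_icd = c(563, 9096), cost_well_pharm = c(42, 9195))
  pick_range <- function(id, range) {
    if (!is.null(range)) range
    else if (id %in% names(published)) published[[id]]
    else dsa_bounds(params, id)
  }
  range_a <- pick_range(param_a, range_a)
  range_b <- pick_range(param_b, range_b)
  if (is.null(wtp)) wtp <- params$settings$wtp
  grid_a <- seq(range_a[[1]], range_a[[2]], length.out = grid_n)
  grid_b <- seq(range_b[[1]], range_b[[2]], length.out = grid_n)
  base <- base_values(params)
  cells <- expand.grid(value_a = grid_a, value_b = grid_b)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    values <- base
    values[param_a] <- cells$value_a[i]
    values[param_b] <- cells$value_b[i]
    icd <- run_arm(params, "ICD", values)
    pharm <- run_arm(params, "PHARM", values)
    c(nmb_icd = nmb(icd, wtp), nmb_pharm = nmb(pharm, wtp))
  })
  res <- do.call(rbind, res)
  out <- cbind(cells, as.data.frame(res))
  out$preferred <- ifelse(out$nmb_icd > out$nmb_pharm, "ICD", "PHARM")
  attr(out, "param_a") <- param_a
  attr(out, "param_b") <- param_b
  attr(out, "wtp") <- wtp
  class(out) <- c("twoway_result", class(out))
  out
}

# Deterministic per-iteration seed derived from a root seed so that
# extending n_iter never changes earlier iterations. Kept below 2^31.
iteration_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483647)
}

#' Probabilistic sensitivity analysis
#'
#' For each iteration, draws one concrete parameter set from the fitted
#' distributions ([sample_parameters()]), runs both arms, and records the
#' paired (cost, QALY) results. Each iteration seeds its own RNG substream
#' from the root seed, so results are bit-reproducible and extending
#' `n_iter` leaves earlier iterations unchanged.
#'
#' @param params A `cea_parameters` object.
#' @param n_iter Number of Monte-Carlo iterations (default from settings,
#'   1000).
#' @param seed Root seed (default from settings).
#' @return A `psa_sample`: data.frame `iteration, cost_icd, qaly_icd,
#'   cost_pharm, qaly_pharm, delta_cost, delta_effect` with attributes
#'   `seed` and `n_clamped`. Warns when more than 1% of iterations hit a
#'   probability clamp.
#' @export
run_psa <- function(params, n_iter = NULL, seed = NULL) {
  if (is.null(n_iter)) n_iter <- params$settings$psa_iterations
  if (is.null(seed)) seed <- params$settings$seed
  stopifnot(n_iter >= 1)
  rows <- vector("list", n_iter)
  clamped_iters <- 0L
  for (i in seq_len(n_iter)) {
    set.seed(iteration_seed(seed, i))
    values <- sample_parameters(params)
    if (attr(values, "n_clamped") > 0) clamped_iters <- clamped_iters + 1L
    icd <- run_arm(params, "ICD", values)
    pharm <- run_arm(params, "PHARM", values)
    rows[[i]] <- data.frame(iteration = i,
                            cost_icd = icd$discounted_cost,
                            qaly_icd = icd$discounted_qaly,
                            cost_pharm = pharm$discounted_cost,
                            qaly_pharm = pharm$discounted_qaly)
  }
  out <- do.call(rbind, rows)
  out$delta_cost <- out$cost_icd - out$cost_pharm
  out$delta_effect <- out$qaly_icd - out$qaly_pharm
  if (clamped_iters / n_iter > 0.01)
    warning(sprintf("run_psa: %d of %d iterations hit a probability clamp",
                    clamped_iters, n_iter))
  attr(out, "seed") <- seed
  attr(out, "n_clamped") <- clamped_iters
  class(out) <- c("psa_sample", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of PSA iterations whose incremental
#' net monetary benefit `wtp * dE - dC` is positive.
#'
#' @param sample A `psa_sample`.
#' @param wtp_grid Ordered willingness-to-pay grid; default 0 to 50,000
#'   USD/QALY in steps of 500, bracketing both the threshold and the
#'   base-case ICER.
#' @param wtp Threshold at which `prob_at_wtp` is reported (attribute);
#'   default 13,002.
#' @return data.frame `wtp, prob_ce` (class `ceac_curve`) with attribute
#'   `prob_at_wtp`.
#' @export
ceac <- function(sample, wtp_grid = seq(0, 50000, by = 500), wtp = 13002) {
  if (!nrow(sample)) stop("ceac: empty PSA sample")
  if (is.unsorted(wtp_grid)) stop("ceac: wtp_grid must be sorted ascending")
  prob_at <- function(lambda)
    mean(lambda * sample$delta_effect - sample$delta_cost > 0)
  out <- data.frame(wtp = wtp_grid, prob_ce = vapply(wtp_grid, prob_at, 0))
  attr(out, "prob_at_wtp") <- prob_at(wtp)
  attr(out, "wtp") <- wtp
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Export the CE-plane scatter from a PSA sample
#'
#' @param sample A `psa_sample`.
#' @param wtp Threshold for the plane's WTP line (attribute).
#' @return data.frame `iteration, delta_effect, delta_cost` with attribute
#'   `wtp` (the line through the origin with slope `wtp`).
#' @export
ce_scatter_export <- function(sample, wtp = 13002) {
  if (!nrow(sample)) stop("ce_scatter_export: empty PSA sample")
  out <- sample[, c("iteration", "delta_effect", "delta_cost")]
  rownames(out) <- NULL
  attr(out, "wtp") <- wtp
  out
}
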