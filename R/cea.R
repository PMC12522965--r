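# Cost-effectiveness metrics: ICER with dominance handling, ACER, net
# monetary benefit, and cost-effectiveness-plane classification.

as_cost_effect <- function(x) {
  if (inherits(x, "arm_result"))
    return(c(cost = x$discounted_cost, effect = x$discounted_qaly))
  if (is.numeric(x) && length(x) == 2L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("cost", "effect") %in% nm))
      return(c(cost = unname(x[["cost"]]), effect = unname(x[["effect"]])))
    return(c(cost = unname(x[1]), effect = unname(x[2])))
  }
  stop("expected an arm_result or a (cost, effect) pair")
}

#' Incremental cost-effectiveness ratio and CE-plane classification
#'
#' Computes the incremental cost and effect of an intervention over a
#' comparator and classifies the pair on the cost-effectiveness plane
#' (effect on x, cost on y). The ICER is reported as a number only where a
#' ratio is meaningful: in the NE quadrant (more costly, more effective)
#' and, with an explicit tag, in the SW quadrant. A cheaper, no-less
#' effective intervention is `"dominant"`; a costlier, no-more effective
#' one is `"dominated"`.
#'
#' @param intervention,comparator `arm_result` objects or `(cost, effect)`
#'   pairs.
#' @param wtp Willingness-to-pay threshold (USD/QALY) used for the NMB and
#'   the cost-effectiveness verdict.
#' @return A `cea_result`: list with `delta_cost`, `delta_effect`, `icer`
#'   (numeric or NA), `label` (`"NE"`, `"SW"`, `"dominant"`, `"dominated"`),
#'   `quadrant`, per-arm `acer` and `nmb`, `wtp`, and `cost_effective`
#'   (TRUE iff the intervention's NMB exceeds the comparator's).
#' @examples
#' icer(c(41135, 12.63), c(8592, 11.29), wtp = 13002)
#' @export
icer <- function(intervention, comparator, wtp = 13002) {
  i <- as_cost_effect(intervention)
  c_ <- as_cost_effect(comparator)
  dc <- i[["cost"]] - c_[["cost"]]
  de <- i[["effect"]] - c_[["effect"]]
  if (dc == 0 && de == 0)
    stop("icer: both deltas are zero; the ratio is indeterminate")
  quadrant <- paste0(if (dc >= 0) "N" else "S", if (de >= 0) "E" else "W")
  if (dc <= 0 && de >= 0) {
    ratio <- NA_real_; label <- "dominant"
  } else if (dc >= 0 && de <= 0) {
    ratio <- NA_real_; label <- "dominated"
  } else {
    ratio <- dc / de
    label <- quadrant  # NE, or SW with the ratio tagged as such
  }
  nmb_i <- wtp * i[["effect"]] - i[["cost"]]
  nmb_c <- wtp * c_[["effect"]] - c_[["cost"]]
  structure(list(delta_cost = dc, delta_effect = de, icer = ratio,
                 label = label, quadrant = quadrant,
                 acer_intervention = if (i[["effect"]] > 0) i[["cost"]] / i[["effect"]] else NA_real_,
                 acer_comparator = if (c_[["effect"]] > 0) c_[["cost"]] / c_[["effect"]] else NA_real_,
                 nmb_intervention = nmb_i, nmb_comparator = nmb_c,
                 wtp = wtp, cost_effective = nmb_i > nmb_c),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  delta cost  $%s,  delta effect %.2f QALYs\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_effect))
  if (is.na(x$icer)) {
    cat(sprintf("  intervention is %s\n", x$label))
  } else {
    cat(sprintf("  ICER $%s/QALY (%s)\n",
                format(round(x$icer), big.mark = ","), x$label))
  }
  cat(sprintf("  at WTP $%s/QALY: %scost-effective (NMB %s vs %s)\n",
              format(x$wtp, big.mark = ","),
              if (x$cost_effective) "" else "NOT ",
              format(round(x$nmb_intervention), big.mark = ","),
              format(round(x$nmb_comparator), big.mark = ",")))
  invisible(x)
}

#' Average cost-effectiveness ratio
#'
#' @param result An `arm_result` or `(cost, effect)` pair.
#' @return `cost / effect` in USD/QALY.
#' @examples
#' acer(c(41135, 12.63))
#' @export
acer <- function(result) {
  x <- as_cost_effect(result)
  if (x[["effect"]] <= 0)
    stop("acer: effect must be positive, got ", x[["effect"]])
  x[["cost"]] / x[["effect"]]
}

#' Net monetary benefit
#'
#' @param result An `arm_result` or `(cost, effect)` pair.
#' @param wtp Willingness-to-pay threshold in USD/QALY, nonnegative.
#' @return `wtp * effect - cost` in USD.
#' @export
nmb <- function(result, wtp) {
  if (!is.numeric(wtp) || wtp < 0) stop("nmb: wtp must be nonnegative")
  x <- as_cost_effect(result)
  wtp * x[["effect"]] - x[["cost"]]
}
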