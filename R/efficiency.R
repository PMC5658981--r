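# Value-for-money: cost per value unit, incremental cost-value ratios,
# dominance and the efficiency frontier on the value-cost plane.

#' Cost profile of an option
#'
#' Drug (purchasing) and administration costs are kept outside the value
#' model: only attributes of benefit act as criteria, and the cost side
#' enters through these profiles.  A `rounded_total` may be carried
#' separately from the exact component sum for reporting parity with
#' published figures.
#'
#' @param option Option id.
#' @param drug_cost,admin_cost Non-negative costs (GBP).
#' @param rounded_total Optional reported total; defaults to
#'   `drug_cost + admin_cost`.
#' @return Object of class `"cost_profile"`.
#' @export
cost_profile <- function(option, drug_cost, admin_cost, rounded_total = NULL) {
  stopifnot(drug_cost >= 0, admin_cost >= 0)
  total <- drug_cost + admin_cost
  structure(list(option = option, drug_cost = drug_cost,
                 admin_cost = admin_cost, total_cost = total,
                 rounded_total = if (is.null(rounded_total)) total
                                 else rounded_total),
            class = "cost_profile")
}

reported_cost <- function(cost) {
  if (inherits(cost, "cost_profile")) cost$rounded_total else as.numeric(cost)
}

#' Cost per unit of value
#'
#' Total cost divided by the overall weighted preference value.
#'
#' @param cost A [cost_profile()] (its reported total is used) or a bare
#'   total cost.
#' @param value Overall WPV of the option; must be positive, since a
#'   cost-per-value ratio is undefined for non-positive value.
#' @return GBP per value point.
#' @export
cost_per_value_unit <- function(cost, value) {
  if (!is.finite(value) || value <= 0)
    stop("undefined efficiency for non-positive value", call. = FALSE)
  reported_cost(cost) / value
}

#' Incremental cost-value ratio or dominance verdict
#'
#' When one option has at least as much value for no more cost (one
#' strictly), it dominates and no ratio is meaningful; otherwise the
#' genuine trade-off is summarized as incremental cost per incremental
#' value point.
#'
#' @param cost_a,cost_b Costs ([cost_profile()] or numeric).
#' @param value_a,value_b Overall WPV scores.
#' @param id_a,id_b Option labels for the verdict text.
#' @return List with `type` (`"icvr"`, `"dominance"` or `"equivalent"`),
#'   `icvr` (GBP per value point, `NA` unless a trade-off), and
#'   `dominant` (id of the dominating option, if any).
#' @export
icvr <- function(cost_a, cost_b, value_a, value_b,
                 id_a = "A", id_b = "B") {
  ca <- reported_cost(cost_a); cb <- reported_cost(cost_b)
  if (value_a == value_b && ca == cb)
    return(list(type = "equivalent", icvr = NA_real_, dominant = NA_character_,
                message = "equivalent options"))
  if (value_a >= value_b && ca <= cb)
    return(list(type = "dominance", icvr = NA_real_, dominant = id_a,
                message = paste(id_a, "dominates", id_b)))
  if (value_b >= value_a && cb <= ca)
    return(list(type = "dominance", icvr = NA_real_, dominant = id_b,
                message = paste(id_b, "dominates", id_a)))
  list(type = "icvr", icvr = (ca - cb) / (value_a - value_b),
       dominant = NA_character_,
       message = "trade-off: incremental cost per incremental value point")
}

#' Efficiency frontier on the value-cost plane
#'
#' Non-dominated options under (maximize value, minimize cost).
#'
#' @param costs Named list of [cost_profile()]s (or named numeric costs).
#' @param values Named numeric of overall WPV scores for the same
#'   options.
#' @return Data frame (option, value, cost, efficient) -- the plane
#'   coordinates for plotting, with the frontier flagged.
#' @export
frontier <- function(costs, values) {
  opts <- names(values)
  if (is.null(opts)) stop("values must be named by option", call. = FALSE)
  cost_of <- function(o) {
    c0 <- if (is.list(costs)) costs[[o]] else costs[[o]]
    reported_cost(c0)
  }
  cv <- vapply(opts, cost_of, numeric(1))
  eff <- vapply(seq_along(opts), function(i) {
    !any(vapply(seq_along(opts), function(j) {
      j != i && values[j] >= values[i] && cv[j] <= cv[i] &&
        (values[j] > values[i] || cv[j] < cv[i])
    }, logical(1)))
  }, logical(1))
  data.frame(option = opts, value = as.numeric(values), cost = cv,
             efficient = eff, row.names = NULL)
}

#' Read cost profiles from CSV
#'
#' Columns: `option`, `drug_cost`, `admin_cost`, optional
#' `rounded_total`.
#'
#' @param path CSV file path.
#' @return Named list of [cost_profile()]s.
#' @export
read_costs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("option", "drug_cost", "admin_cost")
  if (!all(need %in% names(df)))
    stop("costs CSV needs columns option, drug_cost, admin_cost",
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    cost_profile(df$option[i], df$drug_cost[i], df$admin_cost[i],
                 if ("rounded_total" %in% names(df)) df$rounded_total[i]))
  stats::setNames(out, df$option)
}
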