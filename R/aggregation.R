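# Additive aggregation: V(a) = sum_i w_i v_i(a).

#' Aggregate partial scores into overall weighted preference values
#'
#' The additive multi-attribute value model: each option's overall value
#' is the weight-weighted sum of its partial preference value scores.
#' Options are ranked by descending overall value; exact ties (|dV| <
#' `tie_tol`) form tie groups, broken lexicographically by option id for
#' deterministic output.
#'
#' @param scores Numeric matrix of partial value scores (rows = options,
#'   columns = attributes), e.g. from [score_table()].
#' @param w Normalized weights (see [normalize_weights()]) over the same
#'   attributes.
#' @param tie_tol Absolute overall-value difference below which two
#'   options are treated as exactly tied (default 1e-6).
#' @return Object of class `"mavt_evaluation"`: list with `values`
#'   (named overall WPV), `contributions` (option x attribute matrix of
#'   `w_i * v_i(a)`), `ranking` (data frame with rank and tie group) and
#'   the weights used.
#' @export
overall_value <- function(scores, w, tie_tol = 1e-6) {
  stopifnot(is.matrix(scores))
  wv <- stats::setNames(as.numeric(w), names(w))
  if (!setequal(colnames(scores), names(wv)))
    stop("model mismatch: score and weight attribute sets differ",
         call. = FALSE)
  wv <- wv[colnames(scores)]
  contributions <- sweep(scores, 2, wv, `*`)
  values <- rowSums(contributions)
  ord <- order(-values, rownames(scores))
  ranked <- values[ord]
  tie_group <- cumsum(c(TRUE, diff(ranked) < -tie_tol))
  ranking <- data.frame(
    option = names(ranked),
    value = as.numeric(ranked),
    rank = match(tie_group, tie_group),   # min-rank within tie group
    tie_group = tie_group,
    row.names = NULL
  )
  structure(list(values = values, contributions = contributions,
                 scores = scores, ranking = ranking, weights = wv,
                 tie_tol = tie_tol),
            class = "mavt_evaluation")
}

#' @export
print.mavt_evaluation <- function(x, ...) {
  cat("Overall weighted preference values:\n")
  df <- x$ranking
  df$value <- round(df$value, 1)  # reporting precision; full kept internally
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-attribute contribution decomposition of one option
#'
#' @param result An [overall_value()] evaluation.
#' @param option Option id.
#' @return Data frame (attribute, weight, score, contribution) ordered by
#'   decreasing contribution; contributions sum to the option's overall
#'   value and are reported signed.
#' @export
decompose <- function(result, option) {
  stopifnot(inherits(result, "mavt_evaluation"))
  if (!option %in% rownames(result$contributions))
    stop("unknown option id '", option, "'", call. = FALSE)
  contr <- result$contributions[option, ]
  df <- data.frame(
    attribute = colnames(result$contributions),
    weight = as.numeric(result$weights),
    score = as.numeric(result$scores[option, ]),
    contribution = as.numeric(contr),
    row.names = NULL
  )
  df[order(-df$contribution), ]
}

#' Ranking with tie groups
#'
#' @param result An [overall_value()] evaluation.
#' @return The ranking data frame (option, value, rank, tie_group).
#' @export
rank_options <- function(result) {
  stopifnot(inherits(result, "mavt_evaluation"))
  result$ranking
}
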