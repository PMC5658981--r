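# Value functions: performance level -> partial preference value on the
# 0/100 reference-anchored interval scale.

#' Build a value function for an attribute
#'
#' Continuous attributes get a piecewise-linear function through ordered
#' anchor points; ordinal/binary attributes get a direct level-to-score
#' lookup.  The anchors must include both reference levels at scores 0
#' and 100, be (weakly) monotone in the preference direction, and cover
#' the full attribute range: evaluation never extrapolates.
#'
#' @param attr An [mavt_attribute()].
#' @param anchors For continuous attributes a two-column data frame /
#'   matrix `(x, v)`, or an anchored [macbeth_scale][derive_scale] whose
#'   stimulus names parse as numbers.  For ordinal attributes a named
#'   numeric vector `level -> score` (or an anchored scale with level
#'   names).
#' @return Object of class `"mavt_value_function"`.
#' @examples
#' os <- mavt_attribute("os", cluster = "the", range = c(6.2, 14.9),
#'                      lower_ref = 6.2, higher_ref = 14.9)
#' vf <- value_function(os, data.frame(x = c(6.2, 14.9), v = c(0, 100)))
#' score_option(vf, 10.55)  # 50
#' @export
value_function <- function(attr, anchors) {
  stopifnot(inherits(attr, "mavt_attribute"))
  if (inherits(anchors, "macbeth_scale")) {
    if (!isTRUE(attr(anchors, "anchored")))
      stop("scale must be anchored before use as a value function",
           call. = FALSE)
    anchors <- if (attr$scale == "continuous")
      data.frame(x = as.numeric(names(anchors)), v = as.numeric(anchors))
    else stats::setNames(as.numeric(anchors), names(anchors))
  }
  if (attr$scale == "continuous") {
    anchors <- as.data.frame(anchors)
    names(anchors) <- c("x", "v")
    anchors <- anchors[order(anchors$x), , drop = FALSE]
    if (anyDuplicated(anchors$x))
      stop("duplicate anchor positions", call. = FALSE)
    ref_v <- function(ref) {
      i <- which(abs(anchors$x - ref) < 1e-12)
      if (!length(i)) NA_real_ else anchors$v[i]
    }
    if (is.na(ref_v(attr$lower_ref)) || is.na(ref_v(attr$higher_ref)))
      stop("reference anchors missing: anchors must include x_l and x_h",
           call. = FALSE)
    if (abs(ref_v(attr$lower_ref)) > 1e-9 ||
        abs(ref_v(attr$higher_ref) - 100) > 1e-9)
      stop("reference anchors missing: v(x_l) must be 0 and v(x_h) 100",
           call. = FALSE)
    dv <- diff(anchors$v)
    mono_ok <- if (attr$direction == "increasing") all(dv >= -1e-9)
               else all(dv <= 1e-9)
    if (!mono_ok)
      stop("non-monotone anchors", call. = FALSE)
    if (anchors$x[1] > attr$range[1] + 1e-12 ||
        anchors$x[nrow(anchors)] < attr$range[2] - 1e-12)
      stop("anchors must cover the full attribute range", call. = FALSE)
    structure(list(attribute = attr$id, scale = "continuous",
                   direction = attr$direction, anchors = anchors),
              class = "mavt_value_function")
  } else {
    scores <- anchors
    if (is.null(names(scores)) || !all(attr$levels %in% names(scores)))
      stop("ordinal value function needs a score for every level",
           call. = FALSE)
    scores <- scores[attr$levels]
    if (abs(scores[[attr$lower_ref]]) > 1e-9 ||
        abs(scores[[attr$higher_ref]] - 100) > 1e-9)
      stop("reference anchors missing: v(x_l) must be 0 and v(x_h) 100",
           call. = FALSE)
    if (any(diff(as.numeric(scores)) < -1e-9))
      stop("non-monotone anchors", call. = FALSE)
    structure(list(attribute = attr$id, scale = attr$scale,
                   levels = attr$levels,
                   scores = stats::setNames(as.numeric(scores), attr$levels)),
              class = "mavt_value_function")
  }
}

#' @export
print.mavt_value_function <- function(x, ...) {
  cat("<value function>", x$attribute, "\n")
  if (x$scale == "continuous") print(x$anchors) else print(x$scores)
  invisible(x)
}

#' Score a performance level
#'
#' Linear interpolation between adjacent anchors for continuous
#' attributes, direct lookup for ordinal levels.  Values outside the
#' anchor coverage raise an error rather than extrapolate: elicited value
#' functions carry no information beyond their anchors.
#'
#' @param vf A [value_function()].
#' @param performance Numeric performance (continuous) or level label.
#' @return Partial preference value (may be negative or above 100).
#' @export
score_option <- function(vf, performance) {
  stopifnot(inherits(vf, "mavt_value_function"))
  if (vf$scale == "continuous") {
    x <- as.numeric(performance)
    rng <- range(vf$anchors$x)
    if (any(is.na(x)))
      stop("missing performance", call. = FALSE)
    if (any(x < rng[1] - 1e-12 | x > rng[2] + 1e-12))
      stop("extrapolation required: performance outside anchor coverage",
           call. = FALSE)
    stats::approx(vf$anchors$x, vf$anchors$v, xout = x, ties = "ordered")$y
  } else {
    lev <- as.character(performance)
    if (!all(lev %in% vf$levels))
      stop("extrapolation required: undeclared ordinal level '",
           paste(setdiff(lev, vf$levels), collapse = "', '"), "'",
           call. = FALSE)
    unname(vf$scores[lev])
  }
}

#' Score a full performance table
#'
#' Applies [score_option()] cell-wise.
#'
#' @param perf Performance data frame (first column `option`).
#' @param vfs Named list of [value_function()]s covering every attribute
#'   column, or an [mavt_model()] carrying them.
#' @return Numeric matrix, rows = options, columns = attributes, of
#'   partial preference value scores.
#' @export
score_table <- function(perf, vfs) {
  if (inherits(vfs, "mavt_model")) vfs <- vfs$value_functions
  stopifnot(is.data.frame(perf), !is.null(vfs))
  attrs <- intersect(names(perf)[-1], names(vfs))
  if (!setequal(attrs, names(vfs)))
    stop("value functions and performance columns differ", call. = FALSE)
  opts <- as.character(perf$option)
  out <- matrix(NA_real_, length(opts), length(attrs),
                dimnames = list(opts, attrs))
  for (a in attrs)
    out[, a] <- vapply(seq_along(opts),
                       function(i) score_option(vfs[[a]], perf[[a]][i]),
                       numeric(1))
  out
}
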