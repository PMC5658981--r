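# One-way weight sensitivity: rank-reversal thresholds under proportional
# renormalization of the remaining weights, plus robustness checks.

#' Weight at which two options' overall values equalize
#'
#' One-way sensitivity on a single attribute's weight: as `w(attr)` moves
#' away from its baseline, all other weights are rescaled proportionally
#' so the vector stays normalized.  With partial scores `a = v_A(attr)`,
#' `b = v_B(attr)` and rest-values `R_X = (V_X - w0 x) / (1 - w0)`, the
#' overall values as a function of the attribute weight `w` are
#' `V_X(w) = w x + (1 - w) R_X`, and they cross at
#' `w* = (R_B - R_A) / ((a - b) - (R_A - R_B))`.
#'
#' @param attr Attribute id.
#' @param opt_a,opt_b Option ids (any order; a threshold is a crossing
#'   point of the two overall-value lines).
#' @param scores Partial-score matrix (rows = options).
#' @param w Normalized weights.
#' @return List with `w_star` (crossing weight in `[0, 1]`, or `NA` when
#'   no crossing exists there), baseline `w0`, `direction`
#'   (`"increase"`/`"decrease"`/`NA`) and `rel_change` = `|w* - w0| / w0`.
#' @export
weight_threshold <- function(attr, opt_a, opt_b, scores, w) {
  wv <- stats::setNames(as.numeric(w), names(w))[colnames(scores)]
  if (abs(sum(wv) - 1) > 1e-9)
    stop("weights must be normalized", call. = FALSE)
  if (!attr %in% colnames(scores))
    stop("unknown attribute '", attr, "'", call. = FALSE)
  if (!all(c(opt_a, opt_b) %in% rownames(scores)))
    stop("unknown option id", call. = FALSE)
  w0 <- wv[[attr]]
  if (w0 >= 1 - 1e-12)
    stop("degenerate renormalization: remaining weights are zero",
         call. = FALSE)
  a <- scores[opt_a, attr]; b <- scores[opt_b, attr]
  V_A <- sum(wv * scores[opt_a, ]); V_B <- sum(wv * scores[opt_b, ])
  R_A <- (V_A - w0 * a) / (1 - w0)
  R_B <- (V_B - w0 * b) / (1 - w0)
  denom <- (a - b) - (R_A - R_B)
  out <- list(attribute = attr, option_a = opt_a, option_b = opt_b,
              w0 = w0, w_star = NA_real_, direction = NA_character_,
              rel_change = NA_real_)
  # equal partial scores: V_A - V_B is proportional to (1 - w), so the
  # only root is the degenerate w = 1 where every other weight vanishes
  if (abs(a - b) < 1e-12) return(out)
  if (abs(denom) < 1e-12) return(out)   # parallel value lines: no crossing
  w_star <- (R_B - R_A) / denom
  if (w_star < -1e-12 || w_star > 1 + 1e-12) return(out)
  w_star <- min(max(w_star, 0), 1)
  out$w_star <- w_star
  out$direction <- if (w_star >= w0) "increase" else "decrease"
  out$rel_change <- if (w0 > 0) abs(w_star - w0) / w0 else Inf
  out
}

#' One-way weight sensitivity report
#'
#' Thresholds for every attribute and every requested option pair.
#'
#' @param scores Partial-score matrix.
#' @param w Normalized weights.
#' @param pairs Data frame (or 2-column matrix) of option id pairs; by
#'   default every adjacent pair of the baseline ranking (higher-ranked
#'   first).
#' @return Object of class `"mavt_sensitivity"`: data frame with one row
#'   per (attribute, pair) -- baseline weight, threshold weight (`NA`
#'   when no reversal exists in `[0, 1]`), direction of change, and
#'   relative change.
#' @export
one_way_report <- function(scores, w, pairs = NULL) {
  wv <- stats::setNames(as.numeric(w), names(w))
  if (is.null(pairs)) {
    r <- overall_value(scores, wv)$ranking
    pairs <- data.frame(a = r$option[-nrow(r)], b = r$option[-1])
  }
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("a", "b")
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    for (attr in colnames(scores)) {
      th <- weight_threshold(attr, pairs$a[p], pairs$b[p], scores, wv)
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = attr, option_a = pairs$a[p], option_b = pairs$b[p],
        w0 = th$w0, w_star = th$w_star, direction = th$direction,
        rel_change = th$rel_change, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("mavt_sensitivity", "data.frame"))
}

#' @export
print.mavt_sensitivity <- function(x, ...) {
  df <- as.data.frame(x)
  df$w0 <- round(100 * df$w0, 1)        # thresholds on the 0-100 scale
  df$w_star <- round(100 * df$w_star, 1)
  df$rel_change <- round(df$rel_change, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Robustness margin of a ranking
#'
#' The minimal relative change of any single baseline weight that causes
#' a rank change, taken over a sensitivity report computed for the
#' adjacent-rank pairs.
#'
#' @param report An [one_way_report()] result.
#' @return Single number: `min |w* - w0| / w0` over entries with a
#'   threshold in `[0, 1]` (`Inf` when no reversal is possible at all).
#' @export
robustness_margin <- function(report) {
  rel <- report$rel_change[!is.na(report$w_star)]
  if (!length(rel)) return(Inf)
  min(rel)
}

#' Stability of the ranking under bounded score perturbations
#'
#' For each attribute independently, every option's partial score on that
#' attribute may shift by up to `delta_points` value points in either
#' direction (worst case against the current ranking, one attribute at a
#' time).  An adjacent pair (A above B) swaps when
#' `V_A - V_B < 2 * delta * w_i`, the worst case being A shifted down and
#' B up on attribute i.  This per-attribute semantics is this package's
#' own definition of the perturbation space (see the methods vignette);
#' a simultaneous all-attribute adversarial shift is deliberately not
#' used.
#'
#' @param scores Partial-score matrix.
#' @param w Normalized weights.
#' @param delta_points Non-negative perturbation size in value points.
#' @return List with `stable` (logical) and `flagged`: data frame of
#'   (attribute, option_a, option_b, margin) rows where the ranking can
#'   swap, `margin` being `V_A - V_B - 2 delta w_i` (negative = swap
#'   possible).
#' @export
reference_perturbation_check <- function(scores, w, delta_points) {
  stopifnot(delta_points >= 0)
  wv <- stats::setNames(as.numeric(w), names(w))[colnames(scores)]
  r <- overall_value(scores, wv)$ranking
  flagged <- list()
  for (p in seq_len(nrow(r) - 1)) {
    A <- r$option[p]; B <- r$option[p + 1]
    dV <- r$value[p] - r$value[p + 1]
    for (attr in colnames(scores)) {
      margin <- dV - 2 * delta_points * wv[[attr]]
      if (margin < 0)
        flagged[[length(flagged) + 1L]] <- data.frame(
          attribute = attr, option_a = A, option_b = B, margin = margin,
          stringsAsFactors = FALSE)
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(attribute = character(0), option_a = character(0),
               option_b = character(0), margin = numeric(0))
  list(stable = nrow(flagged) == 0L, flagged = flagged)
}
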