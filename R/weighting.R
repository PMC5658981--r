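# Criteria weights from qualitative swing comparisons.

#' Normalize raw weights
#'
#' Proportional scaling to sum 1.  Zero-weight attributes are retained;
#' an all-zero input is a degenerate model.
#'
#' @param w Named (or plain) non-negative numeric vector.
#' @return Object of class `"mavt_weights"`: normalized weights with the
#'   normalization constant stored as attribute `"total"`.
#' @export
normalize_weights <- function(w) {
  w <- unclass(w)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  total <- sum(w)
  if (total <= 0)
    stop("degenerate weights: at least one weight must be positive",
         call. = FALSE)
  structure(w / total, class = "mavt_weights", total = total)
}

#' @export
print.mavt_weights <- function(x, ...) {
  v <- stats::setNames(as.numeric(x), names(x))
  print(round(100 * v[order(-v)], 1))
  invisible(x)
}

#' Derive criteria weights from a swing judgment matrix
#'
#' Qualitative swing weighting: stimuli are the `x_l -> x_h` improvement
#' swings on each attribute plus a fictitious null swing (no improvement)
#' that must sit at the bottom of the preference ordering.  The MACBETH
#' scale of the swing matrix, with the null swing at 0, is normalized
#' into weights.
#'
#' @param jm A [judgment_matrix()] whose stimuli are attribute ids plus
#'   the null swing.
#' @param null_id Id of the null swing stimulus (default `"null"`).
#' @param delta Passed to [derive_scale()].
#' @return `"mavt_weights"` over the attribute stimuli.
#' @export
weights_from_swings <- function(jm, null_id = "null", delta = 1) {
  stopifnot(inherits(jm, "judgment_matrix"))
  stimuli <- rownames(jm)
  if (!null_id %in% stimuli)
    stop("swing matrix must include the null swing '", null_id, "'",
         call. = FALSE)
  if (match(null_id, stimuli) != length(stimuli))
    stop("the null swing must be the bottom (least preferred) stimulus",
         call. = FALSE)
  s <- derive_scale(jm, delta)
  raw <- as.numeric(s)[-length(s)]
  names(raw) <- stimuli[-length(stimuli)]
  normalize_weights(raw)
}

#' Cluster weight roll-ups
#'
#' Cluster weights carry no information of their own: they are the sums
#' of their member attributes' weights.
#'
#' @param w Normalized weights covering every leaf of `tree`.
#' @param tree A [value_tree()].
#' @return Named numeric vector of cluster weights (summing to 1).
#' @export
cluster_weights <- function(w, tree) {
  stopifnot(inherits(tree, "mavt_tree"))
  wv <- stats::setNames(as.numeric(w), names(w))
  leaves <- unlist(lapply(tree$clusters, `[[`, "attributes"),
                   use.names = FALSE)
  if (!all(leaves %in% names(wv)))
    stop("weights must cover all leaves of the tree", call. = FALSE)
  vapply(tree$clusters, function(cl) sum(wv[cl$attributes]), numeric(1))
}
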