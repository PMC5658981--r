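# MACBETH: qualitative pairwise difference-of-attractiveness judgments
# converted into cardinal value scales by linear programming.

#' Semantic judgment categories
#'
#' The seven ordered categories used to express the difference of
#' attractiveness between two stimuli, coded 0 ("no" difference) to 6
#' ("extreme").
#'
#' @format Named integer vector of length 7.
#' @export
macbeth_categories <- c(
  "no" = 0L, "very weak" = 1L, "weak" = 2L, "moderate" = 3L,
  "strong" = 4L, "very strong" = 5L, "extreme" = 6L
)

#' Construct a judgment matrix
#'
#' A judgment matrix records, for every ordered pair of stimuli, the
#' qualitative category of the difference of attractiveness between them.
#' Stimuli are listed from most to least preferred; only the cells above
#' the diagonal are meaningful.
#'
#' @param judgments Square matrix (character category labels or integer
#'   codes 0--6) with identical row and column names giving the stimuli in
#'   decreasing order of preference.  Cells on or below the diagonal are
#'   ignored.
#' @return Object of class `"judgment_matrix"`: an integer matrix with the
#'   stimulus ordering in its dimnames.
#' @examples
#' m <- matrix(NA, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' m["a", "b"] <- "weak"; m["b", "c"] <- "strong"; m["a", "c"] <- "very strong"
#' jm <- judgment_matrix(m)
#' @export
judgment_matrix <- function(judgments) {
  if (!is.matrix(judgments) || nrow(judgments) != ncol(judgments))
    stop("`judgments` must be a square matrix", call. = FALSE)
  stimuli <- rownames(judgments)
  if (is.null(stimuli) || !identical(stimuli, colnames(judgments)))
    stop("row and column names must both give the stimulus ordering",
         call. = FALSE)
  if (anyDuplicated(stimuli))
    stop("stimulus ids must be unique", call. = FALSE)
  n <- length(stimuli)
  codes <- matrix(NA_integer_, n, n, dimnames = list(stimuli, stimuli))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      codes[i, j] <- as_category_code(judgments[i, j], i, j, stimuli)
    }
  }
  if (n >= 2 && anyNA(codes[upper.tri(codes)]))
    stop("every above-diagonal cell must be filled", call. = FALSE)
  structure(codes, class = "judgment_matrix")
}

as_category_code <- function(x, i, j, stimuli) {
  if (length(x) != 1 || is.na(x))
    return(NA_integer_)
  if (is.character(x)) {
    x <- trimws(x)
    if (x == "") return(NA_integer_)
    if (!x %in% names(macbeth_categories)) {
      suppressWarnings(num <- as.integer(x))
      if (is.na(num))
        stop(sprintf("unknown judgment category '%s' for (%s, %s)",
                     x, stimuli[i], stimuli[j]), call. = FALSE)
      x <- num
    } else {
      return(macbeth_categories[[x]])
    }
  }
  x <- as.integer(x)
  if (x < 0L || x > 6L)
    stop(sprintf("judgment code must be in 0..6, got %d for (%s, %s)",
                 x, stimuli[i], stimuli[j]), call. = FALSE)
  x
}

#' @export
print.judgment_matrix <- function(x, ...) {
  lab <- names(macbeth_categories)[unclass(x) + 1L]
  out <- matrix(lab, nrow(x), ncol(x), dimnames = dimnames(x))
  out[is.na(unclass(x))] <- "."
  cat("MACBETH judgment matrix (", nrow(x), " stimuli)\n", sep = "")
  print(out, quote = FALSE)
  invisible(x)
}

# ---- LP formulation --------------------------------------------------------
#
# Variables: v(x_i) for each stimulus, bottom stimulus fixed at 0.
# For every pair (a, b), a preferred, in category k >= 1:
#     v(a) - v(b) >= k * delta
# Pairs in category 0 are constrained equal.
# For every two pairs p1 (category k1) and p2 (category k2), k1 > k2 >= 1:
#     d(p1) >= d(p2) + (k1 - k2) * delta
# (the k2 = 0 case is implied: those pairs have difference 0, so the
# per-pair bound already enforces it).
# Objective: minimize v(top).

macbeth_pairs <- function(jm) {
  n <- nrow(jm)
  idx <- which(upper.tri(jm), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             k = unclass(jm)[upper.tri(jm)])
}

# Build the full inequality/equality system on variables v_1..v_n.
# Returns list(A_geq, b_geq, A_eq, b_eq) with A %*% v >= b / == b.
macbeth_constraints <- function(jm, delta = 1) {
  n <- nrow(jm)
  pr <- macbeth_pairs(jm)
  # pair incidence matrix: row p is e_i - e_j for pair p = (i, j)
  P <- nrow(pr)
  D <- matrix(0, P, n)
  D[cbind(seq_len(P), pr$i)] <- 1
  D[cbind(seq_len(P), pr$j)] <- -1
  eq0 <- pr$k == 0L
  A_eq <- rbind(D[eq0, , drop = FALSE],
                `[<-`(numeric(n), n, 1))   # bottom stimulus anchored at 0
  b_eq <- rep(0, nrow(A_eq))
  A_geq <- D[!eq0, , drop = FALSE]
  b_geq <- pr$k[!eq0] * delta
  # inter-pair dominance: d(p1) >= d(p2) + (k1 - k2) * delta for k1 > k2
  pos <- which(!eq0)
  if (length(pos) >= 2) {
    cmb <- expand.grid(p1 = pos, p2 = pos)
    cmb <- cmb[pr$k[cmb$p1] > pr$k[cmb$p2], , drop = FALSE]
    if (nrow(cmb)) {
      A_geq <- rbind(A_geq, D[cmb$p1, , drop = FALSE] -
                            D[cmb$p2, , drop = FALSE])
      b_geq <- c(b_geq, (pr$k[cmb$p1] - pr$k[cmb$p2]) * delta)
    }
  }
  list(A_geq = A_geq, b_geq = b_geq, A_eq = A_eq, b_eq = b_eq)
}

# Solve min/max of a linear objective over the MACBETH polytope.
# MACBETH constraint systems built from integer category data are
# massively degenerate at their vertices, which defeats textbook simplex
# implementations; instead the LP is solved as a dual active-set QP
# (quadprog) minimizing lambda * c'v + ||v||^2 / 2.  The identity Hessian
# keeps the solve perfectly conditioned, lambda = 1e5 dominates every
# attainable score magnitude (scores are bounded by 6 * (n - 1) * delta,
# and feasible_bounds caps at `ceiling` < lambda), so the solution sits on
# the LP-optimal face -- cross-checked against an exact solver to 1e-10 --
# and the norm term picks its minimum-norm point deterministically.
# `extra_eq` allows additional equality rows (used by feasible_bounds).
# Returns list(x, ok).
macbeth_solve <- function(cons, objective, maximize = FALSE,
                          ub = NULL, extra_eq = NULL, extra_beq = NULL,
                          lambda = 1e5) {
  n <- length(objective)
  A_eq <- cons$A_eq; b_eq <- cons$b_eq
  if (!is.null(extra_eq)) {
    A_eq <- rbind(A_eq, extra_eq)
    b_eq <- c(b_eq, extra_beq)
  }
  # Non-negativity is implied (every stimulus pairs with the zero-anchored
  # bottom at some category k >= 0); adding it as explicit rows only feeds
  # the degeneracy.  An upper cap, when requested, goes on the objective's
  # own variable(s).
  A_geq <- cons$A_geq; b_geq <- cons$b_geq
  if (!is.null(ub)) {
    for (i in which(objective != 0)) {
      r <- numeric(n); r[i] <- -1
      A_geq <- rbind(A_geq, r)
      b_geq <- c(b_geq, -ub)
    }
  }
  # Deduplicate inequality rows and apply a tiny lexicographic loosening
  # of the right-hand sides: the dual active-set method can cycle on the
  # exactly-degenerate vertices these integer systems produce, and the
  # perturbation (1e-9 per row) breaks every exact tie while moving the
  # solution by far less than any stated tolerance.
  M <- cbind(A_geq, b_geq)
  M <- M[!duplicated(M), , drop = FALSE]
  A_geq <- M[, seq_len(n), drop = FALSE]
  b_geq <- M[, n + 1L] - 1e-9 * seq_len(nrow(M))
  # quadprog rejects linearly dependent equality rows (e.g. a matrix of
  # all-tied stimuli yields more equalities than variables): keep an
  # independent subset and verify the dropped rows against the solution.
  drop_A <- NULL; drop_b <- NULL
  if (nrow(A_eq) > 1) {
    qrA <- qr(t(A_eq))
    keep <- sort(qrA$pivot[seq_len(qrA$rank)])
    if (length(keep) < nrow(A_eq)) {
      drop_A <- A_eq[-keep, , drop = FALSE]
      drop_b <- b_eq[-keep]
      A_eq <- A_eq[keep, , drop = FALSE]
      b_eq <- b_eq[keep]
    }
  }
  obj <- if (maximize) -objective else objective
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = -lambda * obj,
                       Amat = t(rbind(A_eq, A_geq)),
                       bvec = c(b_eq, b_geq), meq = nrow(A_eq)),
    error = function(e) e
  )
  if (inherits(res, "error"))
    return(list(x = NULL, ok = FALSE, message = conditionMessage(res)))
  if (!is.null(drop_A) &&
      max(abs(drop_A %*% res$solution - drop_b)) > 1e-6)
    return(list(x = NULL, ok = FALSE,
                message = "dependent equality constraints inconsistent"))
  list(x = res$solution, ok = TRUE)
}

#' Check a judgment matrix for ordinal and cardinal consistency
#'
#' The ordinal check requires that a pair spanning a wider stretch of the
#' preference ordering never carries a strictly smaller category than a
#' pair nested inside it.  The cardinal check is feasibility of the linear
#' program used by [derive_scale()].
#'
#' @param jm A [judgment_matrix()].
#' @param delta Minimal value-scale unit per category step (default 1; any
#'   positive value yields the same anchored scale).
#' @return Object of class `"macbeth_consistency"`: list with elements
#'   `consistent`, `ordinal_ok`, `cardinal_ok` and a data frame
#'   `violations` naming each offending cell pair.
#' @export
check_consistency <- function(jm, delta = 1) {
  stopifnot(inherits(jm, "judgment_matrix"))
  n <- nrow(jm)
  stimuli <- rownames(jm)
  viol <- list()
  m <- unclass(jm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # widening the span along the row must not shrink the category
      if (j - i > 1) {
        if (m[i, j] < m[i, j - 1L])
          viol[[length(viol) + 1L]] <- data.frame(
            a = stimuli[i], b = stimuli[j],
            nested_a = stimuli[i], nested_b = stimuli[j - 1L],
            category = m[i, j], nested_category = m[i, j - 1L])
        if (m[i, j] < m[i + 1L, j])
          viol[[length(viol) + 1L]] <- data.frame(
            a = stimuli[i], b = stimuli[j],
            nested_a = stimuli[i + 1L], nested_b = stimuli[j],
            category = m[i, j], nested_category = m[i + 1L, j])
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(a = character(0), b = character(0),
               nested_a = character(0), nested_b = character(0),
               category = integer(0), nested_category = integer(0))
  ordinal_ok <- nrow(violations) == 0L
  cardinal_ok <- NA
  if (ordinal_ok) {
    cons <- macbeth_constraints(jm, delta)
    obj <- numeric(n); obj[1] <- 1
    cardinal_ok <- macbeth_solve(cons, obj)$ok
  }
  structure(list(
    consistent = isTRUE(ordinal_ok) && isTRUE(cardinal_ok),
    ordinal_ok = ordinal_ok,
    cardinal_ok = cardinal_ok,
    violations = violations
  ), class = "macbeth_consistency")
}

#' @export
print.macbeth_consistency <- function(x, ...) {
  cat("MACBETH consistency check:",
      if (x$consistent) "consistent" else "INCONSISTENT", "\n")
  cat("  ordinal:", x$ordinal_ok,
      " cardinal (LP feasible):", x$cardinal_ok, "\n")
  if (nrow(x$violations)) {
    cat("  violated cell pairs:\n")
    print(x$violations)
  }
  invisible(x)
}

#' Derive a cardinal value scale from a judgment matrix
#'
#' Solves the MACBETH linear program: the bottom stimulus is fixed at 0,
#' every pair judged in category *k* must differ by at least *k* value
#' units, differences respect the category ordering across pairs, and the
#' top stimulus' score is minimized.
#'
#' @inheritParams check_consistency
#' @return Object of class `"macbeth_scale"`: named numeric vector of
#'   scores (stimuli in matrix order) with attribute `anchored = FALSE`.
#' @examples
#' m <- matrix(NA, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' m["a", "b"] <- "moderate"
#' derive_scale(judgment_matrix(m))  # b = 0, a = 3
#' @export
derive_scale <- function(jm, delta = 1) {
  stopifnot(inherits(jm, "judgment_matrix"), delta > 0)
  n <- nrow(jm)
  cons <- macbeth_constraints(jm, delta)
  obj <- numeric(n); obj[1] <- 1
  sol <- macbeth_solve(cons, obj)
  if (!sol$ok)
    stop(macbeth_infeasible_condition(jm))
  scores <- sol$x
  names(scores) <- rownames(jm)
  structure(scores, class = "macbeth_scale", anchored = FALSE, delta = delta)
}

macbeth_infeasible_condition <- function(jm) {
  pr <- macbeth_pairs(jm)
  stimuli <- rownames(jm)
  constraint_set <- sprintf("(%s, %s) = %s", stimuli[pr$i], stimuli[pr$j],
                            names(macbeth_categories)[pr$k + 1L])
  structure(
    class = c("macbeth_incompatible", "error", "condition"),
    list(message = paste0(
      "incompatible judgments: no cardinal scale satisfies the ",
      "constraint set {", paste(constraint_set, collapse = "; "), "}"),
      call = NULL, constraints = constraint_set)
  )
}

#' @export
print.macbeth_scale <- function(x, ...) {
  cat("MACBETH", if (isTRUE(attr(x, "anchored"))) "anchored" else "unanchored",
      "scale:\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Feasible score interval for one stimulus
#'
#' With every other stimulus fixed at its derived score, finds the
#' interval of scores for `stimulus` compatible with the judgment matrix,
#' by minimizing and maximizing its value over the LP polytope.  The upper
#' end is capped at `ceiling` and reported as `Inf` (with `capped = TRUE`)
#' when the cap is attained, since the basic formulation imposes no upper
#' bound on the top stimulus.
#'
#' @inheritParams check_consistency
#' @param stimulus Stimulus id.
#' @param scale Optional [derive_scale()] result to fix the other stimuli
#'   at; derived afresh when omitted.
#' @param ceiling Finite cap used to detect unboundedness (default 1e4).
#' @return List with `lower`, `upper` and logical `capped`.
#' @export
feasible_bounds <- function(jm, stimulus, scale = NULL, delta = 1,
                            ceiling = 1e4) {
  stopifnot(inherits(jm, "judgment_matrix"))
  stimuli <- rownames(jm)
  s <- match(stimulus, stimuli)
  if (is.na(s)) stop("unknown stimulus '", stimulus, "'", call. = FALSE)
  if (is.null(scale)) scale <- derive_scale(jm, delta)
  n <- length(stimuli)
  cons <- macbeth_constraints(jm, delta)
  others <- setdiff(seq_len(n), s)
  # fix the other stimuli as two-sided inequalities with a small slack:
  # the derived scores sit exactly on active constraints, so hard
  # equalities there are numerically borderline
  tol <- 1e-6
  fix <- matrix(0, 2 * length(others), n)
  bfix <- numeric(2 * length(others))
  for (k in seq_along(others)) {
    i <- others[k]; v <- as.numeric(scale)[i]
    fix[2 * k - 1, i] <- 1;  bfix[2 * k - 1] <- v - tol
    fix[2 * k, i]     <- -1; bfix[2 * k]     <- -v - tol
  }
  cons$A_geq <- rbind(cons$A_geq, fix)
  cons$b_geq <- c(cons$b_geq, bfix)
  obj <- numeric(n); obj[s] <- 1
  lo <- macbeth_solve(cons, obj, maximize = FALSE, ub = ceiling)
  hi <- macbeth_solve(cons, obj, maximize = TRUE, ub = ceiling)
  if (!lo$ok || !hi$ok)
    stop(macbeth_infeasible_condition(jm))
  upper <- hi$x[s]
  capped <- upper >= ceiling - 1e-6
  list(lower = lo$x[s], upper = if (capped) Inf else upper, capped = capped)
}

#' Anchor a cardinal scale at two reference stimuli
#'
#' Applies the linear transform `v'(x) = 100 * (s(x) - s(x_l)) /
#' (s(x_h) - s(x_l))`, so the lower reference maps to 0 and the higher to
#' 100.  Stimuli outside the reference interval map below 0 or above 100.
#'
#' @param scale A `"macbeth_scale"` (or named numeric vector).
#' @param x_l,x_h Stimulus ids of the lower and higher reference levels.
#' @return Anchored `"macbeth_scale"`.
#' @export
anchor_scale <- function(scale, x_l, x_h) {
  s <- as.numeric(scale)
  names(s) <- names(scale)
  if (!x_l %in% names(s) || !x_h %in% names(s))
    stop("reference levels must be among the scale's stimuli", call. = FALSE)
  if (s[[x_h]] <= s[[x_l]])
    stop("reference levels not increasing in preference", call. = FALSE)
  out <- 100 * (s - s[[x_l]]) / (s[[x_h]] - s[[x_l]])
  structure(out, class = "macbeth_scale", anchored = TRUE,
            delta = attr(scale, "delta"))
}

#' Read a judgment matrix from CSV
#'
#' Expects stimulus ids as the header and in the first column, category
#' labels (or codes) in the above-diagonal cells and empty cells below the
#' diagonal.
#'
#' @param path CSV file path.
#' @return A [judgment_matrix()].
#' @export
read_judgments <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stimuli <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- stimuli
  judgment_matrix(m)
}

#' Write a judgment matrix to CSV
#'
#' @param jm A [judgment_matrix()].
#' @param path Output path.
#' @export
write_judgments <- function(jm, path) {
  lab <- names(macbeth_categories)[unclass(jm) + 1L]
  out <- matrix(lab, nrow(jm), ncol(jm))
  out[is.na(unclass(jm))] <- ""
  df <- data.frame(stimulus = rownames(jm), out, check.names = FALSE)
  colnames(df) <- c("stimulus", colnames(jm))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Assert (for tests and the verification harness) that a scale satisfies
# every LP constraint of its matrix.  Returns the worst violation margin
# (non-positive when all constraints hold).
macbeth_constraint_violation <- function(jm, scale, delta = 1, tol = 1e-7) {
  cons <- macbeth_constraints(jm, delta)
  v <- as.numeric(scale)
  worst <- -Inf
  if (nrow(cons$A_geq))
    worst <- max(worst, max(cons$b_geq - cons$A_geq %*% v))
  if (nrow(cons$A_eq))
    worst <- max(worst, max(abs(cons$A_eq %*% v - cons$b_eq)))
  worst
}
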