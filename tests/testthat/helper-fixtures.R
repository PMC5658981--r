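# Shared helpers: compact judgment-matrix builder, independent oracles.

# Build a judgment matrix from (a, b, category) triples.
jm <- function(stimuli, ...) {
  m <- matrix(NA, length(stimuli), length(stimuli),
              dimnames = list(stimuli, stimuli))
  for (cell in list(...)) m[cell[[1]], cell[[2]]] <- cell[[3]]
  judgment_matrix(m)
}

# A tiny two-attribute model used across validation tests.
toy_model <- function() {
  tree <- value_tree(list(benefit = c("eff", "qol")))
  attrs <- list(
    mavt_attribute("eff", cluster = "benefit", range = c(0, 10),
                   lower_ref = 2, higher_ref = 8),
    mavt_attribute("qol", cluster = "benefit", direction = "decreasing",
                   range = c(0, 100), lower_ref = 80, higher_ref = 20))
  vfs <- list(
    eff = value_function(attrs[[1]], data.frame(x = c(0, 2, 8, 10),
                                                v = c(-20, 0, 100, 120))),
    qol = value_function(attrs[[2]], data.frame(x = c(0, 20, 80, 100),
                                                v = c(120, 100, 0, -30))))
  mavt_model(tree, attrs, value_functions = vfs,
             weights = list(base = c(eff = 60, qol = 40)))
}

# Independent interpolation oracle: brute-force segment search.
interp_oracle <- function(xs, vs, x) {
  ord <- order(xs); xs <- xs[ord]; vs <- vs[ord]
  for (i in seq_len(length(xs) - 1)) {
    if (x >= xs[i] - 1e-12 && x <= xs[i + 1] + 1e-12) {
      t <- (x - xs[i]) / (xs[i + 1] - xs[i])
      return((1 - t) * vs[i] + t * vs[i + 1])
    }
  }
  stop("outside")
}

# Overall value when attribute `attr` has weight wx and all other
# weights are rescaled proportionally.
value_at_weight <- function(option, attr, wx, scores, w) {
  wv <- stats::setNames(as.numeric(w), names(w))[colnames(scores)]
  w0 <- wv[[attr]]
  wnew <- wv * (1 - wx) / (1 - w0)
  wnew[[attr]] <- wx
  sum(wnew * scores[option, ])
}

# Bisection oracle for the rank-reversal threshold on [0, 1].
threshold_bisect <- function(attr, opt_a, opt_b, scores, w, tol = 1e-9) {
  f <- function(wx) value_at_weight(opt_a, attr, wx, scores, w) -
                    value_at_weight(opt_b, attr, wx, scores, w)
  grid <- seq(0, 1, length.out = 201)
  fg <- vapply(grid, f, numeric(1))
  idx <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (!length(idx)) return(NA_real_)
  lo <- grid[idx[1]]; hi <- grid[idx[1] + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# O(n^2) dominance filter for the efficiency frontier.
frontier_oracle <- function(values, costs) {
  n <- length(values)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (values[j] >= values[i] && costs[j] <= costs[i] &&
          (values[j] > values[i] || costs[j] < costs[i])) dominated <- TRUE
    }
    keep[i] <- !dominated
  }
  keep
}
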