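# Random decision problems with the statistical structure the pipeline
# assumes: monotone latent value functions, positive normalized weights,
# performances within attribute ranges, and judgment matrices binned
# from latent value differences.

#' Generate a random decision problem
#'
#' Emulates an elicited appraisal model: per attribute a random range, a
#' monotone piecewise-linear latent value function with 3--6 knots, a
#' lower reference level placed strictly inside the range (a
#' satisfactory-performance benchmark, so worse performances score below
#' 0) and a higher reference at the preferred range end; positive
#' normalized weights; option performances uniform within ranges.
#'
#' @param n_options Number of options (>= 2).
#' @param n_attributes Number of attributes (>= 1).
#' @param seed Integer seed; the problem is reproducible given the seed.
#' @param config List of overrides: `n_knots` (range, default `c(3, 6)`),
#'   `prop_decreasing` (share of decreasing-preference attributes,
#'   default 0.3), `lower_ref` (`"interior"` default, or `"min"` for a
#'   reference at the worst range end).
#' @return Object of class `"synthetic_problem"`: list with `model`
#'   (tree, attributes, value functions, weights), `performance`,
#'   `true_scores`, `true_wpv`, `latent` (per-attribute latent knot
#'   functions), `seed`, `config`.
#' @export
generate_problem <- function(n_options, n_attributes, seed = 1L,
                             config = list()) {
  if (n_options < 2 || n_attributes < 1)
    stop("need n_options >= 2 and n_attributes >= 1", call. = FALSE)
  cfg <- utils::modifyList(
    list(n_knots = c(3L, 6L), prop_decreasing = 0.3, lower_ref = "interior"),
    config)
  set.seed(seed)
  attr_ids <- sprintf("attr%02d", seq_len(n_attributes))
  opt_ids <- sprintf("opt%02d", seq_len(n_options))
  cluster_ids <- c("benefit", "risk")
  assignment <- sample(cluster_ids, n_attributes, replace = TRUE)
  assignment[1] <- "benefit"   # never an empty first cluster
  attributes <- list(); vfs <- list(); latent <- list()
  for (i in seq_len(n_attributes)) {
    lo <- round(stats::runif(1, 0, 50), 3)
    hi <- lo + round(stats::runif(1, 5, 100), 3)
    k <- sample(seq(cfg$n_knots[1], cfg$n_knots[2]), 1)
    xs <- sort(c(lo, hi, stats::runif(k - 2, lo, hi)))
    dirn <- if (stats::runif(1) < cfg$prop_decreasing) "decreasing"
            else "increasing"
    u <- cumsum(c(0, stats::runif(k - 1, 0.2, 1)))   # increasing latent
    if (dirn == "decreasing") u <- rev(u)            # in preference order
    # reference knots: lower interior (satisfactory), higher at best end
    if (dirn == "increasing") {
      l_idx <- if (cfg$lower_ref == "interior" && k > 2) 2L else 1L
      h_idx <- k
    } else {
      l_idx <- if (cfg$lower_ref == "interior" && k > 2) k - 1L else k
      h_idx <- 1L
    }
    x_l <- xs[l_idx]; x_h <- xs[h_idx]
    v <- 100 * (u - u[l_idx]) / (u[h_idx] - u[l_idx])
    a <- mavt_attribute(attr_ids[i], cluster = assignment[i],
                        scale = "continuous", direction = dirn,
                        range = c(lo, hi), lower_ref = x_l, higher_ref = x_h)
    attributes[[i]] <- a
    vfs[[i]] <- value_function(a, data.frame(x = xs, v = v))
    latent[[i]] <- list(x = xs, v = v, direction = dirn)
  }
  names(vfs) <- attr_ids
  names(latent) <- attr_ids
  w_raw <- stats::rgamma(n_attributes, shape = 2, rate = 1) + 1e-3
  weights <- normalize_weights(stats::setNames(w_raw, attr_ids))
  perf <- data.frame(option = opt_ids)
  for (i in seq_len(n_attributes)) {
    a <- attributes[[i]]
    perf[[attr_ids[i]]] <- round(stats::runif(n_options, a$range[1],
                                              a$range[2]), 6)
  }
  clusters <- lapply(cluster_ids, function(cl)
    attr_ids[assignment == cl])
  names(clusters) <- cluster_ids
  clusters <- clusters[vapply(clusters, length, 1L) > 0]
  tree <- value_tree(clusters)
  model <- mavt_model(tree, attributes, value_functions = vfs,
                      weights = list(true = stats::setNames(as.numeric(weights),
                                                            attr_ids)),
                      name = sprintf("synthetic problem (seed %d)", seed))
  # true scores/WPV computed directly from the latent knots
  true_scores <- matrix(NA_real_, n_options, n_attributes,
                        dimnames = list(opt_ids, attr_ids))
  for (i in seq_len(n_attributes))
    true_scores[, i] <- stats::approx(latent[[i]]$x, latent[[i]]$v,
                                      xout = perf[[attr_ids[i]]],
                                      ties = "ordered")$y
  true_wpv <- as.numeric(true_scores %*% as.numeric(weights))
  names(true_wpv) <- opt_ids
  structure(list(model = model, performance = perf,
                 weights = weights, true_scores = true_scores,
                 true_wpv = true_wpv, latent = latent,
                 seed = seed, config = cfg),
            class = "synthetic_problem")
}

#' @export
print.synthetic_problem <- function(x, ...) {
  cat("<synthetic problem>", nrow(x$performance), "options x",
      length(x$model$attributes), "attributes (seed", x$seed, ")\n")
  invisible(x)
}

#' Generate a judgment matrix from a latent value scale
#'
#' The category for a pair is the equal-width bin index of the latent
#' value difference over `(0, max difference]`, mapped to 1..6 (0 for
#' exact ties).  With `corruption_rate = 0` the resulting matrix is
#' ordinally and cardinally consistent by construction; a positive rate
#' randomly perturbs categories by one step to exercise the
#' inconsistency paths.
#'
#' @param latent Named numeric vector of latent scores (any order).
#' @param n_categories Number of semantic difference categories
#'   (default 6).
#' @param corruption_rate Probability of perturbing each filled cell.
#' @return A [judgment_matrix()] over the latent stimuli, ordered most
#'   to least preferred.
#' @export
generate_judgments <- function(latent, n_categories = 6L,
                               corruption_rate = 0) {
  if (length(latent) < 2 || is.null(names(latent)))
    stop("latent scale needs >= 2 named stimuli", call. = FALSE)
  latent <- sort(latent, decreasing = TRUE)
  n <- length(latent)
  maxdiff <- latent[[1]] - latent[[n]]
  if (maxdiff <= 0 && stats::var(latent) > 0)
    stop("latent scale must have distinct scores or all-equal", call. = FALSE)
  codes <- matrix(NA_integer_, n, n,
                  dimnames = list(names(latent), names(latent)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- latent[[i]] - latent[[j]]
      k <- if (d <= 0) 0L else as.integer(ceiling(d / maxdiff * n_categories))
      k <- min(k, n_categories)
      if (k >= 1L && corruption_rate > 0 &&
          stats::runif(1) < corruption_rate)
        k <- max(1L, min(n_categories, k + sample(c(-1L, 1L), 1)))
      codes[i, j] <- k
    }
  }
  judgment_matrix(codes)
}

#' Write a synthetic problem as a standard input bundle
#'
#' Emits the model JSON and performance CSV that [run_pipeline()]
#' accepts.
#'
#' @param problem A [generate_problem()] result.
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
write_problem <- function(problem, dir) {
  stopifnot(inherits(problem, "synthetic_problem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(model = file.path(dir, "model.json"),
                performance = file.path(dir, "performance.csv"))
  write_model(problem$model, paths$model)
  utils::write.csv(problem$performance, paths$performance, row.names = FALSE)
  invisible(paths)
}
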