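test_that("generated problems have the requested shape and are reproducible", {
  p <- generate_problem(3, 9, seed = 1)
  expect_identical(dim(p$true_scores), c(3L, 9L))
  expect_length(p$model$attributes, 9)
  p2 <- generate_problem(3, 9, seed = 1)
  expect_identical(p$performance, p2$performance)
  expect_equal(p$true_wpv, p2$true_wpv, tolerance = 0)
  p3 <- generate_problem(3, 9, seed = 2)
  expect_false(identical(p$performance, p3$performance))
  expect_error(generate_problem(1, 4), "n_options >= 2")
})

test_that("generated problems always validate", {
  for (i in 1:60) {
    p <- generate_problem(sample(2:6, 1), sample(1:9, 1), seed = 1000 + i)
    expect_true(validate_model(p$model)$valid)
    expect_true(validate_performance(p$performance, p$model)$valid)
  }
})

test_that("judgment binning follows the latent differences", {
  m <- generate_judgments(c(a = 100, b = 50, c = 0))
  codes <- unclass(m)
  expect_identical(codes["a", "b"], codes["b", "c"])
  expect_identical(codes["a", "c"], 6L)
  m2 <- generate_judgments(c(a = 10, b = 9.3))
  expect_true(unclass(m2)["a", "b"] %in% 1:6)
})

test_that("uncorrupted judgments are consistent; corruption can break them", {
  set.seed(404)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    latent <- stats::setNames(c(0, sort(stats::runif(n - 1, 0, 100))),
                              paste0("s", seq_len(n)))
    expect_true(check_consistency(generate_judgments(latent))$consistent)
  }
  # heavy corruption eventually produces an ordinal violation
  set.seed(405)
  broke <- FALSE
  for (i in 1:50) {
    latent <- stats::setNames(c(0, sort(stats::runif(4, 0, 100))), letters[1:5])
    if (!check_consistency(generate_judgments(latent,
                                              corruption_rate = 0.8))$consistent)
      broke <- TRUE
  }
  expect_true(broke)
})

test_that("scale derivation recovers the latent ordering and rough cardinality", {
  set.seed(406)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    latent <- stats::setNames(c(0, sort(stats::runif(n - 1, 0, 100))),
                              paste0("s", seq_len(n)))
    s <- derive_scale(generate_judgments(latent))
    lat <- sort(latent, decreasing = TRUE)
    expect_identical(rank(-as.numeric(s)), rank(-as.numeric(lat)))
    nm <- names(s)
    anchored <- anchor_scale(s, nm[n], nm[1])
    lat_anchored <- 100 * (lat - min(lat)) / (max(lat) - min(lat))
    # categories carry the latent differences only at bin resolution, and
    # the minimizing objective returns the tightest compatible scale, so
    # agreement is bounded by ~1.5 bin widths (see the methods vignette)
    expect_lt(max(abs(as.numeric(anchored) - as.numeric(lat_anchored))),
              1.5 * 100 / 6)
  }
})

test_that("the pipeline reproduces a problem's own truth exactly", {
  for (seed in c(31, 32, 33)) {
    p <- generate_problem(4, 6, seed = seed)
    sm <- score_table(p$performance, p$model$value_functions)
    expect_equal(sm, p$true_scores, tolerance = 1e-9)
    ev <- overall_value(sm, p$weights)
    expect_equal(ev$values[names(p$true_wpv)], p$true_wpv, tolerance = 1e-9)
  }
})

test_that("problems serialize to a bundle the pipeline accepts", {
  p <- generate_problem(3, 4, seed = 9)
  d <- tempfile()
  paths <- write_problem(p, d)
  res <- run_pipeline(paths$model, paths$performance, out_dir = NULL,
                      verbose = FALSE)
  expect_equal(res$evaluation$values[names(p$true_wpv)], p$true_wpv,
               tolerance = 1e-9)
})
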