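test_that("published partial scores fall out of the packaged anchors", {
  cs <- mcrc_case_study()
  vfs <- cs$model$value_functions
  # overall survival: linear between the references
  expect_equal(score_option(vfs$os, 13.5), 83.9, tolerance = 1e-9)
  expect_equal(score_option(vfs$os, 6.2), 0, tolerance = 1e-12)
  # Grade 4 adverse events: interpolation on the (0,100)-(10,0) segment
  expect_equal(score_option(vfs$g4ae, 5), 50, tolerance = 1e-9)
  expect_equal(score_option(vfs$g4ae, 7), 30, tolerance = 1e-9)
  # beyond the lower reference the elicited score is strongly negative
  expect_equal(score_option(vfs$g4ae, 21), -117.9, tolerance = 1e-9)
  # reference anchoring identity on every attribute
  for (a in names(vfs)) {
    at <- cs$model$attributes[[a]]
    expect_equal(score_option(vfs[[a]], at$lower_ref), 0, tolerance = 1e-9)
    expect_equal(score_option(vfs[[a]], at$higher_ref), 100,
                 tolerance = 1e-9)
  }
})

test_that("interpolation matches a brute-force oracle", {
  cs <- mcrc_case_study()
  pfs <- cs$model$value_functions$pfs
  expect_equal(score_option(pfs, 4.25), 53.5, tolerance = 1e-9)
  xs <- pfs$anchors$x; vs <- pfs$anchors$v
  for (x in seq(1.9, 7.6, by = 0.37))
    expect_equal(score_option(pfs, x), interp_oracle(xs, vs, x),
                 tolerance = 1e-9)
})

test_that("value functions reject bad anchor sets and extrapolation", {
  a <- mavt_attribute("x", cluster = "c", range = c(0, 10),
                      lower_ref = 2, higher_ref = 8)
  expect_error(value_function(a, data.frame(x = c(0, 2, 8, 10),
                                            v = c(-10, 0, 100, 90))),
               "non-monotone")
  expect_error(value_function(a, data.frame(x = c(0, 10), v = c(0, 100))),
               "reference anchors missing")
  expect_error(value_function(a, data.frame(x = c(2, 8), v = c(0, 100))),
               "cover the full attribute range")
  vf <- value_function(a, data.frame(x = c(0, 2, 8, 10),
                                     v = c(-10, 0, 100, 110)))
  expect_error(score_option(vf, 10.5), "extrapolation required")
  expect_error(score_option(vf, -0.1), "extrapolation required")
})

test_that("ordinal attributes score by direct level lookup", {
  cs <- mcrc_case_study()
  pos <- cs$model$value_functions$posology
  expect_equal(score_option(pos, "1 hour, every week"), 37.5)
  expect_error(score_option(pos, "twice daily"), "extrapolation required")
})

test_that("score_table reproduces the published 27-cell matrix", {
  cs <- mcrc_case_study()
  sm <- score_table(cs$performance, cs$model$value_functions)
  exp <- cs$expected$partial_scores
  expect_equal(sm[rownames(exp), colnames(exp)], exp, tolerance = 1e-9)
  expect_equal(unname(sm[, "hrqol"]), rep(15, 3), tolerance = 1e-9)
})

test_that("scores at the lower references are all zero", {
  cs <- mcrc_case_study()
  at <- cs$model$attributes
  perf0 <- data.frame(option = "ref")
  for (a in names(at)) perf0[[a]] <- at[[a]]$lower_ref
  sm <- score_table(perf0, cs$model$value_functions)
  expect_equal(unname(sm["ref", ]), rep(0, 9), tolerance = 1e-9)
})

test_that("scoring is order-preserving and unit-rescaling invariant", {
  set.seed(11)
  prob <- generate_problem(6, 5, seed = 11)
  vfs <- prob$model$value_functions
  for (a in names(vfs)) {
    at <- prob$model$attributes[[a]]
    xs <- sort(stats::runif(10, at$range[1], at$range[2]))
    sc <- vapply(xs, function(x) score_option(vfs[[a]], x), numeric(1))
    if (at$direction == "increasing") expect_true(all(diff(sc) >= -1e-9))
    else expect_true(all(diff(sc) <= 1e-9))

    # months -> weeks style rescaling of units and anchors together
    k <- 4.348
    at2 <- mavt_attribute(at$id, cluster = at$cluster,
                          direction = at$direction, range = k * at$range,
                          lower_ref = k * at$lower_ref,
                          higher_ref = k * at$higher_ref)
    vf2 <- value_function(at2, data.frame(x = k * vfs[[a]]$anchors$x,
                                          v = vfs[[a]]$anchors$v))
    for (x in xs)
      expect_equal(score_option(vf2, k * x), score_option(vfs[[a]], x),
                   tolerance = 1e-9)
  }
})
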