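test_that("consistency check separates ordinal violations from feasibility", {
  ok <- jm(c("a", "b", "c"), list("a", "b", "weak"), list("b", "c", "strong"),
           list("a", "c", "very strong"))
  rep <- check_consistency(ok)
  expect_true(rep$consistent)
  expect_true(rep$ordinal_ok)
  expect_true(rep$cardinal_ok)

  # the longer span judged smaller than a nested pair
  bad <- jm(c("a", "b", "c"), list("a", "b", "strong"),
            list("b", "c", "strong"), list("a", "c", "weak"))
  rep2 <- check_consistency(bad)
  expect_false(rep2$consistent)
  expect_false(rep2$ordinal_ok)
  expect_true(all(rep2$violations$a == "a" & rep2$violations$b == "c"))

  tie <- jm(c("a", "b"), list("a", "b", "no"))
  rep3 <- check_consistency(tie)
  expect_true(rep3$consistent)
  expect_equal(as.numeric(derive_scale(tie)), c(0, 0), tolerance = 1e-6)
})

test_that("derived scales solve the minimizing linear program", {
  two <- jm(c("a", "b"), list("a", "b", "moderate"))
  expect_equal(as.numeric(derive_scale(two)), c(3, 0), tolerance = 1e-6)

  three <- jm(c("a", "b", "c"), list("a", "b", "weak"),
              list("b", "c", "strong"), list("a", "c", "very strong"))
  s <- derive_scale(three)
  expect_equal(as.numeric(s), c(6, 4, 0), tolerance = 1e-6)
  expect_identical(names(s), c("a", "b", "c"))

  all_no <- jm(c("a", "b", "c"), list("a", "b", "no"), list("b", "c", "no"),
               list("a", "c", "no"))
  expect_equal(as.numeric(derive_scale(all_no)), c(0, 0, 0),
               tolerance = 1e-6)
})

test_that("incompatible judgments raise a typed error with the constraint set", {
  bad <- jm(c("a", "b", "c"), list("a", "b", "strong"),
            list("b", "c", "strong"), list("a", "c", "weak"))
  err <- tryCatch(derive_scale(bad), error = function(e) e)
  expect_s3_class(err, "macbeth_incompatible")
  expect_true(length(err$constraints) == 3)
})

test_that("feasible bounds bracket the derived score", {
  two <- jm(c("a", "b"), list("a", "b", "moderate"))
  fb <- feasible_bounds(two, "a")
  expect_equal(fb$lower, 3, tolerance = 1e-6)
  expect_true(fb$capped)
  expect_identical(fb$upper, Inf)

  # bottom stimulus is pinned at zero
  fb0 <- feasible_bounds(two, "b")
  expect_equal(fb0$lower, 0, tolerance = 1e-6)
  expect_equal(fb0$upper, 0, tolerance = 1e-6)

  three <- jm(c("a", "b", "c"), list("a", "b", "weak"),
              list("b", "c", "strong"), list("a", "c", "very strong"))
  fb_mid <- feasible_bounds(three, "b")
  expect_true(fb_mid$lower <= 4 + 1e-6 && fb_mid$upper >= 4 - 1e-6)
})

test_that("anchoring maps references to 0/100 and is affine-invariant", {
  s <- structure(c(a = 6, b = 4, c = 0), class = "macbeth_scale")
  a <- anchor_scale(s, "c", "a")
  expect_equal(as.numeric(a), c(100, 200 / 3, 0), tolerance = 1e-9)

  s4 <- structure(c(p = 6, q = 5, r = 2, t = 0), class = "macbeth_scale")
  a4 <- anchor_scale(s4, "r", "p")
  expect_equal(as.numeric(a4), c(100, 75, 0, -50), tolerance = 1e-9)

  # anchoring removes any positive affine transform of the input
  s_aff <- structure(3.7 * c(p = 6, q = 5, r = 2, t = 0) + 11,
                     class = "macbeth_scale")
  expect_equal(as.numeric(anchor_scale(s_aff, "r", "p")), as.numeric(a4),
               tolerance = 1e-9)

  expect_error(anchor_scale(s, "a", "c"), "not increasing in preference")
})

test_that("derived scales satisfy every LP constraint by substitution", {
  set.seed(301)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    latent <- stats::setNames(c(0, sort(stats::runif(n - 1, 0, 100))),
                              paste0("s", seq_len(n)))
    m <- generate_judgments(latent)
    s <- derive_scale(m)
    expect_lt(mavtkit:::macbeth_constraint_violation(m, s), 1e-5)
  }
})

test_that("judgment matrices survive a CSV round trip", {
  m <- jm(c("a", "b", "c"), list("a", "b", "weak"), list("b", "c", "strong"),
          list("a", "c", "very strong"))
  p <- tempfile(fileext = ".csv")
  write_judgments(m, p)
  m2 <- read_judgments(p)
  expect_identical(unclass(m), unclass(m2))
})
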