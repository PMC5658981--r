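cs <- mcrc_case_study()
res <- run_pipeline(cs$model, cs$performance, cs$costs, out_dir = NULL,
                    verbose = FALSE)

test_that("published one-way thresholds are reproduced within 0.7 points", {
  exp <- cs$expected$thresholds
  pairs <- list(
    panitumumab_vs_cetuximab = c("panitumumab", "cetuximab"),
    aflibercept_vs_cetuximab = c("aflibercept_folfiri", "cetuximab"),
    aflibercept_vs_panitumumab = c("aflibercept_folfiri", "panitumumab"))
  for (pn in names(exp)) {
    ids <- pairs[[pn]]
    rep <- one_way_report(res$scores, res$weights,
                          pairs = data.frame(a = ids[1], b = ids[2]))
    found <- rep[!is.na(rep$w_star), ]
    # attribute membership of the reversal set matches the published one
    expect_setequal(found$attribute, names(exp[[pn]]))
    for (a in names(exp[[pn]])) {
      row <- found[found$attribute == a, ]
      expect_equal(100 * row$w_star, exp[[pn]][[a]], tolerance = 0.7)
      expect_identical(row$direction,
                       if (exp[[pn]][[a]] > 100 * row$w0) "increase"
                       else "decrease")
    }
  }
})

test_that("attributes scoring equally for both options yield no reversal", {
  th <- weight_threshold("hrqol", "panitumumab", "cetuximab",
                         res$scores, res$weights)
  expect_true(is.na(th$w_star))
})

test_that("a threshold equalizes the two overall values by substitution", {
  rep <- one_way_report(res$scores, res$weights)
  found <- rep[!is.na(rep$w_star), ]
  for (i in seq_len(nrow(found))) {
    r <- found[i, ]
    va <- value_at_weight(r$option_a, r$attribute, r$w_star, res$scores,
                          res$weights)
    vb <- value_at_weight(r$option_b, r$attribute, r$w_star, res$scores,
                          res$weights)
    expect_lt(abs(va - vb), 1e-6)
  }
})

test_that("closed-form thresholds match the bisection oracle", {
  set.seed(55)
  for (i in 1:30) {
    prob <- generate_problem(3, 5, seed = 500 + i)
    w <- prob$weights
    for (attr in colnames(prob$true_scores)[c(1, 3)]) {
      th <- weight_threshold(attr, "opt01", "opt02", prob$true_scores, w)
      wb <- threshold_bisect(attr, "opt01", "opt02", prob$true_scores, w)
      if (is.na(th$w_star)) {
        # oracle must find no interior crossing either (boundary crossings
        # at exactly 0 or 1 are reported by the closed form)
        expect_true(is.na(wb) || wb < 1e-6 || wb > 1 - 1e-6)
      } else {
        expect_equal(th$w_star, wb, tolerance = 1e-6)
      }
    }
  }
})

test_that("thresholds ignore uniform pre-normalization rescaling", {
  th1 <- weight_threshold("posology", "panitumumab", "cetuximab",
                          res$scores, res$weights)
  w_scaled <- normalize_weights(7.3 * cs$model$weights$precise)
  th2 <- weight_threshold("posology", "panitumumab", "cetuximab",
                          res$scores, w_scaled)
  expect_equal(th1$w_star, th2$w_star, tolerance = 1e-9)
})

test_that("the ranking survives any single 50% weight change", {
  expect_gt(res$robustness_margin, 0.5)
  # the two most sensitive attributes and their published relative changes
  rep <- one_way_report(res$scores, res$weights,
                        pairs = data.frame(a = "panitumumab",
                                           b = "cetuximab"))
  pos <- rep[rep$attribute == "posology", ]
  med <- rep[rep$attribute == "medical_costs", ]
  expect_equal(pos$rel_change, 0.69, tolerance = 0.02)
  expect_equal(med$rel_change, 0.81, tolerance = 0.02)
  expect_identical(pos$direction, "increase")
  expect_identical(med$direction, "increase")
})

test_that("tied options give a zero robustness margin", {
  scores <- rbind(o1 = c(60, 40), o2 = c(40, 60))
  colnames(scores) <- c("x", "y")
  w <- normalize_weights(c(x = 1, y = 1))
  rep <- one_way_report(scores, w)
  expect_equal(robustness_margin(rep), 0, tolerance = 1e-9)
})

test_that("score perturbation stability follows the worst-case margin", {
  pert <- reference_perturbation_check(res$scores, res$weights, 5)
  expect_true(pert$stable)
  expect_true(reference_perturbation_check(res$scores, res$weights,
                                           0)$stable)
  # constructed boundary case: adjacent gap smaller than 2 * delta * w_i
  scores <- rbind(hi = c(52, 50), lo = c(48, 50))
  colnames(scores) <- c("x", "y")
  w <- normalize_weights(c(x = 1, y = 1))
  pert2 <- reference_perturbation_check(scores, w, 5)   # gap 2 < 2*5*0.5
  expect_false(pert2$stable)
  expect_true("x" %in% pert2$flagged$attribute)

  # exhaustive sign enumeration oracle agrees on the fixture at delta = 5
  delta <- 5
  wv <- res$weights
  r <- overall_value(res$scores, wv)$ranking
  swap_found <- FALSE
  for (attr in colnames(res$scores)) {
    for (signs in asplit(as.matrix(expand.grid(rep(list(c(-1, 1)),
                                                   nrow(res$scores)))), 1)) {
      s2 <- res$scores
      s2[, attr] <- s2[, attr] + delta * as.numeric(signs)
      r2 <- overall_value(s2, wv)$ranking
      if (!identical(r2$option, r$option)) swap_found <- TRUE
    }
  }
  expect_false(swap_found)
})
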