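test_that("the packaged appraisal model passes structural validation", {
  cs <- mcrc_case_study()
  expect_length(cs$model$attributes, 9)
  expect_length(cs$model$tree$clusters, 4)
  rep <- validate_model(cs$model)
  expect_true(rep$valid)
  expect_identical(nrow(rep$violations), 0L)
  # idempotent and side-effect free
  rep2 <- validate_model(cs$model)
  expect_identical(rep$violations, rep2$violations)
})

test_that("structural violations are itemized, not thrown", {
  attrs <- list(
    mavt_attribute("a1", cluster = "c1", range = c(0, 1),
                   lower_ref = 0, higher_ref = 1),
    mavt_attribute("a2", cluster = "c1", range = c(0, 1),
                   lower_ref = 0.2, higher_ref = 0.8))
  # attribute assigned to two clusters
  tree <- value_tree(list(c1 = c("a1", "a2"), c2 = "a1"))
  rep <- validate_model(tree, attrs)
  expect_false(rep$valid)
  expect_true("duplicate leaf" %in% rep$violations$code)

  # degenerate reference interval
  bad <- mavt_attribute("a3", cluster = "c1", range = c(0, 1),
                        lower_ref = 0.5, higher_ref = 0.5)
  rep2 <- validate_model(value_tree(list(c1 = "a3")), list(bad))
  expect_false(rep2$valid)
  expect_true("degenerate reference interval" %in% rep2$violations$code)

  # reference moving against the declared direction
  bad_dir <- mavt_attribute("a4", cluster = "c1", direction = "decreasing",
                            range = c(0, 10), lower_ref = 2, higher_ref = 8)
  rep3 <- validate_model(value_tree(list(c1 = "a4")), list(bad_dir))
  expect_true("references against direction" %in% rep3$violations$code)

  # binary attribute with three levels
  bad_bin <- mavt_attribute("a5", cluster = "c1", scale = "binary",
                            levels = c("lo", "mid", "hi"),
                            lower_ref = "lo", higher_ref = "hi")
  rep4 <- validate_model(value_tree(list(c1 = "a5")), list(bad_bin))
  expect_true("binary levels" %in% rep4$violations$code)
})

test_that("performance validation flags incompleteness and range breaches", {
  cs <- mcrc_case_study()
  expect_true(validate_performance(cs$performance, cs$model)$valid)

  p1 <- cs$performance
  p1$posology[p1$option == "panitumumab"] <- NA
  rep <- validate_performance(p1, cs$model)
  expect_false(rep$valid)
  expect_true("incomplete" %in% rep$violations$code)

  p2 <- cs$performance
  p2$os[1] <- -1
  rep2 <- validate_performance(p2, cs$model)
  expect_false(rep2$valid)
  expect_true("out of range" %in% rep2$violations$code)

  p3 <- cs$performance[, setdiff(names(cs$performance), "pfs")]
  expect_true("incomplete" %in%
                validate_performance(p3, cs$model)$violations$code)
})

test_that("model serialization round-trips byte-identically", {
  src <- system.file("extdata", "mcrc_model.json", package = "mavtkit")
  m <- read_model(src)
  out1 <- tempfile(fileext = ".json")
  out2 <- tempfile(fileext = ".json")
  write_model(m, out1)
  write_model(read_model(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_identical(readLines(src), readLines(out1))
})

test_that("malformed model documents raise input errors", {
  p <- tempfile(fileext = ".json")
  writeLines('{"schema": "other/9"}', p)
  expect_error(read_model(p), class = "mavt_input_error")
  expect_error(read_model(tempfile()), class = "mavt_input_error")
})
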