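# Published surfaces and polynomial evaluation.

test_that("built-in models carry the published coefficients", {
  h <- builtin_surface("human", "as_printed")
  expect_equal(nrow(h$terms), 7)
  expect_equal(h$terms$coef[h$terms$ph_pow == 0 & h$terms$temp_pow == 0],
               -0.17363)
  p <- builtin_surface("porcine", "as_printed")
  expect_equal(nrow(p$terms), 9)
  expect_equal(p$terms$coef[p$terms$ph_pow == 3 & p$terms$temp_pow == 0],
               0.04129)
  # porcine "corrected" is an identity amendment: same coefficients,
  # different variant tag
  pc <- builtin_surface("porcine", "corrected")
  expect_identical(pc$terms, p$terms)
  expect_identical(pc$variant, "corrected")
  # human corrected applies exactly one documented amendment
  hc <- builtin_surface("human", "corrected")
  changed <- hc$terms$coef != h$terms$coef
  expect_equal(sum(changed), 1)
  expect_equal(hc$terms$coef[hc$terms$ph_pow == 0 & hc$terms$temp_pow == 1],
               0.088912)
  expect_true(length(hc$amendments) > 0)
})

test_that("evaluation at the optimum matches hand-computed values", {
  # frozen from term-by-term hand evaluation of the printed coefficients
  p <- builtin_surface("porcine", "as_printed")
  expect_equal(evaluate_log10(p, 2, 37), 1.774584, tolerance = 1e-6)
  expect_equal(predict_activity(p, 2, 37)$activity_pct, 59.50918,
               tolerance = 1e-5)
  hc <- builtin_surface("human", "corrected")
  expect_equal(evaluate_log10(hc, 2, 37), 2.005024, tolerance = 1e-6)
  ha <- builtin_surface("human", "as_printed")
  expect_equal(evaluate_log10(ha, 2, 37), 31.61272, tolerance = 1e-5)
})

test_that("an intercept-only surface is constant", {
  s <- pepsin_surface(data.frame(ph_pow = 0, temp_pow = 0, coef = 2))
  expect_equal(evaluate_log10(s, c(1, 3, 7), c(4, 20, 60)), rep(2, 3))
  pr <- predict_activity(s, 3, 20)
  expect_equal(pr$activity_pct, 100)
  expect_false(pr$extrapolated)
  expect_equal(predict_relative(s, 5.5, 50), 100)
})

test_that("evaluate_log10 agrees with a brute-force monomial oracle", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_surface()
    ph <- runif(1, 1, 7)
    tc <- runif(1, 4, 60)
    got <- evaluate_log10(s, ph, tc)
    want <- oracle_log10(s$terms, ph, tc)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("relative prediction is exactly 100 at the reference condition", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_surface()
    expect_identical(predict_relative(s, 2, 37), 100)
  }
  expect_identical(
    predict_relative(builtin_surface("porcine", "as_printed"), 2, 37), 100)
})

test_that("porcine relative activity drops steeply with pH at 37 degC", {
  p <- builtin_surface("porcine", "as_printed")
  # frozen from hand evaluation: 100 * 10^(log10@(3,37) - log10@(2,37))
  expect_equal(predict_relative(p, 3, 37), 47.13136, tolerance = 1e-5)
})

test_that("built-in surfaces are positive and finite over the closed domain", {
  grid <- design_grid(15, 15)
  for (sp in c("human", "porcine")) {
    s <- builtin_surface(sp, "as_printed")
    v <- suppressWarnings(predict_activity(s, grid$ph, grid$temp_c)$activity_pct)
    expect_true(all(is.finite(v)))
    expect_true(all(v > 0))
  }
})

test_that("extrapolation policies behave as documented", {
  p <- builtin_surface("porcine", "as_printed")
  expect_error(predict_activity(p, 0.5, 37, policy = "forbid"),
               "below lower bound")
  expect_warning(predict_activity(p, 0.5, 37, policy = "warn"),
                 "outside the calibrated domain")
  expect_silent(res <- predict_activity(p, 0.5, 37, policy = "allow"))
  expect_true(res$extrapolated)
  expect_false(predict_activity(p, 2, 37, policy = "allow")$extrapolated)
  expect_error(predict_activity(p, 2, 70, policy = "forbid"),
               "above upper bound")
})

test_that("the as-printed human surface triggers the mis-scaling warning", {
  ha <- builtin_surface("human", "as_printed")
  expect_warning(res <- predict_activity(ha, 2, 37), "mis-scaled")
  expect_gt(res$activity_pct, 1e20)  # physically impossible magnitude
  # the corrected variant does not warn
  expect_silent(predict_activity(builtin_surface("human", "corrected"), 2, 37))
  # and self-normalization side-steps the scale defect entirely
  expect_silent(rel <- predict_relative(ha, 2, 37))
  expect_identical(rel, 100)
})

test_that("non-finite inputs and malformed terms are rejected", {
  p <- builtin_surface("porcine", "as_printed")
  expect_error(evaluate_log10(p, NaN, 37), "finite")
  expect_error(evaluate_log10(p, 2, Inf), "finite")
  expect_error(pepsin_surface(data.frame(ph_pow = 1, temp_pow = 0, coef = 1)),
               "intercept")
  expect_error(
    pepsin_surface(data.frame(ph_pow = c(0, 1, 1), temp_pow = c(0, 0, 0),
                              coef = 1:3)), "duplicated")
  expect_error(
    pepsin_surface(data.frame(ph_pow = c(0, 4), temp_pow = c(0, 0),
                              coef = 1:2)), "0..3")
})

test_that("JSON round trip reproduces predictions bit for bit", {
  path <- withr::local_tempfile(fileext = ".json")
  set.seed(11)
  for (s in list(builtin_surface("human", "corrected"), random_surface())) {
    write_surface_json(s, path)
    s2 <- read_surface_json(path)
    expect_identical(s2$terms$coef, s$terms$coef)
    ph <- runif(20, 1, 7)
    tc <- runif(20, 4, 60)
    expect_identical(evaluate_log10(s2, ph, tc), evaluate_log10(s, ph, tc))
  }
})
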