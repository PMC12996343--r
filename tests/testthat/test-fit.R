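# Response-surface fitting: design matrices, ANOVA, PRESS, outliers,
# D-optimal design, surface export.

test_that("design matrices follow the basis order and coding map", {
  one <- data.frame(ph = 2, temp_c = 37)
  X <- design_matrix(one, line_basis)
  expect_equal(unname(X[1, ]), c(1, 2))
  Xc <- design_matrix(one, line_basis,
                      coding = list(ph = c(1, 7), temp_c = c(4, 60)))
  expect_equal(unname(Xc[1, ]), c(1, -2/3))  # (2 - 4) / 3
  b <- data.frame(ph_pow = c(0, 1), temp_pow = c(0, 2))
  X2 <- design_matrix(data.frame(ph = 3, temp_c = 2), b)
  expect_equal(unname(X2[1, 2]), 12)  # 3 * 2^2
})

test_that("underdetermined designs are refused", {
  d <- data.frame(ph = c(1, 2), temp_c = c(4, 6), activity_pct = c(10, 20))
  expect_error(fit_activity_surface(d, basis = "seven_term"),
               "underdetermined")
})

test_that("toy straight-line ANOVA reproduces hand-computed statistics", {
  # slope 0.5, intercept 1/6, SS_res = 1/6, SS_model = 1/2
  fit <- fit_activity_surface(toy_line_data(), basis = line_basis,
                              transform = "identity")
  expect_equal(fit$F_value, 3.0, tolerance = 1e-12)
  expect_equal(fit$R2, 0.75, tolerance = 1e-12)
  expect_equal(fit$adjusted_R2, 0.5, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(1/6, 1/2), tolerance = 1e-12)
  expect_equal(fit$ss_residual, 1/6, tolerance = 1e-12)
})

test_that("noise-free data from a known surface is recovered exactly", {
  truth <- builtin_surface("porcine", "corrected")
  d <- simulate_activity_data(truth, design_grid(5, 5), noise_sd_log10 = 0)
  fit <- fit_activity_surface(d, basis = "nine_term")
  expect_equal(unname(coef(fit)), truth$terms$coef, tolerance = 1e-8)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
  # round trip through as_surface reproduces the generator's predictions
  s <- as_surface(fit)
  ph <- seq(1, 7, by = 0.5)
  expect_equal(evaluate_log10(s, ph, 37), evaluate_log10(truth, ph, 37),
               tolerance = 1e-8)
})

test_that("a perfectly linear dataset gives PRESS 0 and predicted R2 1", {
  d <- data.frame(ph = c(0, 1, 2), temp_c = 0, activity_pct = c(0, 1, 2))
  fit <- fit_activity_surface(d, basis = line_basis, transform = "identity")
  expect_equal(fit$PRESS, 0, tolerance = 1e-20)
  expect_equal(fit$predicted_R2, 1, tolerance = 1e-12)
})

test_that("hat-matrix predicted R2 equals explicit leave-one-out refits", {
  truth <- builtin_surface("porcine", "corrected")
  for (seed in c(3, 14, 159)) {
    d <- simulate_activity_data(truth, design_grid(4, 3),
                                noise_sd_log10 = 0.08, seed = seed)
    fit <- fit_activity_surface(d, basis = "seven_term")
    loo <- predicted_r2_loo(d, basis = "seven_term")
    expect_equal(fit$predicted_R2, loo, tolerance = 1e-10)
  }
})

test_that("fit statistics are invariant under actual<->coded factors", {
  truth <- builtin_surface("human", "corrected")
  d <- simulate_activity_data(truth, design_grid(5, 4),
                              noise_sd_log10 = 0.05, seed = 21)
  coding <- list(ph = c(1, 7), temp_c = c(4, 60))
  for (basis in c("seven_term", "nine_term")) {
    fa <- fit_activity_surface(d, basis = basis)
    fc <- fit_activity_surface(d, basis = basis, coding = coding)
    expect_equal(fa$F_value, fc$F_value, tolerance = 1e-9)
    expect_equal(fa$R2, fc$R2, tolerance = 1e-9)
    expect_equal(fa$adjusted_R2, fc$adjusted_R2, tolerance = 1e-9)
    expect_equal(fa$predicted_R2, fc$predicted_R2, tolerance = 1e-9)
    # decoded coded-fit coefficients equal the actual-unit coefficients
    sa <- as_surface(fa)
    sc <- as_surface(fc)
    pts <- design_grid(6, 6)
    expect_equal(evaluate_log10(sc, pts$ph, pts$temp_c),
                 evaluate_log10(sa, pts$ph, pts$temp_c), tolerance = 1e-8)
  }
})

test_that("PRESS strictly exceeds the residual SS on real fits", {
  truth <- builtin_surface("porcine", "corrected")
  d <- simulate_activity_data(truth, design_grid(5, 5),
                              noise_sd_log10 = 0.05, seed = 5)
  fit <- fit_activity_surface(d, basis = "seven_term")
  expect_gt(fit$PRESS, fit$ss_residual)
  expect_lte(fit$predicted_R2, fit$R2)
  expect_lte(fit$adjusted_R2, fit$R2)
})

test_that("rank-deficient designs name the collinear columns", {
  b <- data.frame(ph_pow = c(0, 1, 1), temp_pow = c(0, 0, 1))
  d <- data.frame(ph = c(1, 2, 3, 4, 5), temp_c = 1,  # pH == pH*T when T = 1
                  activity_pct = c(1, 2, 3, 4, 5))
  expect_error(fit_activity_surface(d, basis = b, transform = "identity"),
               "collinear")
})

test_that("a degenerate constant response yields R2 = 0 and NaN F", {
  d <- data.frame(ph = 1:5, temp_c = c(4, 10, 20, 40, 60),
                  activity_pct = rep(50, 5))
  expect_warning(fit <- fit_activity_surface(d, basis = line_basis),
                 "degenerate")
  expect_equal(fit$R2, 0)
  expect_true(is.nan(fit$F_value))
})

test_that("studentized-residual flagging finds a planted outlier", {
  truth <- builtin_surface("porcine", "corrected")
  d <- simulate_activity_data(truth, design_grid(5, 5),
                              noise_sd_log10 = 0.05, seed = 8)
  clean_fit <- fit_activity_surface(d, basis = "seven_term")
  expect_identical(flag_outliers(clean_fit, threshold = 3), integer(0))
  # displace one observation by ~10 residual SDs on the log scale
  bump <- d
  bump$activity_pct[12] <- bump$activity_pct[12] * 10^(10 * clean_fit$sigma)
  fit <- fit_activity_surface(bump, basis = "seven_term")
  expect_identical(flag_outliers(fit, threshold = 3), 12L)
  # brute-force confirmation: that run has the largest |studentized residual|
  rs <- residuals(fit, type = "studentized")
  expect_equal(as.integer(names(which.max(abs(rs)))), 12L)
})

test_that("explicit flagging returns the declared exclusions unchanged", {
  truth <- builtin_surface("porcine", "corrected")
  d <- simulate_activity_data(truth, design_grid(6, 6),
                              noise_sd_log10 = 0.05, seed = 9)
  d2 <- activity_dataset(d$ph, d$temp_c, d$activity_pct,
                         exclude = c(6L, 26L, 27L))
  fit <- fit_activity_surface(d2, basis = "seven_term")
  expect_identical(flag_outliers(fit, method = "explicit"), c(6L, 26L, 27L))
  expect_equal(fit$n_used, nrow(d2) - 3)
})

test_that("removing a flagged outlier never decreases R2", {
  truth <- builtin_surface("porcine", "corrected")
  d <- simulate_activity_data(truth, design_grid(5, 5),
                              noise_sd_log10 = 0.08, seed = 13)
  bump <- d
  bump$activity_pct[7] <- bump$activity_pct[7] * 10^1.5
  fit <- fit_activity_surface(bump, basis = "seven_term")
  flagged <- flag_outliers(fit, threshold = 3)
  expect_true(7L %in% flagged)
  refit <- fit_activity_surface(bump, basis = "seven_term", exclude = flagged)
  expect_gte(refit$R2, fit$R2)
})

test_that("D-optimal selection on one factor picks the extremes", {
  cand <- data.frame(ph = 1:10, temp_c = 0)
  sel <- doptimal_design(cand, basis = line_basis, n_points = 2, seed = 1)
  expect_setequal(sel$points$ph, c(1, 10))
  # brute force over all 45 pairs confirms the maximum
  best <- -Inf
  for (i in 1:9) for (j in (i + 1):10) {
    X <- cbind(1, c(i, j))
    best <- max(best, det(crossprod(X)))
  }
  expect_equal(exp(sel$log_det), best, tolerance = 1e-9)
})

test_that("D-optimal selection is deterministic and beats random subsets", {
  cand <- design_grid(6, 6)
  s1 <- doptimal_design(cand, basis = "seven_term", n_points = 10, seed = 4)
  s2 <- doptimal_design(cand, basis = "seven_term", n_points = 10, seed = 4)
  expect_identical(s1$index, s2$index)
  X <- design_matrix(cand, "seven_term")
  set.seed(99)
  for (i in 1:50) {
    idx <- sample.int(nrow(cand), 10)
    d <- determinant(crossprod(X[idx, ]), logarithm = TRUE)
    ld <- if (d$sign <= 0) -Inf else as.numeric(d$modulus)
    expect_gte(s1$log_det, ld - 1e-9)
  }
})

test_that("n_points equal to a known nonsingular candidate set returns it", {
  cand <- data.frame(ph = c(1, 4), temp_c = c(10, 50))
  sel <- doptimal_design(cand, basis = line_basis, n_points = 2, seed = 7)
  expect_identical(sort(sel$index), c(1L, 2L))
  expect_error(doptimal_design(cand, basis = line_basis, n_points = 1),
               ">=")
  expect_error(doptimal_design(cand, basis = line_basis, n_points = 3),
               "fewer candidates")
})

test_that("an intercept-only fit of a constant response predicts it everywhere", {
  b <- data.frame(ph_pow = 0, temp_pow = 0)
  d <- data.frame(ph = 1:4, temp_c = c(4, 20, 40, 60),
                  activity_pct = rep(100, 4))
  fit <- suppressWarnings(fit_activity_surface(d, basis = b))
  s <- as_surface(fit)
  expect_equal(predict(s, ph = c(1.5, 6), temp_c = c(10, 55),
                       policy = "allow"),
               c(100, 100), tolerance = 1e-10)
})

test_that("the label-swap resolver matches datasets by outlier fingerprints", {
  # synthetic stand-ins: the dataset carrying the published 3-outlier
  # fingerprint (20.62, 7.63, 11.28%) must be routed to the 7-term
  # model, the one carrying 14.3% to the 9-term model
  set.seed(31)
  base_p <- simulate_activity_data(builtin_surface("porcine", "corrected"),
                                   design_grid(6, 6), 0.05, seed = 101)
  base_h <- simulate_activity_data(builtin_surface("human", "corrected"),
                                   design_grid(6, 6), 0.05, seed = 102)
  base_p$activity_pct[c(6, 26, 27)] <- c(20.62, 7.63, 11.28)
  base_h$activity_pct[23] <- 14.3
  rep <- reproduce_published_fits(human_data = base_h, porcine_data = base_p)
  expect_identical(rep$assignment$seven_term$species, "porcine")
  expect_identical(sort(rep$assignment$seven_term$outlier_ids), c(6L, 26L, 27L))
  expect_identical(rep$assignment$nine_term$species, "human")
  expect_identical(rep$assignment$nine_term$outlier_ids, 23L)
  expect_identical(rep$fits$seven_term$declared_excluded, c(6L, 26L, 27L))
  expect_equal(nrow(rep$table), 6)
  # swapped arguments resolve to the same assignment by content
  rep2 <- reproduce_published_fits(human_data = base_p, porcine_data = base_h)
  expect_identical(rep2$assignment$seven_term$species, "human")
  expect_error(reproduce_published_fits(base_h, base_h), "no dataset")
})

test_that("fit methods expose the modelling interface", {
  truth <- builtin_surface("porcine", "corrected")
  d <- simulate_activity_data(truth, design_grid(5, 5),
                              noise_sd_log10 = 0.05, seed = 77)
  fit <- fit_activity_surface(d, basis = "nine_term")
  expect_s3_class(summary(fit), "summary.pepsin_fit")
  expect_output(print(fit), "adjusted R2")
  nd <- data.frame(ph = c(2, 3), temp_c = c(37, 37))
  act <- predict(fit, newdata = nd, type = "activity")
  expect_equal(act, 10^predict(fit, newdata = nd, type = "response"))
  expect_length(residuals(fit), fit$n_used)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "activity_dataset")
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims[[1]]$activity_pct, sims2[[1]]$activity_pct)
})
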