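# Shared fixtures, all built in code.

# Brute-force monomial-sum oracle for surface evaluation, written
# deliberately as a scalar loop, independent of the vectorized path.
oracle_log10 <- function(terms, ph, temp_c) {
  total <- 0
  for (i in seq_len(nrow(terms))) {
    total <- total + terms$coef[i] * ph^terms$ph_pow[i] *
      temp_c^terms$temp_pow[i]
  }
  total
}

# Toy straight-line ANOVA dataset: response 0, 1, 1 at x = 0, 1, 2.
toy_line_data <- function() {
  data.frame(ph = c(0, 1, 2), temp_c = c(0, 0, 0),
             activity_pct = c(0, 1, 1))
}

line_basis <- data.frame(ph_pow = c(0, 1), temp_pow = c(0, 0))

# A random but valid surface on the standard domain: bounded random
# coefficients on the seven-term basis.
random_surface <- function() {
  b <- term_basis("seven_term")
  b$coef <- stats::runif(nrow(b), -0.05, 0.05)
  b$coef[1] <- stats::runif(1, 0, 2)  # intercept
  pepsin_surface(b)
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.8g - %.8g| <= %g", actual, expected, tol))
}
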