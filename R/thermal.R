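#' Thermal inactivation reference table
#'
#' Residual porcine pepsin activity (percent of optimum, measured back
#' at pH 2 / 37 degC) after heat treatment. Built-in values: at 65 degC
#' residual activity is 95.35, 72.37 and 45.21% after 5, 10 and 15 min;
#' at 75, 85 and 95 degC activity is 0 at all tested durations
#' (irreversible inactivation). Custom tables may be supplied as a
#' data.frame with the same columns; residual activity must be
#' non-increasing in duration at each temperature.
#'
#' @param records optional data.frame with columns `temp_c`,
#'   `duration_min`, `residual_pct`.
#' @return data.frame of class `inactivation_table`.
#' @export
inactivation_table <- function(records = NULL) {
  if (is.null(records)) {
    records <- data.frame(
      temp_c = rep(c(65, 75, 85, 95), each = 3),
      duration_min = rep(c(5, 10, 15), times = 4),
      residual_pct = c(95.35, 72.37, 45.21, rep(0, 9)))
  }
  records <- as.data.frame(records)[c("temp_c", "duration_min", "residual_pct")]
  if (any(records$residual_pct < 0) || any(records$duration_min < 0)) {
    stop("residual activity and duration must be >= 0", call. = FALSE)
  }
  records <- records[order(records$temp_c, records$duration_min), ]
  for (tc in unique(records$temp_c)) {
    r <- records$residual_pct[records$temp_c == tc]
    if (any(diff(r) > 0)) {
      stop("residual activity must be non-increasing in duration at ",
           tc, " degC", call. = FALSE)
    }
  }
  structure(records, row.names = seq_len(nrow(records)),
            class = c("inactivation_table", "data.frame"))
}

#' Residual activity after a heat treatment
#'
#' Exact table values at tabulated (temperature, duration) points;
#' linear interpolation in duration at tabulated temperatures. Between
#' tabulated temperatures the answer from the *cooler* neighbouring
#' temperature (the higher residual) is returned and flagged: reporting
#' the conservative residual avoids false "inactivated" calls. Queries
#' outside the tabulated temperature or duration range are errors — the
#' table is never extrapolated.
#'
#' @param table an [inactivation_table()].
#' @param temp_c treatment temperature, degC.
#' @param duration_min treatment duration, minutes.
#' @return residual activity in percent of optimum, with attribute
#'   `interpolated` (TRUE where the query fell between tabulated
#'   temperatures).
#' @examples
#' tab <- inactivation_table()
#' residual_heat_activity(tab, 65, 5)   # 95.35
#' residual_heat_activity(tab, 75, 5)   # 0
#' @export
residual_heat_activity <- function(table = inactivation_table(), temp_c,
                                   duration_min) {
  stopifnot(inherits(table, "inactivation_table"))
  n <- max(length(temp_c), length(duration_min))
  temp_c <- rep_len(temp_c, n)
  duration_min <- rep_len(duration_min, n)
  temps <- sort(unique(table$temp_c))
  durs <- sort(unique(table$duration_min))
  if (any(temp_c < min(temps) | temp_c > max(temps))) {
    stop(sprintf("temperature outside tabulated range [%g, %g] degC",
                 min(temps), max(temps)), call. = FALSE)
  }
  if (any(duration_min < min(durs) | duration_min > max(durs))) {
    stop(sprintf("duration outside tabulated range [%g, %g] min",
                 min(durs), max(durs)), call. = FALSE)
  }
  at_temp <- function(tc, d) {
    sub <- table[table$temp_c == tc, ]
    stats::approx(sub$duration_min, sub$residual_pct, xout = d)$y
  }
  val <- numeric(n)
  interp <- logical(n)
  for (i in seq_len(n)) {
    if (temp_c[i] %in% temps) {
      val[i] <- at_temp(temp_c[i], duration_min[i])
    } else {
      lower <- max(temps[temps < temp_c[i]])
      val[i] <- at_temp(lower, duration_min[i])
      interp[i] <- TRUE
    }
  }
  attr(val, "interpolated") <- interp
  val
}

#' Is a heat treatment sufficient for irreversible inactivation?
#'
#' TRUE only for treatments at or beyond the minimal validated
#' condition: 75 degC for 5 min. The rule is deliberately conservative:
#' durations below 5 min return FALSE even at high temperature, because
#' shorter treatments were never validated.
#'
#' @param temp_c treatment temperature, degC.
#' @param duration_min treatment duration, minutes.
#' @return logical (vectorized).
#' @export
is_irreversibly_inactivated <- function(temp_c, duration_min) {
  temp_c >= 75 & duration_min >= 5
}

#' First-order (log-linear) inactivation rate fit
#'
#' Least-squares fit of `ln(residual activity)` against duration at one
#' temperature; the inactivation rate constant is minus the slope
#' (per minute). With `include_origin = TRUE` the point (0 min, 100%)
#' is added as an untreated anchor. The 65 degC data are visibly not
#' first order (the loss accelerates), so this is a descriptive summary
#' to be read together with its R2, not a kinetic model, and should
#' never be extrapolated beyond the tabulated durations.
#'
#' @param duration_min treatment durations, minutes.
#' @param residual_pct residual activities (percent), > 0.
#' @param include_origin add the (0, 100%) untreated anchor?
#' @return list with `k` (rate constant, per min), `r_squared`,
#'   `intercept` (ln scale), and `n`.
#' @export
fit_inactivation_rate <- function(duration_min, residual_pct,
                                  include_origin = TRUE) {
  keep <- residual_pct > 0
  if (!any(keep)) {
    stop("no positive residual activities; rate is not identifiable",
         call. = FALSE)
  }
  x <- duration_min[keep]
  y <- log(residual_pct[keep])
  if (include_origin) {
    x <- c(0, x)
    y <- c(log(100), y)
  }
  if (length(x) < 2) {
    stop("need at least 2 points (including any origin anchor)",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r2 <- if (length(x) == 2) 1 else suppressWarnings(summary(fit)$r.squared)
  list(k = -unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x))
}
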