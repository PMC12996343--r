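#' Gastric digestion condition profiles
#'
#' A `digestion_profile` is an ordered time series of gastric
#' conditions: time (minutes), pH and temperature (degC). Static
#' digestions hold all conditions constant; semi-dynamic protocols let
#' pH fall gradually towards 2 by the end of the gastric phase.
#'
#' @param t_min time points, minutes, strictly increasing, >= 2 points.
#' @param ph pH at each time point.
#' @param temp_c temperature at each time point (degC); scalar values
#'   are recycled (37 by default, the standard digestion temperature).
#' @param label free-text scenario label.
#' @return data.frame of class `digestion_profile`.
#' @export
digestion_profile <- function(t_min, ph, temp_c = 37, label = "profile") {
  n <- length(t_min)
  if (n < 2L) stop("a profile needs at least 2 time points", call. = FALSE)
  if (any(diff(t_min) <= 0)) {
    stop("t_min must be strictly increasing", call. = FALSE)
  }
  ph <- rep_len(ph, n)
  temp_c <- rep_len(temp_c, n)
  if (!all(is.finite(t_min)) || !all(is.finite(ph)) || !all(is.finite(temp_c))) {
    stop("profile fields must be finite", call. = FALSE)
  }
  if (any(t_min < 0)) stop("t_min must be >= 0", call. = FALSE)
  structure(
    data.frame(t_min = as.numeric(t_min), ph = as.numeric(ph),
               temp_c = as.numeric(temp_c)),
    label = label, class = c("digestion_profile", "data.frame"))
}

#' Read a digestion profile from CSV
#'
#' Expects columns `t_min,ph,temp_c` (header required; `temp_c`
#' defaults to 37 if absent).
#'
#' @param path CSV file path.
#' @param label scenario label.
#' @return a [digestion_profile()].
#' @export
read_profile_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  digestion_profile(d$t_min, d$ph, d$temp_c %||% 37, label = label)
}

#' Interpolate gastric conditions at arbitrary times
#'
#' Piecewise-linear interpolation of pH and temperature independently.
#' Conditions are never extrapolated: querying outside the profile's
#' time range is an error.
#'
#' @param profile a [digestion_profile()].
#' @param t times (minutes) within the profile range.
#' @return data.frame with columns `t_min`, `ph`, `temp_c`.
#' @export
interpolate_conditions <- function(profile, t) {
  stopifnot(inherits(profile, "digestion_profile"))
  rng <- range(profile$t_min)
  if (any(t < rng[1] | t > rng[2])) {
    stop(sprintf("time outside profile range [%g, %g] min", rng[1], rng[2]),
         call. = FALSE)
  }
  data.frame(
    t_min = t,
    ph = stats::approx(profile$t_min, profile$ph, xout = t)$y,
    temp_c = stats::approx(profile$t_min, profile$temp_c, xout = t)$y)
}

#' Predicted activity along a digestion profile
#'
#' Evaluates a pepsin activity surface at every time point of a
#' digestion profile and summarizes the resulting activity-time curve
#' by its trapezoidal area under the curve (AUC, in percent x minutes)
#' over the native, possibly irregular, grid. The AUC is exact for
#' piecewise-linear activity curves and matches spreadsheet-style AUC
#' computation.
#'
#' @param surface a [pepsin_surface()].
#' @param profile a [digestion_profile()].
#' @param relative use [predict_relative()] (recommended, default) or
#'   absolute [predict_activity()].
#' @param policy extrapolation policy passed to the prediction.
#' @return object of class `activity_profile`: a data.frame
#'   `t_min, ph, temp_c, activity_pct` with attributes `auc`, `label`
#'   and `surface_id`.
#' @export
activity_profile <- function(surface, profile, relative = TRUE,
                             policy = "warn") {
  stopifnot(inherits(surface, "pepsin_surface"),
            inherits(profile, "digestion_profile"))
  act <- if (relative) {
    predict_relative(surface, profile$ph, profile$temp_c, policy = policy)
  } else {
    predict_activity(surface, profile$ph, profile$temp_c,
                     policy = policy)$activity_pct
  }
  out <- data.frame(t_min = profile$t_min, ph = profile$ph,
                    temp_c = profile$temp_c, activity_pct = act)
  structure(out,
            auc = pracma::trapz(out$t_min, out$activity_pct),
            label = attr(profile, "label"),
            surface_id = sprintf("%s/%s", surface$species, surface$variant),
            class = c("activity_profile", "data.frame"))
}

#' AUC of an activity profile
#'
#' @param x an [activity_profile()].
#' @return trapezoidal area under the activity-time curve, in
#'   percent x minutes.
#' @export
profile_auc <- function(x) {
  stopifnot(inherits(x, "activity_profile"))
  attr(x, "auc")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile '%s' (%s): %d points over [%g, %g] min\n",
              attr(x, "label"), attr(x, "surface_id"), nrow(x),
              min(x$t_min), max(x$t_min)))
  cat(sprintf("  AUC = %.6g %%*min\n", attr(x, "auc")))
  invisible(x)
}

#' @export
plot.activity_profile <- function(x, ...) {
  graphics::plot(x$t_min, x$activity_pct, type = "b",
                 xlab = "Time (min)", ylab = "Activity (% of optimum)",
                 main = attr(x, "label"), ...)
  invisible(x)
}

#' Compare two activity profiles by AUC and pointwise difference
#'
#' AUCs are computed over the overlapping time window; pointwise
#' differences (a - b) are taken on the union grid of both profiles
#' within the overlap, with linear interpolation where grids differ.
#' When the second profile's AUC is zero the ratio is reported as `NA`
#' (undefined) rather than raising an error.
#'
#' @param a,b [activity_profile()]s with overlapping time ranges.
#' @return list with `auc_a`, `auc_b`, `auc_ratio`, `overlap` (window),
#'   and `difference` (data.frame `t_min, activity_a, activity_b, diff`).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "activity_profile"), inherits(b, "activity_profile"))
  lo <- max(min(a$t_min), min(b$t_min))
  hi <- min(max(a$t_min), max(b$t_min))
  if (lo >= hi) {
    stop("profiles do not overlap in time", call. = FALSE)
  }
  clip_auc <- function(x) {
    tt <- sort(unique(c(lo, hi, x$t_min[x$t_min >= lo & x$t_min <= hi])))
    yy <- stats::approx(x$t_min, x$activity_pct, xout = tt)$y
    pracma::trapz(tt, yy)
  }
  auc_a <- clip_auc(a)
  auc_b <- clip_auc(b)
  grid <- sort(unique(c(a$t_min, b$t_min)))
  grid <- grid[grid >= lo & grid <= hi]
  ya <- stats::approx(a$t_min, a$activity_pct, xout = grid)$y
  yb <- stats::approx(b$t_min, b$activity_pct, xout = grid)$y
  list(auc_a = auc_a, auc_b = auc_b,
       auc_ratio = if (auc_b == 0) NA_real_ else auc_a / auc_b,
       overlap = c(lo, hi),
       difference = data.frame(t_min = grid, activity_a = ya,
                               activity_b = yb, diff = ya - yb))
}

#' Write an activity profile to CSV
#'
#' Columns `t_min,ph,temp_c,activity_pct`.
#'
#' @param x an [activity_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "activity_profile"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
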