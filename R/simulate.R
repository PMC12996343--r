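#' Gastric simulation parameters
#'
#' Physiological parameter set for the gastric pepsin mass balance.
#' Defaults correspond to an adult consuming a 50 mL / 50 kcal liquid
#' meal: basal gastric volume 33 mL, basal pepsin concentration
#' 0.4 mg/mL, pepsin secretion 46.8 mg/h, gastric fluid secretion
#' 1 mL/min, caloric emptying 2 kcal/min taken as 2 mL/min for this
#' meal, and an optimal specific activity of 2,000 U/mg used to convert
#' pepsin mass to activity units. `output_reduction = 0.4` with
#' `reduce_basal = TRUE` gives the older-adult scenario (40% lower
#' pepsin output, applied to basal content as well, so the whole pepsin
#' trajectory scales by 0.6 exactly).
#'
#' @param basal_volume mL, fasted gastric volume.
#' @param basal_pepsin_conc mg/mL, fasted pepsin concentration.
#' @param pepsin_secretion_rate mg/h of pepsin secreted.
#' @param fluid_secretion_rate mL/min of gastric fluid secreted.
#' @param meal_volume mL, added instantaneously at t = 0 (pepsin-free).
#' @param meal_energy kcal (recorded; emptying is volumetric here).
#' @param emptying_rate mL/min of well-mixed gastric content emptied.
#' @param optimal_specific_activity U/mg at the pH 2 / 37 degC optimum.
#' @param output_reduction fraction in \[0, 1) by which pepsin secretion
#'   is reduced (0.4 for older adults).
#' @param reduce_basal also scale the basal pepsin content by
#'   `1 - output_reduction`?
#' @param dt Euler time step, minutes.
#' @param duration simulated time, minutes.
#' @return list of class `gastric_params`.
#' @export
gastric_params <- function(basal_volume = 33,
                           basal_pepsin_conc = 0.4,
                           pepsin_secretion_rate = 46.8,
                           fluid_secretion_rate = 1,
                           meal_volume = 50,
                           meal_energy = 50,
                           emptying_rate = 2,
                           optimal_specific_activity = 2000,
                           output_reduction = 0,
                           reduce_basal = TRUE,
                           dt = 1,
                           duration = 80) {
  p <- list(basal_volume = basal_volume,
            basal_pepsin_conc = basal_pepsin_conc,
            pepsin_secretion_rate = pepsin_secretion_rate,
            fluid_secretion_rate = fluid_secretion_rate,
            meal_volume = meal_volume, meal_energy = meal_energy,
            emptying_rate = emptying_rate,
            optimal_specific_activity = optimal_specific_activity,
            output_reduction = output_reduction,
            reduce_basal = isTRUE(reduce_basal),
            dt = dt, duration = duration)
  rates <- unlist(p[c("basal_volume", "basal_pepsin_conc",
                      "pepsin_secretion_rate", "fluid_secretion_rate",
                      "meal_volume", "meal_energy", "emptying_rate",
                      "optimal_specific_activity")])
  if (any(rates < 0)) stop("rates and volumes must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (output_reduction < 0 || output_reduction >= 1) {
    stop("output_reduction must be in [0, 1)", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  class(p) <- "gastric_params"
  p
}

#' Simulate total pepsin activity in the stomach over a meal
#'
#' Explicit-Euler mass balance of gastric fluid volume and pepsin mass
#' under continuous secretion and well-mixed volumetric emptying, with
#' predicted relative activity (from a pepsin activity surface) applied
#' to convert pepsin mass into total activity units:
#' \deqn{V \leftarrow \max(V + (f_{sec} - f_{emp})\,dt,\; 0)}
#' \deqn{P \leftarrow \max(P + s\,(1 - r)\,dt - f_{emp}\,(P/V)\,dt,\; 0)}
#' with the emptying term zero once the volume reaches 0 (at which
#' point the well-mixed model has left its physical validity; a warning
#' is issued). Initial volume is basal + meal; initial pepsin is the
#' basal content, scaled by `1 - output_reduction` when `reduce_basal`.
#' Total units at each step are
#' `pepsin_mass * optimal_specific_activity * relative_activity / 100`.
#'
#' @param params a [gastric_params()].
#' @param ph_curve a [digestion_profile()] (or data.frame `t_min, ph`)
#'   spanning at least `params$duration`; pH is interpolated linearly.
#' @param surface a [pepsin_surface()] used for relative activity;
#'   default is the as-printed porcine surface (self-normalized, so the
#'   printed equation's absolute-scale defect is immaterial).
#' @param temp_curve optional temperature profile (data.frame
#'   `t_min, temp_c`); default fixed 37 degC.
#' @return object of class `gastric_sim`: data.frame with columns
#'   `t_min, volume_ml, pepsin_mg, pepsin_mg_per_ml,
#'   relative_activity_pct, total_units`, with attributes `auc_units`
#'   (trapezoidal U x min), `peak_units`, `peak_time`, `params`, and
#'   cumulative secretion/emptying mass totals for balance checking.
#' @examples
#' curve <- simulate_ph_curve("semidynamic", duration = 80,
#'                            start_ph = 6, end_ph = 2, seed = 1)
#' sim <- simulate_gastric(gastric_params(duration = 80), curve)
#' print(sim)
#' @export
simulate_gastric <- function(params, ph_curve,
                             surface = builtin_surface("porcine", "as_printed"),
                             temp_curve = NULL) {
  stopifnot(inherits(params, "gastric_params"))
  if (!inherits(ph_curve, "digestion_profile")) {
    ph_curve <- digestion_profile(ph_curve$t_min, ph_curve$ph,
                                  label = "ph curve")
  }
  if (max(ph_curve$t_min) < params$duration || min(ph_curve$t_min) > 0) {
    stop(sprintf("pH curve must span [0, %g] min", params$duration),
         call. = FALSE)
  }
  dt <- params$dt
  # per-minute rates
  s_pepsin <- params$pepsin_secretion_rate / 60 * (1 - params$output_reduction)
  f_sec <- params$fluid_secretion_rate
  f_emp <- params$emptying_rate
  if (dt >= 10) {
    warning("dt is large relative to the secretion/emptying timescales; ",
            "results may be poorly resolved", call. = FALSE)
  }
  times <- seq(0, params$duration, by = dt)
  n <- length(times)
  V <- numeric(n)
  P <- numeric(n)
  emptied <- 0   # cumulative pepsin mass emptied, mg
  secreted <- 0  # cumulative pepsin mass secreted, mg
  V[1] <- params$basal_volume + params$meal_volume
  P[1] <- params$basal_volume * params$basal_pepsin_conc *
    (if (params$reduce_basal) 1 - params$output_reduction else 1)
  dried_out <- FALSE
  for (i in seq_len(n - 1)) {
    out_flux <- if (V[i] > 0) f_emp * (P[i] / V[i]) * dt else 0
    out_flux <- min(out_flux, P[i] + s_pepsin * dt)  # cannot empty more than present
    P[i + 1] <- max(P[i] + s_pepsin * dt - out_flux, 0)
    V[i + 1] <- max(V[i] + (f_sec - f_emp) * dt, 0)
    secreted <- secreted + s_pepsin * dt
    emptied <- emptied + out_flux
    if (!dried_out && V[i + 1] == 0) dried_out <- TRUE
  }
  if (dried_out) {
    warning("gastric volume reached 0 during the simulation; the ",
            "well-mixed emptying model is not meaningful beyond that point",
            call. = FALSE)
  }
  ph <- stats::approx(ph_curve$t_min, ph_curve$ph, xout = times)$y
  temp <- if (is.null(temp_curve)) rep(37, n) else {
    stats::approx(temp_curve$t_min, temp_curve$temp_c, xout = times)$y
  }
  rel <- predict_relative(surface, ph, temp, policy = "allow")
  units <- P * params$optimal_specific_activity * rel / 100
  out <- data.frame(t_min = times, volume_ml = V, pepsin_mg = P,
                    pepsin_mg_per_ml = ifelse(V > 0, P / V, NA_real_),
                    ph = ph, relative_activity_pct = rel,
                    total_units = units)
  peak <- which.max(units)
  structure(out,
            auc_units = pracma::trapz(times, units),
            peak_units = units[peak], peak_time = times[peak],
            mass_secreted = secreted, mass_emptied = emptied,
            params = params,
            class = c("gastric_sim", "data.frame"))
}

#' @export
print.gastric_sim <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Gastric pepsin simulation: %g min at dt = %g min\n",
              p$duration, p$dt))
  if (p$output_reduction > 0) {
    cat(sprintf("  pepsin output reduced by %.0f%%%s\n",
                100 * p$output_reduction,
                if (p$reduce_basal) " (incl. basal)" else ""))
  }
  cat(sprintf("  peak total activity: %.5g U at t = %g min\n",
              attr(x, "peak_units"), attr(x, "peak_time")))
  cat(sprintf("  AUC of total units: %.5g U*min\n", attr(x, "auc_units")))
  invisible(x)
}

#' @export
plot.gastric_sim <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 4, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$t_min, x$total_units, type = "l", xlab = "Time (min)",
                 ylab = "Total pepsin activity (U)", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$t_min, x$pepsin_mg_per_ml, type = "l", lty = 2,
                 axes = FALSE, xlab = "", ylab = "", col = "grey40")
  graphics::axis(4, col = "grey40", col.axis = "grey40")
  graphics::mtext("Pepsin concentration (mg/mL)", side = 4, line = 2.5,
                  col = "grey40")
  invisible(x)
}

#' AUC of the total-activity trajectory
#'
#' @param result a [simulate_gastric()] result.
#' @return trapezoidal area under total units, in U x min.
#' @export
auc_units <- function(result) {
  stopifnot(inherits(result, "gastric_sim"))
  attr(result, "auc_units")
}

#' Compare two gastric simulation scenarios
#'
#' Both runs must share the same time grid (same `dt` and `duration`).
#'
#' @param result_a,result_b [simulate_gastric()] results.
#' @return list with `auc_ratio` (a over b), `peak_ratio`, `peak_times`
#'   and the two total-unit trajectories.
#' @export
compare_scenarios <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "gastric_sim"),
            inherits(result_b, "gastric_sim"))
  if (length(result_a$t_min) != length(result_b$t_min) ||
      any(result_a$t_min != result_b$t_min)) {
    stop("scenarios were run on different time grids", call. = FALSE)
  }
  list(auc_ratio = attr(result_a, "auc_units") / attr(result_b, "auc_units"),
       peak_ratio = attr(result_a, "peak_units") / attr(result_b, "peak_units"),
       peak_times = c(a = attr(result_a, "peak_time"),
                      b = attr(result_b, "peak_time")),
       total_units = data.frame(t_min = result_a$t_min,
                                a = result_a$total_units,
                                b = result_b$total_units))
}

#' Pepsin mass-balance check
#'
#' Verifies that initial pepsin + cumulative secreted equals final
#' pepsin + cumulative emptied (exact for the explicit-Euler update,
#' up to floating-point accumulation).
#'
#' @param result a [simulate_gastric()] result.
#' @return list with the four mass components and `relative_error`.
#' @export
mass_balance <- function(result) {
  stopifnot(inherits(result, "gastric_sim"))
  p0 <- result$pepsin_mg[1]
  pT <- result$pepsin_mg[nrow(result)]
  sec <- attr(result, "mass_secreted")
  emp <- attr(result, "mass_emptied")
  lhs <- p0 + sec
  rhs <- pT + emp
  list(initial = p0, secreted = sec, final = pT, emptied = emp,
       relative_error = abs(lhs - rhs) / max(lhs, .Machine$double.eps))
}

#' Write a simulation trajectory to CSV
#'
#' Columns `t_min,volume_ml,pepsin_mg,pepsin_mg_per_ml,
#' relative_activity_pct,total_units`.
#'
#' @param x a [simulate_gastric()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(x, path) {
  stopifnot(inherits(x, "gastric_sim"))
  cols <- c("t_min", "volume_ml", "pepsin_mg", "pepsin_mg_per_ml",
            "relative_activity_pct", "total_units")
  utils::write.csv(as.data.frame(x)[cols], path, row.names = FALSE)
  invisible(path)
}
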