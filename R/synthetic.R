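#' Experimental design helpers
#'
#' `design_grid()` lays a regular grid over the calibrated domain
#' (pH 1-7, 4-60 degC). `design_paper_like()` emulates the structure of
#' the original 37-point experiment: a seeded 26-point D-optimal
#' selection from a candidate grid (for a nine-term reduced cubic
#' basis) plus 11 points sampled along a semi-dynamic digestion
#' trajectory (pH falling from 6.5 to 2 at 37 degC). It reproduces the
#' *structure* of that design, not the undisclosed original points.
#'
#' @param n_ph,n_temp grid resolution per factor.
#' @param domain_ph,domain_temp_c factor ranges.
#' @return data.frame with columns `ph`, `temp_c`.
#' @export
design_grid <- function(n_ph = 7, n_temp = 7, domain_ph = c(1, 7),
                        domain_temp_c = c(4, 60)) {
  expand.grid(ph = seq(domain_ph[1], domain_ph[2], length.out = n_ph),
              temp_c = seq(domain_temp_c[1], domain_temp_c[2],
                           length.out = n_temp))
}

#' @rdname design_grid
#' @param seed RNG seed for the D-optimal selection.
#' @export
design_paper_like <- function(seed = 1L) {
  cand <- design_grid(13, 15)
  sel <- doptimal_design(cand, basis = "nine_term", n_points = 26,
                         seed = seed, n_starts = 2L)
  traj_t <- seq(0, 240, length.out = 11)
  traj_ph <- 2 + (6.5 - 2) * (exp(-3 * traj_t / 240) - exp(-3)) / (1 - exp(-3))
  rbind(sel$points,
        data.frame(ph = traj_ph, temp_c = rep(37, 11)))
}

#' Simulate an activity dataset from a known surface
#'
#' Draws `activity_i = 10^(log10 surface(point_i) + eps_i)` with
#' `eps_i ~ N(0, noise_sd_log10)`, i.e. Gaussian noise on the log10
#' scale, consistent with the log-transformed fitting convention. Run
#' ids are sequential from 1. Deterministic for a fixed seed.
#'
#' @param surface the generating [pepsin_surface()].
#' @param design data.frame with columns `ph`, `temp_c`.
#' @param noise_sd_log10 noise SD on the log10 scale (default 0.05,
#'   a realistic assay repeatability level).
#' @param seed RNG seed (restored on exit); required for noisy draws.
#' @param species label for the dataset.
#' @return an [activity_dataset()].
#' @export
simulate_activity_data <- function(surface, design = design_grid(),
                                   noise_sd_log10 = 0.05, seed = NULL,
                                   species = "synthetic") {
  stopifnot(inherits(surface, "pepsin_surface"))
  if (noise_sd_log10 < 0) stop("noise_sd_log10 must be >= 0", call. = FALSE)
  if (noise_sd_log10 > 0 && is.null(seed)) {
    stop("supply a seed for noisy generation (reproducibility contract)",
         call. = FALSE)
  }
  gen <- function() {
    l10 <- evaluate_log10(surface, design$ph, design$temp_c)
    eps <- if (noise_sd_log10 > 0) {
      stats::rnorm(nrow(design), 0, noise_sd_log10)
    } else 0
    activity_dataset(design$ph, design$temp_c, 10^(l10 + eps),
                     species = species)
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen())
}

#' Simulate a gastric pH curve
#'
#' Three shapes:
#' \describe{
#'   \item{static}{constant `start_ph` throughout (static INFOGEST).}
#'   \item{semidynamic}{monotone exponential-approach descent from
#'     `start_ph`, reaching `end_ph` exactly at `duration` (the
#'     semi-dynamic convention of hitting pH 2 at the end of the
#'     gastric phase). `rate` controls curvature; a seeded jitter can
#'     perturb it.}
#'   \item{invivo_meal}{postprandial in vivo shape: a plateau near
#'     `start_ph` for `plateau_frac` of the duration, then a smooth
#'     descent to `end_ph`.}
#' }
#' Deterministic given the seed.
#'
#' @param kind curve shape.
#' @param duration minutes, > 0.
#' @param start_ph,end_ph boundary pH values.
#' @param n number of anchors.
#' @param rate descent shape parameter (dimensionless, larger = faster
#'   early descent).
#' @param rate_jitter_sd SD of a seeded multiplicative jitter on `rate`.
#' @param plateau_frac fraction of `duration` spent near `start_ph`
#'   (invivo_meal only).
#' @param seed RNG seed (restored on exit).
#' @return a [digestion_profile()] (temperature fixed at 37 degC).
#' @export
simulate_ph_curve <- function(kind = c("static", "semidynamic", "invivo_meal"),
                              duration = 240, start_ph = 6.5, end_ph = 2,
                              n = 25, rate = 3, rate_jitter_sd = 0,
                              plateau_frac = 0.25, seed = NULL) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  t <- seq(0, duration, length.out = n)
  gen <- function() {
    r <- rate
    if (rate_jitter_sd > 0) r <- rate * exp(stats::rnorm(1, 0, rate_jitter_sd))
    ph <- switch(kind,
      static = rep(start_ph, n),
      semidynamic = {
        u <- t / duration
        end_ph + (start_ph - end_ph) * (exp(-r * u) - exp(-r)) / (1 - exp(-r))
      },
      invivo_meal = {
        t0 <- plateau_frac * duration
        u <- pmax(t - t0, 0) / (duration - t0)
        end_ph + (start_ph - end_ph) * (exp(-r * u) - exp(-r)) / (1 - exp(-r))
      })
    digestion_profile(t, ph, temp_c = 37, label = kind)
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen())
}

#' Simulate spectrophotometric assay readings
#'
#' Inverts the unit formula: for a true activity `true_u_per_mL`, the
#' noiseless delta-A280 is
#' `true * 0.001 * incubation_min * enzyme_volume_mL / dilution_factor`;
#' seeded Gaussian noise (SD `noise_sd`, absorbance units) is added to
#' the sample absorbance. Blanks are 0.05 by construction.
#'
#' @param true_u_per_mL true activity, U/mL, >= 0.
#' @param n number of readings, >= 1.
#' @param noise_sd absorbance noise SD.
#' @param incubation_min,enzyme_volume_mL,dilution_factor assay layout.
#' @param seed RNG seed (restored on exit).
#' @return data.frame with the [read_assay_csv()] columns.
#' @export
simulate_assay_readings <- function(true_u_per_mL, n = 3, noise_sd = 0.005,
                                    incubation_min = 10,
                                    enzyme_volume_mL = 0.1,
                                    dilution_factor = 1, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (true_u_per_mL < 0) stop("true activity must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("supply a seed for noisy generation (reproducibility contract)",
         call. = FALSE)
  }
  gen <- function() {
    blank <- 0.05
    dA <- true_u_per_mL * 0.001 * incubation_min * enzyme_volume_mL /
      dilution_factor
    eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    data.frame(sample_id = sprintf("S%02d", seq_len(n)),
               a280_sample = blank + dA + eps,
               a280_blank = blank,
               incubation_min = incubation_min,
               enzyme_volume_mL = enzyme_volume_mL,
               dilution_factor = dilution_factor)
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen())
}
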