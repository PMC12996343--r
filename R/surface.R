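#' Pepsin activity surfaces
#'
#' A `pepsin_surface` is a polynomial in pH and temperature evaluated on
#' the log10 scale: `log10(activity %) = sum coef * pH^ph_pow * T^temp_pow`.
#' Activity is expressed as percent of the activity at the reference
#' condition (pH 2, 37 °C by convention), and may exceed 100% where the
#' surface predicts more activity than at the reference point.
#'
#' @param terms data.frame with integer columns `ph_pow`, `temp_pow`
#'   (exponents, 0..3) and numeric `coef`. Must contain the intercept
#'   term `(0, 0)` and no duplicated exponent pairs.
#' @param species one of `"human"`, `"porcine"`, `"custom"`.
#' @param variant one of `"fitted"`, `"as_printed"`, `"corrected"`.
#' @param domain_ph,domain_temp_c length-2 numeric, the pH and
#'   temperature (°C) intervals over which the surface was calibrated.
#'   Predictions outside are flagged as extrapolated.
#' @param reference named numeric `c(ph = , temp_c = )`, the condition
#'   defining 100% activity. Must lie inside the domain.
#' @param provenance free-text note on where the coefficients came from.
#' @param amendments character vector describing any editorial
#'   amendments applied to published coefficients (empty if none).
#'
#' @return An object of class `pepsin_surface`.
#' @seealso [builtin_surface()], [predict.pepsin_surface()],
#'   [evaluate_log10()], [write_surface_json()]
#' @examples
#' flat <- pepsin_surface(data.frame(ph_pow = 0, temp_pow = 0, coef = 2))
#' predict(flat, ph = 3, temp_c = 20)  # 10^2 = 100%
#' @export
pepsin_surface <- function(terms,
                           species = c("custom", "human", "porcine"),
                           variant = c("fitted", "as_printed", "corrected"),
                           domain_ph = c(1, 7),
                           domain_temp_c = c(4, 60),
                           reference = c(ph = 2, temp_c = 37),
                           provenance = NULL,
                           amendments = character()) {
  species <- match.arg(species)
  variant <- match.arg(variant)
  terms <- as.data.frame(terms)
  req <- c("ph_pow", "temp_pow", "coef")
  if (!all(req %in% names(terms))) {
    stop("`terms` must have columns ph_pow, temp_pow, coef", call. = FALSE)
  }
  terms <- terms[req]
  if (nrow(terms) == 0L) stop("`terms` must be non-empty", call. = FALSE)
  pw <- terms[c("ph_pow", "temp_pow")]
  if (any(pw != round(pw)) || any(pw < 0) || any(pw > 3)) {
    stop("exponents must be integers in 0..3", call. = FALSE)
  }
  if (anyDuplicated(pw)) {
    stop("duplicated (ph_pow, temp_pow) pairs in `terms`", call. = FALSE)
  }
  if (!any(terms$ph_pow == 0 & terms$temp_pow == 0)) {
    stop("`terms` must include the intercept term (0, 0)", call. = FALSE)
  }
  if (!all(is.finite(terms$coef))) stop("non-finite coefficient", call. = FALSE)
  stopifnot(length(domain_ph) == 2L, length(domain_temp_c) == 2L,
            domain_ph[1] < domain_ph[2], domain_temp_c[1] < domain_temp_c[2])
  reference <- c(ph = unname(reference["ph"]), temp_c = unname(reference["temp_c"]))
  if (anyNA(reference)) stop("`reference` needs named elements ph, temp_c", call. = FALSE)
  if (reference["ph"] < domain_ph[1] || reference["ph"] > domain_ph[2] ||
      reference["temp_c"] < domain_temp_c[1] || reference["temp_c"] > domain_temp_c[2]) {
    stop("reference condition must lie inside the domain", call. = FALSE)
  }
  structure(
    list(species = species, variant = variant, terms = terms,
         transform = "log10",
         domain = list(ph = as.numeric(domain_ph),
                       temp_c = as.numeric(domain_temp_c)),
         reference = reference,
         provenance = provenance %||% "user-supplied",
         amendments = amendments),
    class = "pepsin_surface")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Published pepsin activity prediction surfaces
#'
#' Returns the published human or porcine pepsin activity polynomial.
#' The `"as_printed"` variants carry the coefficients exactly as
#' published. The published human equation's temperature-linear
#' coefficient (0.88912) makes the surface predict a physically
#' impossible log10 activity of about 31.6 at its own optimum; the
#' `"corrected"` human variant applies the single documented editorial
#' amendment 0.88912 -> 0.088912, which brings the optimum prediction
#' to about 101%. No amendment is defined for the porcine equation
#' (no single-coefficient fix is defensible), so its `"corrected"`
#' variant is coefficient-identical to `"as_printed"`; for porcine,
#' self-normalized predictions via [predict_relative()] (or refitting
#' from data with [fit_activity_surface()]) are the recommended output,
#' since the printed equation evaluates to ~59.5% rather than 100% at
#' the optimum.
#'
#' @param species `"human"` or `"porcine"`.
#' @param variant `"corrected"` (default) or `"as_printed"`.
#' @return A [pepsin_surface()].
#' @examples
#' m <- builtin_surface("porcine", "as_printed")
#' predict_relative(m, ph = 3, temp_c = 37)  # ~47.1% of optimum
#' @export
builtin_surface <- function(species = c("human", "porcine"),
                            variant = c("corrected", "as_printed")) {
  species <- match.arg(species)
  variant <- match.arg(variant)
  human <- data.frame(
    ph_pow   = c(0, 1, 0, 1, 2, 0, 1),
    temp_pow = c(0, 0, 1, 1, 0, 2, 2),
    coef     = c(-0.17363, 0.76823, 0.88912, -0.02263,
                 -0.08922, -0.00107, 0.00031))
  porcine <- data.frame(
    ph_pow   = c(0, 1, 0, 1, 2, 0, 1, 3, 0),
    temp_pow = c(0, 0, 1, 1, 0, 2, 2, 0, 3),
    coef     = c(-0.104906, 1.50841, 0.03685, -0.02088,
                 -0.49262, 0.00071, 0.00045, 0.04129, -0.00003))
  terms <- if (species == "human") human else porcine
  amendments <- character()
  if (variant == "corrected" && species == "human") {
    i <- which(terms$ph_pow == 0 & terms$temp_pow == 1)
    terms$coef[i] <- 0.088912
    amendments <- paste(
      "temperature-linear coefficient amended 0.88912 -> 0.088912",
      "(published value yields log10 activity ~31.6 at the optimum)")
  }
  pepsin_surface(terms, species = species, variant = variant,
                 provenance = sprintf("published %s pepsin equation (%s)",
                                      species, variant),
                 amendments = amendments)
}

#' Evaluate a surface on the log10 scale
#'
#' Computes `sum(coef * ph^ph_pow * temp_c^temp_pow)` over all terms.
#' Vectorized over `ph` and `temp_c` (recycled to common length).
#'
#' @param surface a [pepsin_surface()].
#' @param ph,temp_c numeric vectors, finite.
#' @return numeric vector of log10(activity %).
#' @export
evaluate_log10 <- function(surface, ph, temp_c) {
  stopifnot(inherits(surface, "pepsin_surface"))
  n <- max(length(ph), length(temp_c))
  ph <- rep_len(as.numeric(ph), n)
  temp_c <- rep_len(as.numeric(temp_c), n)
  if (!all(is.finite(ph)) || !all(is.finite(temp_c))) {
    stop("ph and temp_c must be finite", call. = FALSE)
  }
  tm <- surface$terms
  X <- outer(ph, tm$ph_pow, `^`) * outer(temp_c, tm$temp_pow, `^`)
  drop(X %*% tm$coef)
}

.is_extrapolated <- function(surface, ph, temp_c) {
  d <- surface$domain
  ph < d$ph[1] | ph > d$ph[2] | temp_c < d$temp_c[1] | temp_c > d$temp_c[2]
}

.check_extrapolation <- function(surface, ph, temp_c, policy) {
  out <- .is_extrapolated(surface, ph, temp_c)
  if (any(out)) {
    d <- surface$domain
    i <- which(out)[1L]
    bound <-
      if (ph[i] < d$ph[1]) sprintf("pH %.3g below lower bound %g", ph[i], d$ph[1])
      else if (ph[i] > d$ph[2]) sprintf("pH %.3g above upper bound %g", ph[i], d$ph[2])
      else if (temp_c[i] < d$temp_c[1]) sprintf("temperature %.3g below lower bound %g", temp_c[i], d$temp_c[1])
      else sprintf("temperature %.3g above upper bound %g", temp_c[i], d$temp_c[2])
    msg <- sprintf("%d point(s) outside the calibrated domain (first: %s)",
                   sum(out), bound)
    if (policy == "forbid") stop(msg, call. = FALSE)
    if (policy == "warn") warning(msg, call. = FALSE)
  }
  out
}

# Warn when a surface is badly mis-scaled at its own reference condition
# (e.g. the as-printed human equation). Self-normalized predictions via
# predict_relative are unaffected by the overall scale and do not warn.
.check_reference_sanity <- function(surface) {
  ref <- evaluate_log10(surface, surface$reference["ph"], surface$reference["temp_c"])
  if (abs(ref - 2) > 1) {
    warning(sprintf(paste(
      "surface predicts %.4g%% of optimum at its own reference condition",
      "(log10 = %.4g); coefficients are likely mis-scaled --",
      "consider predict_relative() or a corrected/fitted variant"),
      10^ref, ref), call. = FALSE)
  }
  invisible(ref)
}

#' Predict absolute activity (percent of optimum) with diagnostics
#'
#' Evaluates the surface and returns activity on the percent scale
#' together with the log10 value and an extrapolation flag per point.
#' Values above 100% are allowed and never clipped.
#'
#' @inheritParams evaluate_log10
#' @param policy what to do when a query point lies outside the
#'   calibrated domain: `"warn"` (default), `"forbid"` (error naming the
#'   violated bound), or `"allow"` (silent).
#' @return data.frame with columns `ph`, `temp_c`, `log10_activity`,
#'   `activity_pct`, `extrapolated`.
#' @export
predict_activity <- function(surface, ph, temp_c,
                             policy = c("warn", "forbid", "allow")) {
  policy <- match.arg(policy)
  n <- max(length(ph), length(temp_c))
  ph <- rep_len(as.numeric(ph), n)
  temp_c <- rep_len(as.numeric(temp_c), n)
  l10 <- evaluate_log10(surface, ph, temp_c)
  out <- .check_extrapolation(surface, ph, temp_c, policy)
  .check_reference_sanity(surface)
  data.frame(ph = ph, temp_c = temp_c, log10_activity = l10,
             activity_pct = 10^l10, extrapolated = out)
}

#' Predict activity relative to the surface's own reference condition
#'
#' Returns `100 * activity(ph, temp_c) / activity(reference)`; exactly
#' 100 at the reference condition for every well-formed surface. Because
#' the overall scale cancels, this is the recommended output for
#' published surfaces whose absolute level does not reproduce 100% at
#' the optimum (notably the as-printed porcine equation, ~59.5%).
#'
#' @inheritParams predict_activity
#' @return numeric vector, percent of reference-condition activity.
#' @export
predict_relative <- function(surface, ph, temp_c,
                             policy = c("warn", "forbid", "allow")) {
  policy <- match.arg(policy)
  n <- max(length(ph), length(temp_c))
  ph <- rep_len(as.numeric(ph), n)
  temp_c <- rep_len(as.numeric(temp_c), n)
  .check_extrapolation(surface, ph, temp_c, policy)
  ref <- evaluate_log10(surface, surface$reference["ph"], surface$reference["temp_c"])
  100 * 10^(evaluate_log10(surface, ph, temp_c) - ref)
}

#' @describeIn pepsin_surface convenience predict method; returns a
#'   numeric vector of activity percentages (absolute when
#'   `relative = FALSE`, relative to the reference condition otherwise).
#' @param object a `pepsin_surface`.
#' @param newdata optional data.frame with columns `ph` and `temp_c`
#'   (overrides `ph`/`temp_c`).
#' @param ph,temp_c query condition(s).
#' @param relative logical; normalize by the reference condition?
#' @param policy extrapolation policy, see [predict_activity()].
#' @param ... ignored.
#' @export
predict.pepsin_surface <- function(object, newdata = NULL, ph = NULL,
                                   temp_c = NULL, relative = FALSE,
                                   policy = "warn", ...) {
  if (!is.null(newdata)) {
    ph <- newdata$ph
    temp_c <- newdata$temp_c
  }
  if (is.null(ph) || is.null(temp_c)) {
    stop("supply `newdata` or both `ph` and `temp_c`", call. = FALSE)
  }
  if (relative) {
    predict_relative(object, ph, temp_c, policy = policy)
  } else {
    predict_activity(object, ph, temp_c, policy = policy)$activity_pct
  }
}

#' @export
print.pepsin_surface <- function(x, ...) {
  cat(sprintf("Pepsin activity surface (%s, %s)\n", x$species, x$variant))
  cat(sprintf("  log10(activity %%) polynomial, %d terms\n", nrow(x$terms)))
  cat(sprintf("  domain: pH [%g, %g], temperature [%g, %g] degC\n",
              x$domain$ph[1], x$domain$ph[2],
              x$domain$temp_c[1], x$domain$temp_c[2]))
  cat(sprintf("  reference (100%%): pH %g, %g degC\n",
              x$reference["ph"], x$reference["temp_c"]))
  if (length(x$amendments)) {
    cat("  amendments:", paste(x$amendments, collapse = "; "), "\n")
  }
  print(coef(x))
  invisible(x)
}

#' @export
coef.pepsin_surface <- function(object, ...) {
  tm <- object$terms
  stats::setNames(tm$coef, term_label(tm$ph_pow, tm$temp_pow))
}

term_label <- function(ph_pow, temp_pow) {
  lab <- function(p, q) {
    parts <- c(if (p == 1) "pH" else if (p > 1) sprintf("pH^%d", p),
               if (q == 1) "T" else if (q > 1) sprintf("T^%d", q))
    if (!length(parts)) "(Intercept)" else paste(parts, collapse = ":")
  }
  mapply(lab, ph_pow, temp_pow, USE.NAMES = FALSE)
}

#' @export
#' @describeIn pepsin_surface filled-contour plot of relative activity
#'   over the calibrated domain.
#' @param x a `pepsin_surface`.
#' @param n grid resolution per axis.
plot.pepsin_surface <- function(x, n = 80, ...) {
  ph <- seq(x$domain$ph[1], x$domain$ph[2], length.out = n)
  tc <- seq(x$domain$temp_c[1], x$domain$temp_c[2], length.out = n)
  z <- outer(ph, tc, function(p, t) predict_relative(x, p, t, policy = "allow"))
  graphics::filled.contour(
    ph, tc, z, xlab = "pH", ylab = "Temperature (degC)",
    main = sprintf("%s pepsin activity (%% of optimum)", x$species), ...)
  invisible(x)
}

#' Write / read a surface as JSON
#'
#' Serializes all information needed to reproduce predictions exactly:
#' species, variant, transform, reference condition, domain, terms and
#' provenance. Full double precision is kept so a round trip reproduces
#' predictions bit for bit.
#'
#' @param surface a [pepsin_surface()].
#' @param path file path.
#' @return `write_surface_json` returns `path` invisibly;
#'   `read_surface_json` returns a [pepsin_surface()].
#' @export
write_surface_json <- function(surface, path) {
  stopifnot(inherits(surface, "pepsin_surface"))
  obj <- list(
    species = surface$species,
    variant = surface$variant,
    transform = "log10",
    reference = list(ph = unname(surface$reference["ph"]),
                     temp_c = unname(surface$reference["temp_c"])),
    domain = list(ph = surface$domain$ph, temp_c = surface$domain$temp_c),
    terms = lapply(seq_len(nrow(surface$terms)), function(i) {
      list(ph_pow = surface$terms$ph_pow[i],
           temp_pow = surface$terms$temp_pow[i],
           coef = surface$terms$coef[i])
    }),
    provenance = surface$provenance,
    amendments = as.list(surface$amendments))
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  obj <- jsonlite::read_json(path)
  terms <- do.call(rbind, lapply(obj$terms, function(t) {
    data.frame(ph_pow = t$ph_pow, temp_pow = t$temp_pow, coef = t$coef)
  }))
  pepsin_surface(
    terms,
    species = obj$species, variant = obj$variant,
    domain_ph = unlist(obj$domain$ph),
    domain_temp_c = unlist(obj$domain$temp_c),
    reference = c(ph = obj$reference$ph, temp_c = obj$reference$temp_c),
    provenance = obj$provenance,
    amendments = unlist(obj$amendments) %||% character())
}
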