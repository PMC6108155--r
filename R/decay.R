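# Gaussian distance-decay impedance on travel-time sub-zones.
#
# A catchment is cut into travel-time bands ("sub-zones"); every trip that
# falls in a band is weighted by exp(-d^2 / beta) evaluated at the band's
# representative (mean) travel time, so weights are piecewise constant
# within the catchment and zero beyond it.

#' Travel-time sub-zone scheme
#'
#' Defines the ordered travel-time bands of a catchment and the
#' representative travel time used to evaluate the decay weight in each
#' band. Intervals are left-closed and right-open, except the last band,
#' which is closed at the catchment threshold, so every in-catchment time
#' maps to exactly one band.
#'
#' @param breakpoints Numeric vector of band boundaries in minutes,
#'   strictly increasing, starting at 0. `length(breakpoints) - 1` bands
#'   are defined; the final value is the catchment threshold.
#' @param representative_times Optional numeric vector, one travel time
#'   per band, each inside its band. Defaults to the arithmetic midpoint
#'   of each band (e.g. 5, 15, 25 minutes for breakpoints 0/10/20/30).
#'
#' @return An object of class `subzone_scheme` with elements
#'   `breakpoints`, `representative_times`, and `threshold`.
#' @examples
#' subzone_scheme(c(0, 10, 20, 30))             # car-style, 3 bands
#' subzone_scheme(c(0, 10, 20, 30, 60))         # bus-style, 4 bands
#' @export
subzone_scheme <- function(breakpoints, representative_times = NULL) {
  if (!is.numeric(breakpoints) || length(breakpoints) < 2)
    stop("`breakpoints` must be a numeric vector of length >= 2", call. = FALSE)
  if (breakpoints[1] != 0)
    stop("first breakpoint must be 0", call. = FALSE)
  if (any(diff(breakpoints) <= 0))
    stop("`breakpoints` must be strictly increasing", call. = FALSE)
  n <- length(breakpoints) - 1L
  if (is.null(representative_times)) {
    representative_times <- (breakpoints[-1] + breakpoints[-length(breakpoints)]) / 2
  }
  if (length(representative_times) != n)
    stop("need one representative time per sub-zone (", n, ")", call. = FALSE)
  lo <- breakpoints[-length(breakpoints)]
  hi <- breakpoints[-1]
  if (any(representative_times < lo | representative_times > hi))
    stop("each representative time must lie inside its sub-zone", call. = FALSE)
  structure(
    list(breakpoints = as.numeric(breakpoints),
         representative_times = as.numeric(representative_times),
         threshold = as.numeric(breakpoints[length(breakpoints)])),
    class = "subzone_scheme")
}

#' Gaussian impedance weight
#'
#' The decay kernel `W = exp(-d^2 / beta)`: weight 1 at zero travel time,
#' falling towards 0 as travel time grows; larger `beta` means slower
#' decay.
#'
#' @param d Travel time(s) in minutes, non-negative. Vectorised.
#' @param beta Impedance coefficient (minutes squared), positive scalar.
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' gaussian_weight(5, 140)   # 0.836 to 3 d.p.
#' gaussian_weight(45, 440)  # 0.010 to 3 d.p.
#' @export
gaussian_weight <- function(d, beta) {
  check_beta(beta)
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0))
    stop("`d` must be non-negative travel time in minutes", call. = FALSE)
  exp(-d^2 / beta)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  invisible(beta)
}

#' Classify a travel time into a sub-zone
#'
#' @param t Travel time(s) in minutes, non-negative. Vectorised.
#' @param scheme A [subzone_scheme()].
#' @return Integer vector of 1-based sub-zone indices; `NA` for times
#'   beyond the catchment threshold. A time exactly equal to the threshold
#'   falls in the last sub-zone (closed last interval).
#' @export
subzone_of <- function(t, scheme) {
  stopifnot(inherits(scheme, "subzone_scheme"))
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0))
    stop("`t` must be non-negative travel time in minutes", call. = FALSE)
  z <- findInterval(t, scheme$breakpoints, rightmost.closed = TRUE)
  z[t > scheme$threshold] <- NA_integer_
  as.integer(z)
}

#' Stepped sub-zone decay weight
#'
#' Looks up the sub-zone of each travel time and evaluates the Gaussian
#' kernel at that sub-zone's representative time, so all times within a
#' band share one weight. Times beyond the catchment return `NA` and are
#' treated by the access computations as non-contributing.
#'
#' @inheritParams subzone_of
#' @param beta Impedance coefficient, positive scalar.
#' @return Numeric weights; `NA` outside the catchment.
#' @examples
#' sch <- subzone_scheme(c(0, 10, 20, 30))
#' subzone_weight(c(5, 8, 15, 35), sch, beta = 140)  # 0.836 0.836 0.200 NA
#' @export
subzone_weight <- function(t, scheme, beta) {
  z <- subzone_of(t, scheme)
  w <- rep(NA_real_, length(z))
  ok <- !is.na(z)
  if (any(ok))
    w[ok] <- gaussian_weight(scheme$representative_times[z[ok]], beta)
  w
}

#' Derive an impedance coefficient from a critical weight
#'
#' Solves `exp(-d_ref^2 / beta) = w_crit` for `beta`, the standard way of
#' anchoring the Gaussian coefficient when no realized-access data exist:
#' pick the travel time of the outermost sub-zone and the critical weight
#' (typically 0.01 or 0.1) it should receive.
#'
#' @param d_ref Reference travel time in minutes, positive.
#' @param w_crit Target weight at `d_ref`, strictly between 0 and 1.
#' @return The coefficient `beta = -d_ref^2 / log(w_crit)`.
#' @examples
#' derive_beta(25, 0.01)  # ~135.7; grid minimum rounded to 140
#' derive_beta(45, 0.01)  # ~439.7; grid minimum rounded to 440
#' @export
derive_beta <- function(d_ref, w_crit) {
  if (!is.numeric(d_ref) || length(d_ref) != 1L || is.na(d_ref) || d_ref <= 0)
    stop("`d_ref` must be a single positive travel time", call. = FALSE)
  if (!is.numeric(w_crit) || length(w_crit) != 1L || is.na(w_crit) ||
      w_crit <= 0 || w_crit >= 1)
    stop("`w_crit` must lie strictly between 0 and 1", call. = FALSE)
  -d_ref^2 / log(w_crit)
}

#' Sub-zone weight table over coefficient grids
#'
#' Tabulates the stepped decay weight of every sub-zone for every
#' coefficient in per-mode grids, one row per (mode, beta, sub-zone).
#' With the default car/bus schemes and the default 13-value grids this
#' reproduces the standard published impedance-coefficient table.
#'
#' @param schemes Named list of [subzone_scheme()]s, one per mode.
#'   Defaults to the car (30 min, 3 sub-zones) and bus (60 min, 4
#'   sub-zones) schemes.
#' @param betas Named list of numeric coefficient vectors, names matching
#'   `schemes`. Defaults to the 140--320 (car) and 440--1040 (bus)
#'   13-value grids.
#' @param digits Optional rounding (half away from zero) applied to the
#'   `weight` column for presentation; `NULL` (default) keeps full
#'   precision.
#' @return A data.frame with columns `mode`, `beta`, `subzone`,
#'   `rep_time_min`, `weight`.
#' @export
weight_table <- function(schemes = default_schemes(),
                         betas = default_beta_grids(),
                         digits = NULL) {
  if (is.null(names(schemes)) || is.null(names(betas)) ||
      !setequal(names(schemes), names(betas)))
    stop("`schemes` and `betas` must be named lists over the same modes",
         call. = FALSE)
  rows <- lapply(names(schemes), function(m) {
    sch <- schemes[[m]]
    bs <- betas[[m]]
    for (b in bs) check_beta(b)
    nz <- length(sch$representative_times)
    data.frame(
      mode = m,
      beta = rep(bs, each = nz),
      subzone = rep(seq_len(nz), times = length(bs)),
      rep_time_min = rep(sch$representative_times, times = length(bs)),
      weight = as.vector(vapply(
        bs, function(b) gaussian_weight(sch$representative_times, b),
        numeric(nz))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) out$weight <- round_half_away(out$weight, digits)
  rownames(out) <- NULL
  out
}

#' Round half away from zero
#'
#' Presentation rounding used in the reported tables (0.0005 rounds up to
#' 0.001), as opposed to R's round-half-even. Internal computation is
#' always at full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Transport-mode specification
#'
#' Bundles a mode's name, catchment threshold, sub-zone scheme and
#' impedance coefficient. The threshold must equal the scheme's last
#' breakpoint.
#'
#' @param name Mode label (matches `pop_<name>` demand columns and the
#'   OD matrix of that mode).
#' @param scheme A [subzone_scheme()]; the catchment threshold is its
#'   last breakpoint.
#' @param beta Impedance coefficient, positive.
#' @param threshold Catchment limit in minutes; defaults to the scheme's
#'   threshold and must agree with it.
#' @return An object of class `mode_spec`.
#' @export
mode_spec <- function(name, scheme, beta, threshold = scheme$threshold) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(inherits(scheme, "subzone_scheme"))
  check_beta(beta)
  if (!isTRUE(all.equal(threshold, scheme$threshold)))
    stop("`threshold` must equal the scheme's last breakpoint", call. = FALSE)
  structure(list(name = name, threshold = as.numeric(threshold),
                 scheme = scheme, beta = as.numeric(beta)),
            class = "mode_spec")
}

#' @rdname weight_table
#' @export
default_schemes <- function() {
  list(car = subzone_scheme(c(0, 10, 20, 30)),
       bus = subzone_scheme(c(0, 10, 20, 30, 60)))
}

#' @rdname weight_table
#' @export
default_beta_grids <- function() {
  list(car = build_grid(140, 320, 13),
       bus = build_grid(440, 1040, 13))
}

#' Default car/bus mode specifications
#'
#' Car: 30-minute catchment, sub-zones 0-10/10-20/20-30 min. Bus:
#' 60-minute catchment, sub-zones 0-10/10-20/20-30/30-60 min. Default
#' coefficients are the grid minima (140 car, 440 bus), anchored at a
#' critical weight of 0.01 in the outermost sub-zone.
#'
#' @param beta_car,beta_bus Impedance coefficients.
#' @return A list of two [mode_spec()]s named `car` and `bus`.
#' @export
default_modes <- function(beta_car = 140, beta_bus = 440) {
  sch <- default_schemes()
  list(car = mode_spec("car", sch$car, beta_car),
       bus = mode_spec("bus", sch$bus, beta_bus))
}
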