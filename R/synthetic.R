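# Reproducible synthetic scenes with the structural signature of a
# car-oriented city: supply clustered in an urban core, bus service
# confined to the core, bus always slower than car, and a car-dominant
# mode split. Travel times come from planar geometry; the access model
# consumes only OD minutes, so network realism is irrelevant to
# correctness.

#' Synthetic scene specification
#'
#' Defaults emulate a mid-size car-oriented metropolitan area: 293
#' supply sites and 543 demand units (mean unit population ~1600) on a
#' 60 km square, supply overwhelmingly concentrated in an 8 km core,
#' bus service limited to a 10 km radius around the center, car roughly
#' 60 km/h and bus 18 km/h door-to-door plus a 10-minute access/wait
#' overhead, and vehicle ownership markedly lower in the core than in
#' the periphery. Under the default 30-minute car / 60-minute bus
#' catchments this leaves roughly half the demand units with no
#' bus-reachable supply at all.
#'
#' @param n_supply,n_demand Numbers of supply sites and demand units.
#' @param region_size Side of the square region, km.
#' @param core_radius Radius of the urban core around the region center, km.
#' @param supply_core_fraction,demand_core_fraction Shares of sites /
#'   units drawn uniformly inside the core (the rest uniform over the
#'   whole square).
#' @param bus_service_radius Radius within which bus service exists, km;
#'   bus travel time is defined only when both trip endpoints lie inside.
#' @param car_speed,bus_speed Effective speeds, km per minute
#'   (`bus_speed < car_speed`).
#' @param bus_overhead Fixed walk+wait minutes added to every bus trip.
#' @param vehicle_ownership_core,vehicle_ownership_periphery Probability
#'   that a resident has a vehicle (core typically lower).
#' @param mean_unit_population Expected residents per demand unit
#'   (Poisson).
#' @param mean_capacity Expected providers per supply site (Poisson,
#'   floored at 1).
#' @param car_time_noise_sd SD of the lognormal multiplicative noise on
#'   car times (small, so car stays faster than bus for every pair).
#' @param seed Integer random seed; the scene is fully reproducible from it.
#' @return A validated list of class `scene_spec`.
#' @export
scene_spec <- function(n_supply = 293, n_demand = 543,
                       region_size = 60, core_radius = 8,
                       supply_core_fraction = 0.95,
                       demand_core_fraction = 0.45,
                       bus_service_radius = 10,
                       car_speed = 1.0, bus_speed = 0.3,
                       bus_overhead = 10,
                       vehicle_ownership_core = 0.75,
                       vehicle_ownership_periphery = 0.97,
                       mean_unit_population = 1600,
                       mean_capacity = 4,
                       car_time_noise_sd = 0.08,
                       seed = 42) {
  spec <- list(n_supply = n_supply, n_demand = n_demand,
               region_size = region_size, core_radius = core_radius,
               supply_core_fraction = supply_core_fraction,
               demand_core_fraction = demand_core_fraction,
               bus_service_radius = bus_service_radius,
               car_speed = car_speed, bus_speed = bus_speed,
               bus_overhead = bus_overhead,
               vehicle_ownership_core = vehicle_ownership_core,
               vehicle_ownership_periphery = vehicle_ownership_periphery,
               mean_unit_population = mean_unit_population,
               mean_capacity = mean_capacity,
               car_time_noise_sd = car_time_noise_sd,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_supply >= 1, n_demand >= 1, region_size > 0)
    if (car_speed <= 0 || bus_speed <= 0 || bus_speed >= car_speed)
      stop("need 0 < bus_speed < car_speed", call. = FALSE)
    if (bus_overhead < 0 || car_time_noise_sd < 0)
      stop("bus_overhead and car_time_noise_sd must be non-negative",
           call. = FALSE)
    for (p in c(supply_core_fraction, demand_core_fraction,
                vehicle_ownership_core, vehicle_ownership_periphery))
      if (p < 0 || p > 1) stop("fractions/probabilities must be in [0, 1]",
                               call. = FALSE)
    if (!(core_radius <= bus_service_radius &&
          bus_service_radius <= region_size))
      stop("need core_radius <= bus_service_radius <= region_size",
           call. = FALSE)
    if (mean_unit_population <= 0 || mean_capacity <= 0)
      stop("mean population and capacity must be positive", call. = FALSE)
  })
  structure(spec, class = "scene_spec")
}

# n points: `frac` uniform in the core disk, rest uniform in the square
sample_points <- function(n, frac, spec) {
  ctr <- spec$region_size / 2
  in_core <- stats::runif(n) < frac
  n_core <- sum(in_core)
  x <- stats::runif(n, 0, spec$region_size)
  y <- stats::runif(n, 0, spec$region_size)
  if (n_core > 0) {
    r <- spec$core_radius * sqrt(stats::runif(n_core))
    th <- stats::runif(n_core, 0, 2 * pi)
    x[in_core] <- ctr + r * cos(th)
    y[in_core] <- ctr + r * sin(th)
  }
  data.frame(x = x, y = y)
}

#' Generate a synthetic scene
#'
#' Draws supply and demand locations with core clustering, splits each
#' unit's Poisson population into car and bus riders by the local
#' vehicle-ownership probability (binomial, so the split is exactly
#' additive), and builds per-mode OD matrices: car time is Euclidean
#' distance over `car_speed` with small lognormal noise for every pair;
#' bus time is `bus_overhead + distance / bus_speed`, defined only when
#' both endpoints lie within `bus_service_radius` of the region center.
#' The RNG state of the caller is left untouched.
#'
#' @param spec A [scene_spec()].
#' @return An [scene()] with modes `car` and `bus`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  sup_xy <- sample_points(spec$n_supply, spec$supply_core_fraction, spec)
  dem_xy <- sample_points(spec$n_demand, spec$demand_core_fraction, spec)
  ctr <- spec$region_size / 2
  dist_ctr_dem <- sqrt((dem_xy$x - ctr)^2 + (dem_xy$y - ctr)^2)
  dist_ctr_sup <- sqrt((sup_xy$x - ctr)^2 + (sup_xy$y - ctr)^2)

  capacity <- pmax(1L, stats::rpois(spec$n_supply, spec$mean_capacity))
  pop_total <- stats::rpois(spec$n_demand, spec$mean_unit_population)
  own <- ifelse(dist_ctr_dem <= spec$core_radius,
                spec$vehicle_ownership_core,
                spec$vehicle_ownership_periphery)
  pop_car <- stats::rbinom(spec$n_demand, pop_total, own)
  pop_bus <- pop_total - pop_car

  sup_id <- sprintf("s%03d", seq_len(spec$n_supply))
  dem_id <- sprintf("u%03d", seq_len(spec$n_demand))
  supply <- data.frame(id = sup_id, capacity = capacity,
                       x = sup_xy$x, y = sup_xy$y, stringsAsFactors = FALSE)
  demand <- data.frame(id = dem_id, pop_car = pop_car, pop_bus = pop_bus,
                       x = dem_xy$x, y = dem_xy$y, stringsAsFactors = FALSE)

  # all-pairs Euclidean distances, demand rows x supply columns
  dd <- sqrt(outer(dem_xy$x, sup_xy$x, "-")^2 +
             outer(dem_xy$y, sup_xy$y, "-")^2)
  noise <- exp(stats::rnorm(length(dd), 0, spec$car_time_noise_sd))
  car_min <- as.vector(dd) / spec$car_speed * noise
  od_car <- data.frame(
    origin_id = rep(dem_id, times = spec$n_supply),
    dest_id = rep(sup_id, each = spec$n_demand),
    minutes = car_min, stringsAsFactors = FALSE)

  served <- outer(dist_ctr_dem <= spec$bus_service_radius,
                  dist_ctr_sup <= spec$bus_service_radius, "&")
  keep <- as.vector(served)
  od_bus <- data.frame(
    origin_id = od_car$origin_id[keep],
    dest_id = od_car$dest_id[keep],
    minutes = spec$bus_overhead + as.vector(dd)[keep] / spec$bus_speed,
    stringsAsFactors = FALSE)

  scene(supply, demand, list(car = od_car, bus = od_bus))
}

#' Reachability summary of a scene
#'
#' Per mode and catchment threshold: the fraction of demand units with
#' no supply site reachable within the threshold, and the mean number of
#' reachable sites among the units that can reach at least one.
#'
#' @inheritParams supply_ratio_multimodal
#' @return data.frame with columns `mode`, `threshold_min`,
#'   `frac_unreachable`, `mean_reachable_sites`.
#' @export
scene_summary <- function(sc, modes) {
  modes <- check_modes(sc, modes)
  do.call(rbind, lapply(names(modes), function(m) {
    o <- sc$od[[m]]
    o <- o[o$minutes <= modes[[m]]$threshold, , drop = FALSE]
    counts <- stats::setNames(numeric(nrow(sc$demand)), sc$demand$id)
    if (nrow(o) > 0) {
      tb <- table(o$origin_id)
      counts[names(tb)] <- as.numeric(tb)
    }
    data.frame(mode = m, threshold_min = modes[[m]]$threshold,
               frac_unreachable = mean(counts == 0),
               mean_reachable_sites = if (any(counts > 0))
                 mean(counts[counts > 0]) else 0,
               stringsAsFactors = FALSE)
  }))
}
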