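# Fixture builders. Random scenes are assembled with plain base R
# (independently of generate_scene) so access-core property tests do not
# lean on the synthetic-data module they also help validate.

# the 1x1 two-mode instance used in the hand-derived examples:
# one site (C = 10), one unit (pop_car = 100, pop_bus = 50),
# 5 car-minutes and 45 bus-minutes apart
tiny_scene <- function() {
  scene(
    supply = data.frame(id = "s1", capacity = 10),
    demand = data.frame(id = "u1", pop_car = 100, pop_bus = 50),
    od = list(
      car = data.frame(origin_id = "u1", dest_id = "s1", minutes = 5),
      bus = data.frame(origin_id = "u1", dest_id = "s1", minutes = 45)))
}

# random two-mode scene with sparse OD tables; some pairs unreachable,
# some beyond-catchment times retained to exercise the cutoff
random_scene <- function(n_sites, n_units, seed) {
  set.seed(seed)
  sup <- data.frame(id = sprintf("s%02d", seq_len(n_sites)),
                    capacity = rpois(n_sites, 5))
  pop <- rpois(n_units, 800)
  car <- rbinom(n_units, pop, 0.9)
  dem <- data.frame(id = sprintf("u%03d", seq_len(n_units)),
                    pop_car = car, pop_bus = pop - car)
  pairs <- expand.grid(origin_id = dem$id, dest_id = sup$id,
                       stringsAsFactors = FALSE)
  mk_od <- function(p_drop, tmax) {
    keep <- runif(nrow(pairs)) > p_drop
    data.frame(origin_id = pairs$origin_id[keep],
               dest_id = pairs$dest_id[keep],
               minutes = runif(sum(keep), 0, tmax),
               stringsAsFactors = FALSE)
  }
  scene(sup, dem, list(car = mk_od(0.3, 45), bus = mk_od(0.6, 90)))
}

# brute-force conservation sum: population-weighted total access vs the
# capacity of sites whose step-1 denominator is positive
conservation_gap <- function(sc, res) {
  lhs <- 0
  for (m in names(res$modes))
    lhs <- lhs + sum(sc$demand[[paste0("pop_", m)]] *
                       res$scores[[paste0("spai_", m)]])
  rhs <- sum(sc$supply$capacity[match(
    res$site_ratios$id[res$site_ratios$ratio > 0], sc$supply$id)])
  abs(lhs - rhs) / max(rhs, 1)
}

# small scene spec so synthetic-module tests stay fast
small_spec <- function(seed = 7, ...) {
  scene_spec(n_supply = 25, n_demand = 60, seed = seed, ...)
}

# fresh scratch directory under the session tempdir
tmp_dir <- function() {
  d <- tempfile("mmspar")
  dir.create(d)
  d
}
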