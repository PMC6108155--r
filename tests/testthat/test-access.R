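# Three-step multi-modal access pipeline and single-mode baseline.
# Hand-derived expectations were computed from the defining formulas with
# independent full-precision arithmetic before implementation.

test_that("step 1 reproduces the hand-derived 1x1 ratios", {
  modes <- default_modes()
  sc_car_only <- scene(
    supply = data.frame(id = "s1", capacity = 10),
    demand = data.frame(id = "u1", pop_car = 100, pop_bus = 0),
    od = list(car = data.frame(origin_id = "u1", dest_id = "s1", minutes = 5),
              bus = data.frame(origin_id = character(0),
                               dest_id = character(0), minutes = numeric(0))))
  r <- supply_ratio_multimodal(sc_car_only, modes)
  expect_equal(unname(r), 10 / (100 * exp(-25 / 140)), tolerance = 1e-12)
  expect_equal(round(unname(r), 5), 0.11955)

  r2 <- supply_ratio_multimodal(tiny_scene(), modes)
  expect_equal(unname(r2), 0.118838404659, tolerance = 1e-10)
})

test_that("a site with no in-catchment demand gets ratio 0", {
  sc <- scene(
    supply = data.frame(id = c("s1", "s2"), capacity = c(10, 7)),
    demand = data.frame(id = "u1", pop_car = 100, pop_bus = 0),
    od = list(car = data.frame(origin_id = c("u1", "u1"),
                               dest_id = c("s1", "s2"),
                               minutes = c(5, 95)),
              bus = data.frame(origin_id = character(0),
                               dest_id = character(0), minutes = numeric(0))))
  r <- supply_ratio_multimodal(sc, default_modes())
  expect_equal(unname(r["s2"]), 0)
})

test_that("step 2 reproduces the hand-derived 1x1 scores", {
  modes <- default_modes()
  sc <- tiny_scene()
  r <- supply_ratio_multimodal(sc, modes)
  a <- spai_multimodal(r, sc, modes)
  expect_equal(a$spai_car, 0.0994040838332, tolerance = 1e-10)
  expect_equal(a$spai_bus, 0.00119183233353, tolerance = 1e-10)
  expect_equal(a$spai_integrated, a$spai_car + a$spai_bus)
})

test_that("spar normalizes to mean one and flags the no-access case", {
  s <- spar(c(2, 4))
  expect_equal(as.numeric(s), c(2 / 3, 4 / 3))
  expect_equal(attr(s, "mean_spai"), 3)
  expect_equal(as.numeric(spar(rep(5, 7))), rep(1, 7))
  for (seed in 1:5) {
    set.seed(seed)
    x <- rgamma(50, 2)
    expect_equal(mean(spar(x)), 1, tolerance = 1e-12)
  }
  expect_warning(s0 <- spar(c(0, 0, 0)), "all SPAI are zero")
  expect_equal(as.numeric(s0), c(0, 0, 0))
  expect_true(attr(s0, "no_access"))
  expect_error(spar(numeric(0)), "non-empty")
  expect_error(spar(c(1, -1)), "non-negative")
})

test_that("run_access populates consistent fields on the 1x1 scene", {
  res <- run_access(tiny_scene(), default_modes())
  expect_s3_class(res, "mm_access")
  expect_equal(res$scores$spar_integrated, 1)
  expect_equal(res$scores$spar_car, 1)
  expect_equal(unname(res$mean_spai["integrated"]), 0.100595916167,
               tolerance = 1e-10)
})

test_that("conservation holds on random scenes up to 50x100", {
  for (cfg in list(c(5, 8, 1), c(20, 40, 2), c(50, 100, 3))) {
    sc <- random_scene(cfg[1], cfg[2], seed = cfg[3])
    res <- run_access(sc, default_modes())
    expect_lt(conservation_gap(sc, res), 1e-9)
    expect_true(all(res$scores$spai_integrated >= 0))
    expect_true(all(res$site_ratios$ratio >= 0))
    for (f in c("car", "bus", "integrated")) {
      sp <- res$scores[[paste0("spar_", f)]]
      if (res$mean_spai[f] > 0) expect_equal(mean(sp), 1, tolerance = 1e-12)
    }
  }
})

test_that("SPAR is invariant under capacity and population scaling", {
  sc <- random_scene(12, 30, seed = 11)
  res <- run_access(sc, default_modes())

  sc2 <- sc
  sc2$supply$capacity <- sc2$supply$capacity * 7
  res2 <- run_access(scene(sc2$supply, sc2$demand, sc2$od), default_modes())
  # SPAI scales linearly in capacity, SPAR unchanged
  expect_equal(res2$scores$spai_integrated, 7 * res$scores$spai_integrated,
               tolerance = 1e-12)
  for (f in c("spar_car", "spar_bus", "spar_integrated"))
    expect_equal(res2$scores[[f]], res$scores[[f]], tolerance = 1e-12)

  sc3 <- sc
  sc3$demand$pop_car <- sc3$demand$pop_car * 3
  sc3$demand$pop_bus <- sc3$demand$pop_bus * 3
  res3 <- run_access(scene(sc3$supply, sc3$demand, sc3$od), default_modes())
  for (f in c("spar_car", "spar_bus", "spar_integrated"))
    expect_equal(res3$scores[[f]], res$scores[[f]], tolerance = 1e-12)
})

test_that("permuting demand rows leaves per-id scores unchanged", {
  sc <- random_scene(10, 25, seed = 5)
  res <- run_access(sc, default_modes())
  set.seed(99)
  perm <- sample(nrow(sc$demand))
  sc_p <- scene(sc$supply, sc$demand[perm, , drop = FALSE], sc$od)
  res_p <- run_access(sc_p, default_modes())
  ix <- match(res$scores$id, res_p$scores$id)
  expect_equal(res_p$scores$spai_integrated[ix], res$scores$spai_integrated)
  expect_equal(res_p$scores$spar_car[ix], res$scores$spar_car)
})

test_that("adding a supply site never decreases any SPAI", {
  sc <- random_scene(8, 20, seed = 21)
  res <- run_access(sc, default_modes())
  sup2 <- rbind(sc$supply, data.frame(id = "s99", capacity = 5))
  od2 <- sc$od
  od2$car <- rbind(od2$car, data.frame(origin_id = sc$demand$id,
                                       dest_id = "s99",
                                       minutes = runif(nrow(sc$demand), 0, 40)))
  res2 <- run_access(scene(sup2, sc$demand, od2), default_modes())
  for (f in c("spai_car", "spai_bus", "spai_integrated"))
    expect_true(all(res2$scores[[f]] - res$scores[[f]] >= -1e-14))
})

test_that("single-mode baseline matches the classic formulas", {
  # 1 site C=10, 1 unit P=100 at 15 min, beta=140:
  # R = 10 / (100 exp(-225/140)) = 0.498854, A = R * W = 0.1 exactly
  sc <- scene(
    supply = data.frame(id = "s1", capacity = 10),
    demand = data.frame(id = "u1", pop_car = 100, pop_bus = 0),
    od = list(car = data.frame(origin_id = "u1", dest_id = "s1", minutes = 15),
              bus = data.frame(origin_id = character(0),
                               dest_id = character(0), minutes = numeric(0))))
  res <- e2sfca_single_mode(sc, default_modes()$car)
  expect_equal(res$site_ratios$ratio, 0.498853788167, tolerance = 1e-10)
  expect_equal(res$scores$spai_car, 0.1, tolerance = 1e-12)

  # a genuinely single-mode scene: baseline == multi-modal pipeline, bitwise
  sc1 <- scene(sc$supply,
               data.frame(id = "u1", pop_car = 100),
               sc$od["car"])
  expect_identical(run_access(sc1, list(default_modes()$car))$scores,
                   e2sfca_single_mode(sc1, default_modes()$car)$scores)
})

test_that("continuous weighting is accepted as an alternative", {
  sc <- tiny_scene()
  res <- run_access(sc, default_modes(), weighting = "continuous")
  # exact-time kernel, not the stepped representative-time one
  expect_equal(unname(res$mean_spai["car"]),
               10 / (100 * exp(-25 / 140) + 50 * exp(-2025 / 440)) *
                 exp(-25 / 140),
               tolerance = 1e-12)
})

test_that("validation errors are raised for malformed scenes", {
  expect_error(scene(data.frame(id = c("a", "a"), capacity = c(1, 2)),
                     data.frame(id = "u", pop_car = 1),
                     list(car = data.frame(origin_id = "u", dest_id = "a",
                                           minutes = 1))),
               "duplicate supply ids")
  expect_error(scene(data.frame(id = "s", capacity = -1),
                     data.frame(id = "u", pop_car = 1),
                     list(car = data.frame(origin_id = "u", dest_id = "s",
                                           minutes = 1))),
               "non-negative")
  expect_error(scene(data.frame(id = "s", capacity = 1),
                     data.frame(id = "u", pop_car = -5),
                     list(car = data.frame(origin_id = "u", dest_id = "s",
                                           minutes = 1))),
               "population")
  expect_error(scene(data.frame(id = "s", capacity = 1),
                     data.frame(id = "u", pop_car = 5),
                     list(car = data.frame(origin_id = "zz", dest_id = "s",
                                           minutes = 1))),
               "unknown demand id")
  sc <- tiny_scene()
  expect_error(run_access(sc, list(default_modes()$car)), "no mode_spec")
})
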