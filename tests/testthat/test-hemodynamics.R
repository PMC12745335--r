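test_that("total resistance is SBP/flow with validation", {
  expect_equal(round(total_resistance(159, 25.00), 2), 6.36)
  expect_equal(round(total_resistance(119, 8.89), 2), 13.39)
  expect_equal(round(total_resistance(147, 26.64), 2), 5.52)
  expect_equal(round(total_resistance(168, 25.00), 2), 6.72)
  expect_equal(total_resistance(100, 1), 100)
  expect_error(total_resistance(-1, 5), "positive")
})

test_that("1/7 power-law inlet: mean/peak ratio, flow conversion, profile", {
  inl <- inlet_from_velocity(radius = 12.5, flow = 25)
  expect_equal(inl$mean_velocity / inl$peak_velocity, 49 / 60,
               tolerance = 1e-12)
  expect_equal(inl$flow * 1000 / 60, 416.667, tolerance = 1e-3)  # mL/s
  expect_equal(inl$profile(1), 0)
  expect_equal(inl$profile(0), inl$peak_velocity)
  ## forward mode round-trips the inverse mode
  fwd <- inlet_from_velocity(peak_velocity = inl$peak_velocity,
                             radius = 12.5)
  expect_equal(fwd$flow, 25, tolerance = 1e-9)
})

test_that("Murray allocation: conductance by area, parallel recombination", {
  one <- allocate_outlets(7.5, areas = 42)
  expect_equal(one$resistance, 7.5)

  two <- allocate_outlets(5, areas = c(10, 10))
  expect_equal(two$resistance, c(10, 10))

  split <- allocate_outlets(4, areas = c(1, 3))
  expect_equal(split$resistance, c(16, 16 / 3), tolerance = 1e-12)

  set.seed(3)
  for (i in 1:10) {
    areas <- runif(sample(2:6, 1), 5, 200)
    R <- runif(1, 2, 20)
    out <- allocate_outlets(R, areas)
    expect_lt(abs(1 / sum(1 / out$resistance) - R) / R, 1e-9)
  }
  expect_error(allocate_outlets(5, numeric(0)), "empty")
})

test_that("network: series drop, Poiseuille WSS, flow conservation", {
  sc <- tube_scene()  # straight tube, single distal outlet
  st <- tube_structured()
  inl <- inlet_from_velocity(radius = 15, flow = 25)
  out <- allocate_outlets(total_resistance(120, 25), sc$outlets$area)
  fld <- solve_network(sc, inl, out, structured = st)

  ## single-outlet series circuit: inlet pressure = Q * (R_segments + R_out)
  seg_R <- (fld$p_true[1] - fld$p_true[length(fld$p_true)]) / 25
  expect_equal(fld$p_true[length(fld$p_true)], 25 * out$resistance[1],
               tolerance = 1e-6)
  expect_true(all(diff(fld$p_true) <= 1e-12))  # monotone along the tube

  ## flow conservation: outlet flows sum to the inlet flow
  q_out <- fld$p_true[length(fld$p_true)] / out$resistance[1]
  expect_lt(abs(q_out - 25) / 25, 1e-9)

  ## WSS closed form 4 mu Q / (pi r^3)
  expect_equal(aortagrowth:::wss_poiseuille(25, 12.5, 0.004),
               4 * 0.004 * (25 / 60000) / (pi * 0.0125^3),
               tolerance = 1e-12)
  expect_true(all(fld$wss_pa >= 0))
  expect_true(all(fld$pressure_mmhg <= fld$p_true[1] + 1e-9))

  ## disconnected false lumen: stagnation pressure + warning
  sc_seal <- make_dissected_aorta(tears = NULL, seed = 2)
  st_seal <- parameterize_surface(sc_seal, n_layers = 60, n_nodes = 24)
  out2 <- allocate_outlets(6.36, sc_seal$outlets$area)
  expect_warning(f2 <- solve_network(sc_seal, inl, out2,
                                     structured = st_seal), "tear")
  fl <- is.finite(f2$p_false)
  expect_true(all(abs(f2$p_false[fl] - f2$p_false[which(fl)[1]]) < 1e-9))
})

test_that("resistance tuning reaches 2% MAPE; adjustment sign patterns", {
  sc <- dissected_scene()
  st <- dissected_structured()
  inl <- inlet_from_velocity(radius = 15, flow = 25)
  tun <- tune_total_resistance(sc, inl, target_sbp = 159, structured = st)
  expect_lte(tun$achieved_mape, 0.02)
  ## wide lumen, negligible internal drop: tuned ~ calculated
  expect_lt(abs(tun$adjustment_percent), 5)

  ## narrow lumen, large internal drop: tuned < calculated
  sc_n <- make_dissected_aorta(radius = 5.5, length = 400, arch_radius = 35,
                               taper = 0.2, flap = NULL, tears = NULL,
                               outlets = data.frame(s = c(300, 400),
                                                    area = c(20, 40)),
                               landmark_arclength = 97, seed = 6)
  st_n <- parameterize_surface(sc_n, n_layers = 60, n_nodes = 24)
  inl_n <- inlet_from_velocity(radius = 5.5, flow = 18)
  tun_n <- tune_total_resistance(sc_n, inl_n, target_sbp = 130,
                                 structured = st_n)
  expect_lte(tun_n$achieved_mape, 0.02)
  expect_lt(tun_n$adjustment_percent, -1)
})

test_that("lumen pressure summary: degenerate, closed-form t, antisymmetry", {
  mk <- function(tl, fl) list(pressure_mmhg = c(tl, fl),
                              lumen = c("true", "false"))
  same <- lapply(c(100, 120, 140), function(p) mk(p, p))
  s0 <- lumen_pressure_summary(same)
  expect_equal(s0$t_test$statistic, 0)
  expect_equal(s0$t_test$p.value, 1)

  ## differences (1, 2, 3): t = mean/SE = 2 / (1/sqrt(3)), p from t_2
  flds <- Map(function(tl, fl) mk(tl, fl),
              c(101, 122, 143), c(100, 120, 140))
  s1 <- lumen_pressure_summary(flds)
  t_hand <- 2 / (sd(1:3) / sqrt(3))
  expect_equal(s1$t_test$statistic, t_hand, tolerance = 1e-9)
  expect_equal(s1$t_test$p.value, 2 * pt(-t_hand, df = 2), tolerance = 1e-9)

  swapped <- Map(function(tl, fl) mk(fl, tl),
                 c(101, 122, 143), c(100, 120, 140))
  s2 <- lumen_pressure_summary(swapped)
  expect_equal(s2$t_test$statistic, -s1$t_test$statistic, tolerance = 1e-9)
  expect_equal(s2$t_test$p.value, s1$t_test$p.value, tolerance = 1e-9)
  expect_error(lumen_pressure_summary(same[1]), "2 patients")
})
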