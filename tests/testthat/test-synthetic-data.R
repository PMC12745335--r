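test_that("undissected straight tube has constant 30 mm cross-sections", {
  st <- tube_structured()
  d <- layer_diameters(st)
  expect_true(all(abs(d - 30) < 0.05))  # chordal sampling tolerance
})

test_that("scene generation is deterministic for a fixed seed", {
  a <- make_dissected_aorta(seed = 3, radius_noise = 0.04)
  b <- make_dissected_aorta(seed = 3, radius_noise = 0.04)
  expect_identical(a$outer_surface$vertices, b$outer_surface$vertices)
  expect_identical(a$flap_surface$vertices, b$flap_surface$vertices)
  c_ <- make_dissected_aorta(seed = 4, radius_noise = 0.04)
  expect_false(identical(a$outer_surface$vertices,
                         c_$outer_surface$vertices))
})

test_that("flap Euler characteristic counts tears", {
  base <- list(seed = 2)
  sc0 <- make_dissected_aorta(tears = NULL, seed = 2)
  sc1 <- make_dissected_aorta(tears = data.frame(s = 200, w = 0, radius = 8),
                              seed = 2)
  sc2 <- make_dissected_aorta(seed = 2)  # two default tears
  expect_identical(euler_characteristic(sc0$flap_surface), 1L)  # disc
  expect_identical(euler_characteristic(sc1$flap_surface), 0L)  # one hole
  expect_identical(euler_characteristic(sc2$flap_surface), -1L) # two holes
})

test_that("flap boundary vertices lie on the outer surface", {
  sc <- dissected_scene()
  fv <- sc$flap_surface$vertices
  nn <- aortagrowth:::nn_index(fv, sc$outer_surface$vertices)
  ## the chord-endpoint columns coincide with outer-surface vertices
  ## (two per flap layer; tears only remove interior vertices); 1e-5
  ## absorbs the cancellation error of the expanded distance formula at
  ## coordinates ~10^2 mm from the origin
  n_edge <- sum(nn$dist < 1e-5)
  expect_gte(n_edge, 2L * length(sc$flap_surface$s))
  ## interior flap vertices are strictly inside the lumen
  expect_gt(max(nn$dist), 1)
})

test_that("invalid scene specs error", {
  expect_error(make_dissected_aorta(radius = -1), "positive")
  expect_error(make_dissected_aorta(
    tears = data.frame(s = 200, w = 0, radius = 20)), "tear")
  expect_error(make_dissected_aorta(
    flap = NULL, tears = NULL,
    thrombus = list(s_range = c(200, 300), frac = 0.5, thickness = 5)),
    "flap")
})

test_that("grow_aorta: identity, similarity, and analytic ramp", {
  sc <- tube_scene()
  same <- grow_aorta(sc, growth_field(1.0, duration = 1))
  expect_equal(same$outer_surface$vertices, sc$outer_surface$vertices,
               tolerance = 1e-12)

  grown <- grow_aorta(sc, growth_field(1.1, duration = 1))
  d <- layer_diameters(parameterize_surface(grown, n_layers = 50,
                                            n_nodes = 50))
  expect_true(all(abs(d - 33) < 0.06))

  ramp <- function(s) 1 + 0.2 / (1 + exp(-(s - 100) / 15))
  grown2 <- grow_aorta(sc, growth_field(ramp, duration = 2))
  st2 <- parameterize_surface(grown2, n_layers = 50, n_nodes = 50)
  d2 <- layer_diameters(st2)
  expect_true(all(abs(d2 / 30 - ramp(st2$s)) < 0.005))

  expect_error(grow_aorta(sc, growth_field(function(s) s - 1e9, 1)),
               "positive")
})

test_that("make_cohort: noise-free limit, determinism, OLS slope recovery", {
  spec0 <- cohort_spec(beta0 = 0, beta1 = 0.1, sd_b0 = 0, sd_b1 = 0,
                       sd_eps = 0, seed = 3)
  co0 <- make_cohort(spec0)
  expect_equal(co0$growth_pct_per_year, 0.1 * co0$stress_kpa,
               tolerance = 1e-12)

  expect_identical(make_cohort(cohort_spec(seed = 5)),
                   make_cohort(cohort_spec(seed = 5)))

  ## pooled OLS slope vs closed-form sampling SD under the generative model
  spec <- cohort_spec(seed = 17)  # beta1 = 0.095, sd_b0 27.8, sd_b1 0.13
  co <- make_cohort(spec)
  x <- co$stress_kpa; y <- co$growth_pct_per_year
  w <- (x - mean(x)) / sum((x - mean(x))^2)
  slope <- sum(w * y)
  ids <- unique(co$patient_id)
  v <- spec$sd_eps^2 * sum(w^2) +
    spec$sd_b0^2 * sum(vapply(ids, function(m)
      sum(w[co$patient_id == m])^2, numeric(1))) +
    spec$sd_b1^2 * sum(vapply(ids, function(m)
      sum((w * x)[co$patient_id == m])^2, numeric(1)))
  expect_lt(abs(slope - spec$beta1), 3 * sqrt(v))
})

test_that("cohort sample moments match spec moments at 1e4 points", {
  ## constant stress turns the model into an i.i.d. normal mixture whose
  ## pooled moments are available in closed form
  x0 <- 200
  spec <- cohort_spec(n_patients = 264L, beta0 = 5, beta1 = 0.05,
                      sd_b0 = 10, sd_b1 = 0.05, sd_eps = 8, seed = 9)
  co <- make_cohort(spec, stress_generator = function(m, k) rep(x0, k))
  g <- co$growth_pct_per_year
  n <- length(g)
  mu <- spec$beta0 + spec$beta1 * x0
  sig2 <- spec$sd_b0^2 + x0^2 * spec$sd_b1^2 + spec$sd_eps^2
  expect_gt(n, 1e4 - 1)
  expect_lt(abs(mean(g) - mu), 3 * sqrt(sig2 / spec$n_patients))  # clustered
  expect_lt(abs(sd(g) - sqrt(sig2)) / sqrt(sig2), 0.1)
})

test_that("cylinder fixture construction and validation", {
  cyl <- make_cylinder_fixture(r = 15, t = 2, L = 100, n_layers = 4,
                               n_circ = 24, n_axial = 10)
  expect_identical(nrow(cyl$elems), 24L * 10L * 4L)
  rr <- sqrt(rowSums(cyl$nodes[, 1:2]^2))
  expect_lt(abs(min(rr) - 15), 1e-9)
  expect_lt(abs(max(rr) - 17), 1e-9)
  expect_error(make_cylinder_fixture(r = 2, t = 2, L = 10), "thickness")
  expect_error(make_cylinder_fixture(r = 15, t = 2, L = 0), "positive")
})
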