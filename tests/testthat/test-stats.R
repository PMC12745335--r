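test_that("fit_lme: noise-free limit and balanced two-patient toy", {
  set.seed(2)
  pid <- rep(paste0("P", 1:4), each = 20)
  x <- rnorm(80, 100, 30)
  f <- suppressWarnings(fit_lme(x, 2 * x + 1, pid))
  expect_equal(f$beta$estimate[f$beta$term == "(Intercept)"], 1,
               tolerance = 1e-6)
  expect_equal(f$beta$estimate[f$beta$term == "x"], 2, tolerance = 1e-6)
  expect_lt(f$sd_b0 + f$sd_b1 + f$sd_eps, 1e-4)

  xx <- rep(seq(-2, 2, length.out = 10), 2)
  pp <- rep(c("a", "b"), each = 10)
  yy <- ifelse(pp == "a", xx, 3 * xx)
  f2 <- suppressWarnings(fit_lme(xx, yy, pp))
  expect_equal(f2$beta$estimate[f2$beta$term == "x"], 2, tolerance = 1e-6)
  expect_equal(sort(f2$blup$b1), c(-1, 1), tolerance = 1e-4)

  expect_error(fit_lme(x, 2 * x, rep("P1", 80)), "2 patients")
  expect_error(fit_lme(rep(1, 80), rnorm(80), pid), "distinct")
})

test_that("fit_lme reporting invariants: AIC/BIC identities, CIs, options", {
  co <- make_cohort(cohort_spec(seed = 21))
  f <- fit_lme(co$stress_kpa, co$growth_pct_per_year, co$patient_id)
  k <- attr(logLik(f$model), "df")
  expect_equal(f$AIC, -2 * f$logLik + 2 * k, tolerance = 1e-9)
  expect_equal(f$BIC, -2 * f$logLik + k * log(f$n_obs), tolerance = 1e-9)
  b <- f$beta
  expect_true(all(b$lower <= b$estimate & b$estimate <= b$upper))
  expect_identical(f$n_obs, 342L)
  expect_identical(f$n_patients, 9L)
  expect_identical(f$df_residual, 342L - 2L - 18L)

  ## residual-df option changes only the denominator df
  ft_res <- ftest_fixed_slope(f, df = "residual")
  ft_sat <- ftest_fixed_slope(f)
  expect_equal(ft_res$F, ft_sat$F)
  expect_identical(ft_res$df2, 322L)

  ## quadratic and covariate variants carry the extra fixed effect
  fq <- fit_lme(co$stress_kpa, co$growth_pct_per_year, co$patient_id,
                quadratic = TRUE)
  expect_true("I(x^2)" %in% fq$beta$term)
  fc <- fit_lme(co$stress_kpa, co$growth_pct_per_year, co$patient_id,
                covariate = rep(runif(9, 1, 5), each = 38))
  expect_true("cov" %in% fc$beta$term)

  ## profile CIs for the random-effect SDs contain the point estimates
  fs <- fit_lme(co$stress_kpa, co$growth_pct_per_year, co$patient_id,
                sd_ci = TRUE)
  expect_false(is.null(fs$sd_ci))
  expect_true(fs$sd_ci[".sig01", 1] <= fs$sd_b0 &&
                fs$sd_b0 <= fs$sd_ci[".sig01", 2])
})

test_that("likelihood invariant to patient relabeling and row order", {
  co <- make_cohort(cohort_spec(seed = 31))
  f1 <- fit_lme(co$stress_kpa, co$growth_pct_per_year, co$patient_id)
  relab <- factor(co$patient_id,
                  labels = sample(LETTERS[1:9]))
  f2 <- fit_lme(co$stress_kpa, co$growth_pct_per_year, as.character(relab))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  ord <- sample(nrow(co))
  f3 <- fit_lme(co$stress_kpa[ord], co$growth_pct_per_year[ord],
                co$patient_id[ord])
  expect_equal(f1$beta$estimate, f3$beta$estimate, tolerance = 1e-6)
})

test_that("F-test: zero slope, monotone tail, zero-SE error", {
  fake <- structure(list(
    beta = data.frame(term = "x", estimate = 0, se = 0.05, df = 20),
    df_method = "satterthwaite", df_residual = 100), class = "growth_lme")
  ft <- ftest_fixed_slope(fake)
  expect_equal(ft$F, 0)
  expect_equal(ft$p, 1)

  ps <- vapply(c(0.01, 0.05, 0.1, 0.2), function(b) {
    fake$beta$estimate <- b
    ftest_fixed_slope(fake)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  fake$beta$se <- 0
  expect_error(ftest_fixed_slope(fake), "zero")
})

test_that("fixed-effects-only and mixed slopes agree when sds are zero", {
  spec <- cohort_spec(beta1 = 0.08, sd_b0 = 0, sd_b1 = 0, sd_eps = 6,
                      seed = 12)
  co <- make_cohort(spec)
  f <- suppressWarnings(fit_lme(co$stress_kpa, co$growth_pct_per_year,
                                co$patient_id))
  expect_lt(abs(f$beta$estimate[f$beta$term == "x"] -
                  unname(f$fixed_only$beta["x"])), 0.01)
})

test_that("quadratic term with true beta2 = 0 barely moves AIC", {
  ## adding x^2 when the generative model is linear should not
  ## substantially improve AIC
  d_aic <- vapply(1:20, function(s) {
    co <- make_cohort(cohort_spec(seed = 100 + s))
    f1 <- suppressWarnings(fit_lme(co$stress_kpa, co$growth_pct_per_year,
                                   co$patient_id))
    f2 <- suppressWarnings(fit_lme(co$stress_kpa, co$growth_pct_per_year,
                                   co$patient_id, quadratic = TRUE))
    f2$AIC - f1$AIC
  }, numeric(1))
  expect_lt(abs(mean(d_aic)), 2)
})

test_that("pearson_by_patient: exact, affine-invariant, degenerate", {
  pid <- rep(c("A", "B"), each = 10)
  x <- rep(1:10, 2)
  tab <- pearson_by_patient(x, x, pid)
  expect_equal(tab$r, c(1, 1))

  set.seed(5)
  y <- rnorm(20)
  t1 <- pearson_by_patient(x, y, pid)
  t2 <- pearson_by_patient(3 * x - 7, y, pid)
  expect_equal(t1$r, t2$r, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)

  xz <- c(rep(1, 10), 1:10)
  tz <- pearson_by_patient(xz, y, pid)
  expect_true(tz$degenerate[1])
  expect_true(is.na(tz$r[1]))
  expect_error(pearson_by_patient(1:4, 1:4, c("A", "A", "B", "B")),
               "3 points")
})

test_that("thrombus presence and region indicator rules", {
  st <- ring_surface(rep(10, 40), landmark = 11)

  ## no thrombus: all absent
  expect_true(all(thrombus_presence(st, NULL) == 0))

  ## a thrombus node on the surface marks its node present
  node <- matrix(st$nodes[20, 5, ], 1)
  pres <- thrombus_presence(st, node)
  expect_identical(pres[20, 5], 1L)

  ## centroid farther than the max radius from every node: all absent
  far <- matrix(c(500, 500, 500), 1)
  expect_true(all(thrombus_presence(st, far) == 0))

  ## hemi-annular thrombus: the radius-threshold rule marks every node of
  ## the constructed wedge present, dilates by construction (any node
  ## within one local radius of the wedge also qualifies: 2r sin(dtheta/2)
  ## < r up to dtheta = 60 degrees), and dies off beyond that reach
  sc <- dissected_scene()
  stc <- dissected_structured()
  pres2 <- thrombus_presence(stc, sc$thrombus$nodes)
  r_loc <- 12  # descending local radius, mm
  in_span <- stc$s >= 240 & stc$s <= 340
  near <- stc$s >= 240 - 1.2 * r_loc & stc$s <= 340 + 1.2 * r_loc
  ## nodes radially opposite the wedge within the span: angular distance
  ## > 60 degrees from the wedge edge -> absent; nodes on the wedge ->
  ## present. Check via the wedge's own sector angles.
  expect_gt(mean(pres2[in_span, ]), 0.5)    # wedge + one-radius dilation
  expect_lt(mean(pres2[in_span, ]), 1.0)    # far side of the ring absent
  expect_equal(mean(pres2[!near, ]), 0, tolerance = 1e-12)

  ## strict > 0.5 rule on a clean 4-layer partition (exact averages)
  part4 <- partition_regions(40, landmark_layer = 9, n_regions = 10,
                             n_ascending = 2)
  pm_06 <- matrix(0, 40, 50); pm_06[9:12, 1:30] <- 1     # average 0.6
  pm_05 <- matrix(0, 40, 50); pm_05[9:12, 1:25] <- 1     # average exactly 0.5
  expect_identical(thrombus_region_indicator(pm_06, part4)[1], 1L)
  expect_identical(thrombus_region_indicator(pm_05, part4)[1], 0L)
  expect_true(all(thrombus_region_indicator(matrix(0, 40, 50), part4) == 0L))
})
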