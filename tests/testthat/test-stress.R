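test_that("single-hex patch test reproduces constant stress to 1e-8", {
  ## unit cube, pressure p on the top face, bottom held axially:
  ## sigma_zz = -p uniformly, all other components zero
  nodes <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))[
    c(1, 2, 4, 3, 5, 6, 8, 7), ]
  elems <- matrix(1:8, 1)
  lf <- list(faces = matrix(c(5, 6, 7, 8), 1),
             into_solid = matrix(c(0, 0, -1), 1), lumen = "true")
  solid <- aortagrowth:::new_solid_mesh(nodes, elems, "wall", lf,
                                        list(end1 = 1L, end2 = 1L))
  ## bottom uz, plus minimal in-plane pins
  fixed <- c(3 * (1:4 - 1) + 3,        # uz of bottom nodes
             3 * (1 - 1) + 1:2,        # node 1 in-plane
             3 * (2 - 1) + 2)          # node 2 y (blocks rotation)
  p <- 10
  sf <- forward_penalty_stress(solid, p, material_spec(E_wall = 1000),
                               fixed_ends = fixed)
  sig <- sf$element_stress[1, ]
  expect_lt(abs(sig[3] + p) / p, 1e-8)           # sigma_zz = -p
  expect_lt(max(abs(sig[c(1, 2, 4, 5, 6)])), 1e-8 * p)
})

test_that("forward penalty: zero load, linearity, static determinacy", {
  cyl <- laplace_cylinder()
  blocks <- aortagrowth:::stiffness_blocks(cyl, 0.3)

  s0 <- forward_penalty_stress(cyl, 0, fixed_ends = "ends_axial",
                               unit_blocks = blocks)
  expect_equal(max(abs(s0$element_stress)), 0)
  expect_equal(max(abs(s0$displacement)), 0)

  p120 <- 120 * 0.133322
  s1 <- forward_penalty_stress(cyl, p120, fixed_ends = "ends_axial",
                               unit_blocks = blocks)
  s2 <- forward_penalty_stress(cyl, p120,
                               material_spec(E_wall = 1e6,
                                             E_thrombus = 5e4),
                               fixed_ends = "ends_axial",
                               unit_blocks = blocks)
  ## uniform stiffness rescaling: stress identical, displacement halved
  expect_equal(s2$element_stress, s1$element_stress, tolerance = 1e-13)
  expect_equal(s2$displacement, s1$displacement / 2, tolerance = 1e-12)
})

test_that("pressure mapping: uniform, flap superposition, axial ramp", {
  solid <- dissected_solid()
  pts <- solid$nodes[solid$meta$outer_nodes, , drop = FALSE]

  uni <- list(points = pts, pressure_mmhg = rep(120, nrow(pts)),
              lumen = rep("true", nrow(pts)))
  tr_u <- map_pressure_to_solid(uni, solid)
  expect_true(all(abs(tr_u - 120 * 0.133322) < 1e-9))

  ## distinct lumen pressures: flap faces see their own lumen (120 vs 110)
  two <- list(points = rbind(pts, pts),
              pressure_mmhg = c(rep(120, nrow(pts)), rep(110, nrow(pts))),
              lumen = c(rep("true", nrow(pts)), rep("false", nrow(pts))))
  tr2 <- map_pressure_to_solid(two, solid)
  expect_true(all(abs(tr2[solid$load_faces$lumen == "true"] -
                        120 * 0.133322) < 1e-9))
  expect_true(all(abs(tr2[solid$load_faces$lumen == "false"] -
                        110 * 0.133322) < 1e-9))

  ## linear axial pressure ramp is reproduced at the facets
  ramp <- list(points = pts, pressure_mmhg = 100 + 0.1 * pts[, 3],
               lumen = rep("true", nrow(pts)))
  tr_r <- map_pressure_to_solid(ramp, solid)
  ctr <- aortagrowth:::facet_centers(solid$nodes, solid$load_faces$faces)
  sel <- solid$load_faces$lumen == "true"
  expect_lt(max(abs(tr_r[sel] / 0.133322 - (100 + 0.1 * ctr[sel, 3]))), 1.5)
  expect_error(map_pressure_to_solid(list(points = pts[0, , drop = FALSE]),
                                     solid), "empty")
})

test_that("regional stiffness sensitivity is below 10% MAPE", {
  solid <- dissected_solid()
  tract <- dissected_tractions()
  sens <- stiffness_sensitivity(solid, tract,
                                structured = dissected_structured())
  expect_true(all(sens$mape_percent <= 10))
  expect_setequal(unique(sens$region),
                  c("wall_tl", "wall_fl", "flap", "thrombus"))
  ## scaling every region by the same factor is exact (uniform rescale)
  blocks <- aortagrowth:::stiffness_blocks(solid, 0.3)
  ref <- forward_penalty_stress(solid, tract, unit_blocks = blocks)
  all_half <- forward_penalty_stress(
    solid, tract, unit_blocks = blocks,
    region_factors = c(wall_tl = 0.5, wall_fl = 0.5, flap = 0.5,
                       thrombus = 0.5))
  expect_equal(all_half$element_stress, ref$element_stress,
               tolerance = 1e-12)
})

test_that("stress registration: copy, uniform field, axial gradient", {
  cyl <- laplace_cylinder()
  sf <- forward_penalty_stress(cyl, 2, fixed_ends = "ends_axial")

  ## structured surface coincident with the outer solid nodes
  outer <- cyl$meta$outer_nodes
  nl <- cyl$meta$n_axial + 1L; nn_ <- cyl$meta$n_circ
  st <- ring_surface(rep(16, nl), n_nodes = nn_,
                     z = seq(0, 100, length.out = nl))
  ## rebuild exact node positions from the solid mesh ordering
  pos <- cyl$nodes[outer, ]
  ord <- order(round(pos[, 3], 9), atan2(pos[, 2], pos[, 1]) %% (2 * pi))
  for (j in seq_len(nl)) {
    st$nodes[j, , ] <- pos[ord[(j - 1L) * nn_ + seq_len(nn_)], ]
  }
  reg <- register_stress_to_structured(sf, st)
  vals <- sf$node_max_principal[outer]
  expect_equal(sort(as.vector(reg)), sort(vals), tolerance = 1e-12)

  ## uniform synthetic field maps to a uniform structured field
  sf_u <- sf
  sf_u$node_max_principal <- rep(42, nrow(cyl$nodes))
  expect_true(all(register_stress_to_structured(sf_u, st) == 42))

  ## linear axial field reproduces the gradient within one element spacing
  sf_g <- sf
  sf_g$node_max_principal <- 5 + 2 * cyl$nodes[, 3]
  reg_g <- register_stress_to_structured(sf_g, st)
  expect_lt(max(abs(sweep(reg_g, 1, 5 + 2 * st$s))), 2 * (100 / 24) + 1e-9)
})

test_that("mesh refinement changes max von Mises by under 2%", {
  ## halve the in-plane element size at fixed transmural layering (the
  ## transmural sampling points must match for a like-for-like comparison)
  coarse <- make_cylinder_fixture(r = 14, t = 2, L = 100, n_layers = 4,
                                  n_circ = 24, n_axial = 12)
  fine <- laplace_cylinder()  # 4 layers, 48 x 24
  p <- 16
  s_c <- forward_penalty_stress(coarse, p, fixed_ends = "ends_axial")
  s_f <- forward_penalty_stress(fine, p, fixed_ends = "ends_axial")
  mid_vm <- function(solid, sf) {
    cen_z <- vapply(seq_len(nrow(solid$elems)), function(e)
      mean(solid$nodes[solid$elems[e, ], 3]), numeric(1))
    max(sf$element_von_mises[cen_z > 30 & cen_z < 70])
  }
  v1 <- mid_vm(coarse, s_c); v2 <- mid_vm(fine, s_f)
  expect_lt(abs(v2 - v1) / v1, 0.02)
})
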