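test_that("parameterization: tube radii, cone linearity, idempotence", {
  st <- tube_structured()
  for (j in c(1, 25, 50, 75, 100)) {
    rel <- sweep(matrix(st$nodes[j, , ], 50, 3), 2, st$layer_centers[j, ])
    expect_true(all(abs(sqrt(rowSums(rel^2)) - 15) < 0.02))
  }

  cone <- make_dissected_aorta(radius = 10, length = 200, arch_radius = 0,
                               taper = -1, flap = NULL, tears = NULL,
                               landmark_arclength = 50, n_axial = 120,
                               n_circ = 64, seed = 1)
  stc <- parameterize_surface(cone, n_layers = 80, n_nodes = 50)
  analytic <- 2 * 10 * (1 + stc$s / 200)
  expect_true(all(abs(layer_diameters(stc) - analytic) / analytic < 0.002))

  ## re-parameterizing an already-structured surface leaves nodes in place
  nl <- st$n_layers; nn_ <- st$n_nodes
  v <- matrix(aperm(st$nodes, c(2, 1, 3)), nl * nn_, 3)
  vid <- function(i, j) (i - 1L) * nn_ + ((j - 1L) %% nn_) + 1L
  fs <- do.call(rbind, lapply(seq_len(nl - 1L), function(i) {
    j <- seq_len(nn_)
    rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j + 1L)),
          cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i + 1L, j)))
  }))
  st2 <- parameterize_surface(list(vertices = v, faces = fs),
                              centerline = tube_scene()$centerline,
                              n_layers = nl, n_nodes = nn_)
  expect_lt(max(abs(st2$nodes - st$nodes)), 1e-9)
})

test_that("local frames: orthonormal, right-handed, tangent-following", {
  st <- tube_structured()
  fr <- st$frames
  for (j in c(1, 50, 100)) {
    R <- matrix(fr$radial[j, , ], 50, 3)
    C <- matrix(fr$circumferential[j, , ], 50, 3)
    A <- matrix(fr$axial[j, , ], 50, 3)
    expect_lt(max(abs(rowSums(R * C))), 1e-8)
    expect_lt(max(abs(rowSums(R * A))), 1e-8)
    expect_lt(max(abs(rowSums(R^2) - 1)), 1e-8)
    ## right-handed: radial x circumferential = axial
    expect_lt(max(abs(aortagrowth:::cross3(R, C) - A)), 1e-8)
    ## straight tube: axial is the global z axis
    expect_lt(max(abs(sweep(A, 2, c(0, 0, 1)))), 1e-8)
  }

  ## arched tube: axial follows the centerline tangent
  sta <- dissected_structured()
  sc <- dissected_scene()
  tan_true <- aortagrowth:::interp_centerline(sc$centerline, sta$s)$tangents
  ax <- t(vapply(seq_len(sta$n_layers), function(j) sta$frames$axial[j, 1, ],
                 numeric(3)))
  ang <- acos(pmin(1, rowSums(ax * tan_true)))
  ## forward-difference axial directions lag the arch tangent by about one
  ## layer spacing (4 mm on a 35 mm arch at this resolution)
  expect_lt(max(ang), 5 * pi / 180)

  degen <- ring_surface(c(10, 10), z = c(0, 1))
  degen$layer_centers[2, ] <- degen$layer_centers[1, ]  # coincident centers
  expect_error(local_frames(degen), "coincident")
})

test_that("layer diameters: circle, ellipse oracle, rigid invariance", {
  st <- ring_surface(rep(12, 5))
  expect_equal(layer_diameters(st), rep(24, 5), tolerance = 1e-12)

  ## ellipse semi-axes 10, 20: diameter = 2 x mean radius at 50 equal angles
  th <- 2 * pi * (0:49) / 50
  r_ell <- sqrt(1 / ((cos(th) / 10)^2 + (sin(th) / 20)^2))
  ell <- ring_surface(rep(1, 3))
  for (j in 1:3) {
    ell$nodes[j, , 1] <- r_ell * cos(th)
    ell$nodes[j, , 2] <- r_ell * sin(th)
  }
  expect_equal(layer_diameters(ell), rep(2 * mean(r_ell), 3),
               tolerance = 1e-9)

  ## rigid motion leaves diameters unchanged
  R <- aortagrowth:::rotation_matrix(c(1, 2, 3), 0.7)
  moved <- ell
  for (j in 1:3) {
    moved$nodes[j, , ] <- sweep(matrix(ell$nodes[j, , ], 50, 3) %*% t(R),
                                2, c(5, -4, 12), "+")
    moved$layer_centers[j, ] <- as.vector(R %*% ell$layer_centers[j, ]) +
      c(5, -4, 12)
  }
  expect_equal(layer_diameters(moved), layer_diameters(ell),
               tolerance = 1e-9)
})

test_that("region partition anchors region 13 at the landmark", {
  p49 <- partition_regions(200, landmark_layer = 49)
  expect_identical(nrow(p49), 50L)
  expect_true(all(p49$layer_end - p49$layer_start + 1L == 4L))
  expect_identical(p49$layer_start[13], 49L)
  expect_identical(sum(p49$descending), 38L)
  expect_identical(p49$layer_end[50], 200L)

  p42 <- partition_regions(200, landmark_layer = 42)
  sizes_asc <- with(p42[!p42$descending, ], layer_end - layer_start + 1L)
  sizes_desc <- with(p42[p42$descending, ], layer_end - layer_start + 1L)
  expect_identical(p42$layer_start[13], 42L)
  expect_lte(diff(range(sizes_asc)), 1L)
  expect_lte(diff(range(sizes_desc)), 1L)
  ## tiling 1..200, disjoint
  layers <- unlist(Map(seq, p42$layer_start, p42$layer_end))
  expect_identical(sort(layers), 1:200)

  ## boundary: 12 ascending regions of one layer each
  p13 <- partition_regions(200, landmark_layer = 13)
  expect_true(all(with(p13[!p13$descending, ],
                       layer_end - layer_start + 1L) == 1L))
  expect_error(partition_regions(200, landmark_layer = 12), "proximal")
  expect_error(partition_regions(200, landmark_layer = 170), "distal")
})

test_that("region averages: constant, layer-index oracle, permutation", {
  part <- partition_regions(200, landmark_layer = 49)
  const <- matrix(7, 200, 50)
  expect_true(all(region_average(const, part) == 7))

  field <- matrix(rep(1:200, 50), 200, 50)
  avg <- region_average(field, part)
  expect_equal(unname(avg[1]), mean(49:52))  # region 13 = layers 49-52
  expect_equal(unname(avg[38]), mean(197:200))

  shuffled <- t(apply(field, 1, sample))
  expect_equal(region_average(shuffled, part), avg)
})

test_that("solid tube mesh: offsets, node count, labels, Jacobians", {
  sc <- tube_scene()
  solid <- build_solid_mesh(sc, n_circ = 20, n_axial = 16)
  rr <- sqrt(rowSums(solid$nodes[, 1:2]^2))
  expect_lt(abs(min(rr) - 14), 0.05)  # 1 mm inward offset of r = 15
  expect_lt(abs(max(rr) - 16), 0.05)  # 1 mm outward
  expect_true(all(solid$material == "wall_tl"))
  ## structured count x (n_hex_layers + 1) nodes for the plain tube
  expect_identical(nrow(solid$nodes), 16L * 20L * 5L)
  ## positive Jacobians (assembly errors otherwise)
  expect_no_error(aortagrowth:::assemble_unit_stiffness(
    solid$nodes, solid$elems, nu = 0.3))
  expect_identical(sort(unique(solid$load_faces$lumen)), "true")

  ## dissected mesh: all four materials, both lumen labels, conforming ids
  ds <- dissected_solid()
  expect_setequal(unique(ds$material),
                  c("wall_tl", "wall_fl", "flap", "thrombus"))
  expect_setequal(unique(ds$load_faces$lumen), c("true", "false"))
  expect_error(thickness_spec(true_lumen_wall = 2, false_lumen_wall = 0.7,
                              flap = 1), "consistency")
})

test_that("avg_descending_growth matches layer-weighted oracles", {
  base <- ring_surface(rep(10, 40), landmark = 11)
  expect_equal(avg_descending_growth(base, base, years = 3), 0)

  up <- ring_surface(rep(11, 40), landmark = 11)  # +2 mm diameter
  expect_equal(avg_descending_growth(base, up, years = 1), 2)

  ## +4 mm over the distal half of the 30 descending layers, 2 years
  radii <- rep(10, 40); radii[26:40] <- 12
  half <- ring_surface(radii, landmark = 11)
  expected <- (4 * 15 / 30) / 2
  expect_equal(avg_descending_growth(base, half, years = 2), expected)
  expect_error(avg_descending_growth(base, up, years = 0), "positive")
})
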