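## Synthetic dissected-aorta scenes.
##
## A scene is an analytic "candy-cane" tube (semicircular arch + straight
## descending limb, or a plain straight tube), with an optional dissection
## flap modeled as a ruled chord surface splitting the lumen into true (TL)
## and false (FL) channels, circular tears (fenestrations) in the flap, and
## an optional mural thrombus wedge attached to the FL wall. All meshes are
## rebuilt deterministically from the stored parameters, so generators are
## pure functions of (spec, seed).

#' Centerline of a scene geometry
#'
#' Arch (semicircle of radius `arch_radius` in the x-z plane) followed by a
#' straight descending limb along -z; `arch_radius = 0` gives a straight
#' tube along +z. Cross-section bases are e2 = +y and e1 = e2 x tangent.
#'
#' @param s arclengths (mm).
#' @param arch_radius arch radius (mm), 0 for a straight tube.
#' @return list with `points`, `tangents`, `e1`, `e2` (n x 3 matrices).
#' @keywords internal
centerline_eval <- function(s, arch_radius) {
  n <- length(s)
  p <- matrix(0, n, 3); tg <- matrix(0, n, 3)
  if (arch_radius <= 0) {
    p[, 3] <- s
    tg[, 3] <- 1
  } else {
    s_arch <- pi * arch_radius
    in_arch <- s <= s_arch
    phi <- s[in_arch] / arch_radius
    p[in_arch, 1] <- -arch_radius * cos(phi)
    p[in_arch, 3] <- arch_radius * sin(phi)
    tg[in_arch, 1] <- sin(phi)
    tg[in_arch, 3] <- cos(phi)
    ds <- s[!in_arch] - s_arch
    p[!in_arch, 1] <- arch_radius
    p[!in_arch, 3] <- -ds
    tg[!in_arch, 3] <- -1
  }
  e2 <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  e1 <- cross3(e2, tg)
  list(points = p, tangents = tg, e1 = e1, e2 = e2)
}

#' Growth field: prescribed circumferential stretch over arclength
#'
#' Ground-truth input for [grow_aorta()]: a circumferential stretch factor
#' per arclength (optionally also per angle) applied over a duration.
#'
#' @param stretch a single number, a function of arclength `s` (mm), or a
#'   function of `(s, theta)` when `per_angle = TRUE`.
#' @param duration elapsed time in years (> 0).
#' @param per_angle does `stretch` take an angle argument?
#' @return object of class `growth_field`.
#' @export
#' @examples
#' gf <- growth_field(function(s) 1 + 0.1 * s / 400, duration = 2)
growth_field <- function(stretch, duration, per_angle = FALSE) {
  stopifnot(duration > 0)
  if (is.numeric(stretch) && length(stretch) == 1L) {
    val <- stretch
    stretch <- function(s) rep(val, length(s))
  }
  stopifnot(is.function(stretch))
  structure(list(stretch = stretch, duration = duration,
                 per_angle = per_angle),
            class = "growth_field")
}

default_outlets <- function(length, arch_radius, radius) {
  s_arch <- if (arch_radius > 0) pi * arch_radius else 0
  if (arch_radius > 0) {
    ## three arch branches, two visceral branches, distal outlet
    data.frame(
      s = c(0.25 * s_arch, 0.45 * s_arch, 0.65 * s_arch,
            0.72 * length, 0.78 * length, length),
      area = c(80, 30, 40, 45, 45, 150))
  } else {
    data.frame(s = length, area = pi * radius^2 * 0.7)
  }
}

#' Generate a synthetic dissected-aorta scene
#'
#' @param radius proximal outer radius (mm).
#' @param length total centerline arclength (mm).
#' @param arch_radius radius of the semicircular arch (mm); 0 gives a
#'   straight tube (used by fixtures).
#' @param taper fractional reduction of radius at the distal end
#'   (r_distal = radius * (1 - taper)); negative values widen distally.
#' @param flap `NULL` for an undissected tube, otherwise a list with
#'   `s_range` (arclength span, mm), `theta1`, `theta2` (chord attachment
#'   angles, radians; a span of pi puts the chord through the center).
#' @param tears data frame with columns `s` (arclength of tear center, mm),
#'   `w` (lateral offset along the chord from its midpoint, mm), and
#'   `radius` (mm); `NULL` for none.
#' @param thrombus `NULL` or list with `s_range`, `frac` (fraction of the
#'   FL angular sector covered, centered in the sector), `thickness` (mm,
#'   radially inward from the FL wall).
#' @param outlets data frame with columns `s`, `area` (mm^2); defaults to
#'   three arch branches, two visceral branches and a distal outlet.
#' @param landmark_arclength arclength of the left-subclavian surrogate
#'   landmark (mm).
#' @param radius_noise standard deviation of a smooth multiplicative radius
#'   perturbation (fraction, e.g. 0.03); gives patient-to-patient variation.
#' @param n_axial,n_circ generation-mesh resolution.
#' @param seed integer seed; generators are pure functions of (spec, seed).
#' @return object of class `aorta_scene` with elements `outer_surface`,
#'   `flap_surface`, `thrombus`, `centerline`, `outlets`,
#'   `landmark_arclength` and the generation parameters.
#' @export
#' @examples
#' sc <- make_dissected_aorta(radius = 15, length = 200, arch_radius = 0,
#'                            taper = 0, flap = NULL, seed = 1)
make_dissected_aorta <- function(radius = 15, length = 400, arch_radius = 35,
                                 taper = 0.25,
                                 flap = list(s_range = c(130, 370),
                                             theta1 = -pi / 2, theta2 = pi / 2),
                                 tears = data.frame(s = c(140, 360), w = 0,
                                                    radius = c(5, 4)),
                                 thrombus = NULL,
                                 outlets = NULL,
                                 landmark_arclength = 0.2425 * length,
                                 radius_noise = 0,
                                 n_axial = 220, n_circ = 64,
                                 seed = 1) {
  if (radius <= 0 || length <= 0) stop("radii and length must be positive")
  if (arch_radius > 0 && pi * arch_radius >= length)
    stop("arch longer than total length")
  if (landmark_arclength <= 0 || landmark_arclength >= length)
    stop("landmark_arclength outside centerline range")
  if (is.null(outlets)) outlets <- default_outlets(length, arch_radius, radius)
  if (any(outlets$area <= 0)) stop("outlet areas must be positive")

  s_surf <- seq(0, length, length.out = n_axial)
  theta <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]

  r_axial <- radius * (1 - taper * s_surf / length)
  if (radius_noise > 0) {
    r_axial <- r_axial * with_seed(seed, {
      k <- 1:3
      amp <- rnorm(3, 0, radius_noise / sqrt(3))
      ph <- runif(3, 0, 2 * pi)
      1 + Reduce(`+`, lapply(seq_along(k), function(i)
        amp[i] * cos(2 * pi * k[i] * s_surf / length + ph[i])))
    })
  }
  if (any(r_axial <= 0)) stop("radius profile not positive")
  radius_matrix <- matrix(r_axial, n_axial, n_circ)

  if (!is.null(flap)) {
    if (flap$s_range[1] < 0 || flap$s_range[2] > length ||
        diff(flap$s_range) <= 0)
      stop("flap s_range outside geometry")
    ## snap chord attachment angles to generation-grid angles
    flap$theta1 <- theta[which.min(abs(((flap$theta1 - theta + pi) %% (2 * pi)) - pi))]
    flap$theta2 <- theta[which.min(abs(((flap$theta2 - theta + pi) %% (2 * pi)) - pi))]
    if (!is.null(tears) && nrow(tears) > 0) {
      half_chord <- radius  # conservative bound at chord through center
      for (i in seq_len(nrow(tears))) {
        if (tears$radius[i] <= 0) stop("tear radius must be positive")
        if (tears$s[i] - tears$radius[i] <= flap$s_range[1] ||
            tears$s[i] + tears$radius[i] >= flap$s_range[2])
          stop("tear not strictly inside flap (axial)")
        if (abs(tears$w[i]) + tears$radius[i] >= half_chord)
          stop("tear larger than flap extent")
      }
    }
  } else {
    tears <- NULL
    if (!is.null(thrombus)) stop("thrombus requires a flap (false lumen)")
  }

  params <- list(radius = radius, length = length, arch_radius = arch_radius,
                 taper = taper, flap = flap, tears = tears,
                 thrombus = thrombus, outlets = outlets,
                 landmark_arclength = landmark_arclength,
                 n_axial = n_axial, n_circ = n_circ, seed = seed)
  build_scene(params, s_surf, theta, radius_matrix, rigid = NULL)
}

## Assemble the scene meshes from parameters + radius field (pure).
build_scene <- function(params, s_surf, theta, radius_matrix, rigid = NULL) {
  n_axial <- length(s_surf); n_circ <- length(theta)
  cl <- centerline_eval(s_surf, params$arch_radius)

  ## lateral surface vertices: row-major (axial i, circumferential j)
  dirs <- array(0, dim = c(n_axial, n_circ, 3))
  verts <- matrix(0, n_axial * n_circ, 3)
  for (i in seq_len(n_axial)) {
    d <- outer(cos(theta), cl$e1[i, ]) + outer(sin(theta), cl$e2[i, ])
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <-
      matrix(cl$points[i, ], n_circ, 3, byrow = TRUE) + radius_matrix[i, ] * d
  }
  vid <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L

  faces <- vector("list", n_axial - 1L)
  for (i in seq_len(n_axial - 1L)) {
    j <- seq_len(n_circ)
    a <- vid(i, j); b <- vid(i, j + 1L)
    c_ <- vid(i + 1L, j + 1L); d <- vid(i + 1L, j)
    faces[[i]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  faces <- do.call(rbind, faces)
  ## end caps (fans to the section centers) -> watertight closed surface
  cap1 <- nrow(verts) + 1L; cap2 <- nrow(verts) + 2L
  verts <- rbind(verts, cl$points[1, ], cl$points[n_axial, ])
  j <- seq_len(n_circ)
  faces <- rbind(faces,
                 cbind(rep(cap1, n_circ), vid(1L, j + 1L), vid(1L, j)),
                 cbind(rep(cap2, n_circ), vid(n_axial, j), vid(n_axial, j + 1L)))
  dimnames(faces) <- NULL
  outer_surface <- list(vertices = verts, faces = faces,
                        n_axial = n_axial, n_circ = n_circ)

  flap_surface <- NULL
  if (!is.null(params$flap)) {
    flap_surface <- build_flap_surface(params, s_surf, theta, radius_matrix, cl)
  }
  thrombus <- NULL
  if (!is.null(params$thrombus)) {
    thrombus <- build_thrombus(params, s_surf, theta, radius_matrix, cl)
  }

  centerline <- list(s = s_surf, points = cl$points, tangents = cl$tangents)

  scene <- structure(list(
    outer_surface = outer_surface,
    flap_surface = flap_surface,
    thrombus = thrombus,
    centerline = centerline,
    outlets = params$outlets,
    landmark_arclength = params$landmark_arclength,
    tears = params$tears,
    flap = params$flap,
    params = params,
    s_surf = s_surf, theta = theta, radius_matrix = radius_matrix,
    rigid = NULL), class = "aorta_scene")

  if (!is.null(rigid)) scene <- apply_rigid_to_scene(scene, rigid)
  scene
}

## flap: ruled chord surface between attachment angles, quad grid
## triangulated, faces inside tears removed.
build_flap_surface <- function(params, s_surf, theta, radius_matrix, cl) {
  flap <- params$flap
  rows <- which(s_surf >= flap$s_range[1] & s_surf <= flap$s_range[2])
  if (length(rows) < 2) stop("flap span under-resolved by generation mesh")
  j1 <- which.min(abs(((flap$theta1 - theta + pi) %% (2 * pi)) - pi))
  j2 <- which.min(abs(((flap$theta2 - theta + pi) %% (2 * pi)) - pi))
  n_chord <- max(12L, params$n_circ %/% 4L)
  u <- seq(0, 1, length.out = n_chord + 1L)

  nv <- length(rows) * (n_chord + 1L)
  verts <- matrix(0, nv, 3)
  wcoord <- matrix(0, length(rows), n_chord + 1L)  # chordwise mm from midpoint
  scoord <- s_surf[rows]
  for (ii in seq_along(rows)) {
    i <- rows[ii]
    d1 <- cos(theta[j1]) * cl$e1[i, ] + sin(theta[j1]) * cl$e2[i, ]
    d2 <- cos(theta[j2]) * cl$e1[i, ] + sin(theta[j2]) * cl$e2[i, ]
    p1 <- cl$points[i, ] + radius_matrix[i, j1] * d1
    p2 <- cl$points[i, ] + radius_matrix[i, j2] * d2
    pts <- outer(1 - u, p1) + outer(u, p2)
    verts[(ii - 1L) * (n_chord + 1L) + seq_len(n_chord + 1L), ] <- pts
    half <- sqrt(sum((p2 - p1)^2)) / 2
    wcoord[ii, ] <- (u - 0.5) * 2 * half
  }
  fid <- function(ii, jj) (ii - 1L) * (n_chord + 1L) + jj
  faces <- list(); keep_quad <- list()
  for (ii in seq_len(length(rows) - 1L)) {
    for (jj in seq_len(n_chord)) {
      cs <- (scoord[ii] + scoord[ii + 1L]) / 2
      cw <- (wcoord[ii, jj] + wcoord[ii, jj + 1L]) / 2
      inside_tear <- FALSE
      if (!is.null(params$tears) && nrow(params$tears) > 0) {
        dd <- sqrt((params$tears$s - cs)^2 + (params$tears$w - cw)^2)
        inside_tear <- any(dd < params$tears$radius)
      }
      if (!inside_tear) {
        a <- fid(ii, jj); b <- fid(ii, jj + 1L)
        c_ <- fid(ii + 1L, jj + 1L); d <- fid(ii + 1L, jj)
        faces[[length(faces) + 1L]] <- rbind(c(a, b, c_), c(a, c_, d))
      }
    }
  }
  faces <- do.call(rbind, faces)
  ## drop unreferenced vertices (tear interiors)
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nv); remap[used] <- seq_along(used)
  list(vertices = verts[used, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3),
       s = scoord, n_chord = n_chord,
       theta1 = theta[j1], theta2 = theta[j2])
}

## mural thrombus: wedge between FL wall and an inward-offset surface,
## covering `frac` of the FL angular sector, closed triangulated surface
## plus a node cloud for distance queries.
build_thrombus <- function(params, s_surf, theta, radius_matrix, cl) {
  th <- params$thrombus; flap <- params$flap
  rows <- which(s_surf >= th$s_range[1] & s_surf <= th$s_range[2])
  if (length(rows) < 2) stop("thrombus span under-resolved")
  fl <- fl_sector(theta, flap)          # indices of FL-sector angles
  n_fl <- length(fl)
  n_keep <- max(3L, round(th$frac * n_fl))
  start <- (n_fl - n_keep) %/% 2L
  sector <- fl[seq_len(n_keep) + start]

  outer_pts <- list(); inner_pts <- list()
  for (ii in seq_along(rows)) {
    i <- rows[ii]
    d <- outer(cos(theta[sector]), cl$e1[i, ]) +
      outer(sin(theta[sector]), cl$e2[i, ])
    r_out <- radius_matrix[i, sector]
    r_in <- pmax(r_out - th$thickness, 0.2 * r_out)
    ctr <- matrix(cl$points[i, ], length(sector), 3, byrow = TRUE)
    outer_pts[[ii]] <- ctr + r_out * d
    inner_pts[[ii]] <- ctr + r_in * d
  }
  outer_m <- do.call(rbind, outer_pts)
  inner_m <- do.call(rbind, inner_pts)
  nr <- length(rows); nc <- length(sector)
  verts <- rbind(outer_m, inner_m)
  idx_o <- function(i, j) (i - 1L) * nc + j
  idx_i <- function(i, j) nr * nc + (i - 1L) * nc + j
  faces <- list()
  for (i in seq_len(nr - 1L)) {
    for (j in seq_len(nc - 1L)) {
      faces[[length(faces) + 1L]] <- rbind(
        c(idx_o(i, j), idx_o(i, j + 1L), idx_o(i + 1L, j + 1L)),
        c(idx_o(i, j), idx_o(i + 1L, j + 1L), idx_o(i + 1L, j)),
        c(idx_i(i, j), idx_i(i + 1L, j + 1L), idx_i(i, j + 1L)),
        c(idx_i(i, j), idx_i(i + 1L, j), idx_i(i + 1L, j + 1L)))
    }
  }
  ## side + end walls to close the surface
  for (i in seq_len(nr - 1L)) {
    faces[[length(faces) + 1L]] <- rbind(
      c(idx_o(i, 1L), idx_i(i, 1L), idx_i(i + 1L, 1L)),
      c(idx_o(i, 1L), idx_i(i + 1L, 1L), idx_o(i + 1L, 1L)),
      c(idx_o(i, nc), idx_i(i + 1L, nc), idx_i(i, nc)),
      c(idx_o(i, nc), idx_o(i + 1L, nc), idx_i(i + 1L, nc)))
  }
  for (j in seq_len(nc - 1L)) {
    faces[[length(faces) + 1L]] <- rbind(
      c(idx_o(1L, j), idx_i(1L, j + 1L), idx_i(1L, j)),
      c(idx_o(1L, j), idx_o(1L, j + 1L), idx_i(1L, j + 1L)),
      c(idx_o(nr, j), idx_i(nr, j), idx_i(nr, j + 1L)),
      c(idx_o(nr, j), idx_i(nr, j + 1L), idx_o(nr, j + 1L)))
  }
  faces <- do.call(rbind, faces)
  list(vertices = verts, faces = faces, nodes = verts,
       s_range = th$s_range, thickness = th$thickness,
       sector_theta = theta[sector])
}

## indices of generation-grid angles lying in the false-lumen sector
fl_sector <- function(theta, flap) {
  mid_tl <- (flap$theta1 + flap$theta2) / 2
  ang <- ((theta - mid_tl + pi) %% (2 * pi)) - pi
  half_span <- abs(((flap$theta2 - flap$theta1 + pi) %% (2 * pi)) - pi) / 2
  which(abs(ang) > half_span + 1e-9)
}

apply_rigid_to_scene <- function(scene, rigid) {
  R <- rigid$R; t <- rigid$t
  tx <- function(m) sweep(m %*% t(R), 2, t, "+")
  scene$outer_surface$vertices <- tx(scene$outer_surface$vertices)
  if (!is.null(scene$flap_surface))
    scene$flap_surface$vertices <- tx(scene$flap_surface$vertices)
  if (!is.null(scene$thrombus)) {
    scene$thrombus$vertices <- tx(scene$thrombus$vertices)
    scene$thrombus$nodes <- tx(scene$thrombus$nodes)
  }
  scene$centerline$points <- tx(scene$centerline$points)
  scene$centerline$tangents <- scene$centerline$tangents %*% t(R)
  scene$rigid <- rigid
  scene
}

#' Apply a prescribed growth field to a scene
#'
#' Scales each cross-section radius by the local circumferential stretch
#' factor; the centerline is preserved. An optional rigid perturbation
#' (applied after growth) supports registration tests.
#'
#' @param scene an `aorta_scene`.
#' @param growth a [growth_field()].
#' @param rigid optional list with rotation `R` (3x3) and translation `t`.
#' @return the follow-up `aorta_scene`.
#' @export
grow_aorta <- function(scene, growth, rigid = NULL) {
  stopifnot(inherits(scene, "aorta_scene"), inherits(growth, "growth_field"))
  s <- scene$s_surf; theta <- scene$theta
  if (growth$per_angle) {
    fac <- outer(s, theta, growth$stretch)
  } else {
    fac <- matrix(growth$stretch(s), length(s), length(theta))
  }
  if (any(!is.finite(fac)) || any(fac <= 0))
    stop("stretch factor must be positive everywhere")
  rm_new <- scene$radius_matrix * fac
  out <- build_scene(scene$params, s, theta, rm_new, rigid = rigid)
  out$growth_applied <- growth
  out
}

#' @export
print.aorta_scene <- function(x, ...) {
  cat("aorta_scene:", nrow(x$outer_surface$vertices), "outer vertices;",
      if (is.null(x$flap_surface)) "no flap" else
        paste0("flap with ", if (is.null(x$tears)) 0 else nrow(x$tears), " tear(s)"),
      "\n  length", x$params$length, "mm, arch radius",
      x$params$arch_radius, "mm, landmark at s =",
      x$landmark_arclength, "mm\n")
  invisible(x)
}

#' Euler characteristic V - E + F of a triangle mesh
#' @param mesh list with `vertices` and triangle `faces`.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  v <- length(unique(as.vector(f)))
  e <- unique(t(apply(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]),
                      1, sort)))
  v - nrow(e) + nrow(f)
}
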