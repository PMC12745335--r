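## Structured cylindrical parameterization of the outer wall.
##
## The outer surface is resampled onto a cylinder-topology grid of
## `n_layers` circumferential layers (default 200) times `n_nodes` nodes
## per layer (default 50). Layer j lies on the cross-section plane at the
## j-th of n_layers equally spaced arclengths; the 50 nodes sit at equally
## spaced angles about the layer center, with the angular origin given by
## the projection of a fixed global axis onto the cross-section plane (a
## deterministic convention; the nonrigid registration stage absorbs any
## residual azimuthal offset between time points).

#' Resample a tube-topology surface onto a structured cylindrical grid
#'
#' @param x an `aorta_scene`, or a list with `vertices`/`faces` plus a
#'   `centerline` argument.
#' @param centerline list with `s`, `points`, `tangents`; taken from the
#'   scene when `x` is an `aorta_scene`.
#' @param n_layers number of circumferential layers (axial stations).
#' @param n_nodes nodes per layer.
#' @param ref_axis global axis whose in-plane projection fixes the angular
#'   origin.
#' @return object of class `structured_surface`: `nodes` (n_layers x
#'   n_nodes x 3), `layer_centers`, `s` (layer arclengths),
#'   `landmark_layer`, and (after [local_frames()]) per-node frames.
#' @export
parameterize_surface <- function(x, centerline = NULL,
                                 n_layers = 200L, n_nodes = 50L,
                                 ref_axis = c(0, 1, 0)) {
  if (inherits(x, "aorta_scene")) {
    mesh <- x$outer_surface
    centerline <- x$centerline
    landmark_arclength <- x$landmark_arclength
  } else {
    mesh <- x
    landmark_arclength <- attr(x, "landmark_arclength")
    if (is.null(centerline)) stop("centerline required for a bare mesh")
  }
  v <- mesh$vertices; f <- mesh$faces
  s_rng <- range(centerline$s)
  ## layers at cell-centered, equally spaced arclengths (avoids the caps)
  s_layers <- s_rng[1] + (seq_len(n_layers) - 0.5) / n_layers * diff(s_rng)
  cl <- interp_centerline(centerline, s_layers)

  edges <- unique_edges(f)
  p1 <- v[edges[, 1], , drop = FALSE]
  p2 <- v[edges[, 2], , drop = FALSE]

  nodes <- array(0, dim = c(n_layers, n_nodes, 3))
  centers <- matrix(0, n_layers, 3)
  theta_out <- 2 * pi * (seq_len(n_nodes) - 1L) / n_nodes

  for (j in seq_len(n_layers)) {
    c0 <- cl$points[j, ]; tg <- cl$tangents[j, ]
    f1 <- (p1 - matrix(c0, nrow(p1), 3, byrow = TRUE)) %*% tg
    f2 <- (p2 - matrix(c0, nrow(p2), 3, byrow = TRUE)) %*% tg
    hit <- which(pmin(f1, f2) <= 0 & pmax(f1, f2) >= 0 & !(f1 == 0 & f2 == 0))
    if (length(hit) < 3) stop("cross-section slice failed: non-tube topology?")
    tt <- f1[hit] / (f1[hit] - f2[hit])
    pts <- p1[hit, , drop = FALSE] +
      tt * (p2[hit, , drop = FALSE] - p1[hit, , drop = FALSE])
    ## keep only the local cross-section (a slicing plane can also cut the
    ## far limb of an arched tube): split at the largest multiplicative gap
    ## in the sorted center distances and keep the near cluster
    d0 <- sqrt(rowSums(sweep(pts, 2, c0)^2))
    ds <- sort(d0)
    ratio <- ds[-1] / pmax(ds[-length(ds)], 1e-12)
    gap <- which(ratio > 2)[1]
    if (!is.na(gap) && gap >= 3) pts <- pts[d0 <= ds[gap], , drop = FALSE]
    if (nrow(pts) < 3) stop("cross-section slice degenerate")

    ## in-plane basis from the projected reference axis
    u <- ref_axis - sum(ref_axis * tg) * tg
    if (sqrt(sum(u^2)) < 1e-8) stop("ref_axis parallel to centerline tangent")
    u <- u / sqrt(sum(u^2))
    w <- cross3(tg, u)[1, ]

    for (it in 1:3) {  # re-center: layer center = mean of resampled nodes
      rel <- sweep(pts, 2, c0)
      a <- atan2(rel %*% w, rel %*% u) %% (2 * pi)
      r <- sqrt(rowSums(rel^2))
      rr <- interp_periodic(as.vector(a), r, theta_out)
      ring <- matrix(c0, n_nodes, 3, byrow = TRUE) +
        rr * (outer(cos(theta_out), u) + outer(sin(theta_out), w))
      c_new <- colMeans(ring)
      if (sqrt(sum((c_new - c0)^2)) < 1e-9) { c0 <- c_new; break }
      c0 <- c_new
    }
    nodes[j, , ] <- ring
    centers[j, ] <- c0
  }

  landmark_layer <- if (!is.null(landmark_arclength))
    which.min(abs(s_layers - landmark_arclength)) else NA_integer_
  out <- structure(list(nodes = nodes, layer_centers = centers,
                        s = s_layers, n_layers = n_layers, n_nodes = n_nodes,
                        landmark_layer = landmark_layer),
                   class = "structured_surface")
  out$frames <- local_frames(out)
  out
}

interp_centerline <- function(centerline, s_out) {
  pts <- apply(centerline$points, 2, function(col)
    approx(centerline$s, col, xout = s_out, rule = 2)$y)
  tgs <- apply(centerline$tangents, 2, function(col)
    approx(centerline$s, col, xout = s_out, rule = 2)$y)
  tgs <- normalize_rows(tgs)
  list(points = pts, tangents = tgs)
}

unique_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Local aortic frames on a structured surface
#'
#' Radial = outward surface normal direction (center-to-node, the outward
#' in-plane direction); axial = unit vector joining the centers of the
#' current and next layer (last layer copies the penultimate); the
#' circumferential direction completes the right-handed orthonormal triad
#' circ = axial x radial, and radial is re-orthogonalized as circ x axial.
#'
#' @param structured a `structured_surface`.
#' @return list of `radial`, `circumferential`, `axial` arrays
#'   (n_layers x n_nodes x 3).
#' @export
local_frames <- function(structured) {
  nl <- structured$n_layers; nn <- structured$n_nodes
  ctr <- structured$layer_centers
  ax_layer <- rbind(ctr[2:nl, , drop = FALSE] - ctr[1:(nl - 1), , drop = FALSE],
                    ctr[nl, ] - ctr[nl - 1, ])
  if (any(row_norms(ax_layer) < 1e-9)) stop("coincident layer centers")
  ax_layer <- normalize_rows(ax_layer)

  radial <- array(0, c(nl, nn, 3))
  circf <- array(0, c(nl, nn, 3))
  axial <- array(0, c(nl, nn, 3))
  for (j in seq_len(nl)) {
    out_dir <- sweep(matrix(structured$nodes[j, , ], nn, 3), 2, ctr[j, ])
    out_dir <- normalize_rows(out_dir)
    a <- matrix(ax_layer[j, ], nn, 3, byrow = TRUE)
    cir <- cross3(a, out_dir)
    cir <- normalize_rows(cir)
    rad <- cross3(cir, a)          # orthonormal, still outward
    radial[j, , ] <- rad
    circf[j, , ] <- cir
    axial[j, , ] <- a
  }
  list(radial = radial, circumferential = circf, axial = axial)
}

#' Per-layer aortic diameters
#'
#' Diameter of layer j is twice the mean distance from the layer center to
#' its nodes; invariant under rigid motion.
#'
#' @param structured a `structured_surface`.
#' @return numeric vector of length `n_layers` (mm).
#' @export
layer_diameters <- function(structured) {
  nl <- structured$n_layers
  vapply(seq_len(nl), function(j) {
    rel <- sweep(matrix(structured$nodes[j, , ], structured$n_nodes, 3),
                 2, structured$layer_centers[j, ])
    2 * mean(sqrt(rowSums(rel^2)))
  }, numeric(1))
}

#' Spatially averaged descending-aorta diameter growth rate
#'
#' Mean diameter over the descending layers (landmark layer to the last
#' layer) at follow-up minus baseline, divided by elapsed years.
#'
#' @param base,follow `structured_surface` objects sharing the landmark
#'   definition.
#' @param years elapsed time (> 0).
#' @return growth rate in mm/year.
#' @export
avg_descending_growth <- function(base, follow, years) {
  if (years <= 0) stop("years must be positive")
  lm <- base$landmark_layer
  if (is.na(lm)) stop("baseline surface has no landmark layer")
  idx <- lm:base$n_layers
  d0 <- mean(layer_diameters(base)[idx])
  d1 <- mean(layer_diameters(follow)[idx])
  (d1 - d0) / years
}
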