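## Solid wall meshes: hexahedral extrusion of the (structured) outer wall,
## flap and thrombus, with material labels and lumen-labelled loaded facets.
##
## Offset rule for the dissected wall: the surfaces enclosing the true
## lumen are offset inward by the flap thickness (default 1 mm) and the
## entire outer wall outward by the false-lumen wall thickness (default
## 1 mm), so the true-lumen wall is 2 mm thick, the false-lumen wall and
## flap 1 mm each (their sum matching the intact wall in an acute
## dissection). All components share one transmural node spacing
## (true_lumen_wall / n_hex_layers), which makes the flap-wall junction
## node-conforming: the true-lumen wall carries n_hex_layers hex layers,
## the false-lumen wall and flap n_hex_layers/2 each.

#' Wall thickness specification
#'
#' @param true_lumen_wall,false_lumen_wall,flap thicknesses in mm.
#' @param n_hex_layers transmural hex layers across the true-lumen wall.
#' @export
thickness_spec <- function(true_lumen_wall = 2, false_lumen_wall = 1,
                           flap = 1, n_hex_layers = 4L) {
  if (any(c(true_lumen_wall, false_lumen_wall, flap) <= 0))
    stop("thicknesses must be positive")
  if (abs(flap + false_lumen_wall - true_lumen_wall) > 1e-9)
    stop("acute-dissection consistency requires flap + false_lumen_wall ",
         "= true_lumen_wall")
  h <- true_lumen_wall / n_hex_layers
  if (abs(false_lumen_wall / h - round(false_lumen_wall / h)) > 1e-9 ||
      abs(flap / h - round(flap / h)) > 1e-9)
    stop("component thicknesses must be integer multiples of the ",
         "transmural spacing true_lumen_wall/n_hex_layers")
  structure(list(true_lumen_wall = true_lumen_wall,
                 false_lumen_wall = false_lumen_wall, flap = flap,
                 n_hex_layers = as.integer(n_hex_layers), h = h),
            class = "thickness_spec")
}

new_solid_mesh <- function(nodes, elems, material, load_faces, fixed_sets,
                           meta = list()) {
  structure(list(nodes = nodes, elems = elems, material = material,
                 load_faces = load_faces, fixed_sets = fixed_sets,
                 meta = meta),
            class = "solid_mesh")
}

#' @export
print.solid_mesh <- function(x, ...) {
  cat("solid_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "hex elements (",
      paste(names(table(x$material)), as.vector(table(x$material)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Thin-cylinder hex fixture
#'
#' Straight cylinder along +z, inner radius `r`, uniform thickness `t`,
#' length `L`, `n_layers` transmural hex layers; the inner surface facets
#' are the loaded surface (label "true"). Used for Laplace-law and
#' penalty-displacement checks.
#'
#' @param r inner radius (mm), `t` wall thickness (mm, t < r), `L` length.
#' @param n_layers transmural hex layers.
#' @param n_circ,n_axial circumferential / axial element counts.
#' @return a `solid_mesh`.
#' @export
make_cylinder_fixture <- function(r, t, L, n_layers = 4L,
                                  n_circ = 48L, n_axial = 24L) {
  if (t >= r) stop("thickness must be smaller than the inner radius")
  if (L <= 0 || r <= 0 || t <= 0) stop("dimensions must be positive")
  if (n_layers < 1L) stop("need at least one transmural layer")
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  z <- seq(0, L, length.out = n_axial + 1L)
  radii <- r + t * (0:n_layers) / n_layers

  nid <- array(0L, c(n_axial + 1L, n_circ, n_layers + 1L))
  nodes <- matrix(0, (n_axial + 1L) * n_circ * (n_layers + 1L), 3)
  cnt <- 0L
  for (i in seq_len(n_axial + 1L)) for (a in seq_len(n_circ))
    for (k in seq_len(n_layers + 1L)) {
      cnt <- cnt + 1L
      nid[i, a, k] <- cnt
      nodes[cnt, ] <- c(radii[k] * cos(theta[a]), radii[k] * sin(theta[a]),
                        z[i])
    }

  elems <- matrix(0L, n_axial * n_circ * n_layers, 8)
  lf <- matrix(0L, n_axial * n_circ, 4)
  lf_dir <- matrix(0, n_axial * n_circ, 3)
  ecnt <- 0L; fcnt <- 0L
  for (i in seq_len(n_axial)) for (a in seq_len(n_circ)) {
    a2 <- a %% n_circ + 1L
    for (k in seq_len(n_layers)) {
      ecnt <- ecnt + 1L
      elems[ecnt, ] <- c(nid[i, a, k], nid[i, a2, k], nid[i + 1L, a2, k],
                         nid[i + 1L, a, k], nid[i, a, k + 1L],
                         nid[i, a2, k + 1L], nid[i + 1L, a2, k + 1L],
                         nid[i + 1L, a, k + 1L])
    }
    fcnt <- fcnt + 1L
    lf[fcnt, ] <- c(nid[i, a, 1L], nid[i, a2, 1L], nid[i + 1L, a2, 1L],
                    nid[i + 1L, a, 1L])
    mid_th <- theta[a] + pi / n_circ
    lf_dir[fcnt, ] <- c(cos(mid_th), sin(mid_th), 0)  # into the solid
  }
  load_faces <- list(faces = lf, into_solid = lf_dir,
                     lumen = rep("true", fcnt))
  fixed_sets <- list(end1 = as.vector(nid[1L, , ]),
                     end2 = as.vector(nid[n_axial + 1L, , ]))
  grid <- expand.grid(k = seq_len(n_layers + 1L), a = seq_len(n_circ),
                      i = seq_len(n_axial + 1L))[, c(3, 2, 1)]
  meta <- list(kind = "cylinder", r = r, t = t, L = L,
               n_circ = n_circ, n_axial = n_axial, n_layers = n_layers,
               outer_nodes = as.vector(nid[, , n_layers + 1L]),
               axis = c(0, 0, 1))
  new_solid_mesh(nodes, elems, rep("wall", nrow(elems)), load_faces,
                 fixed_sets, meta)
}

#' Build the solid wall mesh of a dissected-aorta scene
#'
#' Extrudes a structured resampling of the outer wall along per-node
#' averaged normals into transmural hex layers, adds flap and thrombus
#' components sharing nodes with the wall, removes flap elements inside
#' tears, and labels lumen-loaded facets.
#'
#' @param scene an `aorta_scene`.
#' @param thickness a [thickness_spec()].
#' @param n_circ,n_axial structured resolution used for the solid mesh
#'   (coarser than the 200 x 50 analysis grid by default; wall stress is
#'   smooth at this scale).
#' @return a `solid_mesh` with materials in
#'   `{wall_tl, wall_fl, flap, thrombus}`.
#' @export
build_solid_mesh <- function(scene, thickness = thickness_spec(),
                             n_circ = 40L, n_axial = 60L) {
  stopifnot(inherits(scene, "aorta_scene"))
  st <- parameterize_surface(scene, n_layers = n_axial, n_nodes = n_circ)
  h <- thickness$h
  k_in <- as.integer(round(thickness$flap / h))          # stations below surface
  k_out <- as.integer(round(thickness$false_lumen_wall / h))  # above surface
  n_flap <- k_in                                          # flap hex layers
  k_all <- -k_in:k_out

  cl <- centerline_eval(st$s, scene$params$arch_radius)
  flap <- scene$flap
  has_flap_layer <- rep(FALSE, n_axial)
  theta_gen <- matrix(0, n_axial, n_circ)  # generation-convention angles
  for (j in seq_len(n_axial)) {
    rel <- sweep(matrix(st$nodes[j, , ], n_circ, 3), 2, st$layer_centers[j, ])
    theta_gen[j, ] <- atan2(rel %*% cl$e2[j, ], rel %*% cl$e1[j, ])
  }
  in_tl <- matrix(TRUE, n_axial, n_circ)
  if (!is.null(flap)) {
    has_flap_layer <- st$s >= flap$s_range[1] & st$s <= flap$s_range[2]
    mid_tl <- (flap$theta1 + flap$theta2) / 2
    half_span <- abs(((flap$theta2 - flap$theta1 + pi) %% (2 * pi)) - pi) / 2
    ang <- ((theta_gen - mid_tl + pi) %% (2 * pi)) - pi
    in_tl <- abs(ang) <= half_span
  }
  ## junction columns: nearest angular node to each attachment angle
  junc <- integer(0)
  if (!is.null(flap)) {
    j_ref <- which(has_flap_layer)[1]
    a1 <- which.min(abs(((theta_gen[j_ref, ] - flap$theta1 + pi) %% (2 * pi)) - pi))
    a2 <- which.min(abs(((theta_gen[j_ref, ] - flap$theta2 + pi) %% (2 * pi)) - pi))
    junc <- c(a1, a2)
  }

  ## column station range: full for TL/junction/no-flap, outward-only for FL
  col_kmin <- matrix(-k_in, n_axial, n_circ)
  if (!is.null(flap)) {
    for (j in seq_len(n_axial)) if (has_flap_layer[j]) {
      fl_cols <- which(!in_tl[j, ])
      fl_cols <- setdiff(fl_cols, junc)
      col_kmin[j, fl_cols] <- 0L
    }
  }

  ## thrombus sector (angular columns + layer span)
  thr_cols <- integer(0); thr_layers <- integer(0); n_thr <- 0L
  if (!is.null(scene$params$thrombus)) {
    th <- scene$params$thrombus
    thr_layers <- which(st$s >= th$s_range[1] & st$s <= th$s_range[2])
    j_ref <- thr_layers[1]
    fl_cols <- which(!in_tl[j_ref, ] & !(seq_len(n_circ) %in% junc))
    ## order FL columns by angle around the FL sector midpoint
    mid_fl <- (flap$theta1 + flap$theta2) / 2 + pi
    off <- ((theta_gen[j_ref, fl_cols] - mid_fl + pi) %% (2 * pi)) - pi
    fl_cols <- fl_cols[order(off)]
    n_keep <- max(2L, round(th$frac * length(fl_cols)))
    start <- (length(fl_cols) - n_keep) %/% 2L
    thr_cols <- fl_cols[seq_len(n_keep) + start]
    n_thr <- 2L
    h_thr <- th$thickness / n_thr
  }

  ## ---- node table -------------------------------------------------------
  key <- new.env(hash = TRUE, parent = emptyenv())
  nodes_list <- list(); n_nodes <- 0L
  add_node <- function(id_key, xyz) {
    if (!is.null(key[[id_key]])) return(key[[id_key]])
    n_nodes <<- n_nodes + 1L
    nodes_list[[n_nodes]] <<- xyz
    key[[id_key]] <- n_nodes
    n_nodes
  }
  wall_node <- function(j, a, k) {
    id <- paste0("w", j, ".", a, ".", k)
    if (!is.null(key[[id]])) return(key[[id]])
    p <- st$nodes[j, a, ] + k * h * st$frames$radial[j, a, ]
    add_node(id, p)
  }

  elems <- list(); mat <- character(0)
  lf_faces <- list(); lf_dir <- list(); lf_lumen <- character(0)
  add_elem <- function(n8, m) {
    elems[[length(elems) + 1L]] <<- n8
    mat[length(mat) + 1L] <<- m
  }
  add_face <- function(n4, dir, lumen) {
    lf_faces[[length(lf_faces) + 1L]] <<- n4
    lf_dir[[length(lf_dir) + 1L]] <<- dir
    lf_lumen[length(lf_lumen) + 1L] <<- lumen
  }

  ## ---- wall hexes -------------------------------------------------------
  for (j in seq_len(n_axial - 1L)) {
    for (a in seq_len(n_circ)) {
      a2 <- a %% n_circ + 1L
      kmin <- max(col_kmin[j, a], col_kmin[j, a2],
                  col_kmin[j + 1L, a], col_kmin[j + 1L, a2])
      if (kmin >= k_out) next
      for (k in kmin:(k_out - 1L)) {
        n8 <- c(wall_node(j, a, k), wall_node(j, a2, k),
                wall_node(j + 1L, a2, k), wall_node(j + 1L, a, k),
                wall_node(j, a, k + 1L), wall_node(j, a2, k + 1L),
                wall_node(j + 1L, a2, k + 1L), wall_node(j + 1L, a, k + 1L))
        tl_elem <- !has_flap_layer[j] || (in_tl[j, a] && in_tl[j, a2])
        add_elem(n8, if (tl_elem) "wall_tl" else "wall_fl")
      }
      ## lumen-facing facet at the innermost shared station
      thr_here <- length(thr_cols) > 0 && a %in% thr_cols && a2 %in% thr_cols &&
        (j %in% thr_layers) && ((j + 1L) %in% thr_layers)
      if (!thr_here) {
        n4 <- c(wall_node(j, a, kmin), wall_node(j, a2, kmin),
                wall_node(j + 1L, a2, kmin), wall_node(j + 1L, a, kmin))
        dirv <- (st$frames$radial[j, a, ] + st$frames$radial[j, a2, ] +
                   st$frames$radial[j + 1L, a, ] +
                   st$frames$radial[j + 1L, a2, ]) / 4
        lum <- if (!has_flap_layer[j] || (in_tl[j, a] && in_tl[j, a2]))
          "true" else "false"
        add_face(n4, dirv / sqrt(sum(dirv^2)), lum)
      }
    }
  }

  ## ---- flap hexes -------------------------------------------------------
  flap_layers <- which(has_flap_layer)
  if (!is.null(flap) && length(flap_layers) >= 2) {
    a1 <- junc[1]; a2j <- junc[2]
    n_chord <- max(8L, n_circ %/% 3L)
    u <- seq(0, 1, length.out = n_chord + 1L)
    ## chord geometry per layer: the flap sheet is extruded along the
    ## chord normal d = axial x chord (oriented toward the false lumen by
    ## reversing the chord traversal if needed); the sheet is attached to
    ## the wall by sharing the junction surface nodes along its k = 0
    ## edge lines
    chord_pts <- function(j) {
      p1 <- st$nodes[j, a1, ]; p2 <- st$nodes[j, a2j, ]
      ax <- st$frames$axial[j, 1, ]
      half <- sqrt(sum((p2 - p1)^2)) / 2
      cdir <- (p2 - p1) / (2 * half)
      nrm <- cross3(ax, cdir)[1, ]
      fl_ref <- which(!in_tl[j, ])[1]
      to_fl <- st$nodes[j, fl_ref, ] - st$layer_centers[j, ]
      swap <- sum(nrm * to_fl) < 0
      if (swap) { tmp <- p1; p1 <- p2; p2 <- tmp; nrm <- -nrm }
      pts <- outer(1 - u, p1) + outer(u, p2)
      list(pts = pts, dir = nrm / sqrt(sum(nrm^2)),
           w = (u - 0.5) * 2 * half, swapped = swap)
    }
    flap_node <- function(j, q, k) {
      cg <- chord_cache[[as.character(j)]]
      if (k == 0L) {  # attachment line shares the wall surface nodes
        if (q == 1L) return(wall_node(j, if (cg$swapped) a2j else a1, 0L))
        if (q == n_chord + 1L)
          return(wall_node(j, if (cg$swapped) a1 else a2j, 0L))
      }
      id <- paste0("f", j, ".", q, ".", k)
      if (!is.null(key[[id]])) return(key[[id]])
      add_node(id, cg$pts[q, ] + k * h * cg$dir)
    }
    chord_cache <- new.env(parent = emptyenv())
    for (j in flap_layers) chord_cache[[as.character(j)]] <- chord_pts(j)
    chord_cache <- as.list(chord_cache)

    for (jj in seq_len(length(flap_layers) - 1L)) {
      j <- flap_layers[jj]
      if (flap_layers[jj + 1L] != j + 1L) next
      cg1 <- chord_cache[[as.character(j)]]
      cg2 <- chord_cache[[as.character(j + 1L)]]
      for (q in seq_len(n_chord)) {
        cs <- (st$s[j] + st$s[j + 1L]) / 2
        cw <- (cg1$w[q] + cg1$w[q + 1L] + cg2$w[q] + cg2$w[q + 1L]) / 4
        if (!is.null(scene$tears) && nrow(scene$tears) > 0) {
          dd <- sqrt((scene$tears$s - cs)^2 + (scene$tears$w - cw)^2)
          if (any(dd < scene$tears$radius)) next  # tear hole
        }
        for (k in 0:(n_flap - 1L)) {
          ## xi along axial, eta along chord: (ax x chord).d > 0
          n8 <- c(flap_node(j, q, k), flap_node(j + 1L, q, k),
                  flap_node(j + 1L, q + 1L, k), flap_node(j, q + 1L, k),
                  flap_node(j, q, k + 1L), flap_node(j + 1L, q, k + 1L),
                  flap_node(j + 1L, q + 1L, k + 1L), flap_node(j, q + 1L, k + 1L))
          add_elem(n8, "flap")
        }
        ## TL-side face (k = 0) loaded by TL pressure, FL side by FL;
        ## cg$dir points toward the FL, i.e. into the solid for TL loads
        d_fl <- (cg1$dir + cg2$dir) / 2
        d_fl <- d_fl / sqrt(sum(d_fl^2))
        add_face(c(flap_node(j, q, 0L), flap_node(j, q + 1L, 0L),
                   flap_node(j + 1L, q + 1L, 0L), flap_node(j + 1L, q, 0L)),
                 d_fl, "true")
        add_face(c(flap_node(j, q, n_flap), flap_node(j, q + 1L, n_flap),
                   flap_node(j + 1L, q + 1L, n_flap),
                   flap_node(j + 1L, q, n_flap)),
                 -d_fl, "false")
      }
    }
  }

  ## ---- thrombus hexes (inward extrusion from the FL wall) ---------------
  if (length(thr_cols) > 0) {
    thr_node <- function(j, a, k) {  # k = 0 shares the wall surface node
      if (k == 0L) return(wall_node(j, a, 0L))
      id <- paste0("t", j, ".", a, ".", k)
      if (!is.null(key[[id]])) return(key[[id]])
      add_node(id, st$nodes[j, a, ] - k * h_thr * st$frames$radial[j, a, ])
    }
    for (jj in seq_len(length(thr_layers) - 1L)) {
      j <- thr_layers[jj]
      if (thr_layers[jj + 1L] != j + 1L) next
      for (qq in seq_len(length(thr_cols) - 1L)) {
        a <- thr_cols[qq]; a2t <- thr_cols[qq + 1L]
        for (k in 0:(n_thr - 1L)) {
          ## inward extrusion: swap station order to keep det > 0
          n8 <- c(thr_node(j, a, k + 1L), thr_node(j, a2t, k + 1L),
                  thr_node(j + 1L, a2t, k + 1L), thr_node(j + 1L, a, k + 1L),
                  thr_node(j, a, k), thr_node(j, a2t, k),
                  thr_node(j + 1L, a2t, k), thr_node(j + 1L, a, k))
          add_elem(n8, "thrombus")
        }
        dirv <- (st$frames$radial[j, a, ] + st$frames$radial[j, a2t, ]) / 2
        add_face(c(thr_node(j, a, n_thr), thr_node(j, a2t, n_thr),
                   thr_node(j + 1L, a2t, n_thr), thr_node(j + 1L, a, n_thr)),
                 dirv / sqrt(sum(dirv^2)), "false")
      }
    }
  }

  nodes <- do.call(rbind, nodes_list)
  elems_m <- do.call(rbind, elems)
  load_faces <- list(faces = do.call(rbind, lf_faces),
                     into_solid = do.call(rbind, lf_dir),
                     lumen = lf_lumen)
  ## end rings: all nodes of the first/last structured layer columns
  end1 <- unlist(lapply(seq_len(n_circ), function(a) {
    sapply(k_all, function(k) key[[paste0("w", 1L, ".", a, ".", k)]])
  }))
  end2 <- unlist(lapply(seq_len(n_circ), function(a) {
    sapply(k_all, function(k) key[[paste0("w", n_axial, ".", a, ".", k)]])
  }))
  outer_nodes <- unlist(lapply(seq_len(n_axial), function(j)
    lapply(seq_len(n_circ), function(a) key[[paste0("w", j, ".", a, ".",
                                                    k_out)]])))
  meta <- list(kind = "aorta", structured = st, h = h,
               n_circ = n_circ, n_axial = n_axial,
               outer_nodes = as.integer(outer_nodes),
               end_layers = 2L)
  new_solid_mesh(nodes, elems_m, mat, load_faces,
                 list(end1 = as.integer(unlist(end1)),
                      end2 = as.integer(unlist(end2))), meta)
}
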