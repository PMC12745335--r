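## Reduced-order lumen hemodynamics.
##
## The steady systolic flow field is replaced by a one-dimensional
## Poiseuille resistive network: the true lumen is a chain of segments
## along the centerline, the false lumen a parallel chain over the flap
## span, tears are short orifice resistors coupling the two, and each
## branch outlet drains through its Windkessel resistance. The network
## preserves the calibration mathematics (total resistance from SBP/flow,
## Murray-law allocation by branch area, fine-tuning of the arch pressure
## to within 2% MAPE) and the true/false-lumen pressure-difference
## mechanism, at desk scale.

#' Total vascular resistance from systolic pressure and flow
#'
#' @param sbp systolic blood pressure (mmHg).
#' @param flow systolic flow rate (L/min).
#' @return total resistance in mmHg.min/L.
#' @export
#' @examples
#' total_resistance(159, 25)   # 6.36
total_resistance <- function(sbp, flow) {
  if (any(sbp <= 0) || any(flow <= 0)) stop("sbp and flow must be positive")
  sbp / flow
}

#' Inlet condition from a 1/7 power-law velocity profile
#'
#' The turbulent 1/7 power-law profile u(r) = u_max (1 - r/R)^(1/7) has
#' mean/peak velocity ratio 2 n^2 / ((n+1)(2n+1)) = 49/60 for n = 7.
#' Forward mode computes the flow from a peak velocity; inverse mode
#' (`flow` given) derives the peak velocity for a target flow.
#'
#' @param peak_velocity peak (centerline) velocity, m/s.
#' @param radius inlet radius, mm.
#' @param flow optional target flow (L/min) for the inverse mode.
#' @return list with `peak_velocity` (m/s), `mean_velocity` (m/s), `flow`
#'   (L/min), `radius` (mm), `profile` (function of r/R in [0, 1]).
#' @export
inlet_from_velocity <- function(peak_velocity = NULL, radius, flow = NULL) {
  if (radius <= 0) stop("radius must be positive")
  ratio <- 49 / 60
  area_m2 <- pi * (radius / 1000)^2
  if (is.null(peak_velocity)) {
    if (is.null(flow) || flow <= 0) stop("give peak_velocity or flow > 0")
    mean_v <- (flow / 1000 / 60) / area_m2
    peak_velocity <- mean_v / ratio
  } else {
    if (peak_velocity <= 0) stop("peak velocity must be positive")
    mean_v <- ratio * peak_velocity
    flow <- mean_v * area_m2 * 1000 * 60
  }
  pk <- peak_velocity
  structure(list(peak_velocity = pk, mean_velocity = mean_v, flow = flow,
                 radius = radius,
                 profile = function(r_rel) pk * (1 - pmin(pmax(r_rel, 0), 1))^(1 / 7)),
            class = "inlet_condition")
}

#' Allocate total resistance over outlets by Murray's law
#'
#' Outlet conductances are proportional to branch cross-sectional area
#' (larger branches carry more flow), and sum to 1/R_total, so the
#' parallel combination of outlet resistances reproduces the total.
#'
#' @param R_total total resistance (mmHg.min/L).
#' @param areas outlet cross-sectional areas (mm^2).
#' @return object of class `outlet_set`: data frame of `area`,
#'   `resistance`, plus attribute `R_total`.
#' @export
allocate_outlets <- function(R_total, areas) {
  if (length(areas) == 0) stop("empty outlet list")
  if (R_total <= 0 || any(areas <= 0)) stop("inputs must be positive")
  g <- (1 / R_total) * areas / sum(areas)
  out <- data.frame(area = areas, resistance = 1 / g)
  attr(out, "R_total") <- R_total
  class(out) <- c("outlet_set", "data.frame")
  out
}

## effective Poiseuille radius (mm) per lumen per segment arclength
lumen_radii <- function(scene, s) {
  r_full <- approx(scene$s_surf, rowMeans(scene$radius_matrix),
                   xout = s, rule = 2)$y
  flap <- scene$flap
  tl <- r_full; fl <- rep(NA_real_, length(s))
  if (!is.null(flap)) {
    span <- abs(((flap$theta2 - flap$theta1 + pi) %% (2 * pi)) - pi)
    ## chord through the section: split disc into circular segments;
    ## effective radius from the sector areas r_eff = sqrt(A / pi)
    frac_tl <- span / (2 * pi)
    in_flap <- s >= flap$s_range[1] & s <= flap$s_range[2]
    a_full <- pi * r_full^2
    a_tl <- a_full * frac_tl
    a_fl <- a_full - a_tl
    if (!is.null(scene$params$thrombus)) {
      th <- scene$params$thrombus
      in_th <- in_flap & s >= th$s_range[1] & s <= th$s_range[2]
      ## thrombus wedge occupies ~frac of the FL sector to depth thickness
      occ <- th$frac * (2 * r_full * th$thickness - th$thickness^2) * pi / 2
      a_fl[in_th] <- pmax(a_fl[in_th] - occ[in_th], 0.1 * a_fl[in_th])
    }
    tl[in_flap] <- sqrt(a_tl[in_flap] / pi)
    fl[in_flap] <- sqrt(a_fl[in_flap] / pi)
  }
  list(tl = tl, fl = fl)
}

## Poiseuille resistance of a segment, mmHg.min/L
poiseuille_R <- function(radius_mm, length_mm, mu = 0.004) {
  r <- radius_mm / 1000; l <- length_mm / 1000
  R_si <- 8 * mu * l / (pi * r^4)          # Pa.s/m^3
  R_si / PA_PER_MMHG / 60000               # mmHg.min/L  (1 m^3/s = 60000 L/min)
}

#' Solve the reduced-order lumen network
#'
#' Kirchhoff solve of the Poiseuille network for segment pressures; tears
#' couple the lumens as short orifices of the tear radius (length = flap
#' thickness); outlets drain to zero (venous) reference through their
#' Windkessel resistances; the inlet injects the systolic flow. Pressures
#' and wall shear stress (4 mu Q / (pi r^3)) are then sampled onto the
#' structured-surface nodes of the scene.
#'
#' @param scene an `aorta_scene`.
#' @param inlet an `inlet_condition` (only `flow` is used by the network).
#' @param outlets an `outlet_set` aligned with `scene$outlets` rows.
#' @param mu blood dynamic viscosity (Pa.s).
#' @param n_seg number of centerline segments.
#' @param structured optional `structured_surface` on which to sample the
#'   field (defaults to a 200 x 50 parameterization of the scene).
#' @return object of class `pressure_field`: `points` (sample locations),
#'   `pressure_mmhg`, `wss_pa`, `lumen` ("true"/"false") per structured
#'   node (layer-major), plus the network solution (`node_s`, `p_true`,
#'   `p_false`, `arch_pressure`, flows).
#' @export
solve_network <- function(scene, inlet, outlets, mu = 0.004, n_seg = 100L,
                          structured = NULL) {
  stopifnot(inherits(scene, "aorta_scene"))
  if (nrow(outlets) != nrow(scene$outlets))
    stop("outlet set does not match scene outlets")
  L <- scene$params$length
  s_nodes <- seq(0, L, length.out = n_seg + 1L)
  rads <- lumen_radii(scene, (s_nodes[-1] + s_nodes[-(n_seg + 1L)]) / 2)
  seg_len <- diff(s_nodes)

  flap <- scene$flap
  fl_present <- !is.null(flap)
  fl_nodes <- if (fl_present)
    which(s_nodes >= flap$s_range[1] & s_nodes <= flap$s_range[2]) else integer(0)

  n_tl <- n_seg + 1L
  idx_fl <- if (length(fl_nodes) > 0)
    setNames(n_tl + seq_along(fl_nodes), fl_nodes) else integer(0)
  n_tot <- n_tl + length(fl_nodes)

  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  add_edge <- function(a, b, g) {
    ii <<- c(ii, a, b, a, b); jj <<- c(jj, a, b, b, a)
    gg <<- c(gg, g, g, -g, -g)
  }
  ## true-lumen chain
  for (k in seq_len(n_seg)) {
    g <- 1 / poiseuille_R(rads$tl[k], seg_len[k], mu)
    add_edge(k, k + 1L, g)
  }
  ## false-lumen chain
  if (length(fl_nodes) > 1) {
    for (q in seq_len(length(fl_nodes) - 1L)) {
      k <- fl_nodes[q]
      r_fl <- rads$fl[min(k, n_seg)]
      g <- 1 / poiseuille_R(r_fl, s_nodes[fl_nodes[q + 1L]] - s_nodes[k], mu)
      add_edge(idx_fl[q], idx_fl[q + 1L], g)
    }
  }
  ## tears couple TL and FL
  n_tears <- 0L
  if (fl_present && !is.null(scene$tears) && nrow(scene$tears) > 0 &&
      length(fl_nodes) > 0) {
    for (tt in seq_len(nrow(scene$tears))) {
      k <- which.min(abs(s_nodes - scene$tears$s[tt]))
      qf <- which.min(abs(fl_nodes - k))
      g <- 1 / poiseuille_R(scene$tears$radius[tt],
                            max(scene$params$flap_thickness %||% 1, 1), mu)
      add_edge(k, idx_fl[qf], g)
      n_tears <- n_tears + 1L
    }
  }
  fl_disconnected <- fl_present && length(fl_nodes) > 0 && n_tears == 0L
  if (fl_disconnected)
    warning("false lumen has no tear: assigned stagnation pressure")

  ## outlets to ground (diagonal conductance)
  diag_extra <- numeric(n_tot)
  for (o in seq_len(nrow(outlets))) {
    k <- which.min(abs(s_nodes - scene$outlets$s[o]))
    diag_extra[k] <- diag_extra[k] + 1 / outlets$resistance[o]
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = gg, dims = c(n_tot, n_tot))
  Matrix::diag(G) <- Matrix::diag(G) + diag_extra
  b <- numeric(n_tot)
  b[1] <- inlet$flow          # flow injection (L/min)

  if (fl_disconnected) {
    keep <- seq_len(n_tl)
    p <- numeric(n_tot)
    p[keep] <- as.vector(Matrix::solve(G[keep, keep], b[keep]))
    p[-keep] <- p[fl_nodes[1]]   # inlet-side (proximal) stagnation pressure
  } else {
    p <- as.vector(Matrix::solve(G, b))
  }

  p_true <- p[seq_len(n_tl)]
  p_false <- rep(NA_real_, n_tl)
  if (length(fl_nodes) > 0) p_false[fl_nodes] <- p[idx_fl]

  ## segment flows and WSS
  q_tl <- -diff(p_true) / vapply(seq_len(n_seg), function(k)
    poiseuille_R(rads$tl[k], seg_len[k], mu), numeric(1))
  wss_tl <- wss_poiseuille(abs(q_tl), rads$tl, mu)
  wss_fl <- rep(NA_real_, n_seg)
  if (length(fl_nodes) > 1) {
    for (q in seq_len(length(fl_nodes) - 1L)) {
      k <- fl_nodes[q]
      Rseg <- poiseuille_R(rads$fl[min(k, n_seg)],
                           s_nodes[fl_nodes[q + 1L]] - s_nodes[k], mu)
      qfl <- (p[idx_fl[q]] - p[idx_fl[q + 1L]]) / Rseg
      kk <- k:(fl_nodes[q + 1L] - 1L)
      wss_fl[kk] <- wss_poiseuille(abs(qfl), rads$fl[pmin(kk, n_seg)], mu)
    }
  } else if (length(fl_nodes) == 1 || fl_disconnected) {
    wss_fl[] <- 0
  }

  ## arch pressure: mean TL pressure proximal to the landmark
  arch <- s_nodes <= scene$landmark_arclength
  arch_pressure <- mean(p_true[arch])

  ## sample onto the structured surface
  if (is.null(structured)) structured <- parameterize_surface(scene)
  samp <- sample_field_on_structured(scene, structured, s_nodes, p_true,
                                     p_false, wss_tl, wss_fl)
  structure(c(samp, list(node_s = s_nodes, p_true = p_true,
                         p_false = p_false, arch_pressure = arch_pressure,
                         inlet_flow = inlet$flow,
                         fl_disconnected = fl_disconnected,
                         structured = structured)),
            class = "pressure_field")
}

wss_poiseuille <- function(q_lmin, r_mm, mu) {
  q <- q_lmin / 60000           # m^3/s
  r <- r_mm / 1000
  4 * mu * q / (pi * r^3)       # Pa
}

sample_field_on_structured <- function(scene, structured, s_nodes,
                                       p_true, p_false, wss_tl, wss_fl) {
  nl <- structured$n_layers; nn <- structured$n_nodes
  cl <- centerline_eval(structured$s, scene$params$arch_radius)
  flap <- scene$flap
  pressure <- matrix(0, nl, nn); wss <- matrix(0, nl, nn)
  lumen <- matrix("true", nl, nn)
  seg_mid <- (s_nodes[-1] + s_nodes[-length(s_nodes)]) / 2
  for (j in seq_len(nl)) {
    s_j <- structured$s[j]
    in_fl_span <- !is.null(flap) && s_j >= flap$s_range[1] &&
      s_j <= flap$s_range[2]
    if (in_fl_span) {
      rel <- sweep(matrix(structured$nodes[j, , ], nn, 3), 2,
                   structured$layer_centers[j, ])
      th <- atan2(rel %*% cl$e2[j, ], rel %*% cl$e1[j, ])
      mid_tl <- (flap$theta1 + flap$theta2) / 2
      half_span <- abs(((flap$theta2 - flap$theta1 + pi) %% (2 * pi)) - pi) / 2
      is_tl <- abs(((th - mid_tl + pi) %% (2 * pi)) - pi) <= half_span
      lumen[j, !is_tl] <- "false"
    }
    pt <- approx(s_nodes, p_true, xout = s_j, rule = 2)$y
    pf <- if (any(is.finite(p_false)))
      approx(s_nodes[is.finite(p_false)], p_false[is.finite(p_false)],
             xout = s_j, rule = 2)$y else pt
    k <- which.min(abs(seg_mid - s_j))
    wt <- wss_tl[k]
    wf <- if (is.finite(wss_fl[k])) wss_fl[k] else 0
    pressure[j, ] <- ifelse(lumen[j, ] == "true", pt, pf)
    wss[j, ] <- ifelse(lumen[j, ] == "true", wt, wf)
  }
  pts <- matrix(aperm(structured$nodes, c(2, 1, 3)), nl * nn, 3)
  list(points = pts,
       pressure_mmhg = as.vector(t(pressure)),
       wss_pa = as.vector(t(wss)),
       lumen = as.vector(t(lumen)),
       pressure_matrix = pressure, wss_matrix = wss, lumen_matrix = lumen)
}

#' Tune the total resistance to match a target systolic pressure
#'
#' Bisection on a scale factor applied to the calculated total resistance
#' (conductances rescaled uniformly, Murray allocation preserved) until the
#' simulated arch pressure is within `tol` of the target SBP. The
#' pressure-resistance map is monotone, so bisection always terminates on
#' solvable scenes.
#'
#' @param scene an `aorta_scene`; `inlet` an `inlet_condition`.
#' @param target_sbp target systolic pressure (mmHg).
#' @param tol relative tolerance (default 0.02 = 2% MAPE).
#' @param bracket multiplicative search bracket around the calculated
#'   resistance.
#' @param max_iter bisection cap.
#' @return list with `R_calculated`, `R_tuned`, `adjustment_percent`,
#'   `achieved_mape`, `outlets` (tuned `outlet_set`), `field` (the tuned
#'   `pressure_field`).
#' @export
tune_total_resistance <- function(scene, inlet, target_sbp, tol = 0.02,
                                  bracket = c(0.1, 10), max_iter = 60L,
                                  mu = 0.004, n_seg = 100L,
                                  structured = NULL) {
  if (target_sbp <= 0) stop("target SBP must be positive")
  R_calc <- total_resistance(target_sbp, inlet$flow)
  if (is.null(structured)) structured <- parameterize_surface(scene)
  arch_at <- function(scale) {
    out <- allocate_outlets(R_calc * scale, scene$outlets$area)
    fld <- solve_network(scene, inlet, out, mu = mu, n_seg = n_seg,
                         structured = structured)
    list(p = fld$arch_pressure, field = fld, outlets = out)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- arch_at(lo); f_hi <- arch_at(hi)
  if ((f_lo$p - target_sbp) * (f_hi$p - target_sbp) > 0) {
    best <- if (abs(f_lo$p - target_sbp) < abs(f_hi$p - target_sbp)) f_lo else f_hi
    mape <- abs(best$p - target_sbp) / target_sbp
    if (mape > tol)
      stop("tolerance unreachable in bracket; best MAPE ",
           signif(100 * mape, 3), "%")
  }
  mid <- NULL
  for (it in seq_len(max_iter)) {
    sc_mid <- sqrt(lo * hi)
    mid <- arch_at(sc_mid)
    if (abs(mid$p - target_sbp) / target_sbp <= tol) break
    if ((mid$p - target_sbp) * (f_lo$p - target_sbp) > 0) {
      lo <- sc_mid; f_lo <- mid
    } else hi <- sc_mid
  }
  mape <- abs(mid$p - target_sbp) / target_sbp
  if (mape > tol) stop("tolerance unreachable in ", max_iter,
                       " iterations; best MAPE ", signif(100 * mape, 3), "%")
  R_tuned <- attr(mid$outlets, "R_total")
  list(R_calculated = R_calc, R_tuned = R_tuned,
       adjustment_percent = 100 * (R_tuned - R_calc) / R_calc,
       achieved_mape = mape, simulated_sbp = mid$p,
       outlets = mid$outlets, field = mid$field)
}

#' True/false lumen pressure summary with paired t-test
#'
#' Spatially averaged true- and false-lumen pressures per patient and the
#' two-sided paired t-test across patients.
#'
#' @param fields list of `pressure_field`s (>= 2 patients).
#' @return list with `table` (per-patient means) and `t_test`
#'   (statistic, df, p value).
#' @export
lumen_pressure_summary <- function(fields) {
  if (length(fields) < 2) stop("need at least 2 patients")
  tab <- do.call(rbind, lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    data.frame(patient = i,
               tl_mean = mean(f$pressure_mmhg[f$lumen == "true"]),
               fl_mean = mean(f$pressure_mmhg[f$lumen == "false"]))
  }))
  d <- tab$tl_mean - tab$fl_mean
  if (sd(d) < 1e-12) {
    tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
  } else {
    ht <- t.test(tab$tl_mean, tab$fl_mean, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  list(table = tab, t_test = tt)
}
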