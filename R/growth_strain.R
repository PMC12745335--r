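## Growth-rate maps from node-to-node surface correspondence.
##
## With baseline and follow-up structured surfaces in node-to-node
## correspondence, the local surface deformation gradient is estimated at
## each node from the 4-neighbour stencil of the structured grid
## (circumferential neighbours wrap; axial differences are one-sided at the
## end layers; the triad is completed with the unit surface normal, i.e.
## no transverse stretch). The circumferential logarithmic strain is
## ln sqrt(e_c' F'F e_c) with e_c the template's local circumferential
## direction, and dividing by the elapsed years gives the growth rate in
## percent per year. Negative rates (shrinkage) are permitted.

#' Circumferential logarithmic growth-rate map
#'
#' @param template baseline `structured_surface`.
#' @param deformed matched surface with node-to-node correspondence
#'   (a `structured_surface` with identical grid dimensions, e.g. the
#'   `deformed` output of [nonrigid_register()]).
#' @param years elapsed time between the two geometries (> 0).
#' @return object of class `growth_rate_map`: `rate` (n_layers x n_nodes,
#'   %/year, `NA` at degenerate patches), `strain` (log strain), `years`.
#' @export
growth_strain <- function(template, deformed, years) {
  if (years <= 0) stop("years must be positive")
  stopifnot(inherits(template, "structured_surface"),
            template$n_layers == deformed$n_layers,
            template$n_nodes == deformed$n_nodes)
  nl <- template$n_layers; nn <- template$n_nodes
  X <- template$nodes; Y <- deformed$nodes

  strain <- matrix(NA_real_, nl, nn)
  for (j in seq_len(nl)) {
    jm <- max(1L, j - 1L); jp <- min(nl, j + 1L)
    Xj <- matrix(X[j, , ], nn, 3); Yj <- matrix(Y[j, , ], nn, 3)
    ip <- c(2:nn, 1L); im <- c(nn, 1:(nn - 1L))
    tc0 <- (Xj[ip, ] - Xj[im, ]) / 2
    tc1 <- (Yj[ip, ] - Yj[im, ]) / 2
    ta0 <- (matrix(X[jp, , ], nn, 3) - matrix(X[jm, , ], nn, 3)) / (jp - jm)
    ta1 <- (matrix(Y[jp, , ], nn, 3) - matrix(Y[jm, , ], nn, 3)) / (jp - jm)
    n0 <- cross3(tc0, ta0); n1 <- cross3(tc1, ta1)
    l0 <- row_norms(n0); l1 <- row_norms(n1)
    ec <- matrix(template$frames$circumferential[j, , ], nn, 3)
    for (a in seq_len(nn)) {
      M0 <- cbind(tc0[a, ], ta0[a, ], n0[a, ] / max(l0[a], 1e-12))
      M1 <- cbind(tc1[a, ], ta1[a, ], n1[a, ] / max(l1[a], 1e-12))
      if (abs(det(M0)) < 1e-10 || l0[a] < 1e-10 || l1[a] < 1e-10) next
      F_ <- M1 %*% solve(M0)
      v <- F_ %*% ec[a, ]
      lam <- sqrt(sum(v * v))
      if (is.finite(lam) && lam > 0) strain[j, a] <- log(lam)
    }
  }
  structure(list(rate = 100 * strain / years, strain = strain,
                 years = years,
                 landmark_layer = template$landmark_layer),
            class = "growth_rate_map")
}

#' @export
print.growth_rate_map <- function(x, ...) {
  cat("growth_rate_map:", nrow(x$rate), "x", ncol(x$rate),
      "nodes; interval", x$years, "yr; range",
      paste(signif(range(x$rate, na.rm = TRUE), 3), collapse = " to "),
      "%/yr\n")
  invisible(x)
}
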