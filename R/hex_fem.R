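## Linear elastostatics on 8-node hexahedra (trilinear, 2x2x2 Gauss).
##
## The forward-penalty stress computation only ever needs small-strain
## linear elasticity with an artificially stiff isotropic material, so the
## element is the plain displacement-based trilinear hex. For Poisson
## ratios approaching 1/2 a selective-reduced-integration option assembles
## the volumetric (lambda) term with a single center Gauss point to avoid
## locking. Assembly is vectorized across elements; stiffness blocks are
## grouped by material region and scaled by the region Young's modulus at
## solve time, which makes uniform-stiffness rescaling exact and regional
## sensitivity re-solves cheap.

## local corner coordinates (xi, eta, zeta) of the standard hex
hex_corners <- function() {
  cbind(xi   = c(-1,  1,  1, -1, -1,  1, 1, -1),
        eta  = c(-1, -1,  1,  1, -1, -1, 1,  1),
        zeta = c(-1, -1, -1, -1,  1,  1, 1,  1))
}

## shape-function gradients wrt local coords at one local point: 8 x 3
hex_dN <- function(xi, eta, zeta) {
  cc <- hex_corners()
  cbind(cc[, 1] * (1 + eta * cc[, 2]) * (1 + zeta * cc[, 3]),
        cc[, 2] * (1 + xi * cc[, 1]) * (1 + zeta * cc[, 3]),
        cc[, 3] * (1 + xi * cc[, 1]) * (1 + eta * cc[, 2])) / 8
}

gauss_points <- function() {
  g <- 1 / sqrt(3)
  cc <- hex_corners() * g
  list(points = cc, weights = rep(1, 8))
}

## Per-Gauss-point geometry for a block of elements.
## X: list of three nE x 8 matrices (node coordinates per element).
## Returns G (list of three nE x 8 matrices of dN/dx_i) and detJ (nE).
element_gradients <- function(X, dN) {
  J <- vector("list", 9)  # J[[3*(l-1)+j]] = dx_j/dxi_l, length nE
  for (l in 1:3) for (j in 1:3)
    J[[3 * (l - 1) + j]] <- as.vector(X[[j]] %*% dN[, l])
  Jm <- function(l, j) J[[3 * (l - 1) + j]]
  ## cofactor of entry (l, j); (J^{-1})_{j l} = cof(l, j) / det
  cof <- function(l, j) {
    ls <- setdiff(1:3, l); js <- setdiff(1:3, j)
    (Jm(ls[1], js[1]) * Jm(ls[2], js[2]) -
       Jm(ls[1], js[2]) * Jm(ls[2], js[1])) * (-1)^(l + j)
  }
  detJ <- Jm(1, 1) * cof(1, 1) + Jm(1, 2) * cof(1, 2) + Jm(1, 3) * cof(1, 3)
  nE <- nrow(X[[1]])
  G <- vector("list", 3)
  for (i in 1:3) {
    acc <- matrix(0, nE, 8)
    ## dN/dx_i [a] = sum_l (J^{-1})_{i l} dN/dxi_l [a] = sum_l cof(l, i)/det
    for (l in 1:3) acc <- acc +
        (cof(l, i) / detJ) * matrix(dN[, l], nE, 8, byrow = TRUE)
    G[[i]] <- acc
  }
  list(G = G, detJ = detJ)
}

## Accumulate ke contributions of one Gauss point into ke_arr (nE x 576).
## lam/mu are scalars (unit-modulus Lame parameters); set lam = 0 for the
## deviatoric pass of selective reduced integration.
accumulate_ke <- function(ke_arr, G, detJ, w, lam, mu) {
  for (a in 1:8) {
    Ga <- list(G[[1]][, a], G[[2]][, a], G[[3]][, a])
    for (b in 1:8) {
      Gb <- list(G[[1]][, b], G[[2]][, b], G[[3]][, b])
      dot_ab <- Ga[[1]] * Gb[[1]] + Ga[[2]] * Gb[[2]] + Ga[[3]] * Gb[[3]]
      for (i in 1:3) for (j in 1:3) {
        val <- lam * Ga[[i]] * Gb[[j]] + mu * Ga[[j]] * Gb[[i]]
        if (i == j) val <- val + mu * dot_ab
        p <- (a - 1L) * 3L + i; q <- (b - 1L) * 3L + j
        col <- (p - 1L) * 24L + q
        ke_arr[, col] <- ke_arr[, col] + w * detJ * val
      }
    }
  }
  ke_arr
}

#' Assemble the unit-modulus stiffness matrix of an element subset
#'
#' Lame parameters are taken for E = 1 (scale the result by the region
#' Young's modulus); `sri = TRUE` integrates the volumetric term with one
#' center point (selective reduced integration).
#'
#' @keywords internal
assemble_unit_stiffness <- function(nodes, elems, nu, sri = nu > 0.4,
                                    block = 4000L) {
  if (nu <= 0 || nu >= 0.5) stop("poisson ratio must be in (0, 0.5)")
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  ndof <- 3L * nrow(nodes)
  gp <- gauss_points()
  dN_list <- lapply(seq_len(8), function(g)
    hex_dN(gp$points[g, 1], gp$points[g, 2], gp$points[g, 3]))
  dN0 <- hex_dN(0, 0, 0)

  K <- NULL
  nE <- nrow(elems)
  for (start in seq(1L, nE, by = block)) {
    idx <- start:min(start + block - 1L, nE)
    el <- elems[idx, , drop = FALSE]
    X <- lapply(1:3, function(j) matrix(nodes[el, j], length(idx), 8))
    ke_arr <- matrix(0, length(idx), 576)
    for (g in 1:8) {
      eg <- element_gradients(X, dN_list[[g]])
      if (any(eg$detJ <= 0)) stop("non-positive element Jacobian")
      ke_arr <- accumulate_ke(ke_arr, eg$G, eg$detJ, gp$weights[g],
                              if (sri) 0 else lam, mu)
    }
    if (sri) {
      eg <- element_gradients(X, dN0)
      ke_arr <- accumulate_ke(ke_arr, eg$G, eg$detJ, 8, lam, 0)
    }
    dof <- matrix(0L, length(idx), 24)
    for (a in 1:8) for (i in 1:3)
      dof[, (a - 1L) * 3L + i] <- 3L * (el[, a] - 1L) + i
    I <- dof[, rep(1:24, each = 24), drop = FALSE]
    Jc <- dof[, rep(1:24, times = 24), drop = FALSE]
    Kb <- Matrix::sparseMatrix(i = as.vector(I), j = as.vector(Jc),
                               x = as.vector(ke_arr), dims = c(ndof, ndof))
    K <- if (is.null(K)) Kb else K + Kb
  }
  K
}

#' Solve the constrained linear system K u = f
#' @param K assembled stiffness (dgCMatrix), `f` load vector,
#'   `fixed_dofs` integer dof indices clamped to zero.
#' @keywords internal
solve_elasticity <- function(K, f, fixed_dofs) {
  ndof <- length(f)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  if (length(free) == 0) stop("all dofs constrained")
  Kff <- K[free, free, drop = FALSE]
  u <- numeric(ndof)
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff)), f[free]),
    error = function(e) stop("singular or non-positive-definite system ",
                             "(insufficient constraints?): ",
                             conditionMessage(e)))
  u[free] <- as.vector(sol)
  u
}

## Per-element mean stress tensors (6 Voigt components: xx,yy,zz,xy,yz,zx)
## for displacement u; E_vec is the per-element Young's modulus (kPa).
element_stress <- function(nodes, elems, u, E_vec, nu, block = 4000L) {
  lam0 <- nu / ((1 + nu) * (1 - 2 * nu))
  mu0 <- 1 / (2 * (1 + nu))
  gp <- gauss_points()
  dN_list <- lapply(seq_len(8), function(g)
    hex_dN(gp$points[g, 1], gp$points[g, 2], gp$points[g, 3]))
  nE <- nrow(elems)
  sig <- matrix(0, nE, 6)
  vol <- numeric(nE)
  ux <- matrix(u[3 * (elems - 1) + 1], nE, 8)
  uy <- matrix(u[3 * (elems - 1) + 2], nE, 8)
  uz <- matrix(u[3 * (elems - 1) + 3], nE, 8)
  for (start in seq(1L, nE, by = block)) {
    idx <- start:min(start + block - 1L, nE)
    el <- elems[idx, , drop = FALSE]
    X <- lapply(1:3, function(j) matrix(nodes[el, j], length(idx), 8))
    Ux <- ux[idx, , drop = FALSE]; Uy <- uy[idx, , drop = FALSE]
    Uz <- uz[idx, , drop = FALSE]
    acc <- matrix(0, length(idx), 6)
    vsum <- numeric(length(idx))
    for (g in 1:8) {
      eg <- element_gradients(X, dN_list[[g]])
      G <- eg$G
      exx <- rowSums(G[[1]] * Ux); eyy <- rowSums(G[[2]] * Uy)
      ezz <- rowSums(G[[3]] * Uz)
      gxy <- rowSums(G[[2]] * Ux) + rowSums(G[[1]] * Uy)
      gyz <- rowSums(G[[3]] * Uy) + rowSums(G[[2]] * Uz)
      gzx <- rowSums(G[[1]] * Uz) + rowSums(G[[3]] * Ux)
      tr <- exx + eyy + ezz
      w <- eg$detJ  # unit Gauss weights
      acc[, 1] <- acc[, 1] + w * (lam0 * tr + 2 * mu0 * exx)
      acc[, 2] <- acc[, 2] + w * (lam0 * tr + 2 * mu0 * eyy)
      acc[, 3] <- acc[, 3] + w * (lam0 * tr + 2 * mu0 * ezz)
      acc[, 4] <- acc[, 4] + w * mu0 * gxy
      acc[, 5] <- acc[, 5] + w * mu0 * gyz
      acc[, 6] <- acc[, 6] + w * mu0 * gzx
      vsum <- vsum + w
    }
    sig[idx, ] <- acc / vsum * E_vec[idx]
    vol[idx] <- vsum
  }
  list(stress = sig, volume = vol)
}

## principal stresses + von Mises from Voigt rows
principal_von_mises <- function(sig) {
  n <- nrow(sig)
  smax <- numeric(n)
  vm <- sqrt(0.5 * ((sig[, 1] - sig[, 2])^2 + (sig[, 2] - sig[, 3])^2 +
                      (sig[, 3] - sig[, 1])^2) +
               3 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2))
  for (e in seq_len(n)) {
    m <- matrix(c(sig[e, 1], sig[e, 4], sig[e, 6],
                  sig[e, 4], sig[e, 2], sig[e, 5],
                  sig[e, 6], sig[e, 5], sig[e, 3]), 3, 3)
    smax[e] <- max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }
  list(max_principal = smax, von_mises = vm)
}

## volume-weighted element-to-node averaging of per-element values
elements_to_nodes <- function(elems, values, volumes, n_nodes) {
  num <- rep(0, n_nodes); den <- rep(0, n_nodes)
  for (a in 1:8) {
    num <- num + unname(tapply_add(elems[, a], values * volumes, n_nodes))
    den <- den + unname(tapply_add(elems[, a], volumes, n_nodes))
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

tapply_add <- function(index, x, n) {
  out <- numeric(n)
  agg <- rowsum(x, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
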