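## Varifold surface metric and kernel-displacement nonrigid registration.
##
## Surfaces are compared as varifolds: each facet contributes its center c
## and area-weighted normal n, and two surfaces interact through a Gaussian
## spatial kernel K_W times a squared-cosine orientation weight
## (n_i . n_j)^2 / (|n_i| |n_j|). The registration minimizes
##   cost(mu) = D(Phi(T), S) / sigma^2 + sum_kl mu_k' K_R(lambda_k,
##              lambda_l) mu_l
## where D is the full squared varifold distance (self terms included, so
## the minimum is at coincidence) and Phi is a single-step kernel
## displacement field u(x) = sum_k K_R(x, lambda_k) mu_k over control
## points lambda on a regular grid. The momentum term penalizes the kinetic
## energy of the deformation exactly as in control-point LDDMM; the flow
## integration is collapsed to one step, adequate for the modest
## deformations of serial aortic imaging.

## oriented triangle soup from a structured surface (optionally subsampled)
structured_to_varifold <- function(st, layer_step = 1L, node_step = 1L) {
  layers <- seq(1L, st$n_layers, by = layer_step)
  nodes <- seq(1L, st$n_nodes, by = node_step)
  v <- matrix(0, length(layers) * length(nodes), 3)
  for (ii in seq_along(layers))
    v[(ii - 1L) * length(nodes) + seq_along(nodes), ] <-
      matrix(st$nodes[layers[ii], nodes, ], length(nodes), 3)
  nr <- length(layers); nc <- length(nodes)
  vid <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  fs <- vector("list", nr - 1L)
  for (i in seq_len(nr - 1L)) {
    j <- seq_len(nc)
    fs[[i]] <- rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j + 1L)),
                     cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i + 1L, j)))
  }
  list(vertices = v, faces = do.call(rbind, fs))
}

## facet centers and area-weighted normals of a triangle mesh
tri_centers_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]; v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  centers <- (v1 + v2 + v3) / 3
  normals <- 0.5 * cross3(v2 - v1, v3 - v1)
  list(centers = centers, normals = normals)
}

as_varifold <- function(x, layer_step = 1L, node_step = 1L) {
  if (inherits(x, "structured_surface"))
    x <- structured_to_varifold(x, layer_step, node_step)
  if (!is.null(x$centers) && !is.null(x$normals)) return(x)
  if (is.null(x$vertices) || is.null(x$faces))
    stop("surface must have vertices/faces or centers/normals")
  tri_centers_normals(x)
}

## <A, B> varifold inner product; returns value and (optionally) gradients
## wrt A's centers and normals. Processed in row blocks so the n_A x n_B
## kernel intermediates never exceed block x n_B (full surfaces can have
## 10^4 facets; a dense 10^4 x 10^4 kernel matrix would not fit).
varifold_inner <- function(cA, nA, cB, nB, w_W, grad = FALSE,
                           block = 1024L) {
  la <- row_norms(nA); lb <- row_norms(nB)
  if (any(la < 1e-12) || any(lb < 1e-12)) stop("zero-length facet normal")
  nAr <- nrow(cA)
  sumB <- rowSums(cB^2)
  val <- 0
  gC <- if (grad) matrix(0, nAr, 3) else NULL
  gN <- if (grad) matrix(0, nAr, 3) else NULL
  for (start in seq(1L, nAr, by = block)) {
    idx <- start:min(start + block - 1L, nAr)
    cAb <- cA[idx, , drop = FALSE]; nAb <- nA[idx, , drop = FALSE]
    d2 <- sweep(-2 * (cAb %*% t(cB)), 2, sumB, "+") + rowSums(cAb^2)
    k <- exp(-d2 / w_W^2)
    dot <- nAb %*% t(nB)
    invl <- outer(1 / la[idx], 1 / lb)
    kw <- k * dot^2 * invl
    val <- val + sum(kw)
    if (grad) {
      ## d/dcA: sum_j (-2/w^2) (cA_i - cB_j) k_ij wgt_ij
      gC[idx, ] <- (-2 / w_W^2) * (cAb * rowSums(kw) - kw %*% cB)
      ## d/dnA: sum_j k_ij [2 dot n_Bj/(la lb) - dot^2/(la^3 lb) n_Ai]
      t1 <- (k * 2 * dot * invl) %*% nB
      t2 <- rowSums(kw) / la[idx]^2
      gN[idx, ] <- t1 - nAb * t2
    }
  }
  list(value = val, gC = gC, gN = gN)
}

#' Squared varifold distance between oriented surfaces
#'
#' Full squared distance <T,T> - 2<T,S> + <S,S> with Gaussian spatial
#' kernel of width `w_W` and squared-cosine orientation weighting with
#' facet-area weights; non-negative, symmetric, and zero iff the oriented
#' center/normal sets coincide.
#'
#' @param T,S `structured_surface`s, triangle meshes
#'   (`vertices`/`faces`), or lists with `centers` and `normals`.
#' @param w_W spatial kernel width (mm).
#' @return scalar squared distance.
#' @export
varifold_distance <- function(T, S, w_W = 20) {
  A <- as_varifold(T); B <- as_varifold(S)
  if (nrow(A$centers) == 0 || nrow(B$centers) == 0) stop("empty surface")
  varifold_inner(A$centers, A$normals, A$centers, A$normals, w_W)$value -
    2 * varifold_inner(A$centers, A$normals, B$centers, B$normals, w_W)$value +
    varifold_inner(B$centers, B$normals, B$centers, B$normals, w_W)$value
}

## control points on a regular grid over the template bounding box,
## pruned to within 1.5 spacings of the surface
control_grid <- function(pts, spacing) {
  lo <- apply(pts, 2, min) - spacing / 2
  hi <- apply(pts, 2, max) + spacing / 2
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i] + spacing, by = spacing))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  colnames(g) <- NULL
  nn <- nn_index(g, pts)
  g[nn$dist < 1.5 * spacing, , drop = FALSE]
}

gauss_kernel_matrix <- function(a, b, width) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * (a %*% t(b))
  exp(-d2 / width^2)
}

#' Nonrigid registration by kernel displacement under the varifold metric
#'
#' Deforms a template structured surface to match a target surface by
#' minimizing (squared varifold distance)/sigma^2 plus the momentum
#' regularization over control-point momenta (quasi-Newton L-BFGS-B with
#' analytic gradients). The returned deformed surface keeps node-to-node
#' correspondence with the template.
#'
#' @param template a `structured_surface`.
#' @param target a `structured_surface` or triangle mesh.
#' @param sigma data/regularization trade-off (default 1).
#' @param w_W varifold kernel width (mm, default 20).
#' @param w_R deformation kernel width (mm, default 20).
#' @param control_spacing control-point grid spacing (default `w_R`).
#' @param layer_step,node_step structured-grid subsampling used for the
#'   data term (the final displacement is applied to the full grid).
#' @param max_iter optimizer iteration cap.
#' @return list with `deformation` (control points, momenta, widths,
#'   sigma), `deformed` (template after deformation, a
#'   `structured_surface`), `cost_trace`, `converged`, `final_cost`.
#' @export
nonrigid_register <- function(template, target, sigma = 1, w_W = 20,
                              w_R = 20, control_spacing = w_R,
                              layer_step = 4L, node_step = 2L,
                              max_iter = 150L) {
  stopifnot(inherits(template, "structured_surface"))
  sub <- structured_to_varifold(template, layer_step, node_step)
  tgt <- as_varifold(target, layer_step, node_step)
  cB <- tgt$centers; nB <- tgt$normals
  sBB <- varifold_inner(cB, nB, cB, nB, w_W)$value

  lambda <- control_grid(sub$vertices, control_spacing)
  m <- nrow(lambda)
  A <- gauss_kernel_matrix(sub$vertices, lambda, w_R)   # n_v x m
  Kreg <- gauss_kernel_matrix(lambda, lambda, w_R)      # m x m

  f <- sub$faces
  nv <- nrow(sub$vertices)
  trace_env <- new.env(parent = emptyenv())
  trace_env$costs <- numeric(0)

  cost_grad <- function(par, want_grad = TRUE) {
    mu <- matrix(par, m, 3)
    y <- sub$vertices + A %*% mu
    v1 <- y[f[, 1], , drop = FALSE]; v2 <- y[f[, 2], , drop = FALSE]
    v3 <- y[f[, 3], , drop = FALSE]
    cA <- (v1 + v2 + v3) / 3
    nA <- 0.5 * cross3(v2 - v1, v3 - v1)
    self <- varifold_inner(cA, nA, cA, nA, w_W, grad = want_grad)
    crossI <- varifold_inner(cA, nA, cB, nB, w_W, grad = want_grad)
    D <- self$value - 2 * crossI$value + sBB
    reg <- sum(mu * (Kreg %*% mu))
    val <- D / sigma^2 + reg
    if (!want_grad) return(val)
    gC <- 2 * self$gC - 2 * crossI$gC   # dD/d centers
    gN <- 2 * self$gN - 2 * crossI$gN   # dD/d normals
    ## chain rule to vertices
    gV <- matrix(0, nv, 3)
    gc3 <- gC / 3
    for (c_ in 1:3) {
      idx <- f[, c_]
      for (i in 1:3)
        gV[, i] <- gV[, i] + tapply_add(idx, gc3[, i], nv)
    }
    e <- list(y[f[, 2], ] - y[f[, 3], ],   # for v1
              y[f[, 3], ] - y[f[, 1], ],   # for v2
              y[f[, 1], ] - y[f[, 2], ])   # for v3
    for (c_ in 1:3) {
      gn_c <- 0.5 * cross3(e[[c_]], gN)
      idx <- f[, c_]
      for (i in 1:3)
        gV[, i] <- gV[, i] + tapply_add(idx, gn_c[, i], nv)
    }
    gMu <- crossprod(A, gV) / sigma^2 + 2 * (Kreg %*% mu)
    list(value = val, grad = as.vector(gMu))
  }

  ## fn and gr share one evaluation (optim calls them back to back)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- cost_grad(par, want_grad = TRUE)
    cache$par <- par; cache$res <- res
    trace_env$costs <- c(trace_env$costs, res$value)
    res
  }
  fn <- function(par) evaluate(par)$value
  gr <- function(par) evaluate(par)$grad

  opt <- optim(rep(0, 3 * m), fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1e10))
  mu <- matrix(opt$par, m, 3)

  ## apply the fitted displacement to the full template grid
  full_pts <- matrix(aperm(template$nodes, c(2, 1, 3)),
                     template$n_layers * template$n_nodes, 3)
  disp <- gauss_kernel_matrix(full_pts, lambda, w_R) %*% mu
  new_pts <- full_pts + disp
  deformed <- template
  deformed$nodes <- aperm(array(new_pts,
                                c(template$n_nodes, template$n_layers, 3)),
                          c(2, 1, 3))
  deformed$layer_centers <- t(vapply(seq_len(template$n_layers), function(j)
    colMeans(matrix(deformed$nodes[j, , ], template$n_nodes, 3)), numeric(3)))
  deformed$frames <- local_frames(deformed)

  converged <- opt$convergence == 0
  if (!converged)
    warning("nonrigid registration did not converge (code ",
            opt$convergence, "); final cost ", signif(opt$value, 6))
  list(deformation = list(control_points = lambda, momenta = mu,
                          w_W = w_W, w_R = w_R, sigma = sigma),
       deformed = deformed,
       cost_trace = trace_env$costs,
       accepted_costs = cummin(trace_env$costs),
       converged = converged, final_cost = opt$value)
}
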