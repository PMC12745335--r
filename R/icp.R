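## Rigid alignment by iterative closest point with SVD (Kabsch) updates.

#' Rigid transform constructor
#' @param R 3x3 rotation, `t` length-3 translation.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("R is not a proper rotation")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @export
apply_rigid <- function(transform, pts) {
  sweep(as.matrix(pts) %*% t(transform$R), 2, transform$t, "+")
}

#' Compose two rigid transforms (apply `a` after `b`)
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

## least-squares rigid fit of paired point sets via SVD
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.vector(cq - R %*% cp))
}

#' Iterative closest point rigid registration
#'
#' Each iteration matches every source point to its nearest target point
#' (deterministic lowest-index tie-breaking) and solves the least-squares
#' rigid fit by SVD. Iterations stop when the average change of the
#' rotation (angle, radians) and translation (norm, mm) over the three most
#' recent iterations falls below the tolerances. If `prerotate = TRUE`, the
#' registration is restarted from 30-degree pre-rotations about each
#' coordinate axis and the lowest-residual result returned (the manual
#' initialization fallback for badly misaligned scans).
#'
#' @param source_pts,target_pts n x 3 matrices (at least 3 non-collinear
#'   points each).
#' @param init initial [rigid_transform()].
#' @param rot_tol,trans_tol termination tolerances on the windowed average
#'   rotation/translation change.
#' @param window number of most recent iterations averaged for the
#'   termination test.
#' @param max_iter iteration cap.
#' @param prerotate try +/-30 degree pre-rotations about x, y, z and keep
#'   the best result.
#' @return a `rigid_transform` with attributes `rms` (final mean matched
#'   distance) and `iterations`.
#' @export
icp_align <- function(source_pts, target_pts, init = rigid_transform(),
                      rot_tol = 1e-4, trans_tol = 5e-4, window = 3L,
                      max_iter = 200L, prerotate = FALSE) {
  source_pts <- as.matrix(source_pts); target_pts <- as.matrix(target_pts)
  check_noncollinear(source_pts); check_noncollinear(target_pts)

  run_one <- function(init) {
    R <- init$R; tt <- init$t
    dR <- numeric(0); dT <- numeric(0)
    it <- 0L
    repeat {
      it <- it + 1L
      P <- sweep(source_pts %*% t(R), 2, tt, "+")
      nn <- nn_index(P, target_pts)
      fit <- kabsch(source_pts, target_pts[nn$index, , drop = FALSE])
      dR <- c(dR, rotation_angle(t(R) %*% fit$R))
      dT <- c(dT, sqrt(sum((fit$t - tt)^2)))
      R <- fit$R; tt <- fit$t
      if (length(dR) >= window &&
          mean(tail(dR, window)) < rot_tol &&
          mean(tail(dT, window)) < trans_tol) break
      if (it >= max_iter) break
    }
    P <- sweep(source_pts %*% t(R), 2, tt, "+")
    nn <- nn_index(P, target_pts)
    list(R = R, t = tt, rms = mean(nn$dist), it = it)
  }

  inits <- list(init)
  if (prerotate) {
    ctr <- colMeans(source_pts)
    for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
      for (sgn in c(1, -1)) {
        Rp <- rotation_matrix(ax, sgn * pi / 6)
        inits[[length(inits) + 1L]] <-
          rigid_transform(Rp %*% init$R,
                          as.vector(Rp %*% (init$t - ctr)) + ctr)
      }
  }
  best <- NULL
  for (ini in inits) {
    res <- run_one(ini)
    if (is.null(best) || res$rms < best$rms) best <- res
  }
  out <- rigid_transform(best$R, best$t)
  attr(out, "rms") <- best$rms
  attr(out, "iterations") <- best$it
  out
}

check_noncollinear <- function(pts) {
  if (nrow(pts) < 3) stop("need at least 3 points")
  s <- svd(sweep(pts, 2, colMeans(pts)), nu = 0, nv = 0)$d
  if (s[2] < 1e-9 * max(s[1], 1)) stop("degenerate (collinear) point set")
}
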