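## Small internal helpers: vector algebra, nearest neighbours, rotations.

`%||%` <- function(a, b) if (is.null(a)) b else a

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  if (any(n < .Machine$double.eps)) stop("cannot normalize zero-length vector")
  m / n
}

cross3 <- function(a, b) {
  ## cross product for n x 3 matrices (or length-3 vectors)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Nearest-neighbour indices by blocked exhaustive search
#'
#' Deterministic lowest-index tie-breaking (ties resolved by `which.min`).
#' Exhaustive search in blocks keeps memory bounded without an external
#' spatial index; point sets in this package are 10^3-10^4 points.
#'
#' @param query n x 3 matrix of query points.
#' @param ref m x 3 matrix of reference points.
#' @param chunk block size for the query set.
#' @return list with integer `index` (into rows of `ref`) and `dist`.
#' @keywords internal
nn_index <- function(query, ref, chunk = 512L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  if (nrow(ref) == 0L) stop("empty reference point set")
  n <- nrow(query)
  idx <- integer(n); d2 <- numeric(n)
  ref_sq <- rowSums(ref * ref)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    q <- query[start:end, , drop = FALSE]
    ## |q - r|^2 = |q|^2 - 2 q.r + |r|^2
    cross <- q %*% t(ref)
    dmat <- sweep(-2 * cross, 2, ref_sq, "+") + rowSums(q * q)
    j <- max.col(-dmat, ties.method = "first")
    idx[start:end] <- j
    d2[start:end] <- dmat[cbind(seq_len(nrow(dmat)), j)]
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

#' k nearest neighbours (small k), blocked exhaustive search
#' @keywords internal
knn_index <- function(query, ref, k = 4L, chunk = 512L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  if (nrow(ref) == 0L) stop("empty reference point set")
  k <- min(k, nrow(ref))
  n <- nrow(query)
  idx <- matrix(0L, n, k); dd <- matrix(0, n, k)
  ref_sq <- rowSums(ref * ref)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    q <- query[start:end, , drop = FALSE]
    dmat <- sweep(-2 * (q %*% t(ref)), 2, ref_sq, "+") + rowSums(q * q)
    for (r in seq_len(nrow(dmat))) {
      ord <- order(dmat[r, ])[seq_len(k)]
      idx[start + r - 1L, ] <- ord
      dd[start + r - 1L, ] <- sqrt(pmax(dmat[r, ord], 0))
    }
  }
  list(index = idx, dist = dd)
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle in radians.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c_ + s_ * ux + (1 - c_) * (u %o% u)
}

#' Rotation angle (radians) of a rotation matrix
#' @keywords internal
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct)))
}

## deterministic per-call RNG: every generator takes a seed and restores
## the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## periodic linear interpolation of radius-vs-angle samples
interp_periodic <- function(theta_samples, values, theta_out) {
  ord <- order(theta_samples)
  th <- theta_samples[ord]; v <- values[ord]
  th_ext <- c(th, th[1] + 2 * pi)
  v_ext <- c(v, v[1])
  approx(th_ext, v_ext, xout = theta_out %% (2 * pi) +
           ifelse(theta_out %% (2 * pi) < th[1], 2 * pi, 0),
         rule = 2, ties = mean)$y
}
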