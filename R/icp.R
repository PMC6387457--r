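#' Iterative closest point rigid registration
#'
#' Point-to-point ICP: alternates nearest-neighbour correspondence (with a
#' distance cap and optional reciprocal rejection) and the closed-form
#' rigid alignment from the SVD of the correspondence cross-covariance,
#' until the relative change of the residual RMS drops below `tol` or
#' `max_iter` is reached.
#'
#' @param source N x 3 points to move (e.g. a new frame, camera coords).
#' @param target M x 3 reference points (e.g. the ray-cast model).
#' @param init initial [rigid_pose()] mapping source into the target frame.
#' @param max_iter maximum iterations.
#' @param tol relative RMS change at which iteration stops.
#' @param max_corr correspondence rejection distance cap, m.
#' @param reciprocal keep only correspondences that are mutual nearest
#'   neighbours.
#' @return list with `pose` (a [rigid_pose()]), `rms` (final residual RMS,
#'   m), `iterations` and `n_corr` (correspondences in the final fit).
#' @export
icp_register <- function(source, target, init = rigid_pose(), max_iter = 50,
                         tol = 1e-6, max_corr = 0.05, reciprocal = FALSE) {
  src <- unclass(point_cloud(source))
  tgt <- unclass(point_cloud(target))
  if (nrow(src) < 3 || nrow(tgt) < 3)
    stop("degenerate geometry: ICP needs at least 3 points in each cloud")
  .check_noncollinear(src, "source")
  .check_noncollinear(tgt, "target")

  pose <- init
  rms_prev <- Inf
  rms <- Inf
  n_corr <- 0L
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    moved <- sweep(src %*% t(pose$R), 2, pose$t, "+")
    nn <- RANN::nn2(tgt, moved, k = 1)
    keep <- nn$nn.dists[, 1] <= max_corr
    if (reciprocal && any(keep)) {
      back <- RANN::nn2(moved, tgt[nn$nn.idx[keep, 1], , drop = FALSE], k = 1)
      keep[keep] <- back$nn.idx[, 1] == which(keep)
    }
    if (sum(keep) < 3)
      stop("degenerate geometry: fewer than 3 correspondences within the ",
           "distance cap (", signif(max_corr, 3), " m)")
    s <- src[keep, , drop = FALSE]
    t2 <- tgt[nn$nn.idx[keep, 1], , drop = FALSE]
    step <- kabsch_align(s, t2)
    pose <- step$pose
    rms <- step$rms
    n_corr <- sum(keep)
    if (is.finite(rms_prev) &&
        abs(rms_prev - rms) < tol * max(rms_prev, 1e-12)) break
    rms_prev <- rms
  }
  list(pose = pose, rms = rms, iterations = iterations, n_corr = n_corr)
}

.check_noncollinear <- function(m, label) {
  c0 <- sweep(m, 2, colMeans(m))
  sv <- svd(c0, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))
    stop("degenerate geometry: ", label, " points are collinear")
}

#' Closed-form rigid alignment of paired point sets (Kabsch / SVD)
#'
#' Least-squares rotation and translation mapping `source` rows onto their
#' paired `target` rows, from the SVD of the cross-covariance, with the
#' determinant correction that excludes reflections.
#'
#' @param source,target N x 3 matrices of paired points.
#' @return list with `pose` (a [rigid_pose()]) and `rms` residual.
#' @export
kabsch_align <- function(source, target) {
  s <- as.matrix(source); t2 <- as.matrix(target)
  stopifnot(nrow(s) == nrow(t2), ncol(s) == 3, ncol(t2) == 3)
  if (nrow(s) < 3) stop("degenerate geometry: need at least 3 paired points")
  cs <- colMeans(s); ct <- colMeans(t2)
  H <- crossprod(sweep(s, 2, cs), sweep(t2, 2, ct)) / nrow(s)
  sv <- svd(H)
  if (sv$d[3] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: rank < 3 cross-covariance (points coplanar ",
         "or collinear)")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  tv <- ct - as.vector(R %*% cs)
  res <- sweep(s %*% t(R), 2, tv, "+") - t2
  list(pose = rigid_pose(R, tv), rms = sqrt(mean(rowSums(res^2))))
}
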