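#' Least-squares rigid transform between paired point sets (Kabsch/SVD)
#'
#' Closed-form solution of the orthogonal Procrustes problem: the rigid
#' transform minimising the (optionally weighted) sum of squared distances
#' from transformed source points to their paired targets. The reflection
#' case is resolved by flipping the sign of the smallest singular vector so
#' the rotation is proper (det = +1). This is the inner solver of every ICP
#' iteration.
#'
#' @param source_points,target_points n x 3 matrices of paired points, n >= 3.
#' @param weights optional non-negative per-pair weights.
#' @return A [rigid_transform()] `T` with `T(source) ~ target`.
#' @export
estimate_rigid_transform <- function(source_points, target_points,
                                     weights = NULL) {
  src <- as_point_matrix(source_points)
  tgt <- as_point_matrix(target_points)
  n <- nrow(src)
  if (nrow(tgt) != n) stop("point counts differ", call. = FALSE)
  if (n < 3L) stop("degenerate geometry: need at least 3 point pairs",
                   call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  w <- weights / sum(weights)
  cs <- colSums(src * w)
  ct <- colSums(tgt * w)
  X <- sweep(src, 2, cs)
  Y <- sweep(tgt, 2, ct)
  H <- t(X * w) %*% Y
  sX <- svd(X * sqrt(w))$d
  if (sX[2] < 1e-9 * max(sX[1], 1e-300)) {
    stop("degenerate geometry: source points are (near-)collinear",
         call. = FALSE)
  }
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Coarse initial alignment of two point clouds
#'
#' Aligns centroids and principal axes (eigenvectors of the point covariance,
#' in descending eigenvalue order). Among the four proper-rotation sign
#' assignments of the axes it returns the one with the smallest post-alignment
#' nearest-neighbour RMS. This is the "initial alignment" step that brings
#' two scans exported in different coordinate frames close enough for ICP to
#' refine.
#'
#' If any pair of adjacent covariance eigenvalues is closer than a ratio of
#' 1.05 (near-isotropic cloud, axes ill-defined), a warning is issued and a
#' centroid-only alignment is returned.
#'
#' @param source_points,target_points point matrices (>= 3 each).
#' @return A [rigid_transform()] mapping source into the target frame.
#' @export
initial_alignment <- function(source_points, target_points) {
  src <- as_point_matrix(source_points)
  tgt <- as_point_matrix(target_points)
  if (nrow(src) < 3L || nrow(tgt) < 3L) {
    stop("need at least 3 points in each cloud", call. = FALSE)
  }
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  es <- eigen(stats::cov(src), symmetric = TRUE)
  et <- eigen(stats::cov(tgt), symmetric = TRUE)
  ratio_ok <- function(ev) all(ev[1:2] / ev[2:3] >= 1.05)
  if (!ratio_ok(es$values) || !ratio_ok(et$values)) {
    warning("near-isotropic point covariance; falling back to centroid-only ",
            "initial alignment", call. = FALSE)
    return(rigid_transform(diag(3), ct - cs))
  }
  Vs <- right_handed(es$vectors)
  Vt <- right_handed(et$vectors)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  best_rms <- Inf
  for (s in signs) {
    R <- Vt %*% diag(s) %*% t(Vs)
    cand <- rigid_transform(R, ct - as.numeric(R %*% cs))
    moved <- transform_points(cand, src)
    rms <- sqrt(mean(cpp_nearest_neighbour(moved, tgt)$distance^2))
    if (rms < best_rms) {
      best_rms <- rms
      best <- cand
    }
  }
  best
}

right_handed <- function(V) {
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Exact closest point on a single triangle
#'
#' Projects `p` onto the closed triangle `(a, b, c)`, returning the closest
#' point (interior, edge or vertex region) and the Euclidean distance in mm.
#'
#' @param p query point (length 3).
#' @param a,b,c triangle vertices (length 3 each).
#' @return list with `point` and `distance`.
#' @export
nearest_point_on_triangle <- function(p, a, b, c) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  ab <- b - a; ac <- c - a
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  if (sum(cr^2) < 1e-24) stop("degenerate triangle", call. = FALSE)
  cpp_closest_point_triangle(as.numeric(p), a, b, c)
}

#' Closest point on a mesh surface
#'
#' For each query point, the closest point over all mesh triangles, its
#' distance (mm) and the face it lies on. Accelerated with per-face bounding
#' boxes; `exhaustive = TRUE` forces the plain all-triangles scan (the
#' reference the accelerated path is tested against). Distance ties are
#' broken towards the lowest face index so results are reproducible.
#'
#' @param points query point or n x 3 matrix.
#' @param mesh a non-empty [triangle_mesh()].
#' @param exhaustive disable the bounding-box pruning.
#' @return list with `distance` (n), `point` (n x 3) and `face` (n, 1-based).
#' @export
nearest_point_on_mesh <- function(points, mesh, exhaustive = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (n_faces(mesh) == 0L) stop("empty mesh", call. = FALSE)
  pts <- as_point_matrix(points)
  cpp_closest_point_mesh(pts, mesh$vertices, mesh$faces,
                         exhaustive = exhaustive)
}

#' ICP parameter set
#'
#' Controls the optimized-alignment (ICP) stage. The trim fraction discards
#' the worst correspondences each iteration, giving robustness to localized
#' surface defects such as fixation-plate overlay on postoperative scans.
#'
#' @param max_iterations maximum ICP iterations (>= 1).
#' @param rms_change_tolerance convergence threshold on the change in RMS
#'   between iterations (mm).
#' @param trim_fraction fraction in `[0, 1)` of worst pairs dropped per
#'   iteration.
#' @param max_correspondence_distance pairs farther than this (mm) are
#'   rejected; `Inf` disables the gate.
#' @param sample_count use at most this many source points (uniform random
#'   subsample drawn with `seed`); `Inf` uses all.
#' @param seed integer seed for the subsample draw.
#' @return An `icp_params` list.
#' @export
icp_params <- function(max_iterations = 100L, rms_change_tolerance = 1e-5,
                       trim_fraction = 0.1,
                       max_correspondence_distance = Inf,
                       sample_count = Inf, seed = 1L) {
  stopifnot(max_iterations >= 1, rms_change_tolerance > 0,
            trim_fraction >= 0, trim_fraction < 1,
            max_correspondence_distance > 0, sample_count >= 3)
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_change_tolerance = rms_change_tolerance,
                 trim_fraction = trim_fraction,
                 max_correspondence_distance = max_correspondence_distance,
                 sample_count = sample_count, seed = as.integer(seed)),
            class = "icp_params")
}

#' Optimized alignment: trimmed point-to-mesh ICP
#'
#' Iteratively (1) finds for every transformed source point its closest point
#' on the target surface, (2) rejects pairs beyond
#' `max_correspondence_distance` and the worst `trim_fraction` of the rest,
#' (3) solves the rigid least-squares fit ([estimate_rigid_transform()]) on
#' the survivors and composes it onto the running transform. Iteration stops
#' when the RMS over surviving pairs changes by less than
#' `rms_change_tolerance` or at `max_iterations`.
#'
#' Correspondences are point-to-triangle (surface), not vertex-to-vertex, so
#' the result is insensitive to the two scans being tessellated differently.
#'
#' @param source_points points to register (e.g. the T1 reference-region
#'   vertices).
#' @param target_mesh the surface to register onto (e.g. the T0
#'   reference-region sub-mesh).
#' @param init initial [rigid_transform()] (e.g. from
#'   [initial_alignment()]); identity by default.
#' @param params an [icp_params()] set.
#' @return A `registration_report`: list with `final_transform`,
#'   `rms_per_iteration` (mm, over surviving pairs, after each fit),
#'   `iterations_run`, `converged`, `correspondences_used`.
#' @export
icp_refine <- function(source_points, target_mesh, init = NULL,
                       params = icp_params()) {
  src <- as_point_matrix(source_points)
  stopifnot(inherits(target_mesh, "triangle_mesh"))
  if (nrow(src) < 3L) stop("need at least 3 source points", call. = FALSE)
  if (is.null(init)) init <- rigid_transform()
  if (is.finite(params$sample_count) && params$sample_count < nrow(src)) {
    keep <- withr::with_seed(params$seed,
                             sort(sample.int(nrow(src), params$sample_count)))
    src <- src[keep, , drop = FALSE]
  }
  trans <- init
  rms_hist <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  n_surv <- nrow(src)
  for (it in seq_len(params$max_iterations)) {
    moved <- transform_points(trans, src)
    cp <- nearest_point_on_mesh(moved, target_mesh)
    d <- cp$distance
    ok <- which(d <= params$max_correspondence_distance)
    if (length(ok) == 0L) {
      stop("all correspondences rejected; increase ",
           "max_correspondence_distance", call. = FALSE)
    }
    n_keep <- max(3L, ceiling((1 - params$trim_fraction) * length(ok)))
    surv <- ok[order(d[ok])[seq_len(min(n_keep, length(ok)))]]
    if (length(surv) < 3L) {
      stop("fewer than 3 surviving correspondences", call. = FALSE)
    }
    delta <- estimate_rigid_transform(moved[surv, , drop = FALSE],
                                      cp$point[surv, , drop = FALSE])
    trans <- compose_transforms(delta, trans)
    fitted <- transform_points(delta, moved[surv, , drop = FALSE])
    rms <- sqrt(mean(rowSums((fitted - cp$point[surv, , drop = FALSE])^2)))
    if (!is.finite(rms)) stop("non-finite RMS in ICP", call. = FALSE)
    rms_hist <- c(rms_hist, rms)
    n_surv <- length(surv)
    if (abs(prev_rms - rms) < params$rms_change_tolerance) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  structure(list(final_transform = trans, rms_per_iteration = rms_hist,
                 iterations_run = length(rms_hist), converged = converged,
                 correspondences_used = n_surv),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf(
    "<registration_report> %d iterations (%s), final RMS %.6g mm, %d pairs\n",
    x$iterations_run, if (x$converged) "converged" else "not converged",
    utils::tail(x$rms_per_iteration, 1), x$correspondences_used))
  invisible(x)
}
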