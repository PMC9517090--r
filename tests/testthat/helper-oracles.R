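# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (brute force / two-pass / grid
# search) so it shares no code path with the implementation it checks.

# unit cube: 8 vertices, 12 faces, outward winding
make_cube <- function(side = 1, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  # faces by hand (1-based into the expand.grid ordering), outward normals
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  triangle_mesh(v, f)
}

# grid-search closest distance from p to triangle abc over a dense
# barycentric lattice (independent of the analytic projection)
grid_closest_distance <- function(p, a, b, c, n = 400L) {
  u <- rep(seq(0, 1, length.out = n + 1L), each = n + 1L)
  v <- rep(seq(0, 1, length.out = n + 1L), times = n + 1L)
  keep <- u + v <= 1
  u <- u[keep]; v <- v[keep]
  pts <- outer(1 - u - v, a) + outer(u, b) + outer(v, c)
  min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2))
}

# exhaustive per-face scan in R around the single-triangle kernel
r_exhaustive_closest <- function(p, mesh) {
  best <- Inf; bestf <- NA_integer_
  for (f in seq_len(n_faces(mesh))) {
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    d <- nearest_point_on_triangle(p, tri[1, ], tri[2, ], tri[3, ])$distance
    if (d < best) { best <- d; bestf <- f }
  }
  list(distance = best, face = bestf)
}

# two-pass streaming recomputation of the deviation summary
streaming_summary <- function(d) {
  n <- length(d)
  m <- 0
  for (x in d) m <- m + x / n
  ss <- 0
  for (x in d) ss <- ss + x * x / n
  list(max_dev = max(d), min_dev = min(d), mean_dev = m, rms = sqrt(ss),
       n_points = n)
}

# pooled two-sample t from first principles
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  t <- (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# rotation / translation error of a recovered transform vs the applied pose:
# a perfect registration satisfies recovered = pose^-1
recovery_error <- function(recovered, pose) {
  err <- compose_transforms(recovered, pose)
  list(rot_deg = rotation_angle(err),
       trans_mm = sqrt(sum(err$translation^2)))
}
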