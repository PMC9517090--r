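#' Skull phantom specification
#'
#' Parameters of the synthetic plan/postop mesh pair used to exercise the
#' pipeline with known ground truth. The phantom is schematic, not
#' anatomical: a cranial dome (half-ellipsoid with fixed orbital and
#' zygomatic surface bumps) provides the stable registration reference
#' (ROI1), and a detached maxillary body (ellipsoid, or a flat patch for
#' analytic checks) provides the measured region (ROI2).
#'
#' The dome is deliberately anisotropic and asymmetric: a rotationally
#' symmetric cranium would make rotations about its axis unrecoverable by
#' any landmark-free registration, so recovery experiments would be
#' ill-posed.
#'
#' @param cranial_semi_axes half-axis lengths (mm) of the dome in x
#'   (width), y (length), z (height).
#' @param cranial_density `c(n_theta, n_phi)` tessellation counts of the
#'   dome.
#' @param maxilla_shape `"ellipsoid"` or `"patch"` (flat square patch whose
#'   outward normal is +z; used for analytic ground-truth checks).
#' @param maxilla_size semi-axes (mm) of the ellipsoid, or
#'   `c(width, width)` of the patch.
#' @param maxilla_center centre (mm) of the maxillary body.
#' @param maxilla_density tessellation counts (`c(n_theta, n_phi)` for the
#'   ellipsoid, `c(n, n)` grid for the patch).
#' @param residual_transform [rigid_transform()] applied to the maxilla
#'   between plan and postop, about the maxilla centre — the simulated
#'   surgical inaccuracy.
#' @param global_pose [rigid_transform()] applied to the whole postop mesh —
#'   the scan-frame difference registration must undo.
#' @param noise_sd isotropic Gaussian vertex noise on the postop mesh (mm).
#' @param noise_along_normals apply the noise along vertex normals instead
#'   of isotropically (surface-reconstruction-like).
#' @param artifact_fraction fraction (max 0.3) of postop maxillary vertices
#'   given an extra 2-5 mm outward displacement, emulating fixation-plate /
#'   metal rendering artifacts.
#' @param tessellation_jitter sd (mm) of an extra tangential vertex jitter
#'   applied to the postop mesh to emulate independent remeshing of the two
#'   scans (0 keeps identical topology and geometry).
#' @param seed integer; all phantom randomness flows from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(cranial_semi_axes = c(70, 90, 60),
                         cranial_density = c(36L, 12L),
                         maxilla_shape = c("ellipsoid", "patch"),
                         maxilla_size = c(22, 16, 12),
                         maxilla_center = c(0, 70, -35),
                         maxilla_density = c(24L, 12L),
                         residual_transform = rigid_transform(),
                         global_pose = rigid_transform(),
                         noise_sd = 0,
                         noise_along_normals = FALSE,
                         artifact_fraction = 0,
                         tessellation_jitter = 0,
                         seed = 1L) {
  maxilla_shape <- match.arg(maxilla_shape)
  if (any(cranial_semi_axes <= 0) || any(maxilla_size <= 0)) {
    stop("degenerate shape: all dimensions must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (artifact_fraction < 0 || artifact_fraction > 0.3) {
    stop("artifact_fraction must be in [0, 0.3]", call. = FALSE)
  }
  stopifnot(inherits(residual_transform, "rigid_transform"),
            inherits(global_pose, "rigid_transform"))
  structure(list(cranial_semi_axes = cranial_semi_axes,
                 cranial_density = as.integer(cranial_density),
                 maxilla_shape = maxilla_shape,
                 maxilla_size = maxilla_size,
                 maxilla_center = maxilla_center,
                 maxilla_density = as.integer(maxilla_density),
                 residual_transform = residual_transform,
                 global_pose = global_pose,
                 noise_sd = noise_sd,
                 noise_along_normals = noise_along_normals,
                 artifact_fraction = artifact_fraction,
                 tessellation_jitter = tessellation_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# half-ellipsoid dome (z >= 0) with fixed asymmetric surface bumps; UV grid
make_dome <- function(semi_axes = c(70, 90, 60), n_theta = 36L, n_phi = 12L,
                      bumps = TRUE) {
  stopifnot(n_theta >= 8, n_phi >= 4)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  phi <- seq(0, pi / 2, length.out = n_phi + 1L)[-1]   # pole handled apart
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(grid$phi) * cos(grid$theta),
                sin(grid$phi) * sin(grid$theta),
                cos(grid$phi))
  dirs <- rbind(c(0, 0, 1), dirs)                      # pole first
  if (bumps) {
    # two anterior "orbital" bumps + one right "zygomatic" bump; breaks the
    # dome's 180-degree rotational ambiguity and its mirror symmetry
    centres <- rbind(c(-0.35, 0.85, 0.30), c(0.35, 0.85, 0.30),
                     c(0.90, 0.25, 0.25))
    centres <- centres / sqrt(rowSums(centres^2))
    amp <- c(6, 6, 5)
    width <- c(0.18, 0.18, 0.15)                       # in unit-direction chord
    bump <- numeric(nrow(dirs))
    for (i in seq_len(nrow(centres))) {
      chord2 <- rowSums(sweep(dirs, 2, centres[i, ])^2)
      bump <- bump + amp[i] * exp(-chord2 / (2 * width[i]^2))
    }
    radial_scale <- 1 + bump / mean(semi_axes)
  } else {
    radial_scale <- rep(1, nrow(dirs))
  }
  verts <- sweep(dirs * radial_scale, 2, semi_axes, "*")
  faces <- uv_faces(n_theta, n_phi)
  triangle_mesh(verts, faces)
}

# full ellipsoid, UV tessellation, poles at +-z
make_ellipsoid <- function(semi_axes = c(22, 16, 12), center = c(0, 0, 0),
                           n_theta = 24L, n_phi = 12L) {
  stopifnot(n_theta >= 8, n_phi >= 4)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  phi <- seq(0, pi, length.out = n_phi + 1L)[-c(1L, n_phi + 1L)]
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- rbind(c(0, 0, 1),
                cbind(sin(grid$phi) * cos(grid$theta),
                      sin(grid$phi) * sin(grid$theta),
                      cos(grid$phi)),
                c(0, 0, -1))
  verts <- sweep(sweep(dirs, 2, semi_axes, "*"), 2, center, "+")
  n_rings <- n_phi - 1L
  faces <- uv_faces_sphere(n_theta, n_rings)
  triangle_mesh(verts, faces)
}

#' Flat square measurement patch
#'
#' A triangulated square grid in the z = `z` plane (outward normal +z),
#' centred at `center`. The patch is the analytic ground-truth phantom: a
#' copy displaced by a pure translation `t` along +z has every vertex at
#' exactly distance `|t|` from the original surface, so the deviation RMS is
#' `|t|` exactly.
#'
#' @param width side length (mm).
#' @param n grid subdivisions per side (n+1 vertices per side).
#' @param center patch centre (mm).
#' @param z kept for clarity; z-offset of the plane relative to `center[3]`.
#' @return A [triangle_mesh()].
#' @export
make_flat_patch <- function(width = 30, n = 15L, center = c(0, 0, 0), z = 0) {
  stopifnot(width > 0, n >= 1)
  s <- seq(-width / 2, width / 2, length.out = n + 1L)
  g <- expand.grid(x = s, y = s)
  verts <- cbind(g$x + center[1], g$y + center[2], center[3] + z)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  fl <- vector("list", 2L * n * n)
  k <- 1L
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      fl[[k]] <- c(a, b, c2); fl[[k + 1L]] <- c(a, c2, d)
      k <- k + 2L
    }
  }
  triangle_mesh(verts, do.call(rbind, fl))
}

# faces of a UV grid with a single +z pole (vertex 1) and open bottom
uv_faces <- function(n_theta, n_phi) {
  fl <- list()
  nxt <- function(j) if (j == n_theta) 1L else j + 1L
  ring_start <- function(r) 1L + (r - 1L) * n_theta   # rings 1..n_phi
  # pole fan to ring 1 (outward normals: counter-clockwise seen from +z)
  for (j in seq_len(n_theta)) {
    fl[[length(fl) + 1L]] <- c(1L, 1L + j, 1L + nxt(j))
  }
  for (r in seq_len(n_phi - 1L)) {
    a0 <- ring_start(r); b0 <- ring_start(r + 1L)
    for (j in seq_len(n_theta)) {
      a <- a0 + j; b <- a0 + nxt(j)
      c2 <- b0 + j; d <- b0 + nxt(j)
      fl[[length(fl) + 1L]] <- c(a, c2, d)
      fl[[length(fl) + 1L]] <- c(a, d, b)
    }
  }
  do.call(rbind, fl)
}

# faces of a closed UV sphere: vertex 1 = +z pole, rings, last vertex = -z
uv_faces_sphere <- function(n_theta, n_rings) {
  fl <- list()
  nxt <- function(j) if (j == n_theta) 1L else j + 1L
  ring_start <- function(r) 1L + (r - 1L) * n_theta
  south <- 1L + n_rings * n_theta + 1L
  for (j in seq_len(n_theta)) {
    fl[[length(fl) + 1L]] <- c(1L, 1L + j, 1L + nxt(j))
  }
  for (r in seq_len(n_rings - 1L)) {
    a0 <- ring_start(r); b0 <- ring_start(r + 1L)
    for (j in seq_len(n_theta)) {
      a <- a0 + j; b <- a0 + nxt(j)
      c2 <- b0 + j; d <- b0 + nxt(j)
      fl[[length(fl) + 1L]] <- c(a, c2, d)
      fl[[length(fl) + 1L]] <- c(a, d, b)
    }
  }
  a0 <- ring_start(n_rings)
  for (j in seq_len(n_theta)) {
    fl[[length(fl) + 1L]] <- c(a0 + j, south, a0 + nxt(j))
  }
  do.call(rbind, fl)
}

#' Generate a plan/postop phantom pair with known ground truth
#'
#' Builds the planned model (T0) — cranial dome plus maxillary body, with
#' ROI1 = the dome vertices and ROI2 = the maxillary vertices — and the
#' postoperative model (T1): a copy whose maxilla is displaced by the
#' specified residual transform (about the maxilla centre), the whole mesh
#' then moved by the global pose perturbation, optionally jittered, noised,
#' and given outlier "plate/metal" artifacts on a fraction of maxillary
#' vertices. T0 and T1 share tessellation topology; `tessellation_jitter`
#' decouples their geometry when tessellation-independence is under test.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `t0`, `t1` ([triangle_mesh()]es with normals),
#'   `truth` (list: `spec`, `roi1`, `roi2` — [roi_from_indices()] selections
#'   on T0, disjoint —, `residual_transform`, `global_pose`,
#'   `expected_rms_noise_floor`).
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dome <- make_dome(spec$cranial_semi_axes, spec$cranial_density[1],
                    spec$cranial_density[2])
  maxi <- switch(spec$maxilla_shape,
    ellipsoid = make_ellipsoid(spec$maxilla_size, spec$maxilla_center,
                               spec$maxilla_density[1],
                               spec$maxilla_density[2]),
    patch = make_flat_patch(width = spec$maxilla_size[1],
                            n = spec$maxilla_density[1],
                            center = spec$maxilla_center))
  n_dome <- n_vertices(dome)
  t0 <- triangle_mesh(rbind(dome$vertices, maxi$vertices),
                      rbind(dome$faces, maxi$faces + n_dome))
  roi1 <- roi_from_indices(t0, seq_len(n_dome), "ROI1")
  roi2 <- roi_from_indices(t0, n_dome + seq_len(n_vertices(maxi)), "ROI2")
  t0 <- compute_normals(t0)

  withr::with_seed(spec$seed, {
    v1 <- t0$vertices
    idx2 <- roi2$vertex_indices
    ctr <- colMeans(v1[idx2, , drop = FALSE])
    local_res <- about_point(spec$residual_transform, ctr)
    v1[idx2, ] <- transform_points(local_res, v1[idx2, , drop = FALSE])
    t1 <- triangle_mesh(v1, t0$faces)
    t1 <- compute_normals(t1)
    if (spec$artifact_fraction > 0) {
      k <- round(spec$artifact_fraction * length(idx2))
      if (k > 0) {
        hit <- sample(idx2, k)
        mag <- stats::runif(k, 2, 5)
        t1$vertices[hit, ] <- t1$vertices[hit, , drop = FALSE] +
          t1$vertex_normals[hit, , drop = FALSE] * mag
      }
    }
    if (spec$tessellation_jitter > 0) {
      t1$vertices <- t1$vertices +
        matrix(stats::rnorm(3L * nrow(t1$vertices), 0,
                            spec$tessellation_jitter), ncol = 3)
    }
    t1 <- transform_mesh(t1, spec$global_pose)
    if (spec$noise_sd > 0) {
      if (spec$noise_along_normals) {
        mag <- stats::rnorm(nrow(t1$vertices), 0, spec$noise_sd)
        t1$vertices <- t1$vertices + t1$vertex_normals * mag
      } else {
        t1$vertices <- t1$vertices +
          matrix(stats::rnorm(3L * nrow(t1$vertices), 0, spec$noise_sd),
                 ncol = 3)
      }
    }
    t1 <- compute_normals(triangle_mesh(t1$vertices, t1$faces))
  })
  list(t0 = t0, t1 = t1,
       truth = list(spec = spec, roi1 = roi1, roi2 = roi2,
                    residual_transform = spec$residual_transform,
                    global_pose = spec$global_pose,
                    expected_rms_noise_floor = spec$noise_sd))
}

# re-express a transform as acting about a fixed point c:
# x -> R (x - c) + c + t
about_point <- function(transform, centre) {
  rigid_transform(transform$rotation,
                  transform$translation + centre -
                    as.numeric(transform$rotation %*% centre))
}

# zero-noise ROI2 RMS produced by translating the maxilla by `mag` along
# `direction`; used to calibrate cohort effect sizes on the T0 geometry
translation_rms <- function(t0, roi2, mag, direction) {
  ref <- extract_submesh(t0, roi2)
  pts <- sweep(t0$vertices[roi2$vertex_indices, , drop = FALSE], 2,
               mag * direction, "+")
  sqrt(mean(nearest_point_on_mesh(pts, ref)$distance^2))
}

# secant solve: translation magnitude whose zero-noise ROI2 RMS equals target
calibrate_residual_magnitude <- function(t0, roi2, target, direction,
                                         tol = 1e-6) {
  if (target < tol) return(0)
  m0 <- target
  f0 <- translation_rms(t0, roi2, m0, direction) - target
  m1 <- m0 * target / (f0 + target)      # proportional first guess
  for (i in 1:20) {
    f1 <- translation_rms(t0, roi2, m1, direction) - target
    if (abs(f1) < tol) return(m1)
    step <- f1 * (m1 - m0) / (f1 - f0)
    m0 <- m1; f0 <- f1
    m1 <- m1 - step
    if (m1 <= 0) m1 <- m0 / 2
  }
  m1
}

#' Generate a synthetic surgical cohort
#'
#' Emulates the two-arm study structure: `n_per_group` cases per technique
#' group ("splintless", "splint"), each a phantom pair whose maxillary
#' residual is a pure translation (inferior direction) with magnitude drawn
#' around the group effect. Within each group the drawn magnitudes are
#' standardised exactly to `group_effects[g]` / `between_patient_sd` (sample
#' mean and SD), and each magnitude is calibrated against the T0 geometry so
#' the zero-noise ROI2 RMS equals the drawn value; the cohort therefore
#' realises its nominal conditions exactly, and what the pipeline recovers
#' measures the pipeline, not the draw. Subgroup labels follow the 3 + 2
#' monobloc/segmental split per group; subgroups label the cases only (the
#' maxilla always moves as one rigid piece).
#'
#' Default effects (1.22, 1.63 mm) and SD (0.4 mm) anchor the cohort to the
#' published group-level 3D errors of the splintless and splint arms.
#'
#' @param out_dir directory for STL, ROI-JSON and manifest files (created if
#'   needed). `NULL` keeps everything in memory.
#' @param n_per_group cases per group (default 5).
#' @param group_effects target mean 3D error (mm) per group.
#' @param between_patient_sd between-case SD (mm) of the drawn magnitudes.
#' @param spec_template [phantom_spec()] whose geometry/noise settings every
#'   case inherits (its residual and seed are overwritten per case).
#' @param seed integer master seed.
#' @return A tibble manifest: `case_id`, `group`, `subgroup`,
#'   `true_rms`, `seed`, and with `out_dir` the file columns `t0_path`,
#'   `t1_path`, `roi1_path`, `roi2_path`; otherwise a `pair` list-column of
#'   [generate_phantom_pair()] results.
#' @export
generate_cohort <- function(out_dir = NULL, n_per_group = 5L,
                            group_effects = c(splintless = 1.22,
                                              splint = 1.63),
                            between_patient_sd = 0.4,
                            spec_template = phantom_spec(noise_sd = 0.05),
                            seed = 1L) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (any(group_effects < 0) || between_patient_sd < 0) {
    stop("effect sizes and SD must be non-negative", call. = FALSE)
  }
  groups <- names(group_effects) %||% c("splintless", "splint")
  direction <- c(0, 0, -1)   # inferior displacement of the maxilla
  # calibration geometry: one noise-free template T0
  base <- generate_phantom_pair(
    phantom_spec(cranial_semi_axes = spec_template$cranial_semi_axes,
                 cranial_density = spec_template$cranial_density,
                 maxilla_shape = spec_template$maxilla_shape,
                 maxilla_size = spec_template$maxilla_size,
                 maxilla_center = spec_template$maxilla_center,
                 maxilla_density = spec_template$maxilla_density,
                 seed = spec_template$seed))
  rows <- withr::with_seed(seed, {
    out <- list()
    for (g in seq_along(groups)) {
      z <- stats::rnorm(n_per_group)
      z <- if (n_per_group >= 2L) (z - mean(z)) / stats::sd(z) else 0 * z
      mags <- pmax(0, group_effects[g] + between_patient_sd * z)
      sub <- rep(c("monobloc", "segmental"),
                 c(ceiling(0.6 * n_per_group),
                   n_per_group - ceiling(0.6 * n_per_group)))
      for (i in seq_len(n_per_group)) {
        mag <- calibrate_residual_magnitude(base$t0, base$truth$roi2,
                                            mags[i], direction)
        case_seed <- sample.int(.Machine$integer.max, 1L)
        pose <- rigid_transform(random_rotation(10),
                                stats::runif(3, -10, 10))
        out[[length(out) + 1L]] <- list(
          case_id = sprintf("case_%s_%02d", groups[g], i),
          group = groups[g], subgroup = sub[i], true_rms = mags[i],
          residual = rigid_transform(diag(3), mag * direction),
          pose = pose, seed = case_seed)
      }
    }
    out
  })
  pairs <- lapply(rows, function(r) {
    sp <- spec_template
    sp$residual_transform <- r$residual
    sp$global_pose <- r$pose
    sp$seed <- r$seed
    class(sp) <- "phantom_spec"
    generate_phantom_pair(sp)
  })
  manifest <- tibble::tibble(
    case_id = vapply(rows, `[[`, "", "case_id"),
    group = vapply(rows, `[[`, "", "group"),
    subgroup = vapply(rows, `[[`, "", "subgroup"),
    true_rms = vapply(rows, `[[`, 0, "true_rms"),
    seed = vapply(rows, function(r) as.integer(r$seed), 1L))
  if (is.null(out_dir)) {
    manifest$pair <- pairs
    return(manifest)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(seq_along(pairs), function(i) {
    id <- manifest$case_id[i]
    t0p <- file.path(out_dir, paste0(id, "_t0.stl"))
    t1p <- file.path(out_dir, paste0(id, "_t1.stl"))
    write_stl(pairs[[i]]$t0, t0p, dialect = "binary")
    write_stl(pairs[[i]]$t1, t1p, dialect = "binary")
    r1p <- file.path(out_dir, paste0(id, "_roi1.json"))
    r2p <- file.path(out_dir, paste0(id, "_roi2.json"))
    # predicate ROIs survive the STL round trip (vertex order changes when a
    # reader re-merges duplicated facet vertices, so index lists would not)
    write_roi_definition(list(name = "ROI1", type = "halfspace",
                              normal = c(0, 0, 1), offset = -5), r1p)
    write_roi_definition(list(name = "ROI2", type = "sphere",
                              center = spec_template$maxilla_center,
                              radius = 1.25 * max(spec_template$maxilla_size)),
                         r2p)
    c(t0p, t1p, r1p, r2p)
  })
  pm <- do.call(rbind, paths)
  manifest$t0_path <- pm[, 1]
  manifest$t1_path <- pm[, 2]
  manifest$roi1_path <- pm[, 3]
  manifest$roi2_path <- pm[, 4]
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
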