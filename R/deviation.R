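#' Point-to-surface deviation of a registered region
#'
#' For every sample point (typically the registered postoperative maxillary
#' vertices, in planned-model space), the distance to the nearest point of
#' the reference surface (the planned maxillary sub-mesh). With
#' `signed = TRUE`, the sign is that of the dot product between the offset
#' vector (sample minus closest point) and the face normal at the closest
#' point; zero distances are counted positive. Signed mode requires the
#' reference mesh to carry normals ([compute_normals()]) with consistent
#' winding — an inconsistently wound reference raises an error advising
#' unsigned mode.
#'
#' @param sample_points n x 3 matrix of measurement points (mm).
#' @param reference_mesh [triangle_mesh()] to measure against.
#' @param signed logical; compute signed distances.
#' @param reference_region label recorded in the result (e.g. `"ROI2"`).
#' @return A `deviation_result`: list with `sample_points`, `distances`,
#'   `closest_points`, `faces`, `signed`, `reference_region`, and `summary`
#'   (a [summarize_deviation()] tibble).
#' @export
surface_deviation <- function(sample_points, reference_mesh, signed = FALSE,
                              reference_region = "ROI2") {
  pts <- as_point_matrix(sample_points)
  if (nrow(pts) == 0L) stop("no sample points", call. = FALSE)
  stopifnot(inherits(reference_mesh, "triangle_mesh"))
  if (signed) {
    if (is.null(reference_mesh$face_normals)) {
      stop("signed deviation needs face normals on the reference mesh; ",
           "run compute_normals() first", call. = FALSE)
    }
    if (!consistent_winding(reference_mesh)) {
      stop("reference mesh has inconsistently wound faces; signed distances ",
           "would be unreliable — use signed = FALSE", call. = FALSE)
    }
  }
  cp <- nearest_point_on_mesh(pts, reference_mesh)
  d <- cp$distance
  if (signed) {
    nrm <- reference_mesh$face_normals[cp$face, , drop = FALSE]
    sgn <- sign(rowSums((pts - cp$point) * nrm))
    sgn[sgn == 0] <- 1
    d <- d * sgn
  }
  structure(list(sample_points = pts, distances = d, closest_points = cp$point,
                 faces = cp$face, signed = signed,
                 reference_region = reference_region,
                 summary = summarize_deviation(d)),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("<deviation_result> %d points vs '%s' (%s)\n",
              length(x$distances), x$reference_region,
              if (x$signed) "signed" else "unsigned"))
  print(x$summary)
  invisible(x)
}

# every interior edge must appear once in each direction
consistent_winding <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  !any(duplicated(key))
}

#' Summary metrics of a deviation field
#'
#' The accuracy read-out of a case: maximum, minimum and mean deviation and
#' the root mean square, RMS = sqrt(mean(d^2)). The RMS over the maxillary
#' region is the "3D error" used to judge a surgical transfer against the
#' +/-2 mm clinical band.
#'
#' @param distances numeric vector of per-point deviations (mm; signed or
#'   unsigned).
#' @return One-row tibble: `max_dev`, `min_dev`, `mean_dev`, `rms`,
#'   `n_points`.
#' @examples
#' summarize_deviation(c(3, 4))  # rms = sqrt(12.5)
#' @export
summarize_deviation <- function(distances) {
  if (length(distances) == 0L) stop("empty deviation field", call. = FALSE)
  if (!all(is.finite(distances))) stop("non-finite deviations", call. = FALSE)
  tibble::tibble(max_dev = max(distances), min_dev = min(distances),
                 mean_dev = mean(distances),
                 rms = sqrt(mean(distances^2)),
                 n_points = length(distances))
}

#' Clinical acceptability of a 3D error
#'
#' An RMS 3D error is clinically acceptable when it lies within the +/-2 mm
#' band reported in the orthognathic-accuracy literature. The boundary is
#' inclusive: exactly 2 mm is acceptable. So that the inclusive boundary is
#' not decided by floating-point residue of the registration (order 1e-13
#' mm), the comparison carries a fixed numeric slack of 1e-9 mm — six orders
#' of magnitude below scanner resolution, with no clinical meaning.
#'
#' @param rms non-negative RMS deviation (mm).
#' @param threshold acceptability threshold (mm), default 2.
#' @return logical: `TRUE` if `rms <= threshold` (within the numeric slack).
#' @export
classify_acceptability <- function(rms, threshold = 2) {
  if (any(rms < 0)) stop("rms must be non-negative", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  rms <= threshold + 1e-9
}

#' Write the deviation colormap for a mesh region
#'
#' Maps the per-vertex deviation field of `result` onto `mesh_region` and
#' writes a colored PLY ([write_colored_ply()]): blue at
#' `-palette_range`, green at zero, red at `+palette_range`.
#'
#' @param mesh_region the [triangle_mesh()] the samples were taken from (one
#'   deviation per vertex, in vertex order).
#' @param result a `deviation_result` for those vertices.
#' @param path output PLY path.
#' @param palette_range colour half-range in mm; defaults to the 2 mm
#'   acceptability threshold.
#' @return `path`, invisibly.
#' @export
deviation_colormap <- function(mesh_region, result, path, palette_range = 2) {
  stopifnot(inherits(result, "deviation_result"))
  if (length(result$distances) != n_vertices(mesh_region)) {
    stop("deviation count (", length(result$distances),
         ") != region vertex count (", n_vertices(mesh_region), ")",
         call. = FALSE)
  }
  write_colored_ply(mesh_region, result$distances, path, palette_range)
}
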