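#' Triangulated surface mesh
#'
#' The package's canonical surface representation: an indexed triangle mesh
#' with vertex coordinates in millimetres (the CBCT export convention; STL
#' itself stores no units). Faces are stored as 1-based vertex-index triples.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param vertex_normals optional n x 3 matrix of unit vertex normals.
#' @param face_normals optional m x 3 matrix of unit face normals.
#' @return An object of class `triangle_mesh`.
#' @seealso [read_stl()], [validate_mesh()], [compute_normals()]
#' @export
triangle_mesh <- function(vertices, faces, vertex_normals = NULL,
                          face_normals = NULL) {
  vertices <- as_point_matrix(vertices)
  if (is.null(dim(faces))) faces <- matrix(faces, ncol = 3, byrow = TRUE)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (!all(is.finite(vertices))) {
    stop("vertex coordinates must be finite", call. = FALSE)
  }
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range [1, vertex count]", call. = FALSE)
  }
  check_unit <- function(nrm, what) {
    if (is.null(nrm)) return(NULL)
    nrm <- as_point_matrix(nrm)
    len <- sqrt(rowSums(nrm^2))
    if (any(abs(len - 1) > 1e-6)) {
      stop(what, " must be unit vectors (length 1 within 1e-6)",
           call. = FALSE)
    }
    nrm
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_normals = check_unit(vertex_normals, "vertex normals"),
                 face_normals = check_unit(face_normals, "face normals")),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh>  %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$face_normals)) ", with normals" else ""))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh A [triangle_mesh()].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Clean a mesh of degenerate geometry
#'
#' Removes faces with repeated vertex indices and faces whose area falls below
#' `area_epsilon`, then drops vertices no longer referenced by any face.
#' Postoperative CBCT surfaces can carry rendering defects (metal scatter,
#' fixation-plate overlay), so downstream geometry always assumes a validated
#' mesh. The operation is idempotent.
#'
#' @param mesh A [triangle_mesh()].
#' @param area_epsilon minimum face area in mm^2; faces below it are dropped.
#' @return The cleaned `triangle_mesh`, with a `validation_report` attribute:
#'   a tibble with columns `degenerate_faces_removed`,
#'   `small_faces_removed`, `unreferenced_vertices_removed`.
#' @export
validate_mesh <- function(mesh, area_epsilon = 1e-10) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  repeated <- if (nrow(f)) (f[, 1] == f[, 2] | f[, 1] == f[, 3] |
                            f[, 2] == f[, 3]) else logical(0)
  f1 <- f[!repeated, , drop = FALSE]
  area <- face_areas(mesh$vertices, f1)
  small <- area < area_epsilon
  f2 <- f1[!small, , drop = FALSE]
  used <- sort(unique(as.vector(f2)))
  n_unref <- nrow(mesh$vertices) - length(used)
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  out <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(remap[f2], ncol = 3))
  attr(out, "validation_report") <- tibble::tibble(
    degenerate_faces_removed = sum(repeated),
    small_faces_removed = sum(small),
    unreferenced_vertices_removed = n_unref
  )
  out
}

#' Compute face and vertex normals
#'
#' Face normals are the normalised cross products of the edge vectors in face
#' winding order (right-hand rule); vertex normals are the area-weighted
#' averages of incident face normals, renormalised. Winding is trusted
#' as-read from file; the package never re-orients faces globally.
#'
#' @param mesh A valid [triangle_mesh()] (run [validate_mesh()] first if in
#'   doubt; degenerate faces raise an error here).
#' @return The mesh with `face_normals` and `vertex_normals` filled in.
#' @export
compute_normals <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) stop("mesh has no faces", call. = FALSE)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))       # = 2 * face area
  if (any(len < 1e-12)) {
    stop("degenerate face encountered; run validate_mesh() first",
         call. = FALSE)
  }
  fn <- cr / len
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {                 # area weight = len / 2, constant dropped
    idx <- f[, k]
    vn[, 1] <- vn[, 1] + tabulate_weighted(idx, cr[, 1], nrow(v))
    vn[, 2] <- vn[, 2] + tabulate_weighted(idx, cr[, 2], nrow(v))
    vn[, 3] <- vn[, 3] + tabulate_weighted(idx, cr[, 3], nrow(v))
  }
  vlen <- sqrt(rowSums(vn^2))
  vlen[vlen == 0] <- 1
  mesh$face_normals <- fn
  mesh$vertex_normals <- vn / vlen
  mesh
}

# scatter-add of weights w at indices idx into a length-n vector
tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

face_areas <- function(v, f) {
  if (nrow(f) == 0) return(numeric(0))
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Apply a rigid transform to a whole mesh
#'
#' Rotates and translates vertex coordinates; normals, if present, are rotated
#' (translation does not affect them).
#'
#' @param mesh A [triangle_mesh()].
#' @param transform A [rigid_transform()].
#' @return The transformed `triangle_mesh`.
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mesh$vertices <- transform_points(transform, mesh$vertices)
  rot <- function(nrm) if (is.null(nrm)) NULL else nrm %*% t(transform$rotation)
  mesh$vertex_normals <- rot(mesh$vertex_normals)
  mesh$face_normals <- rot(mesh$face_normals)
  mesh
}

# merge vertices closer than tol (mm) so faces share indices; used by the STL
# reader to reunify STL's per-facet vertex duplication
merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3))
}
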