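#' Region-of-interest selection on a mesh
#'
#' The analysis uses two named regions on the planned (T0) model: the stable
#' registration reference ("ROI1", typically the orbital frames and the
#' frontal and zygomatic bones, untouched by surgery) and the measured
#' maxillary region ("ROI2", between the Le Fort I osteotomy and the neck of
#' the teeth). Where a clinical workflow paints these by hand, this package
#' defines them as explicit vertex-index sets or geometric predicates so runs
#' are reproducible.
#'
#' @param mesh the [triangle_mesh()] the selection refers to.
#' @param indices integer vector of vertex indices (1-based).
#' @param name label, e.g. `"ROI1"`.
#' @return An object of class `roi_selection` with fields `name`,
#'   `vertex_indices` (sorted, unique) and `provenance`.
#' @export
roi_from_indices <- function(mesh, indices, name = "ROI") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("empty ROI selection", call. = FALSE)
  if (anyNA(indices) || min(indices) < 1L || max(indices) > n_vertices(mesh)) {
    stop("ROI index out of range [1, ", n_vertices(mesh), "]", call. = FALSE)
  }
  structure(list(name = name, vertex_indices = sort(unique(indices)),
                 provenance = "explicit-indices"),
            class = "roi_selection")
}

#' @export
print.roi_selection <- function(x, ...) {
  cat(sprintf("<roi_selection> '%s': %d vertices (%s)\n", x$name,
              length(x$vertex_indices), x$provenance))
  invisible(x)
}

#' Select an ROI by a geometric predicate
#'
#' Selects every mesh vertex inside a closed spatial region (boundary points
#' included). Supported predicates:
#' \describe{
#'   \item{box}{`list(type = "box", lo = c(x,y,z), hi = c(x,y,z))`}
#'   \item{sphere}{`list(type = "sphere", center = c(x,y,z), radius = r)`}
#'   \item{halfspace}{`list(type = "halfspace", normal = c(x,y,z),
#'     offset = d)` selecting vertices with `v . normal >= d`}
#' }
#' All lengths in millimetres.
#'
#' @param mesh A [triangle_mesh()].
#' @param predicate a predicate list as above.
#' @param name ROI label.
#' @return An `roi_selection` with provenance `"spatial-predicate"`.
#' @export
roi_from_predicate <- function(mesh, predicate, name = "ROI") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  inside <- predicate_mask(mesh$vertices, predicate)
  if (!any(inside)) {
    stop("predicate '", predicate$type, "' for ROI '", name,
         "' selects no vertices", call. = FALSE)
  }
  out <- roi_from_indices(mesh, which(inside), name)
  out$provenance <- "spatial-predicate"
  out$predicate <- predicate
  out
}

predicate_mask <- function(v, predicate) {
  if (is.null(predicate$type)) stop("predicate needs a `type`", call. = FALSE)
  switch(predicate$type,
    box = {
      lo <- as.numeric(predicate$lo); hi <- as.numeric(predicate$hi)
      v[, 1] >= lo[1] & v[, 1] <= hi[1] &
        v[, 2] >= lo[2] & v[, 2] <= hi[2] &
        v[, 3] >= lo[3] & v[, 3] <= hi[3]
    },
    sphere = {
      ctr <- as.numeric(predicate$center)
      d2 <- (v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2 + (v[, 3] - ctr[3])^2
      d2 <= predicate$radius^2
    },
    halfspace = {
      n <- as.numeric(predicate$normal)
      as.vector(v %*% n) >= predicate$offset
    },
    stop("unknown predicate type: ", predicate$type, call. = FALSE)
  )
}

#' Extract ROI vertex coordinates
#'
#' Returns the coordinates (and normals, when present on the mesh) of the
#' selected vertices, ordered by ascending vertex index.
#'
#' @param mesh A [triangle_mesh()].
#' @param roi An `roi_selection` made on this mesh.
#' @return A list with `points` (n x 3 matrix) and `normals` (matrix or
#'   `NULL`).
#' @export
extract_points <- function(mesh, roi) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(roi, "roi_selection"))
  idx <- roi$vertex_indices
  if (max(idx) > n_vertices(mesh)) {
    stop("stale ROI '", roi$name, "': index ", max(idx),
         " exceeds vertex count ", n_vertices(mesh),
         " (was the mesh revalidated after selection?)", call. = FALSE)
  }
  list(points = mesh$vertices[idx, , drop = FALSE],
       normals = if (is.null(mesh$vertex_normals)) NULL
                 else mesh$vertex_normals[idx, , drop = FALSE])
}

#' Extract the sub-mesh spanned by an ROI
#'
#' Keeps the faces whose three vertices all belong to the ROI (conservative:
#' no boundary geometry is invented) and reindexes the result.
#'
#' @param mesh A [triangle_mesh()].
#' @param roi An `roi_selection` on this mesh.
#' @return A [triangle_mesh()] restricted to the ROI.
#' @export
extract_submesh <- function(mesh, roi) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(roi, "roi_selection"))
  idx <- roi$vertex_indices
  if (max(idx) > n_vertices(mesh)) {
    stop("stale ROI '", roi$name, "'", call. = FALSE)
  }
  member <- logical(n_vertices(mesh))
  member[idx] <- TRUE
  keep <- member[mesh$faces[, 1]] & member[mesh$faces[, 2]] &
    member[mesh$faces[, 3]]
  if (!any(keep)) {
    stop("ROI '", roi$name, "' contains no complete face", call. = FALSE)
  }
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE], matrix(remap[f], ncol = 3),
                vertex_normals = if (is.null(mesh$vertex_normals)) NULL
                                 else mesh$vertex_normals[used, , drop = FALSE])
}

#' Read / write ROI definition files
#'
#' ROI definitions travel as small JSON documents referenced from a cohort
#' manifest: either `{"name": ..., "type": "indices", "indices": [...]}`
#' (1-based) or a spatial predicate (`"box"`, `"sphere"`, `"halfspace"` with
#' their parameters in mm).
#'
#' @param path JSON file path.
#' @return `read_roi_definition()` returns the definition list;
#'   `resolve_roi()` applies a definition to a mesh and returns an
#'   `roi_selection`.
#' @export
read_roi_definition <- function(path) {
  def <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(def$type)) stop("ROI file ", path, " lacks `type`",
                              call. = FALSE)
  def
}

#' @rdname read_roi_definition
#' @param definition an ROI definition list (as from
#'   [read_roi_definition()]).
#' @param mesh the [triangle_mesh()] to resolve against.
#' @export
resolve_roi <- function(definition, mesh) {
  name <- definition$name %||% "ROI"
  if (identical(definition$type, "indices")) {
    roi_from_indices(mesh, unlist(definition$indices), name)
  } else {
    roi_from_predicate(mesh, definition, name)
  }
}

#' @rdname read_roi_definition
#' @param roi an `roi_selection` or definition list to serialise.
#' @export
write_roi_definition <- function(roi, path) {
  def <- if (inherits(roi, "roi_selection")) {
    if (!is.null(roi$predicate)) c(list(name = roi$name), roi$predicate)
    else list(name = roi$name, type = "indices",
              indices = roi$vertex_indices)
  } else roi
  jsonlite::write_json(def, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
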