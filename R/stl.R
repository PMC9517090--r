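#' Read an STL surface file
#'
#' Reads binary or ASCII STL (dialect auto-detected) into a
#' [triangle_mesh()]. STL stores each facet's three vertices independently;
#' duplicated vertices are merged within a tolerance of 1e-6 mm — large
#' enough to reunify per-facet duplication, far below CBCT voxel size
#' (0.3 mm) — so faces share indices. Coordinates are interpreted as
#' millimetres. Binary attribute bytes are ignored.
#'
#' @param path path to an STL file.
#' @return A [triangle_mesh()].
#' @examples
#' tmp <- tempfile(fileext = ".stl")
#' write_stl(make_flat_patch(width = 2, n = 2), tmp, dialect = "ascii")
#' read_stl(tmp)
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("cannot read STL file: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  mesh <- if (is_ascii_stl(raw)) parse_ascii_stl(raw, path)
          else parse_binary_stl(raw, path)
  m <- merge_vertices(mesh$vertices, mesh$faces, tol = 1e-6)
  triangle_mesh(m$vertices, m$faces)
}

# An ASCII STL starts with "solid", but some binary exporters abuse that
# header; treat as ASCII only if "facet" also appears early in the file.
is_ascii_stl <- function(raw) {
  head <- raw[seq_len(min(512L, length(raw)))]
  head[head == as.raw(0L)] <- as.raw(32L)   # binary headers carry nul bytes
  head <- rawToChar(head)
  grepl("^\\s*solid", head, useBytes = TRUE) &&
    grepl("facet", head, fixed = TRUE, useBytes = TRUE)
}

parse_binary_stl <- function(raw, path) {
  if (length(raw) < 84L) {
    stop("format error in ", path, ": binary STL shorter than 84-byte header",
         call. = FALSE)
  }
  n_tri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  expect <- 84L + 50L * n_tri
  if (length(raw) < expect) {
    stop("format error in ", path, ": truncated binary record at byte ",
         length(raw), " (expected ", expect, " bytes for ", n_tri,
         " triangles)", call. = FALSE)
  }
  if (n_tri == 0L) stop("STL file ", path, " contains no triangles",
                        call. = FALSE)
  # each 50-byte record: 12 floats (normal + 3 vertices) + 2 attribute bytes
  rec0 <- 84L + 50L * (seq_len(n_tri) - 1L)
  float_off <- as.vector(outer(1:48, rec0, "+"))   # 48 float bytes per record
  floats <- readBin(raw[float_off], "double", size = 4, n = 12L * n_tri,
                    endian = "little")
  fm <- matrix(floats, nrow = 12L)                 # cols = triangles
  verts <- matrix(as.vector(fm[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3L * n_tri), ncol = 3, byrow = TRUE)
  if (!all(is.finite(verts))) {
    stop("format error in ", path, ": non-finite vertex coordinates",
         call. = FALSE)
  }
  list(vertices = verts, faces = faces)
}

parse_ascii_stl <- function(raw, path) {
  lines <- strsplit(rawToChar(raw), "\r?\n")[[1]]
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("format error in ", path, ": malformed ASCII facet (",
         length(vl), " vertex lines, not a multiple of 3); near line ",
         if (length(vl)) vl[length(vl)] else 1, call. = FALSE)
  }
  coords <- lapply(strsplit(trimws(lines[vl]), "\\s+"), function(tok) {
    x <- suppressWarnings(as.numeric(tok[2:4]))
    x
  })
  verts <- do.call(rbind, coords)
  if (anyNA(verts) || !all(is.finite(verts))) {
    bad <- vl[which(apply(verts, 1, function(r) anyNA(r) || !all(is.finite(r))))[1]]
    stop("format error in ", path, ": unparsable vertex at line ", bad,
         call. = FALSE)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Write a mesh to STL
#'
#' @param mesh A non-empty [triangle_mesh()].
#' @param path output path.
#' @param dialect `"binary"` (84 + 50 bytes per triangle, attribute bytes
#'   zero) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  if (n_faces(mesh) == 0L) stop("refusing to write an empty mesh",
                                call. = FALSE)
  mesh_n <- if (is.null(mesh$face_normals)) compute_normals(mesh) else mesh
  v <- mesh$vertices
  f <- mesh$faces
  fn <- mesh_n$face_normals
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # 12 floats per record, triangles in columns
    block <- rbind(t(fn), t(v[f[, 1], , drop = FALSE]),
                   t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    attr_bytes <- raw(2L)
    for (i in seq_len(nrow(f))) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(attr_bytes, con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7L * nrow(f) + 2L)
    out[1] <- "solid mesh"
    for (i in seq_len(nrow(f))) {
      j <- 2L + (i - 1L) * 7L
      out[j] <- sprintf("  facet normal %s %s %s", fmt(fn[i, 1]),
                        fmt(fn[i, 2]), fmt(fn[i, 3]))
      out[j + 1L] <- "    outer loop"
      tri <- v[f[i, ], , drop = FALSE]
      for (k in 1:3) {
        out[j + 1L + k] <- sprintf("      vertex %s %s %s", fmt(tri[k, 1]),
                                   fmt(tri[k, 2]), fmt(tri[k, 3]))
      }
      out[j + 5L] <- "    endloop"
      out[j + 6L] <- "  endfacet"
    }
    out[length(out)] <- "endsolid mesh"
    writeLines(out, path)
  }
  invisible(path)
}

#' Write a deviation colormap as ASCII PLY
#'
#' Writes the mesh with one RGB colour per vertex, mapped linearly from the
#' per-vertex scalar field: `-palette_range` maps to blue, 0 to green and
#' `+palette_range` to red; values beyond the range clamp to the end colours.
#' This is the file behind the deviation colormap a mesh-inspection tool
#' shows.
#'
#' @param mesh A [triangle_mesh()].
#' @param scalar_per_vertex numeric vector, one value (mm) per vertex.
#' @param path output path.
#' @param palette_range half-width of the colour scale in mm (default the
#'   2 mm clinical acceptability threshold).
#' @return `path`, invisibly.
#' @export
write_colored_ply <- function(mesh, scalar_per_vertex, path,
                              palette_range = 2) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (length(scalar_per_vertex) != n_vertices(mesh)) {
    stop("need one scalar per vertex (", n_vertices(mesh), "), got ",
         length(scalar_per_vertex), call. = FALSE)
  }
  rgb <- deviation_palette(scalar_per_vertex, palette_range)
  v <- mesh$vertices
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  vlines <- sprintf("%.9g %.9g %.9g %d %d %d", v[, 1], v[, 2], v[, 3],
                    rgb[, 1], rgb[, 2], rgb[, 3])
  flines <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                    mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

# blue -> green -> red linear palette over [-range, +range], clamped
deviation_palette <- function(scalar, palette_range) {
  if (palette_range <= 0) stop("palette_range must be > 0", call. = FALSE)
  t <- pmin(1, pmax(-1, scalar / palette_range))
  r <- ifelse(t > 0, t, 0)
  b <- ifelse(t < 0, -t, 0)
  g <- 1 - abs(t)
  cbind(red = as.integer(round(255 * r)),
        green = as.integer(round(255 * g)),
        blue = as.integer(round(255 * b)))
}
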