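test_that("binary and ASCII STL of one triangle parse to the same mesh", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       c(1L, 2L, 3L))
  fb <- withr::local_tempfile(fileext = ".stl")
  fa <- withr::local_tempfile(fileext = ".stl")
  write_stl(tri, fb, "binary")
  write_stl(tri, fa, "ascii")
  expect_identical(file.size(fb), 84 + 50)   # binary STL size formula
  mb <- read_stl(fb)
  ma <- read_stl(fa)
  expect_identical(n_vertices(mb), 3L)
  expect_identical(n_faces(mb), 1L)
  expect_equal(mb$vertices, ma$vertices, tolerance = 1e-9)
  expect_identical(mb$faces, ma$faces)
})

test_that("STL round trip is the identity for both dialects (12-face cube)", {
  cube <- make_cube()
  for (dialect in c("binary", "ascii")) {
    f <- withr::local_tempfile(fileext = ".stl")
    write_stl(cube, f, dialect)
    m <- read_stl(f)
    expect_identical(n_vertices(m), 8L)
    expect_identical(n_faces(m), 12L)
    # same vertex set within 1e-6 mm and same face topology after relabelling
    perm <- apply(m$vertices, 1, function(p) {
      which(colSums((t(cube$vertices) - p)^2) < 1e-12)
    })
    expect_setequal(perm, 1:8)
    relabelled <- matrix(perm[m$faces], ncol = 3)
    key <- function(f) sort(apply(f, 1, function(r) paste(sort(r),
                                                          collapse = "-")))
    expect_identical(key(relabelled), key(cube$faces))
  }
})

test_that("malformed STL inputs fail with located errors", {
  expect_error(read_stl("no/such/file.stl"), "cannot read")
  f <- withr::local_tempfile(fileext = ".stl")
  cube <- make_cube()
  write_stl(cube, f, "binary")
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:200], f)                     # chop mid-record
  expect_error(read_stl(f), "truncated")
  writeLines(c("solid x", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 zz", "endloop", "endfacet",
               "endsolid x"), f)
  expect_error(read_stl(f), "line")
  empty <- triangle_mesh(matrix(0, 1, 3), matrix(integer(0), 0, 3))
  expect_error(write_stl(empty, f), "empty")
})

test_that("validate_mesh removes degenerate faces and is idempotent", {
  cube <- make_cube()
  bad <- triangle_mesh(rbind(cube$vertices, c(9, 9, 9)),
                       rbind(cube$faces,
                             c(1L, 1L, 2L),          # repeated index
                             c(9L, 9L, 9L)))         # zero area + repeated
  v <- validate_mesh(bad)
  rep1 <- attr(v, "validation_report")
  expect_identical(n_faces(v), 12L)
  expect_identical(n_vertices(v), 8L)                # orphan vertex dropped
  expect_identical(rep1$degenerate_faces_removed, 2L)
  expect_identical(rep1$unreferenced_vertices_removed, 1L)
  v2 <- validate_mesh(v)
  rep2 <- attr(v2, "validation_report")
  expect_identical(v2$vertices, v$vertices)
  expect_identical(v2$faces, v$faces)
  expect_true(all(rep2 == 0L))
  # a fully degenerate mesh validates to empty and downstream ops refuse it
  allbad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0)),
                          rbind(c(1L, 1L, 2L)))
  ve <- validate_mesh(allbad)
  expect_identical(n_faces(ve), 0L)
  expect_error(compute_normals(ve), "no faces")
})

test_that("normals follow winding and rotate with the mesh", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       c(1L, 2L, 3L))
  expect_equal(compute_normals(tri)$face_normals[1, ], c(0, 0, 1))
  rev <- triangle_mesh(tri$vertices, c(1L, 3L, 2L))
  expect_equal(compute_normals(rev)$face_normals[1, ], c(0, 0, -1))

  cube <- compute_normals(make_cube())
  ctr <- colMeans(cube$vertices)
  outward <- rowSums(cube$vertex_normals * sweep(cube$vertices, 2, ctr))
  expect_true(all(outward > 0))                      # all 8 corners

  R <- rotation_about_axis(c(1, 2, 3), 37)
  rotated <- compute_normals(transform_mesh(make_cube(),
                                            rigid_transform(R, c(4, 5, 6))))
  expect_equal(rotated$face_normals, cube$face_normals %*% t(R),
               tolerance = 1e-9)
})

test_that("colored PLY maps deviations blue-green-red with clamping", {
  pal <- orthoicp:::deviation_palette(c(-2, 0, 2, 5, -9), 2)
  expect_equal(pal[1, ], c(red = 0L, green = 0L, blue = 255L))
  expect_equal(pal[2, ], c(red = 0L, green = 255L, blue = 0L))
  expect_equal(pal[3, ], c(red = 255L, green = 0L, blue = 0L))
  expect_identical(pal[4, ], pal[3, ])               # clamp high
  expect_identical(pal[5, ], pal[1, ])               # clamp low

  patch <- make_flat_patch(width = 2, n = 2)
  f <- withr::local_tempfile(fileext = ".ply")
  write_colored_ply(patch, rep(0, n_vertices(patch)), f, palette_range = 2)
  lines <- readLines(f)
  expect_identical(lines[1], "ply")
  vcount <- n_vertices(patch)
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  cols <- do.call(rbind, strsplit(body[seq_len(vcount)], " "))[, 4:6]
  expect_true(all(cols[, 1] == "0" & cols[, 2] == "255" & cols[, 3] == "0"))
  expect_error(write_colored_ply(patch, 1:3, f), "per vertex")
})
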