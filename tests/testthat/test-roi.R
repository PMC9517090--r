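test_that("index ROIs validate their inputs", {
  cube <- make_cube()
  roi <- roi_from_indices(cube, 1:8, "ROI1")
  expect_identical(roi$vertex_indices, 1:8)
  expect_error(roi_from_indices(cube, c(1L, 10L)), "out of range")
  expect_error(roi_from_indices(cube, integer(0)), "empty")
})

test_that("predicate ROIs select closed regions and match brute force", {
  cube <- make_cube()   # corners at +-0.5
  top <- roi_from_predicate(cube, list(type = "halfspace",
                                       normal = c(0, 0, 1), offset = 0.5))
  expect_identical(length(top$vertex_indices), 4L)
  expect_true(all(cube$vertices[top$vertex_indices, 3] == 0.5))

  # zero-radius sphere at a vertex: boundary inclusion picks that vertex
  pin <- roi_from_predicate(cube, list(type = "sphere",
                                       center = cube$vertices[3, ],
                                       radius = 0))
  expect_identical(pin$vertex_indices, 3L)

  allbox <- roi_from_predicate(cube, list(type = "box", lo = c(-1, -1, -1),
                                          hi = c(1, 1, 1)))
  expect_identical(allbox$vertex_indices,
                   roi_from_indices(cube, 1:8)$vertex_indices)
  # brute-force membership against each predicate
  for (i in 1:8) {
    p <- cube$vertices[i, ]
    expect_identical(i %in% allbox$vertex_indices,
                     all(p >= -1 & p <= 1))
  }
  expect_error(roi_from_predicate(cube, list(type = "sphere",
                                             center = c(9, 9, 9),
                                             radius = 0.1)),
               "selects no vertices")
})

test_that("predicate selection is invariant to vertex storage order", {
  cube <- make_cube()
  perm <- c(5L, 3L, 8L, 1L, 2L, 7L, 4L, 6L)
  inv <- order(perm)
  shuffled <- triangle_mesh(cube$vertices[perm, ],
                            matrix(inv[cube$faces], ncol = 3))
  pred <- list(type = "halfspace", normal = c(0, 0, 1), offset = 0.5)
  a <- cube$vertices[roi_from_predicate(cube, pred)$vertex_indices, ]
  b <- shuffled$vertices[roi_from_predicate(shuffled, pred)$vertex_indices, ]
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(a), key(b))
})

test_that("extract_points is index-ordered and detects stale ROIs", {
  cube <- make_cube()
  roi <- roi_from_indices(cube, c(7L, 2L, 5L))
  pts <- extract_points(cube, roi)
  expect_equal(pts$points, cube$vertices[c(2L, 5L, 7L), ])
  expect_null(pts$normals)
  withn <- compute_normals(cube)
  expect_equal(extract_points(withn, roi)$normals,
               withn$vertex_normals[c(2L, 5L, 7L), ])
  smaller <- triangle_mesh(cube$vertices[1:4, ], rbind(c(1L, 2L, 3L)))
  expect_error(extract_points(smaller, roi), "stale")
})

test_that("extract_submesh keeps only fully-contained faces", {
  cube <- make_cube()
  top <- roi_from_predicate(cube, list(type = "halfspace",
                                       normal = c(0, 0, 1), offset = 0.5))
  patch <- extract_submesh(cube, top)
  expect_identical(n_faces(patch), 2L)         # the two top triangles
  expect_identical(n_vertices(patch), 4L)
  expect_true(all(patch$vertices[, 3] == 0.5))

  full <- extract_submesh(cube, roi_from_indices(cube, 1:8))
  expect_identical(n_faces(full), n_faces(cube))
  expect_equal(full$vertices, cube$vertices)

  expect_error(extract_submesh(cube, roi_from_indices(cube, 1L)),
               "no complete face")
})

test_that("ROI definitions round-trip through JSON and resolve identically", {
  cube <- make_cube()
  f <- withr::local_tempfile(fileext = ".json")
  write_roi_definition(list(name = "ROI2", type = "sphere",
                            center = c(0, 0, 0.5), radius = 0.8), f)
  def <- read_roi_definition(f)
  roi <- resolve_roi(def, cube)
  expect_identical(roi$name, "ROI2")
  expect_identical(roi$vertex_indices,
                   roi_from_predicate(cube, def)$vertex_indices)

  f2 <- withr::local_tempfile(fileext = ".json")
  write_roi_definition(roi_from_indices(cube, c(3L, 1L), "picked"), f2)
  back <- resolve_roi(read_roi_definition(f2), cube)
  expect_identical(back$vertex_indices, c(1L, 3L))
})
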