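test_that("nearest_vertex matches a brute-force scan and breaks ties low", {
  m <- tetrahedron()
  expect_identical(nearest_vertex(m, m$vertices[3, ]), 3L)
  set.seed(11)
  for (trial in 1:10) {
    V <- matrix(runif(30, -5, 5), ncol = 3)
    mesh <- surface_mesh(V, rbind(c(1, 2, 3)))
    p <- runif(3, -5, 5)
    expect_identical(nearest_vertex(mesh, p),
                     which.min(colSums((t(V) - p)^2)))
  }
  # two equidistant vertices: lower index wins
  m2 <- surface_mesh(rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_identical(nearest_vertex(m2, c(0, 0, 0)), 1L)
  expect_error(nearest_vertex(m, c(0, Inf, 0)), "finite")
})

test_that("ring_neighborhood matches an independent BFS oracle", {
  m <- flat_sheet(5, 5)
  center <- nearest_vertex(m, c(2, 2, 0))   # interior vertex
  expect_identical(ring_neighborhood(m, center, 0L), center)
  ring1 <- ring_neighborhood(m, center, 1L)
  expect_length(ring1, 7L)                  # centre + 6 neighbours on this grid
  expect_identical(ring1, bfs_oracle(m, center, 1))
  # saturation
  expect_identical(ring_neighborhood(m, 1L, 100L), seq_len(25L))
  expect_error(ring_neighborhood(m, 0L, 1L), "invalid center")

  set.seed(22)
  for (trial in 1:100) {
    mesh <- if (trial %% 2) random_fold_mesh() else make_icosphere(1)
    c0 <- sample(nrow(mesh$vertices), 1)
    k <- sample(0:4, 1)
    expect_identical(ring_neighborhood(mesh, c0, k), bfs_oracle(mesh, c0, k))
  }
})

test_that("ring neighbourhoods are nested in k", {
  set.seed(33)
  mesh <- random_fold_mesh()
  c0 <- sample(nrow(mesh$vertices), 1)
  rings <- lapply(0:5, function(k) ring_neighborhood(mesh, c0, k))
  for (i in seq_len(5))
    expect_true(all(rings[[i]] %in% rings[[i + 1]]))
})

test_that("faces_within returns exactly the fully-contained faces", {
  m <- flat_sheet(4, 4)
  expect_identical(faces_within(m, seq_len(16L)), seq_len(nrow(m$faces)))
  expect_length(faces_within(m, 5L), 0L)
  tri <- single_triangle()
  expect_identical(faces_within(tri, 1:3), 1L)
})

test_that("geodesic distance is the weighted shortest edge path", {
  # single edge of known length
  m <- surface_mesh(rbind(c(0, 0, 0), c(1.3, 0, 0), c(0.65, 1, 0)),
                    rbind(c(1, 2, 3)))
  expect_equal(geodesic_distance(m, 1, 2), 1.3)
  expect_equal(geodesic_distance(m, 2, 2), 0)
  expect_equal(geodesic_distance(m, 1, 3), geodesic_distance(m, 3, 1))

  # unit-spaced strip: endpoints two hops apart
  strip <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(0.5, 1, 0), c(1.5, 1, 0)),
                        rbind(c(1, 2, 4), c(2, 5, 4), c(2, 3, 5)))
  expect_equal(geodesic_distance(strip, 1, 3), 2.0)

  # two disconnected triangles
  disc <- surface_mesh(rbind(diag(3), diag(3) + 10),
                       rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(geodesic_distance(disc, 1, 5), "different connected components")
})

test_that("geodesic distance matches exhaustive path enumeration on tiny meshes", {
  set.seed(44)
  for (trial in 1:10) {
    cfg <- synth_config(x_extent = 2, y_extent = 1, spacing = 1,
                        amplitude = runif(1, 0, 2), wavelength = 10)
    mesh <- make_folded_surfaces(cfg)$mid    # 5 x 3 grid = 15 > 12? use subsets
    mesh <- surface_mesh(mesh$vertices[1:10, ],
                         mesh$faces[apply(mesh$faces <= 10, 1, all), , drop = FALSE])
    ab <- sample(10, 2)
    expect_equal(geodesic_distance(mesh, ab[1], ab[2]),
                 enumeration_oracle(mesh, ab[1], ab[2]), tolerance = 1e-12)
  }
})

test_that("geodesic triangle inequality holds on random meshes", {
  set.seed(55)
  for (trial in 1:5) {
    mesh <- random_fold_mesh()
    v <- sample(nrow(mesh$vertices), 3)
    dab <- geodesic_distance(mesh, v[1], v[2])
    dbc <- geodesic_distance(mesh, v[2], v[3])
    dac <- geodesic_distance(mesh, v[1], v[3])
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("build_roi snaps, grows and collects contained faces", {
  m <- flat_sheet(7, 7)
  r <- build_roi(m, "M1_BANK", c(3, 3, 0))       # default k = 5
  expect_s3_class(r, "roi")
  expect_identical(r$vertices, ring_neighborhood(m, r$center_vertex, 5L))
  expect_identical(r$faces, faces_within(m, r$vertices))
  r0 <- build_roi(m, "X", c(3, 3, 0), k = 0)
  expect_length(r0$vertices, 1L)
  expect_length(r0$faces, 0L)
  # a far-away seed still snaps to the nearest vertex
  far <- build_roi(m, "X", c(1e4, 1e4, 1e4), k = 0)
  expect_identical(far$center_vertex, nearest_vertex(m, c(1e4, 1e4, 1e4)))
})

test_that("resolve_overlaps assigns shared vertices by geodesic distance", {
  m <- flat_sheet(9, 3)
  a <- build_roi(m, "M1_BANK", c(2, 1, 0), k = 3)
  b <- build_roi(m, "M1_CROWN", c(6, 1, 0), k = 3)
  shared <- intersect(a$vertices, b$vertices)
  expect_gt(length(shared), 0L)
  res <- resolve_overlaps(m, a, b)
  expect_length(intersect(res[[1]]$vertices, res[[2]]$vertices), 0L)
  expect_setequal(union(res[[1]]$vertices, res[[2]]$vertices),
                  union(a$vertices, b$vertices))
  for (v in shared) {
    da <- geodesic_distance(m, v, a$center_vertex)
    db <- geodesic_distance(m, v, b$center_vertex)
    in_a <- v %in% res[[1]]$vertices
    if (da < db) expect_true(in_a)
    if (db < da) expect_false(in_a)
    if (da == db) expect_true(in_a)   # tie goes to the bank-labelled ROI
  }
  # faces are recomputed from the updated vertex sets
  expect_identical(res[[1]]$faces, faces_within(m, res[[1]]$vertices))

  disjoint <- resolve_overlaps(m, build_roi(m, "A", c(0, 0, 0), k = 1),
                               build_roi(m, "B", c(8, 2, 0), k = 1))
  expect_identical(disjoint[[1]]$vertices, ring_neighborhood(m, 1L, 1L))
})

test_that("equidistant overlap ties follow the documented label rules", {
  # 5-vertex strip: centres at both ends, middle vertex exactly equidistant
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
                          c(4, 0, 0), c(0.5, 1, 0), c(1.5, 1, 0),
                          c(2.5, 1, 0), c(3.5, 1, 0)),
                    rbind(c(1, 2, 6), c(2, 7, 6), c(2, 3, 7), c(3, 8, 7),
                          c(3, 4, 8), c(4, 9, 8), c(4, 5, 9)))
  bank <- build_roi(m, "S1_BANK", c(0, 0, 0), k = 2)
  crown <- build_roi(m, "S1_CROWN", c(4, 0, 0), k = 2)
  expect_true(3L %in% intersect(bank$vertices, crown$vertices))
  res <- resolve_overlaps(m, crown, bank)   # bank passed second still wins ties
  expect_false(3L %in% res[[1]]$vertices)
  expect_true(3L %in% res[[2]]$vertices)
  # without a bank label, lexicographically smaller label wins
  ra <- build_roi(m, "ALPHA", c(0, 0, 0), k = 2)
  rb <- build_roi(m, "BETA", c(4, 0, 0), k = 2)
  res2 <- resolve_overlaps(m, rb, ra)
  expect_true(3L %in% res2[[2]]$vertices)
})

test_that("roi seed and membership tables round-trip", {
  seeds <- data.frame(subject = "s1", label = c("M1_BANK", "M1_CROWN"),
                      x = c(1.5, 2.5), y = 0, z = c(0, 3))
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  write_roi_seeds(seeds, p)
  expect_equal(read_roi_seeds(p), seeds)
  m <- flat_sheet(4, 4)
  r <- build_roi(m, "M1_BANK", c(1, 1, 0), k = 1)
  tab <- roi_membership(list(r), subject = "s1")
  expect_identical(tab$vertex, r$vertices)
})
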