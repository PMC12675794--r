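# Mesh data model, I/O round trips, axis and radius primitives.

test_that("ASCII STL of a unit cube reads with 12 faces and unit volume", {
  # Build the cube as a triangle soup and write a minimal ASCII STL.
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  tf <- tempfile(fileext = ".stl")
  con <- file(tf, "w")
  writeLines("solid cube", con)
  for (q in quads) {
    for (tri in list(q[c(1, 2, 3)], q[c(1, 3, 4)])) {
      writeLines("facet normal 0 0 0", con)
      writeLines("outer loop", con)
      for (k in tri)
        writeLines(sprintf("vertex %g %g %g", corners[k, 1],
                           corners[k, 2], corners[k, 3]), con)
      writeLines(c("endloop", "endfacet"), con)
    }
  }
  writeLines("endsolid cube", con)
  close(con)
  mesh <- read_mesh(tf)
  expect_equal(nrow(mesh$faces), 12L)
  expect_equal(nrow(mesh$vertices), 8L)
  expect_equal(abs(mesh_volume(mesh)), 1, tolerance = 1e-12)
})

test_that("write/read round trips preserve topology for all three formats", {
  mesh <- tube_model(n_theta = 12, n_z = 5)$mesh
  for (fmt in c("stl", "ply", "obj")) {
    for (binary in if (fmt == "obj") FALSE else c(FALSE, TRUE)) {
      tf <- tempfile(fileext = paste0(".", fmt))
      suppressWarnings(write_mesh(mesh, tf, binary = binary))
      back <- suppressWarnings(read_mesh(tf))
      expect_equal(nrow(back$faces), nrow(mesh$faces),
                   info = paste(fmt, binary))
      # volume is a topology+geometry functional: float-level agreement
      tol <- if (fmt == "stl" && binary) 1e-5 else 1e-12
      expect_equal(mesh_volume(back), mesh_volume(mesh),
                   tolerance = tol, info = paste(fmt, binary))
    }
  }
  # PLY preserves vertex/face arrays and layer labels exactly
  tf <- tempfile(fileext = ".ply")
  write_mesh(mesh, tf, binary = TRUE)
  back <- read_mesh(tf)
  expect_identical(back$vertices, mesh$vertices)
  expect_identical(back$faces, mesh$faces)
  expect_identical(back$labels, mesh$labels)
})

test_that("validate_mesh flags degenerate faces, holes and non-manifold edges", {
  ico <- icosahedron()
  rep0 <- validate_mesh(ico)
  expect_true(rep0$watertight)
  expect_true(rep0$orientable)
  expect_equal(rep0$n_nonmanifold_edges, 0L)
  expect_equal(rep0$n_degenerate, 0L)

  holed <- trimesh(ico$vertices, ico$faces[-1, , drop = FALSE])
  expect_false(validate_mesh(holed)$watertight)

  # zero-area facet: repeated edge midpoint triangle
  v <- rbind(ico$vertices, (ico$vertices[1, ] + ico$vertices[2, ]) / 2)
  deg_face <- c(1L, 2L, 13L)  # vertex 13 is collinear with 1-2
  with_deg <- trimesh(v, rbind(ico$faces, deg_face))
  expect_equal(validate_mesh(with_deg)$n_degenerate, 1L)

  # four triangles fanning around one shared edge: face degree 4 there
  fan <- trimesh(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0.5), c(0, 1, 0.5),
                       c(-1, 0, 0.5), c(0, -1, 0.5)),
                 rbind(c(1, 2, 3), c(2, 1, 4), c(1, 2, 5), c(2, 1, 6)))
  # brute-force count of edges with face degree != 2 must match the report
  f <- fan$faces
  key <- paste(pmin(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
               pmax(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])))
  expect_equal(validate_mesh(fan)$n_nonmanifold_edges,
               sum(table(key) != 2L))
  expect_gte(validate_mesh(fan)$n_nonmanifold_edges, 1L)
})

test_that("long axis is recovered, equivariant, and rejects isotropic clouds", {
  tube <- tube_model(n_theta = 32, n_z = 16)
  ax <- compute_long_axis(tube$mesh)
  expect_equal(abs(sum(ax$axis * c(0, 0, 1))), 1, tolerance = 1e-6)

  th <- 30 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- trimesh(tube$mesh$vertices %*% t(Rx), tube$mesh$faces)
  ax2 <- compute_long_axis(rot)
  expect_equal(abs(sum(ax2$axis * (Rx %*% c(0, 0, 1)))), 1,
               tolerance = 1e-6)

  # translation and uniform scaling leave the axis unchanged
  ts <- trimesh(tube$mesh$vertices * 2.5 +
                  matrix(c(10, -4, 7), nrow(tube$mesh$vertices), 3,
                         byrow = TRUE), tube$mesh$faces)
  expect_equal(abs(sum(compute_long_axis(ts)$axis * c(0, 0, 1))), 1,
               tolerance = 1e-6)

  expect_error(compute_long_axis(icosahedron()), "degenerate")
})

test_that("generalized radius matches tube, frustum brute force, and errors off-bone", {
  tube <- tube_model()
  expect_equal(generalized_radius(tube, 50, 3), 10, tolerance = 1e-9)

  # linear frustum 5 -> 15 mm over 100 mm
  fr <- generate_long_bone(bone_spec(
    length = 100, outer_radius = cbind(c(0, 100), c(5, 15)),
    thickness = 1.5, n_theta = 48, n_z = 40))
  got <- generalized_radius(fr, 50, 4)
  # independent brute force over the fixture's outer-wall vertices
  v <- fr$mesh$vertices
  outer_vid <- sort(unique(as.vector(
    fr$mesh$faces[fr$mesh$labels == 0L, ])))
  vv <- v[outer_vid, ]
  sel <- vv[, 3] >= 46 & vv[, 3] <= 54
  expect_equal(got, mean(sqrt(vv[sel, 1]^2 + vv[sel, 2]^2)),
               tolerance = 1e-12)
  expect_equal(got, 10, tolerance = 0.1)

  expect_error(generalized_radius(tube, 130, 3), "no outer-layer vertices")
})

test_that("signed volume is invariant under rigid transforms", {
  mesh <- tube_model(n_theta = 24, n_z = 10)$mesh
  v0 <- mesh_volume(mesh)
  set.seed(42)
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0),
                c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    v <- mesh$vertices %*% t(Rz %*% Rx) +
      matrix(runif(3, -50, 50), nrow(mesh$vertices), 3, byrow = TRUE)
    expect_equal(mesh_volume(trimesh(v, mesh$faces)), v0,
                 tolerance = 1e-9 * abs(v0))
  }
})
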