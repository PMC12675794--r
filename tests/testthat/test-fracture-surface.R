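# Contour extraction, annulus triangulation, perturbation, assembly.

make_cut_tube <- function(type = "transverse", params = list(v0 = 0),
                          n_theta = 64, strategy = cut_strategy("hybrid", 0.1),
                          height = 51) {
  tube <- tube_model(n_theta = n_theta)
  cyl <- fit_projection_cylinder(tube, height, 16)
  pat <- generate_parametric_pattern(type, params, inner_offset = 0.8,
                                     inner_noise = 0.3, seed = 4)
  pl <- place_pattern(pat, cyl, fracture_height = height)
  emb <- embed_cuts(tube, list(
    compute_cut_points(unwrap_band(tube, cyl, "outer"), pl),
    compute_cut_points(unwrap_band(tube, cyl, "inner"), pl)), strategy)
  emb
}

test_that("fracture contours chain into closed per-layer loops", {
  emb <- make_cut_tube(strategy = cut_strategy("subdivision"))
  ct <- extract_fracture_contours(emb$model$mesh, emb$fracture_edges, 1L)
  # 64 circumferential segments, no snapping: at least 64 vertices per loop
  expect_gte(length(ct$outer), 64L)
  expect_gte(length(ct$inner), 64L)
  # loops close: every contour vertex has exactly two incident loop edges
  expect_equal(length(unique(ct$outer)), length(ct$outer))

  # deleting a fracture edge breaks the chain
  broken <- emb$fracture_edges[-3, ]
  expect_error(extract_fracture_contours(emb$model$mesh, broken, 1L),
               "does not close")
})

test_that("annulus triangulation covers the ring, spares the canal, keeps loops", {
  # concentric circles, radii 10 and 7, 64 points each
  n <- 64
  th <- 2 * pi * (seq_len(n) - 1) / n
  verts <- rbind(cbind(10 * cos(th), 10 * sin(th), 0),
                 cbind(7 * cos(th), 7 * sin(th), 0))
  ct <- structure(list(outer = 1:n, inner = n + 1:n, line = 1L),
                  class = "fracture_contours")
  zone <- triangulate_fracture_zone(verts, ct)
  f <- zone$faces
  v <- zone$verts
  areas <- 0.5 * sqrt(rowSums(cortifrac:::cross3_rows(
    v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])^2))
  expect_equal(sum(areas), pi * (100 - 49), tolerance = 0.01)

  # no triangle centroid inside the inner circle
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  expect_true(all(sqrt(cen[, 1]^2 + cen[, 2]^2) > 7 - 1e-9))

  # boundary edges (face degree 1) are exactly the two input loops
  key <- paste(pmin(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
               pmax(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])))
  boundary <- names(table(key))[table(key) == 1L]
  loop_keys <- function(loop) {
    nx <- c(loop[-1], loop[1])
    paste(pmin(loop, nx), pmax(loop, nx))
  }
  expect_setequal(boundary, c(loop_keys(ct$outer), loop_keys(ct$inner)))
})

test_that("oblique (elliptical) contours keep their boundary exactly", {
  n <- 48
  th <- 2 * pi * (seq_len(n) - 1) / n
  tilt <- 0.4
  verts <- rbind(cbind(10 * cos(th), 10 * sin(th), tilt * 10 * cos(th)),
                 cbind(7 * cos(th), 7 * sin(th), tilt * 7 * cos(th)))
  ct <- structure(list(outer = 1:n, inner = n + 1:n, line = 1L),
                  class = "fracture_contours")
  zone <- triangulate_fracture_zone(verts, ct)
  f <- zone$faces
  key <- paste(pmin(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
               pmax(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])))
  boundary <- names(table(key))[table(key) == 1L]
  loop_keys <- function(loop) {
    nx <- c(loop[-1], loop[1])
    paste(pmin(loop, nx), pmax(loop, nx))
  }
  expect_setequal(boundary, c(loop_keys(ct$outer), loop_keys(ct$inner)))
})

test_that("perturbation contracts: tau bound, exact tripling, determinism", {
  n <- 48
  th <- 2 * pi * (seq_len(n) - 1) / n
  verts <- rbind(cbind(10 * cos(th), 10 * sin(th), 0),
                 cbind(7 * cos(th), 7 * sin(th), 0))
  ct <- structure(list(outer = 1:n, inner = n + 1:n, line = 1L),
                  class = "fracture_contours")
  flat <- triangulate_fracture_zone(verts, ct)

  # tau = 0 is the identity for both methods (B adds undisplaced centroids)
  z0 <- triangulate_fracture_zone(verts, ct,
                                  perturbation_config("pre_triangulation",
                                                      0), seed = 5)
  expect_identical(z0$faces, flat$faces)
  expect_equal(z0$verts, flat$verts)

  cfg <- perturbation_config("post_triangulation", 0.5, seed = 5)
  zb <- triangulate_fracture_zone(verts, ct, cfg, seed = 5)
  expect_equal(nrow(zb$faces), 3L * nrow(flat$faces))
  # boundary vertices untouched
  expect_identical(zb$verts[1:(2 * n), ], verts[1:(2 * n), ])
  # displacement of each added centroid from its flat position <= tau
  f <- flat$faces
  v <- flat$verts
  flat_cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  moved_cen <- zb$verts[(nrow(flat$verts) + 1):nrow(zb$verts), ]
  d <- sqrt(rowSums((moved_cen - flat_cen)^2))
  expect_true(all(d <= 0.5 + 1e-12))
  expect_gt(max(d), 0)

  # fixed seed: bit-identical reruns
  zb2 <- triangulate_fracture_zone(verts, ct, cfg, seed = 5)
  expect_identical(zb$verts, zb2$verts)
  expect_identical(zb$faces, zb2$faces)

  # method A: only interior (mid-ring) vertices move, bounded by tau
  cfg_a <- perturbation_config("pre_triangulation", 0.4, seed = 7)
  za <- triangulate_fracture_zone(verts, ct, cfg_a, seed = 7)
  expect_identical(za$verts[1:(2 * n), ], verts[1:(2 * n), ])
  d_mid <- sqrt(rowSums((za$verts[za$mid_ids, ] -
                           flat$verts[flat$mid_ids, ])^2))
  expect_true(all(d_mid <= 0.4 + 1e-12))
  expect_gt(max(d_mid), 0)

  # with tau = 0 method B's vertex set contains method A's
  expect_true(nrow(zb$verts) > nrow(z0$verts))
  expect_identical(zb$verts[seq_len(nrow(z0$verts)), ], z0$verts)
})

test_that("fragments are watertight and volumes sum exactly across configs", {
  tube <- tube_model()
  v0 <- mesh_volume(tube$mesh)
  pat_t <- generate_parametric_pattern("transverse", list(v0 = 0),
                                       inner_offset = 0.8,
                                       inner_noise = 0.3, seed = 4)
  pat_w <- generate_parametric_pattern("wedge", list(v0 = 47),
                                       inner_offset = 0.8,
                                       inner_noise = 0.3, seed = 4)
  for (pat in list(pat_t, pat_w)) {
    for (pc in list(perturbation_config("none"),
                    perturbation_config("pre_triangulation", 0.5, 11),
                    perturbation_config("post_triangulation", 0.5, 11))) {
      fb <- fracture_bone(tube, pat, fracture_height = 51,
                          perturbation = pc)
      expect_true(all(vapply(fb$fragments, is_closed_mesh, logical(1))))
      expect_equal(sum(fb$volumes), v0, tolerance = 1e-9)
      # positive volumes: consistent outward orientation
      expect_true(all(fb$volumes > 0))
    }
  }
})

test_that("mating fracture surfaces are geometrically identical", {
  tube <- tube_model()
  pat <- generate_parametric_pattern("transverse", list(v0 = 0),
                                     inner_offset = 0.8, inner_noise = 0.3,
                                     seed = 4)
  fb <- fracture_bone(tube, pat, fracture_height = 51,
                      perturbation = perturbation_config(
                        "post_triangulation", 0.5, 11))
  walls <- lapply(fb$fragments, function(fr) {
    ff <- fr$faces[fr$labels == 2L, , drop = FALSE]
    pts <- fr$vertices[sort(unique(as.vector(ff))), , drop = FALSE]
    pts[order(pts[, 1], pts[, 2], pts[, 3]), ]
  })
  expect_equal(walls[[1]], walls[[2]], tolerance = 1e-12)
})
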