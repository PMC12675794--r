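# Shared fixtures, all generated in code.

# Standard test tube: 100 mm shaft, outer radius 10 mm, 3 mm cortex.
tube_model <- function(n_theta = 64, n_z = 32, outer_radius = 10,
                       thickness = 3, length = 100, ...) {
  generate_long_bone(bone_spec(length = length,
                               outer_radius = outer_radius,
                               thickness = thickness,
                               n_theta = n_theta, n_z = n_z, ...))
}

# Analytic shell volume of a straight tube.
tube_shell_volume <- function(outer_radius = 10, thickness = 3,
                              length = 100) {
  pi * (outer_radius^2 - (outer_radius - thickness)^2) * length
}

# Icosahedron (closed, watertight): 12 vertices, 20 faces.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
             c(9, 7, 8), c(10, 9, 2))
  trimesh(v, f)
}

# Mean edge length of a mesh.
mean_edge_length <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  mean(sqrt(rowSums((v[c(f[, 1], f[, 2], f[, 3]), , drop = FALSE] -
                       v[c(f[, 2], f[, 3], f[, 1]), , drop = FALSE])^2)))
}

# Resample a polyline (x, y) densely by arc length.
densify_polyline <- function(xy, n = 1500) {
  fr <- cumsum(c(0, sqrt(rowSums(diff(xy)^2))))
  fr <- fr / max(fr)
  tt <- seq(0, 1, length.out = n)
  cbind(stats::approx(fr, xy[, 1], tt)$y, stats::approx(fr, xy[, 2], tt)$y)
}

# Symmetric Hausdorff distance between two polylines in (x, y) mm, with x
# periodic with period `circ`.
hausdorff_wrapped <- function(A, B, circ) {
  one_way <- function(P, Q) {
    max(vapply(seq_len(nrow(P)), function(i) {
      dx <- abs(Q[, 1] - P[i, 1])
      dx <- pmin(dx, abs(dx - circ), abs(dx + circ))
      min(sqrt(dx^2 + (Q[, 2] - P[i, 2])^2))
    }, numeric(1)))
  }
  max(one_way(A, B), one_way(B, A))
}

# Placed pattern line -> (x, y) mm polyline.
placed_line_xy <- function(line) {
  cbind(line[, 1], line[, 2])
}

# Pattern line (u, v) -> (x, y) mm polyline for a given circumference.
pattern_line_xy <- function(line, circ) {
  uc <- cortifrac:::unroll_u(line)
  cbind(uc * circ, line[, 2])
}

# Watertight + orientable check.
is_closed_mesh <- function(mesh) {
  rep <- validate_mesh(mesh)
  rep$watertight && rep$orientable
}
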