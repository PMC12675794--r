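#' Specification of a synthetic two-layer cortical long bone
#'
#' Parameterizes the deterministic generator [generate_long_bone()]: a hollow
#' diaphyseal shaft built from an outer and an inner concentric tubular
#' surface closed by annular caps. Radius and cortical thickness may vary
#' along the shaft as piecewise-linear profiles.
#'
#' @param length shaft length (mm).
#' @param outer_radius outer cortical radius: a scalar (mm) or a two-column
#'   matrix `(z, radius)` interpolated linearly over `[0, length]`.
#' @param thickness cortical thickness, same forms as `outer_radius`.
#' @param n_theta circumferential segment count (>= 8).
#' @param n_z axial segment count (>= 4).
#' @param curvature bow amplitude (mm): lateral displacement of ring centres
#'   following a half-sine along the shaft. 0 = straight.
#' @param seed integer seed recorded in the spec (the base shell itself is
#'   deterministic; the seed feeds [perturb_surface_noise()]).
#' @return An object of class `bone_spec`.
#' @export
bone_spec <- function(length = 100, outer_radius = 10, thickness = 3,
                      n_theta = 64, n_z = 32, curvature = 0, seed = 1) {
  stopifnot(length > 0, n_theta >= 8, n_z >= 4, curvature >= 0)
  prof <- function(p, what) {
    if (is.matrix(p)) {
      stopifnot(ncol(p) == 2, nrow(p) >= 2)
      stats::approxfun(p[, 1], p[, 2], rule = 2)
    } else {
      force(p)
      function(z) rep_len(p, base::length(z))
    }
  }
  spec <- structure(list(length = length,
                         outer_radius = prof(outer_radius),
                         thickness = prof(thickness),
                         n_theta = as.integer(n_theta),
                         n_z = as.integer(n_z),
                         curvature = curvature,
                         seed = as.integer(seed)),
                    class = "bone_spec")
  z <- seq(0, length, length.out = 257)
  r_out <- spec$outer_radius(z)
  thick <- spec$thickness(z)
  if (any(thick <= 0)) stop("cortical thickness must be positive everywhere")
  if (any(r_out - thick <= 0))
    stop("inner radius non-positive: thickness must be below outer radius")
  spec
}

#' Generate a synthetic two-layer cortical bone shell
#'
#' Builds a watertight shell: outer tube, inner tube at
#' `outer_radius - thickness`, joined by annular caps at both ends. Faces are
#' labeled outer (0; caps included) and inner (1). Deterministic for a fixed
#' spec. The model axis is the construction axis +Z with origin at the vertex
#' centroid.
#'
#' @param spec a [bone_spec].
#' @return A [cortical_bone] model (with the spec attached as `$spec`).
#' @export
generate_long_bone <- function(spec) {
  stopifnot(inherits(spec, "bone_spec"))
  nt <- spec$n_theta
  nz <- spec$n_z
  z <- seq(0, spec$length, length.out = nz + 1L)
  theta <- 2 * pi * (seq_len(nt) - 1L) / nt
  r_out <- spec$outer_radius(z)
  r_in <- r_out - spec$thickness(z)
  bow <- spec$curvature * sin(pi * z / spec$length)

  ring <- function(r, zj, bj)
    cbind(bj + r * cos(theta), r * sin(theta), zj)
  vo <- do.call(rbind, lapply(seq_along(z), function(j)
    ring(r_out[j], z[j], bow[j])))
  vi <- do.call(rbind, lapply(seq_along(z), function(j)
    ring(r_in[j], z[j], bow[j])))
  verts <- rbind(vo, vi)
  n_ring <- nt
  o_id <- function(j, i) (j - 1L) * n_ring + ((i - 1L) %% nt) + 1L
  i_id <- function(j, i) nrow(vo) + o_id(j, i)

  faces <- vector("list", 4L)
  i1 <- seq_len(nt)
  i2 <- i1 + 1L
  # Outer wall, outward normals.
  faces[[1]] <- do.call(rbind, lapply(seq_len(nz), function(j)
    rbind(cbind(o_id(j, i1), o_id(j, i2), o_id(j + 1L, i2)),
          cbind(o_id(j, i1), o_id(j + 1L, i2), o_id(j + 1L, i1)))))
  # Inner wall, normals toward the medullary canal (outward of the solid).
  faces[[2]] <- do.call(rbind, lapply(seq_len(nz), function(j)
    rbind(cbind(i_id(j, i1), i_id(j + 1L, i2), i_id(j, i2)),
          cbind(i_id(j, i1), i_id(j + 1L, i1), i_id(j + 1L, i2)))))
  # Caps: annuli at both ends closing the shell.
  faces[[3]] <- rbind(cbind(o_id(1L, i2), o_id(1L, i1), i_id(1L, i1)),
                      cbind(o_id(1L, i2), i_id(1L, i1), i_id(1L, i2)))
  jt <- nz + 1L
  faces[[4]] <- rbind(cbind(o_id(jt, i1), o_id(jt, i2), i_id(jt, i2)),
                      cbind(o_id(jt, i1), i_id(jt, i2), i_id(jt, i1)))
  fmat <- do.call(rbind, faces)
  labels <- c(integer(nrow(faces[[1]])),            # outer = 0
              rep(1L, nrow(faces[[2]])),            # inner = 1
              integer(nrow(faces[[3]]) + nrow(faces[[4]])))  # caps = 0
  mesh <- trimesh(verts, fmat, labels)
  model <- cortical_bone(mesh, c(0, 0, 1), colMeans(verts), spec$length)
  model$spec <- spec
  model
}

#' Smooth radial surface noise
#'
#' Displaces every vertex radially by a smooth low-frequency sinusoidal field
#' bounded by `amplitude`, emulating anatomical undulation of the bone
#' surface. The same field is applied to both layers, so the local cortical
#' thickness (and layer ordering) is preserved exactly, and the field
#' vanishes at the shaft ends so the caps stay planar and the shell
#' watertight.
#'
#' @param model a [cortical_bone] built by [generate_long_bone()].
#' @param amplitude maximum radial displacement (mm, >= 0).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param n_harmonics number of circumferential/axial harmonics mixed.
#' @return The perturbed [cortical_bone].
#' @export
perturb_surface_noise <- function(model, amplitude, seed = 1,
                                  n_harmonics = 4) {
  stopifnot(inherits(model, "cortical_bone"), amplitude >= 0)
  if (amplitude == 0) return(model)
  spec <- model$spec
  if (is.null(spec))
    stop("perturb_surface_noise needs a generated model (missing spec)")
  v <- model$mesh$vertices
  zs <- v[, 3]
  bow <- spec$curvature * sin(pi * zs / spec$length)
  dx <- v[, 1] - bow
  dy <- v[, 2]
  th <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  pars <- with_seed(seed, list(
    a = stats::runif(n_harmonics, 0.3, 1),
    m = sample(1:4, n_harmonics, replace = TRUE),
    p = sample(1:3, n_harmonics, replace = TRUE),
    phi = stats::runif(n_harmonics, 0, 2 * pi),
    psi = stats::runif(n_harmonics, 0, 2 * pi)))
  field <- 0
  for (k in seq_len(n_harmonics))
    field <- field + pars$a[k] * sin(pars$m[k] * th + pars$phi[k]) *
      sin(pi * pars$p[k] * zs / spec$length + pars$psi[k])
  # sin(pi p z / L) is not zero at the ends for arbitrary psi; damp with an
  # explicit end window so caps remain planar.
  window <- sin(pi * zs / spec$length)
  delta <- amplitude * field / sum(abs(pars$a)) * window
  scale <- ifelse(r > 0, (r + delta) / pmax(r, .Machine$double.eps), 1)
  v2 <- cbind(bow + dx * scale, dy * scale, zs)
  out <- model
  out$mesh <- trimesh(v2, model$mesh$faces, model$mesh$labels)
  out$origin <- colMeans(v2)
  out
}
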