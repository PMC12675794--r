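#' Height map of a fracture zone
#'
#' Places a reference plane perpendicular to the bone axis, `margin` mm
#' above the highest fracture-surface point along the axis, and records the
#' perpendicular distance from the plane down to every fracture-surface
#' vertex. The resulting per-point heights capture the 3D irregularity of
#' the fracture as a comparable height profile.
#'
#' @param x a [trimesh] with fracture-surface faces (label 2), a
#'   [fractured_bone] fragment, or an `n x 3` point matrix (all points are
#'   used).
#' @param axis unit 3-vector: the bone long axis the plane is perpendicular
#'   to.
#' @param margin clearance between the plane and the highest point (mm).
#'   Means are margin-sensitive; comparisons require equal margins.
#' @return An object of class `height_map`: `heights` (mm, all `>= margin`),
#'   `margin`, `axis`, `plane_offset` (axial coordinate of the plane).
#' @export
build_height_map <- function(x, axis = c(0, 0, 1), margin = 1) {
  stopifnot(margin >= 0)
  pts <- if (inherits(x, "trimesh")) {
    ff <- x$faces[x$labels == 2L, , drop = FALSE]
    if (nrow(ff) == 0L)
      stop("mesh has no fracture-surface faces (label 2)")
    x$vertices[sort(unique(as.vector(ff))), , drop = FALSE]
  } else {
    m <- as.matrix(x)
    if (nrow(m) == 0L) stop("empty point set")
    m
  }
  axis <- unit(axis)
  h <- as.vector(pts %*% axis)
  plane <- max(h) + margin
  structure(list(heights = plane - h, margin = margin, axis = axis,
                 plane_offset = plane, n = length(h)),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "height_map: %d points, mean %.3f mm, range %.3f mm (margin %.2f)\n",
    x$n, mma(x), height_range(x), x$margin))
  invisible(x)
}

#' Height-map statistics
#'
#' `mma()` is the mean height over the map (the mean-map value: MMAR when
#' the map comes from a real/reference fracture, MMAS from a simulated one);
#' `height_range()` is the difference between the maximum and minimum
#' heights.
#'
#' @param map a [height_map].
#' @return mean height (mm) / height range (mm).
#' @export
mma <- function(map) {
  stopifnot(inherits(map, "height_map"), length(map$heights) > 0)
  mean(map$heights)
}

#' @rdname mma
#' @export
height_range <- function(map) {
  stopifnot(inherits(map, "height_map"), length(map$heights) > 0)
  max(map$heights) - min(map$heights)
}

#' Comparison report between a reference and a simulated fracture
#'
#' Implements the height-map comparison arithmetic: the simulated mean map
#' value is rescaled by the thickness ratio of the two bones
#' (`mmas_scaled = mmas * t_original / t_new`, with thickness measured as
#' the generalized radius at the fracture height), and the report carries
#' `distance = mmas_scaled - mmar` and
#' `percent_variation = (mmar - mmas_scaled) / mmar * 100`.
#'
#' @param mmar mean map value of the reference fracture (mm).
#' @param mmas mean map value of the simulated fracture (mm).
#' @param t_original,t_new generalized radii (mm) of the reference and
#'   simulated bones (`t_new > 0`).
#' @param range_real,range_sim height-map ranges (mm), optional.
#' @param margin height-map margin the means were computed with.
#' @return An object of class `comparison_report`.
#' @export
comparison_report <- function(mmar, mmas, t_original, t_new,
                              range_real = NA_real_, range_sim = NA_real_,
                              margin = NA_real_) {
  if (t_new <= 0) stop("t_new must be positive")
  mmas_scaled <- mmas * t_original / t_new
  pct <- if (mmar > 0) (mmar - mmas_scaled) / mmar * 100 else {
    warning("mmar is zero; percent variation undefined (reported as NA)")
    NA_real_
  }
  structure(list(mmar = mmar, mmas = mmas,
                 t_original = t_original, t_new = t_new,
                 mmas_scaled = mmas_scaled,
                 range_real = range_real, range_sim = range_sim,
                 distance = mmas_scaled - mmar,
                 percent_variation = pct,
                 margin = margin),
            class = "comparison_report")
}

#' @rdname comparison_report
#' @param real_map,sim_map [height_map]s of the reference and simulated
#'   fracture zones (must share the same margin).
#' @export
compare_height_maps <- function(real_map, sim_map, t_original, t_new) {
  stopifnot(inherits(real_map, "height_map"),
            inherits(sim_map, "height_map"))
  if (abs(real_map$margin - sim_map$margin) > 1e-12)
    stop("height maps have different margins; rebuild with equal margins")
  comparison_report(mma(real_map), mma(sim_map), t_original, t_new,
                    range_real = height_range(real_map),
                    range_sim = height_range(sim_map),
                    margin = real_map$margin)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("height-map comparison\n")
  cat(sprintf("  reference: radius %.2f mm, MMAR %.2f mm, range %.2f mm\n",
              x$t_original, x$mmar, x$range_real))
  cat(sprintf("  simulated: radius %.2f mm, MMAS %.2f mm, range %.2f mm\n",
              x$t_new, x$mmas, x$range_sim))
  cat(sprintf("  MMAS scaled %.2f mm | distance %+.2f mm | variation %+.2f%%\n",
              x$mmas_scaled, x$distance, x$percent_variation))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a [comparison_report].
#' @param path output file.
#' @param provenance optional named list recorded alongside the metrics
#'   (input files, seeds, configuration).
#' @export
write_report <- function(report, path, provenance = list()) {
  stopifnot(inherits(report, "comparison_report"))
  fields <- unclass(report)
  fields <- fields[vapply(fields, function(x)
    is.numeric(x) && length(x) == 1L, logical(1))]
  jsonlite::write_json(c(fields, list(provenance = provenance)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
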