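#' 2D fracture pattern
#'
#' A fracture pattern is a set of polylines on the unwrapped bone surface,
#' one set per cortical layer, in coordinates `(u, v)`: `u` is the
#' normalized circumferential position in `[0, 1)` (rescaled to arc length at
#' projection time) and `v` is the longitudinal position in mm. `u = 0` is an
#' arbitrary but persistent reference meridian; all wrap arithmetic is modulo
#' 1, and consecutive points are joined by the shortest circumferential step
#' (|du| < 0.5). A polyline is closed when its first and last points coincide
#' modulo the u-wrap; all parametrically generated lines are closed loops.
#'
#' @param lines_outer list of `k x 2` matrices (columns `u`, `v`), the
#'   fracture lines on the outer cortical layer.
#' @param lines_inner same structure for the inner layer; when `NULL` the
#'   outer lines are copied with a warning.
#' @param fracture_type one of `"transverse"`, `"oblique"`, `"spiral"`,
#'   `"wedge"`, `"comminuted"`.
#' @param source one of `"drawn"`, `"parametric"`, `"extracted"`.
#' @param meta free-form provenance list; `meta$design_circumference` (mm)
#'   records the circumference the pattern was designed or extracted at and
#'   drives the aspect-ratio feasibility check at projection time.
#' @return An object of class `fracture_pattern`.
#' @export
fracture_pattern <- function(lines_outer, lines_inner = NULL,
                             fracture_type = c("transverse", "oblique",
                                               "spiral", "wedge",
                                               "comminuted"),
                             source = c("parametric", "drawn", "extracted"),
                             meta = list()) {
  fracture_type <- match.arg(fracture_type)
  source <- match.arg(source)
  check_lines <- function(lines, where) {
    if (length(lines) == 0L) return(invisible())
    for (i in seq_along(lines)) {
      l <- lines[[i]]
      if (!is.matrix(l) || ncol(l) != 2L)
        stop(where, "[", i, "]: polyline must be a k x 2 matrix")
      if (nrow(l) < 2L)
        stop(where, "[", i, "]: polyline needs at least 2 points")
      bad <- which(l[, 1] < 0 | l[, 1] >= 1)
      if (length(bad))
        stop(sprintf("%s[%d]: u = %.6g at point %d outside [0, 1)",
                     where, i, l[bad[1], 1], bad[1]))
    }
    invisible()
  }
  lines_outer <- lapply(lines_outer, function(l) {
    m <- matrix(as.numeric(l), ncol = 2)
    colnames(m) <- c("u", "v")
    m
  })
  check_lines(lines_outer, "lines_outer")
  if (is.null(lines_inner)) {
    warning("no inner-layer lines; copying outer lines with zero offset")
    lines_inner <- lines_outer
  } else {
    lines_inner <- lapply(lines_inner, function(l) {
      m <- matrix(as.numeric(l), ncol = 2)
      colnames(m) <- c("u", "v")
      m
    })
    check_lines(lines_inner, "lines_inner")
  }
  structure(list(lines_outer = lines_outer, lines_inner = lines_inner,
                 fracture_type = fracture_type, source = source,
                 meta = meta),
            class = "fracture_pattern")
}

#' @export
print.fracture_pattern <- function(x, ...) {
  vr <- range(unlist(lapply(x$lines_outer, function(l) l[, 2])))
  cat(sprintf(
    "fracture_pattern: %s (%s), %d outer / %d inner lines, v in [%.1f, %.1f] mm\n",
    x$fracture_type, x$source, length(x$lines_outer),
    length(x$lines_inner), vr[1], vr[2]))
  invisible(x)
}

# Shortest circumferential step between two u values (modulo 1).
wrap_du <- function(u_from, u_to) ((u_to - u_from + 0.5) %% 1) - 0.5

# Cumulative (unrolled) u along a polyline so segments never jump across the
# seam; the winding number of a closed loop is the total cumulative change.
unroll_u <- function(line) {
  u <- line[, 1]
  cumsum(c(u[1], wrap_du(u[-length(u)], u[-1])))
}

is_closed_line <- function(line, tol = 1e-9) {
  n <- nrow(line)
  du <- abs(wrap_du(line[n, 1], line[1, 1]))
  du < tol && abs(line[n, 2] - line[1, 2]) < tol
}

# Polyline length with u scaled to mm by `circumference`.
line_length_mm <- function(line, circumference) {
  uc <- unroll_u(line) * circumference
  sum(sqrt(diff(uc)^2 + diff(line[, 2])^2))
}

#' Parametric generation of fracture patterns
#'
#' Generates a closed-loop pattern for each AO/OTA-style fracture type.
#' Detached fragments (wedge, comminuted) are encoded as additional closed
#' loops rather than line junctions, so every line is one fracture interface.
#' The inner-layer lines are the outer lines shifted by `inner_offset` along
#' `v` plus smooth periodic noise bounded by `inner_noise`, reflecting how
#' the fracture line shifts as it traverses the cortical thickness.
#'
#' Type-specific `params`:
#' \describe{
#'   \item{transverse}{`v0` (mm), `waviness` (mm, default 0), `wave_freq`
#'     (integer cycles per wrap, default 2).}
#'   \item{oblique}{`v0`, `angle` (degrees from the transverse plane,
#'     default 30): a wrap-symmetric ramp with |dv/darc| = tan(angle), total
#'     rise-and-fall over one wrap = circumference * tan(angle).}
#'   \item{spiral}{`v0`, `pitch` (axial advance over the single full turn,
#'     mm, default 40); the loop closes with a meridian segment.}
#'   \item{wedge}{`v0`, `width` (fraction of circumference, default 0.25),
#'     `height` (mm, default 15), `gap` (mm above the main line, default 1).}
#'   \item{comminuted}{`v0`, `n_loops` (default 3), `loop_rv` (mm loop
#'     half-height, default 6), `gap` (default 1.5).}
#' }
#'
#' @param fracture_type fracture class.
#' @param params named list of type-specific controls (see Details).
#' @param inner_offset deterministic v-shift of the inner-layer lines (mm).
#' @param inner_noise bound on the smooth periodic inner-line noise (mm).
#' @param seed integer seed for the inner-line noise and comminuted jitter.
#' @param n_seg points per full wrap for smooth lines.
#' @param design_circumference circumference (mm) the pattern is designed
#'   at; recorded in `meta` for aspect-ratio checks and oblique slope.
#' @return A [fracture_pattern] with `source = "parametric"`.
#' @export
generate_parametric_pattern <- function(fracture_type, params = list(),
                                        inner_offset = 0, inner_noise = 0,
                                        seed = 1, n_seg = 96,
                                        design_circumference = 2 * pi * 10) {
  fracture_type <- match.arg(fracture_type,
                             c("transverse", "oblique", "spiral", "wedge",
                               "comminuted"))
  p <- params
  v0 <- p$v0 %||% 50
  cf <- design_circumference
  us <- seq(0, 1, length.out = n_seg + 1L)  # closure point included
  wrap <- function(u) u %% 1
  loop <- function(u, v) cbind(u = wrap(u), v = v)

  lines <- switch(fracture_type,
    transverse = {
      wav <- p$waviness %||% 0
      wf <- round(p$wave_freq %||% 2)
      if (wav < 0) stop("waviness must be >= 0")
      list(loop(us, v0 + wav * sin(2 * pi * wf * us)))
    },
    oblique = {
      ang <- p$angle %||% 30
      if (ang <= 0 || ang >= 80)
        stop("oblique angle must be in (0, 80) degrees")
      tent <- ifelse(us <= 0.5, us, 1 - us)
      list(loop(us, v0 + tan(ang * pi / 180) * cf * tent))
    },
    spiral = {
      pitch <- p$pitch %||% 40
      if (pitch <= 0) stop("spiral pitch must be positive")
      u0 <- p$u0 %||% 0.37  # hinge meridian; offset from the u = 0 seam
      helix <- loop(u0 + us, v0 + pitch * us)
      list(rbind(helix, c(helix[1, 1], v0)))  # meridian closing segment
    },
    wedge = {
      w <- p$width %||% 0.25
      hgt <- p$height %||% 15
      gap <- p$gap %||% 1
      if (w <= 0 || w >= 0.5) stop("wedge width must be in (0, 0.5)")
      if (hgt <= 0) stop("wedge height must be positive")
      base <- loop(us, rep(v0, length(us)))
      uc <- p$u_center %||% 0.5
      tri <- cbind(u = wrap(c(uc - w / 2, uc + w / 2, uc, uc - w / 2)),
                   v = c(v0 + gap, v0 + gap, v0 + gap + hgt, v0 + gap))
      list(base, tri)
    },
    comminuted = {
      k <- p$n_loops %||% 3
      rv <- p$loop_rv %||% 6
      gap <- p$gap %||% 1.5
      if (k < 2) stop("comminuted needs at least 2 detached loops")
      base <- loop(us, rep(v0, length(us)))
      jit <- with_seed(seed, stats::runif(2 * k, -0.2, 0.2))
      loops <- lapply(seq_len(k), function(j) {
        uc <- (j - 0.5) / k + jit[j] / k
        ru <- 0.3 / k
        vc <- v0 + gap + rv * (1 + 0.3 * jit[k + j])
        a <- seq(0, 2 * pi, length.out = 9)  # octagon, closed
        cbind(u = wrap(uc + ru * cos(a)), v = vc + rv * 0.8 * sin(a))
      })
      c(list(base), loops)
    })

  inner <- derive_inner_lines(lines, inner_offset, inner_noise, seed)
  fracture_pattern(lines, inner, fracture_type, source = "parametric",
                   meta = list(design_circumference = cf, params = p,
                               inner_offset = inner_offset,
                               inner_noise = inner_noise, seed = seed))
}

# Inner lines: deterministic v-offset plus seeded smooth periodic noise
# (periodic in normalized arc position, so closed loops stay closed).
derive_inner_lines <- function(lines, inner_offset, inner_noise, seed) {
  if (inner_offset == 0 && inner_noise == 0) return(lines)
  lapply(seq_along(lines), function(i) {
    l <- lines[[i]]
    uc <- unroll_u(l)
    arc <- cumsum(c(0, sqrt(diff(uc)^2 + (diff(l[, 2]) / 30)^2)))
    s <- if (max(arc) > 0) arc / max(arc) else arc
    eps <- 0
    if (inner_noise > 0) {
      pars <- with_seed(child_seed(seed, i), list(
        b = stats::runif(3, 0.3, 1), phi = stats::runif(3, 0, 2 * pi)))
      for (k in 1:3)
        eps <- eps + pars$b[k] * sin(2 * pi * k * s + pars$phi[k])
      eps <- inner_noise * eps / sum(abs(pars$b))
    }
    cbind(u = l[, 1], v = l[, 2] + inner_offset + eps)
  })
}

#' Count the planar regions a pattern cuts the band into
#'
#' Rasterizes the periodic band `[0,1) x [v_min - pad, v_max + pad]`, marks
#' cells crossed by any fracture line of the requested layer, and counts
#' connected components of the free cells (4-connectivity, wrapping in u).
#' On a clean tube this equals the number of fragments produced downstream.
#'
#' @param pattern a [fracture_pattern].
#' @param layer `"outer"` or `"inner"`.
#' @param pad longitudinal padding (mm) standing in for the intact shaft on
#'   both sides of the pattern.
#' @param resolution raster cells per unit u and per band height.
#' @return integer region count.
#' @export
pattern_regions <- function(pattern, layer = "outer", pad = 10,
                            resolution = 256) {
  lines <- if (layer == "outer") pattern$lines_outer else
    pattern$lines_inner
  lines_uv <- lapply(lines, function(l) cbind(unroll_u(l), l[, 2]))
  region_raster(lines_uv, pad = pad, resolution = resolution)$n_regions
}

# Rasterized planar arrangement of the periodic band: marks cells crossed
# by any line (given in unrolled (u, v) coordinates) and labels connected
# components of the free cells (4-connectivity, u wraps, v does not).
region_raster <- function(lines_uv, pad = 10, resolution = 256) {
  vr <- range(unlist(lapply(lines_uv, function(l) l[, 2])))
  v_lo <- vr[1] - pad
  v_hi <- vr[2] + pad
  nu <- resolution
  nv <- resolution
  cell_u <- function(u) pmin(pmax(floor((u %% 1) * nu), 0), nu - 1) + 1L
  cell_v <- function(v)
    pmin(pmax(floor((v - v_lo) / (v_hi - v_lo) * nv), 0), nv - 1) + 1L
  blocked <- matrix(FALSE, nrow = nu, ncol = nv)
  for (l in lines_uv) {
    uc <- l[, 1]
    v <- l[, 2]
    for (k in seq_len(length(uc) - 1L)) {
      len <- max(abs(uc[k + 1] - uc[k]) * nu,
                 abs(v[k + 1] - v[k]) / (v_hi - v_lo) * nv)
      ns <- max(2L, ceiling(len * 3))
      tt <- seq(0, 1, length.out = ns)
      iu <- cell_u(uc[k] + tt * (uc[k + 1] - uc[k]))
      iv <- cell_v(v[k] + tt * (v[k + 1] - v[k]))
      blocked[cbind(iu, iv)] <- TRUE
    }
  }
  comp <- matrix(0L, nrow = nu, ncol = nv)
  n_comp <- 0L
  for (seed_cell in which(!blocked)) {
    if (comp[seed_cell] != 0L) next
    n_comp <- n_comp + 1L
    frontier <- seed_cell
    comp[seed_cell] <- n_comp
    while (length(frontier)) {
      i <- (frontier - 1L) %% nu + 1L
      j <- (frontier - 1L) %/% nu + 1L
      nb <- c((i %% nu) + (j - 1L) * nu + 1L,            # i+1 (wrap)
              ((i - 2L) %% nu) + (j - 1L) * nu + 1L,     # i-1 (wrap)
              ifelse(j < nv, i + j * nu, NA),            # j+1
              ifelse(j > 1L, i + (j - 2L) * nu, NA))     # j-1
      nb <- unique(nb[!is.na(nb)])
      nb <- nb[!blocked[nb] & comp[nb] == 0L]
      comp[nb] <- n_comp
      frontier <- nb
    }
  }
  lookup <- function(u, v) {
    comp[cbind(cell_u(u), cell_v(v))]
  }
  list(n_regions = n_comp, comp = comp, lookup = lookup,
       v_lo = v_lo, v_hi = v_hi)
}

#' Forensic validation criteria
#'
#' Numeric acceptance bounds for generated patterns: fracture-line count per
#' layer, total line length (as a multiple of the circumference), enclosed
#' fragment count, and longitudinal extent. Defaults per fracture type ship
#' in `inst/extdata/forensic_criteria.json` and are editable; pass `file` to
#' use a custom criteria file.
#'
#' @param fracture_type fracture class the criteria apply to.
#' @param file optional path to a JSON criteria file.
#' @param ... named overrides of individual bounds.
#' @return An object of class `forensic_criteria`.
#' @export
forensic_criteria <- function(fracture_type, file = NULL, ...) {
  file <- file %||% system.file("extdata", "forensic_criteria.json",
                                package = "cortifrac")
  all_cr <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  if (!fracture_type %in% names(all_cr))
    stop("no criteria defined for fracture type: ", fracture_type)
  cr <- as.list(all_cr[[fracture_type]])
  dots <- list(...)
  cr[names(dots)] <- dots
  need <- c("min_lines", "max_lines", "min_length", "max_length",
            "min_fragments", "max_fragments", "max_extent")
  miss <- setdiff(need, names(cr))
  if (length(miss)) stop("criteria missing fields: ",
                         paste(miss, collapse = ", "))
  if (cr$min_lines > cr$max_lines || cr$min_length > cr$max_length ||
        cr$min_fragments > cr$max_fragments)
    stop("criteria minima must not exceed maxima")
  structure(c(cr, list(fracture_type = fracture_type)),
            class = "forensic_criteria")
}

#' Validate a fracture pattern against forensic criteria
#'
#' Measures, per layer, the number of fracture lines, the total line length
#' in circumference multiples, the number of enclosed regions (fragments)
#' and the longitudinal extent, and compares each against the criteria.
#' Invalid patterns are returned with per-criterion reasons, never an error.
#'
#' @param pattern a [fracture_pattern].
#' @param criteria a [forensic_criteria]; defaults to the shipped criteria
#'   for the pattern's fracture type.
#' @return An object of class `pattern_validation` with fields `valid` and
#'   `checks` (one row per criterion: measured value, bounds, pass flag).
#' @export
validate_pattern <- function(pattern, criteria = NULL) {
  criteria <- criteria %||% forensic_criteria(pattern$fracture_type)
  cf <- pattern$meta$design_circumference %||% (2 * pi * 10)
  n_lines <- length(pattern$lines_outer)
  tot_len <- if (n_lines) sum(vapply(pattern$lines_outer, line_length_mm,
                                     numeric(1), circumference = cf)) / cf
             else 0
  n_frag <- if (n_lines) pattern_regions(pattern, "outer") else 1L
  extent <- if (n_lines)
    diff(range(unlist(lapply(pattern$lines_outer, function(l) l[, 2]))))
  else 0
  checks <- data.frame(
    criterion = c("line count", "total length / circumference",
                  "fragment count", "longitudinal extent"),
    value = c(n_lines, tot_len, n_frag, extent),
    lower = c(criteria$min_lines, criteria$min_length,
              criteria$min_fragments, 0),
    upper = c(criteria$max_lines, criteria$max_length,
              criteria$max_fragments, criteria$max_extent))
  checks$pass <- checks$value >= checks$lower & checks$value <= checks$upper
  checks$reason <- ifelse(checks$pass, "",
                          ifelse(checks$value < checks$lower,
                                 sprintf("%s %.3g below minimum %.3g",
                                         checks$criterion, checks$value,
                                         checks$lower),
                                 sprintf("%s %.3g above maximum %.3g",
                                         checks$criterion, checks$value,
                                         checks$upper)))
  structure(list(valid = all(checks$pass), checks = checks,
                 fracture_type = pattern$fracture_type),
            class = "pattern_validation")
}

#' @export
print.pattern_validation <- function(x, ...) {
  cat(sprintf("pattern validation (%s): %s\n", x$fracture_type,
              if (x$valid) "VALID" else "INVALID"))
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  %-30s %8.3g in [%g, %g] %s\n",
                x$checks$criterion[i], x$checks$value[i], x$checks$lower[i],
                x$checks$upper[i],
                if (x$checks$pass[i]) "ok" else "FAIL"))
  invisible(x)
}

#' Pattern file I/O
#'
#' Patterns persist as versioned JSON:
#' `{"schema": 1, "type", "source", "lines_outer": [[[u,v],...],...],
#' "lines_inner": [...], "meta": {...}}`. Round trips are lossless. Schema
#' violations raise an error naming the offending element.
#'
#' @param path file path.
#' @return [read_pattern()] returns a [fracture_pattern].
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$schema) || js$schema != 1)
    stop("/schema: expected pattern schema version 1")
  if (is.null(js$type)) stop("/type: missing fracture type")
  to_lines <- function(x, where) {
    if (is.null(x)) return(NULL)
    lapply(seq_along(x), function(i) {
      pts <- x[[i]]
      m <- do.call(rbind, lapply(seq_along(pts), function(k) {
        p <- unlist(pts[[k]])
        if (length(p) != 2L || !is.numeric(p))
          stop(sprintf("/%s/%d/%d: point must be [u, v]", where, i, k))
        if (p[1] < 0 || p[1] >= 1)
          stop(sprintf("/%s/%d/%d/u: value %.6g outside [0, 1)",
                       where, i, k, p[1]))
        p
      }))
      colnames(m) <- c("u", "v")
      m
    })
  }
  lo <- to_lines(js$lines_outer, "lines_outer")
  li <- to_lines(js$lines_inner, "lines_inner")
  if (is.null(lo)) stop("/lines_outer: missing outer fracture lines")
  if (!is.null(li) && length(li) == 0L) li <- NULL
  fracture_pattern(lo, li, fracture_type = js$type,
                   source = js$source %||% "drawn",
                   meta = js$meta %||% list())
}

#' @rdname read_pattern
#' @param pattern a [fracture_pattern].
#' @export
write_pattern <- function(pattern, path) {
  ser_lines <- function(lines)
    lapply(lines, function(l) lapply(seq_len(nrow(l)),
                                     function(k) as.numeric(l[k, ])))
  js <- list(schema = 1L, type = pattern$fracture_type,
             source = pattern$source,
             lines_outer = ser_lines(pattern$lines_outer),
             lines_inner = ser_lines(pattern$lines_inner),
             meta = pattern$meta)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
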