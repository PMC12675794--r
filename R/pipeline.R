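#' Run configuration
#'
#' Validates and normalizes a full simulation run configuration, either from
#' a named list or a YAML file. Fields: `bone` (a mesh `path`, or synthetic
#' generator parameters `length`, `outer_radius`, `thickness`, `n_theta`,
#' `n_z`, `curvature`, `noise_amplitude`), `pattern` (a pattern-file `path`
#' or `type` + `params` + `inner_offset` + `inner_noise`),
#' `fracture_height`, `band_halfwidth`, `strategy` (`mode`, `threshold`,
#' default hybrid 0.10), `perturbation` (`method`, `tau` in [0, 1] mm,
#' default 0.3), `margin` (height-map margin, default 1), `seed`,
#' `out_dir`.
#'
#' @param config named list or path to a YAML config file.
#' @return A validated object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  st <- cfg$strategy %||% list()
  cfg$strategy <- cut_strategy(st$mode %||% "hybrid",
                               st$threshold %||% 0.10)
  pb <- cfg$perturbation %||% list()
  method <- pb$method %||% "none"
  method <- switch(method, pre = "pre_triangulation",
                   post = "post_triangulation", method)
  cfg$perturbation <- perturbation_config(method, pb$tau %||% 0.3,
                                          pb$seed %||% cfg$seed)
  cfg$margin <- cfg$margin %||% 1
  if (cfg$margin < 0) stop("margin must be >= 0")
  if (!is.null(cfg$bone$path) && !file.exists(cfg$bone$path))
    stop("bone mesh file not found: ", cfg$bone$path)
  if (!is.null(cfg$pattern$path) && !file.exists(cfg$pattern$path))
    stop("pattern file not found: ", cfg$pattern$path)
  structure(cfg, class = "run_config")
}

config_bone <- function(cfg) {
  b <- cfg$bone %||% list()
  if (!is.null(b$path)) {
    as_cortical_bone(read_mesh(b$path))
  } else {
    spec <- bone_spec(length = b$length %||% 100,
                      outer_radius = b$outer_radius %||% 10,
                      thickness = b$thickness %||% 3,
                      n_theta = b$n_theta %||% 64,
                      n_z = b$n_z %||% 32,
                      curvature = b$curvature %||% 0,
                      seed = cfg$seed)
    model <- generate_long_bone(spec)
    if (!is.null(b$noise_amplitude) && b$noise_amplitude > 0)
      model <- perturb_surface_noise(model, b$noise_amplitude, cfg$seed)
    model
  }
}

config_pattern <- function(cfg) {
  p <- cfg$pattern %||% list()
  if (!is.null(p$path)) return(read_pattern(p$path))
  generate_parametric_pattern(p$type %||% "transverse",
                              params = p$params %||% list(),
                              inner_offset = p$inner_offset %||% 1,
                              inner_noise = p$inner_noise %||% 0.3,
                              seed = cfg$seed)
}

#' Run a fracture simulation end to end
#'
#' Loads or generates the bone and the pattern, executes
#' [fracture_bone()], writes one labeled PLY per fragment plus a JSON
#' manifest (fragment count, per-fragment volume and quality statistics,
#' seeds, the resolved configuration), and returns the result. Runs with
#' the same configuration and seed are bit-reproducible.
#'
#' @param config a [run_config], a named list, or a YAML file path.
#' @return The [fracture_bone()] result, invisibly, with the manifest
#'   attached as `$manifest`.
#' @export
run_fracture <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  model <- config_bone(cfg)
  pattern <- config_pattern(cfg)
  fb <- fracture_bone(model, pattern,
                      fracture_height = cfg$fracture_height,
                      band_halfwidth = cfg$band_halfwidth,
                      strategy = cfg$strategy,
                      perturbation = cfg$perturbation)
  q <- lapply(fb$fragments, mesh_face_quality)
  manifest <- list(
    n_fragments = fb$n_fragments,
    fragments = lapply(seq_along(fb$fragments), function(i) {
      qi <- q[[i]][is.finite(q[[i]])]
      list(file = sprintf("fragment_%02d.ply", i),
           n_faces = nrow(fb$fragments[[i]]$faces),
           volume_mm3 = fb$volumes[i],
           mean_q = mean(qi), max_q = max(qi),
           watertight = validate_mesh(fb$fragments[[i]])$watertight)
    }),
    intact_volume_mm3 = mesh_volume(fb$cut_model$mesh),
    strategy = unclass(cfg$strategy),
    perturbation = unclass(cfg$perturbation),
    seed = cfg$seed,
    fracture_height = fb$fracture_height)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(fb$fragments))
      write_mesh(fb$fragments[[i]],
                 file.path(cfg$out_dir, sprintf("fragment_%02d.ply", i)))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fb$manifest <- manifest
  invisible(fb)
}

#' Validate a simulated fracture against a reference fragment
#'
#' The height-map validation pipeline: detect the fracture zone on the
#' reference fragment, extract its 2D pattern, project the pattern onto the
#' intact bone and fracture it, detect the fracture zone of the simulated
#' fragment the same way, build height maps of both zones (equal margins),
#' and compare their mean values with the thickness-ratio scaling
#' (`t_original` = reference bone radius, `t_new` = target bone generalized
#' radius). A pattern that cannot be placed within the aspect limit (for
#' example a large-bone pattern on a much thinner bone) surfaces the
#' scale-infeasible error from [place_pattern()].
#'
#' @param real_fragment a [trimesh] (or mesh file path): the reference
#'   fractured fragment.
#' @param intact_model a [cortical_bone] (or mesh file path): the bone to
#'   fracture.
#' @param config a [run_config], named list, or YAML path (strategy,
#'   perturbation, margin, aspect limit).
#' @param fracture_height target height on the intact bone; defaults to
#'   mid-shaft.
#' @param aspect_limit maximum circumference ratio for placement.
#' @return A [comparison_report] with the simulation attached as
#'   `$simulation`.
#' @export
run_validation <- function(real_fragment, intact_model, config = list(),
                           fracture_height = NULL, aspect_limit = 2) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.character(real_fragment)) real_fragment <- read_mesh(real_fragment)
  if (is.character(intact_model))
    intact_model <- as_cortical_bone(read_mesh(intact_model))
  zone <- detect_fracture_zone(real_fragment)
  if (zone$empty) stop("no fracture zone found on the reference fragment")
  pattern <- extract_pattern(zone)
  fb <- fracture_bone(intact_model, pattern,
                      fracture_height = fracture_height,
                      strategy = cfg$strategy,
                      perturbation = cfg$perturbation,
                      aspect_limit = aspect_limit)
  sim_zone <- detect_fracture_zone(fb$fragments[[1]])
  if (sim_zone$empty)
    stop("no fracture zone found on the simulated fragment")
  real_map <- build_height_map(zone$points, zone$axis, cfg$margin)
  sim_map <- build_height_map(sim_zone$points, sim_zone$axis, cfg$margin)
  t_new <- generalized_radius(intact_model, fb$fracture_height)
  report <- compare_height_maps(real_map, sim_map,
                                t_original = zone$radius, t_new = t_new)
  report$simulation <- fb
  report
}
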