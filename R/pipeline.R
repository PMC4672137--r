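# End-to-end pipeline: ROI reduction -> enhancement -> per-slice ACO
# pheromone fields -> seeded likelihoods -> modulated graph-cut -> optional
# evaluation, with a single config object and reproducible seeding.

#' Pipeline configuration
#'
#' Houses every stage's parameters with the standard defaults
#' (`lambda = 0.15`, `mu1 = 12`, `mu2 = 8`, `sigma = 10`).
#'
#' @param seed run seed governing every stochastic stage (default 1).
#' @param bbox `NULL` (no crop), `"auto"` (tight seed box + margin) or a 3x2
#'   inclusive index range matrix.
#' @param margin_mm margin of the auto bounding box in mm (default 30).
#' @param quadrant `NULL` (no quadrant elimination), `"auto"` (detect the
#'   crossline) or a `c(row, col)` crossline centre.
#' @param quadrant_side which quadrant to exclude (default `"right-bottom"`).
#' @param bone_threshold HU threshold of the crossline detector.
#' @param aco_enabled run the swarm stage (`FALSE` gives the plain Gaussian
#'   boundary term, `B = 1`).
#' @param intensity_weight apply the HU-interval weight in the object
#'   expansion (`FALSE` gives the plain connectivity data term).
#' @param data data-term parameters: `mu1`, `mu2`, `q`, `theta`, `hu_low`,
#'   `hu_high` (NULL = estimate from seeds), `eps_floor`, `delta_dis`.
#' @param energy [energy_params] arguments: `lambda`, `sigma`.
#' @param enhance [enhance_params] list.
#' @param aco [aco_params] arguments (the run seed feeds the engine).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, bbox = NULL, margin_mm = 30,
                            quadrant = NULL,
                            quadrant_side = "right-bottom",
                            bone_threshold = 200,
                            aco_enabled = TRUE, intensity_weight = TRUE,
                            data = list(), energy = list(),
                            enhance = list(), aco = list()) {
  data <- utils::modifyList(
    list(mu1 = 12, mu2 = 8, q = -4, theta = 6 / 49, hu_low = NULL,
         hu_high = NULL, eps_floor = 1e-6, delta_dis = 1), data)
  energy <- utils::modifyList(list(lambda = 0.15, sigma = 10), energy)
  enhance <- utils::modifyList(enhance_params(), enhance)
  structure(list(seed = seed, bbox = bbox, margin_mm = margin_mm,
                 quadrant = quadrant, quadrant_side = quadrant_side,
                 bone_threshold = bone_threshold,
                 aco_enabled = aco_enabled,
                 intensity_weight = intensity_weight,
                 data = data, energy = energy, enhance = enhance,
                 aco = aco),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the [pipeline_config]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  spec <- yaml::read_yaml(path)
  do.call(pipeline_config, spec)
}

config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # order-sensitive 64-bit FNV-1a, hex encoded; stable across sessions
  h <- 0
  p <- 31
  m <- 2^48
  for (b in as.integer(raw)) h <- (h * p + b + 1) %% m
  sprintf("%012.0f", h)
}

#' Run the full segmentation pipeline
#'
#' Stages: optional bounding-box crop and crossline quadrant elimination
#' (seeds are never removed; that is an error), ROI-based enhancement,
#' per-slice variant-ACO pheromone fields, object/background likelihood
#' expansion, graph construction with swarm-modulated Gaussian n-links, and
#' the min-cut solve. Identical config and seed give an identical mask.
#'
#' @param volume a [ct_volume].
#' @param seeds a [seed_set] with both classes non-empty.
#' @param config a [pipeline_config].
#' @param reference optional reference mask; when given, a `score_report` is
#'   attached.
#' @return List with `mask` (full-grid [segmentation_mask]), `flow`,
#'   `energy`, `tau`, `enhanced`, `likelihoods`, `report` (or `NULL`) and
#'   `provenance` (config hash, seed, package version).
#' @export
segment_volume <- function(volume, seeds, config = pipeline_config(),
                           reference = NULL) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  check_seeds_usable(seeds)
  full_dim <- vol_dim(volume)

  # ROI: bounding box
  offset <- c(1L, 1L, 1L)
  bbox <- config$bbox
  if (identical(bbox, "auto"))
    bbox <- auto_bbox(seeds, volume, config$margin_mm)
  if (!is.null(bbox)) {
    check_roi_keeps_seeds(seeds, bbox = bbox)
    cropped <- crop_bbox(volume, bbox)
    offset <- attr(cropped, "offset")
    b <- bbox_matrix(bbox)
    seeds <- seed_set(
      seeds$object_mask[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2],
                        drop = FALSE],
      seeds$background_mask[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2],
                            b[3, 1]:b[3, 2], drop = FALSE])
    volume <- cropped
  }

  # ROI: quadrant elimination
  exclusion <- NULL
  if (!is.null(config$quadrant)) {
    cl <- if (identical(config$quadrant, "auto"))
      detect_crossline(volume, config$bone_threshold)
    else as.integer(config$quadrant)
    exclusion <- eliminate_quadrant(volume, cl, config$quadrant_side)
    check_roi_keeps_seeds(seeds, exclusion = exclusion)
    exclusion <- exclusion & !seeds$background_mask  # already hard background
  }

  dt <- config$data
  interval <- if (!is.null(dt$hu_low) && !is.null(dt$hu_high))
    intensity_interval(dt$hu_low, dt$hu_high, theta = dt$theta, q = dt$q)
  else {
    iv <- estimate_interval(volume, seeds, theta = dt$theta, q = dt$q)
    iv
  }

  # swarm stage
  tau <- NULL; enhanced <- NULL
  if (isTRUE(config$aco_enabled)) {
    enh <- enhanced_image(volume, seeds, params = config$enhance,
                          interval = interval)
    enhanced <- enh$enhanced
    aco_args <- utils::modifyList(config$aco, list(seed = config$seed))
    tau <- aco_stack(enhanced, do.call(aco_params, aco_args))
  }

  lik <- likelihood_field(volume, seeds, mu1 = dt$mu1, mu2 = dt$mu2,
                          interval = interval,
                          use_intensity_weight =
                            isTRUE(config$intensity_weight),
                          delta_dis = dt$delta_dis,
                          eps_floor = dt$eps_floor)

  ep <- energy_params(lambda = config$energy$lambda,
                      sigma = config$energy$sigma)
  graph <- build_graph(volume, lik, tau = tau, seeds = seeds,
                       exclusion = exclusion, params = ep,
                       eps_floor = dt$eps_floor)
  sol <- solve_min_cut(graph)
  energy <- cut_energy(sol$mask, graph)

  mask <- embed_mask(sol$mask, offset, full_dim)
  report <- if (!is.null(reference))
    evaluate_segmentation(mask, reference, spacing = mask$spacing) else NULL

  list(mask = mask, flow = sol$flow, energy = energy, tau = tau,
       enhanced = enhanced, likelihoods = lik, report = report,
       provenance = list(config_hash = config_hash(config),
                         seed = config$seed,
                         package_version =
                           as.character(utils::packageVersion("swarmcut"))))
}
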