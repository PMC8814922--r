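# Umbrella pipelines tying the stages together: connectivity-guided
# (cgiTBS) and standard (rTMS) target planning, coil-pose planning on a
# head mesh, and versioned JSON plan export with provenance.

#' Pipeline configuration
#'
#' Central bundle of the planning thresholds and constants. Defaults: ICA /
#' cluster z threshold 1.96; high-pass cutoff 0.01 Hz; nuisance-mask
#' probability threshold 0.98 with 2-voxel spherical erosion; FD limits
#' 3 mm (single frame) and 1 mm (mean); rAI seed sphere radius 6 mm; F3
#' scalp coordinate (-49, 51, 40) mm; coil angle 45 degrees; rotation-to-mm
#' head radius 50 mm.
#'
#' @param z_threshold z threshold for component filtering and clustering.
#' @param highpass_hz high-pass cutoff in Hz.
#' @param mask_prob_threshold nuisance tissue-probability threshold.
#' @param erosion_radius nuisance-mask erosion radius in voxels.
#' @param max_fd,max_mean_fd motion QC limits in mm.
#' @param rai_radius_mm seed sphere radius in mm.
#' @param f3_mm F3 scalp coordinate in mm.
#' @param coil_angle_deg coil angulation rule in degrees.
#' @param head_radius_mm rotation-to-displacement conversion radius.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(z_threshold = 1.96, highpass_hz = 0.01,
                            mask_prob_threshold = 0.98, erosion_radius = 2,
                            max_fd = 3, max_mean_fd = 1, rai_radius_mm = 6,
                            f3_mm = c(-49, 51, 40), coil_angle_deg = 45,
                            head_radius_mm = 50) {
  stopifnot(z_threshold > 0, highpass_hz > 0,
            mask_prob_threshold > 0, mask_prob_threshold <= 1,
            erosion_radius >= 0, max_fd > 0, max_mean_fd > 0,
            rai_radius_mm > 0, length(f3_mm) == 3L)
  structure(list(z_threshold = z_threshold, highpass_hz = highpass_hz,
                 mask_prob_threshold = mask_prob_threshold,
                 erosion_radius = erosion_radius, max_fd = max_fd,
                 max_mean_fd = max_mean_fd, rai_radius_mm = rai_radius_mm,
                 f3_mm = as.numeric(f3_mm),
                 coil_angle_deg = coil_angle_deg,
                 head_radius_mm = head_radius_mm),
            class = "pipeline_config")
}

.stage_error <- function(stage, msg) {
  stop(sprintf("[stage: %s] %s", stage, msg), call. = FALSE)
}

#' Hash a pipeline configuration
#'
#' 32-bit polynomial hash (base 131, modulus 2^31 - 1) of the canonical
#' JSON serialization of the config, returned as an 8-character hex string.
#' Embedded in exported plans so a plan records exactly which thresholds
#' produced it.
#'
#' @param config a `pipeline_config`.
#' @return Character scalar, e.g. `"5b0c2f91"`.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(txt)))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Plan a coil pose for a brain target on a head mesh
#'
#' Builds the NLR frame from the mesh fiducials via the least-squares rigid
#' fit of the four landmark correspondences, transforms the mesh and the
#' brain target into NLR space, picks the nearest scalp vertex, computes
#' its outward normal, and applies the coil angulation rule.
#'
#' @param head a `head_model` carrying a `landmark_set`.
#' @param target_mm brain target in head (T1/anatomical) space, mm.
#' @param angle_deg coil angulation (default 45).
#' @return List: `pose` (`coil_pose`, NLR space), `scalp_vertex_index`,
#'   `nlr_transform` (`rigid_transform`), `target_nlr`, and
#'   `nlr_landmarks` (4 x 3 matrix).
#' @export
plan_coil_pose <- function(head, target_mm, angle_deg = 45) {
  if (is.null(head$landmarks))
    .stage_error("geometry", "head mesh has no fiducial landmarks")
  lm <- head$landmarks
  O <- nlr_origin(lm)
  src <- rbind(O, lm$nasion, lm$left_preauricular, lm$right_preauricular)
  dst <- landmarks_in_nlr(lm)
  xf <- fit_rigid(src, dst)
  mesh_nlr <- head_model(apply_rigid(xf, head$vertices), head$faces)
  target_nlr <- apply_rigid(xf, as.numeric(target_mm))
  vi <- nearest_vertex(mesh_nlr, target_nlr)
  nrm <- vertex_normal(mesh_nlr, vi)
  pose <- coil_pose(nrm, mesh_nlr$vertices[vi, ], angle_deg = angle_deg)
  list(pose = pose, scalp_vertex_index = vi, nlr_transform = xf,
       target_nlr = target_nlr, nlr_landmarks = dst)
}

#' Run the connectivity-guided (cgiTBS) target pipeline
#'
#' Stage order: optional motion QC gate; optional WM/CSF nuisance
#' regression; high-pass filtering; component selection against the network
#' template; restriction of the search region to the suprathreshold part of
#' the winning component inside the lMFG mask; seed-series extraction from
#' the rAI sphere; voxelwise first-order Granger z-map; peak-cluster target
#' extraction; and, when a head mesh with fiducials is supplied, coil-pose
#' geometry.
#'
#' @param bold a `bold_series`.
#' @param components list of z-scored `spatial_map` components.
#' @param template network-template `spatial_map` (e.g. lCEN).
#' @param lmfg_mask search-region `voxel_mask`.
#' @param rai_mask seed-region `voxel_mask`.
#' @param wm_mask,csf_mask optional nuisance `voxel_mask`s.
#' @param motion optional n x 6 motion trace; QC failure aborts.
#' @param head optional `head_model` with landmarks for coil-pose planning.
#' @param config a `pipeline_config`.
#' @return A `target_plan` list: `brain_target`, `kind`, `config`, `log`,
#'   and (with a mesh) `geometry`.
#' @export
run_cgitbs_pipeline <- function(bold = NULL, components = NULL,
                                template = NULL, lmfg_mask = NULL,
                                rai_mask = NULL, wm_mask = NULL,
                                csf_mask = NULL, motion = NULL, head = NULL,
                                config = pipeline_config()) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- list(stage = stage, detail = sprintf(...))
  }
  if (is.null(bold)) .stage_error("inputs", "BOLD series is missing")
  for (nm in c("components", "template", "lmfg_mask", "rai_mask")) {
    if (is.null(get(nm)))
      .stage_error("inputs", paste(nm, "is missing"))
  }
  if (!is.null(motion)) {
    fd <- framewise_displacement(motion, config$head_radius_mm)
    qc <- qc_bold(fd, config$max_fd, config$max_mean_fd)
    if (!qc$pass)
      .stage_error("qc", paste("motion QC failed:",
                               paste(qc$reasons, collapse = "; ")))
    note("qc", "motion QC passed (max FD %.3g mm, mean %.3g mm)",
         qc$fd_max, qc$fd_mean)
  }
  if (!is.null(wm_mask) && !is.null(csf_mask)) {
    bold <- regress_nuisance(bold, wm_mask, csf_mask)
    note("nuisance", "regressed WM/CSF mean series")
  }
  bold <- highpass(bold, config$highpass_hz)
  note("highpass", "high-pass filtered at %.3g Hz", config$highpass_hz)
  sel <- select_component(components, template, config$z_threshold)
  note("component", "selected component %d (r = %.3f)", sel$index,
       sel$correlations[sel$index])
  search <- .mask_values(lmfg_mask) & (sel$map$values > 0)
  if (!any(search))
    .stage_error("mask", "empty search region: component does not overlap the lMFG mask")
  search_mask <- voxel_mask(search, label = "lMFG",
                            voxel_size = bold$voxel_size)
  seed <- seed_series(bold, rai_mask)
  zmap <- gca_zmap(bold, seed, search_mask)
  target <- peak_cluster_target(zmap, search_mask, config$z_threshold)
  note("target", "peak z %.3f at voxel (%s)", target$peak_z,
       paste(target$voxel_index, collapse = ", "))
  plan <- list(brain_target = target, kind = "cgiTBS", config = config,
               component_index = sel$index, log = log)
  if (!is.null(head)) {
    plan$geometry <- plan_coil_pose(head, target$world_mm,
                                    config$coil_angle_deg)
  }
  class(plan) <- "target_plan"
  plan
}

#' Run the standard (rTMS) target pipeline
#'
#' Projects the F3 scalp coordinate onto the nearest brain-parenchyma
#' voxel, then (with a head mesh) plans the coil pose.
#'
#' @param brain_mask nonempty `voxel_mask` of the brain parenchyma.
#' @param f3_mm F3 coordinate in mm (default from `config`).
#' @param head optional `head_model` with landmarks.
#' @param config a `pipeline_config`.
#' @return A `target_plan`.
#' @export
run_rtms_pipeline <- function(brain_mask, f3_mm = NULL, head = NULL,
                              config = pipeline_config()) {
  if (is.null(brain_mask)) .stage_error("inputs", "brain mask is missing")
  if (is.null(f3_mm)) f3_mm <- config$f3_mm
  target <- project_point_to_mask(f3_mm, brain_mask)
  plan <- list(brain_target = target, kind = "rTMS", config = config,
               log = list(list(stage = "target",
                               detail = sprintf("F3 projected %.2f mm",
                                                target$distance_mm))))
  if (!is.null(head)) {
    plan$geometry <- plan_coil_pose(head, target$world_mm,
                                    config$coil_angle_deg)
  }
  class(plan) <- "target_plan"
  plan
}

#' @export
print.target_plan <- function(x, ...) {
  cat(sprintf("<target_plan %s>\n", x$kind))
  print(x$brain_target)
  if (!is.null(x$geometry)) print(x$geometry$pose)
  invisible(x)
}

#' Export a target plan as versioned JSON
#'
#' Schema `brightpath-plan/1`: brain target (voxel index and mm), scalp
#' vertex, rotation matrix, quaternion (w, x, y, z), NLR landmark
#' coordinates, and parameter provenance. Requires a complete plan
#' (geometry included). Reloading with [import_plan()] round-trips the
#' numeric content exactly.
#'
#' @param plan a `target_plan` with geometry.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
export_plan <- function(plan, path) {
  if (!inherits(plan, "target_plan")) stop("not a target_plan")
  if (is.null(plan$geometry))
    stop("incomplete plan: coil-pose geometry is missing")
  g <- plan$geometry
  obj <- list(
    schema = "brightpath-plan/1",
    kind = plan$kind,
    brain_target = list(voxel_index = plan$brain_target$voxel_index,
                        world_mm = plan$brain_target$world_mm,
                        peak_z = plan$brain_target$peak_z),
    scalp_vertex_mm = g$pose$scalp_vertex,
    scalp_vertex_index = g$scalp_vertex_index,
    rotation = lapply(seq_len(nrow(g$pose$rotation)),
                      function(i) unname(g$pose$rotation[i, ])),
    quaternion = g$pose$quaternion,
    nlr_landmarks = lapply(seq_len(nrow(g$nlr_landmarks)),
                           function(i) unname(g$nlr_landmarks[i, ])),
    provenance = list(package_version = as.character(utils::packageVersion("brightpath")),
                      config_hash = config_hash(plan$config),
                      config = unclass(plan$config)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import a target plan written by [export_plan()]
#'
#' Validates the schema tag and required fields.
#'
#' @param path JSON path.
#' @return The parsed plan list.
#' @export
import_plan <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "brightpath-plan/1"))
    stop("unrecognized plan schema: ", obj$schema)
  need <- c("kind", "brain_target", "scalp_vertex_mm", "rotation", "quaternion",
            "nlr_landmarks")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("invalid plan: missing field(s) ", paste(miss, collapse = ", "))
  as_row_matrix <- function(x) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = 3, byrow = TRUE)
  }
  obj$rotation <- as_row_matrix(obj$rotation)
  obj$nlr_landmarks <- as_row_matrix(obj$nlr_landmarks)
  obj
}
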