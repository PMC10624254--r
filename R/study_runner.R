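# Orchestration of the full exposure experiment on synthetic phantoms:
# phantom -> age-scaled properties -> FDTD solve -> B1+ normalization ->
# SAR maps -> 10 g averaging -> room-equilibrium steady state -> transient
# exposure -> report, plus the comparison arithmetic between phantoms.

#' Default study configuration
#'
#' All physical defaults live here, never hard-coded in the pipeline:
#' 297.2 MHz drive, 2 uT B1+ target at the coil center, 23 degC room,
#' 6 / 10 W m^-2 degC^-1 external / internal heat transfer, 900 s scan,
#' 4 mm isotropic desk-scale grid.
#'
#' @param phantoms named list of phantom specs; each is a list with
#'   `layer_radii`, `layer_tissues` and optional `air_cavity` (see
#'   [make_layered_head])
#' @param grid_mm isotropic voxel spacing of the EM/thermal grid
#' @param freq_hz drive frequency
#' @param target_b1_t normalization target (T)
#' @param duration_s transient exposure duration
#' @param dt_s thermal time step
#' @param ambient_c,h_ext,h_int thermal boundary parameters
#' @param coil a [birdcage_coil]
#' @param max_periods FDTD period budget
#' @param seed integer seed echoed into the report (the pipeline is
#'   deterministic; the seed matters when phantom specs use perturbation)
#' @return list of class `study_config`
#' @export
study_config <- function(phantoms = list(
                           head_a = list(layer_radii = c(80, 79, 75, 71, 67)),
                           head_b = list(layer_radii = c(86, 85, 80, 76, 71))
                         ),
                         grid_mm = 4, freq_hz = 297.2e6, target_b1_t = 2e-6,
                         duration_s = 900, dt_s = 5, ambient_c = 23,
                         h_ext = 6, h_int = 10,
                         coil = birdcage_coil(freq_hz = freq_hz),
                         max_periods = 30, seed = 1) {
  structure(list(phantoms = phantoms, grid_mm = grid_mm, freq_hz = freq_hz,
                 target_b1_t = target_b1_t, duration_s = duration_s,
                 dt_s = dt_s, ambient_c = ambient_c, h_ext = h_ext,
                 h_int = h_int, coil = coil, max_periods = max_periods,
                 seed = as.integer(seed), schema = "voxdosim-study/1"),
            class = "study_config")
}

#' Signed percent difference relative to a reference
#'
#' `100 * (other - reference) / reference`. Dosimetry comparisons between
#' two phantoms are conventionally rounded to the nearest integer percent.
#'
#' @param reference nonzero reference value
#' @param other comparison value
#' @param round_to decimal places for the rounded form (0 = integer)
#' @return list with `pct` (exact) and `pct_rounded`
#' @export
percent_difference <- function(reference, other, round_to = 0) {
  if (reference == 0) stop("reference value must be nonzero")
  pct <- 100 * (other - reference) / reference
  list(pct = pct, pct_rounded = round(pct, round_to))
}

#' Sample a map along a grid line through a point
#'
#' Values along the grid line parallel to `axis` passing through the voxel
#' nearest to `through` (world mm). The profile's center value equals the
#' map value at that voxel.
#'
#' @param map 3-D numeric array
#' @param axis 1, 2 or 3
#' @param through world point (mm), length 3
#' @param spacing,origin grid geometry (mm)
#' @return data.frame with `coord_mm` and `value`
#' @export
line_profile <- function(map, axis, through, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(map)
  vox <- round((through - origin) / spacing) + 1
  if (any(vox < 1 | vox > d))
    stop("point lies outside the grid")
  idx <- as.list(vox)
  idx[[axis]] <- seq_len(d[axis])
  vals <- do.call(`[`, c(list(map), idx))
  data.frame(coord_mm = origin[axis] + (seq_len(d[axis]) - 1) * spacing[axis],
             value = as.numeric(vals))
}

#' Run the full exposure study
#'
#' For each configured phantom: build the layered head at the study grid,
#' center it in the birdcage coil domain, solve the EM problem, normalize
#' |B1+| to the target at the coil center, compute pointwise / head-average /
#' maximum 10 g SAR, find the room equilibrium, run the transient exposure,
#' and record the maximum temperature. Cross-phantom percent differences
#' use the first phantom as reference. Deterministic given the config.
#'
#' @param config a [study_config]
#' @return object of class `exposure_study`
#' @export
run_exposure_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  tissues <- load_tissue_table()
  coil <- config$coil
  sp <- config$grid_mm

  # EM domain: shield + margin transverse, shield length + margin axially
  margin <- 6L
  nxy <- 2L * (ceiling(coil$shield_diameter_mm / 2 / sp) + margin) + 1L
  nzz <- 2L * (ceiling(coil$shield_length_mm / 2 / sp) + margin) + 1L

  per_phantom <- list()
  for (nm in names(config$phantoms)) {
    spec <- config$phantoms[[nm]]
    head <- do.call(make_layered_head, c(
      spec[intersect(names(spec), c("layer_radii", "layer_tissues",
                                    "air_cavity"))],
      list(spacing = sp)))
    dom_dim <- pmax(c(nxy, nxy, nzz), dim(head$data))
    phantom <- embed_volume(head, dom_dim)
    bc <- build_birdcage_sources(coil, dim(phantom$data), sp)
    fields <- fdtd_solve(phantom, tissues, bc$sources,
                         freq_hz = config$freq_hz, pec = bc$pec,
                         max_periods = config$max_periods)
    fields <- normalize_fields(fields, target_b1_t = config$target_b1_t,
                               reference_voxel = round(bc$center_voxel))

    air_lab <- internal_air_labels(phantom)
    tissue_mask <- phantom$data > 0L & !(phantom$data %in% air_lab)
    maps <- property_maps(phantom, tissues, c("conductivity", "density"),
                          outside = 0)
    sar <- pointwise_sar(fields, maps$conductivity, maps$density, tissue_mask)
    sar10 <- mass_averaged_sar(sar, maps$density, sp, tissue_mask)
    head_avg <- region_average_sar(sar, maps$density, tissue_mask,
                                   tissue_mask)

    boundary <- boundary_spec(config$h_ext, config$h_int, config$ambient_c)
    blood <- blood_constants()
    equil <- steady_state(phantom, tissues, boundary, blood)
    heated <- transient(equil, phantom, tissues, sar = sar,
                        boundary = boundary, blood = blood,
                        duration = config$duration_s, dt = config$dt_s)
    mt <- max_temperature(heated)

    b1map <- abs(b1_plus(fields)) * 1e6   # uT
    ctr <- round(bc$center_voxel)
    prof <- line_profile(b1map, 1,
                         phantom$origin + (ctr - 1) * phantom$spacing,
                         spacing = phantom$spacing, origin = phantom$origin)
    per_phantom[[nm]] <- list(
      phantom_dim = dim(phantom$data),
      skin_thickness_mm = attr(head, "skin_thickness_achieved"),
      normalization_scale = fields$scale,
      em_periods = fields$periods_run,
      b1_center_uT = b1map[ctr[1], ctr[2], ctr[3]],
      b1_profile = prof,
      head_avg_sar_w_kg = head_avg,
      max_sar10g_w_kg = sar10$max,
      sar10g_inherited_voxels = sar10$n_inherited,
      max_pointwise_sar_w_kg = max(sar[tissue_mask]),
      equilibrium_max_c = max(equil$T, na.rm = TRUE),
      max_temperature_c = mt$value,
      max_temperature_location_mm = mt$location_mm,
      max_temperature_trace = heated$trace
    )
  }

  comparisons <- NULL
  if (length(per_phantom) >= 2) {
    ref <- per_phantom[[1]]
    comparisons <- lapply(per_phantom[-1], function(p) list(
      sar10g_pct = percent_difference(ref$max_sar10g_w_kg,
                                      p$max_sar10g_w_kg)$pct_rounded,
      head_avg_sar_pct = percent_difference(ref$head_avg_sar_w_kg,
                                            p$head_avg_sar_w_kg)$pct_rounded,
      max_temp_pct = percent_difference(ref$max_temperature_c,
                                        p$max_temperature_c,
                                        round_to = 2)$pct_rounded
    ))
  }

  structure(list(per_phantom = per_phantom, comparisons = comparisons,
                 config = config),
            class = "exposure_study")
}

#' @export
print.exposure_study <- function(x, ...) {
  cat("<exposure_study> ", length(x$per_phantom), " phantom(s) @ ",
      x$config$grid_mm, " mm, f = ", x$config$freq_hz / 1e6, " MHz, |B1+| -> ",
      x$config$target_b1_t * 1e6, " uT\n", sep = "")
  for (nm in names(x$per_phantom)) {
    p <- x$per_phantom[[nm]]
    cat(sprintf(
      "  %-8s head SAR %.3f W/kg | max 10g SAR %.3f W/kg | max T %.2f degC | B1+(ctr) %.3f uT\n",
      nm, p$head_avg_sar_w_kg, p$max_sar10g_w_kg, p$max_temperature_c,
      p$b1_center_uT))
  }
  if (!is.null(x$comparisons)) {
    for (nm in names(x$comparisons)) {
      cmp <- x$comparisons[[nm]]
      cat(sprintf("  %s vs %s: max 10g SAR %+d%%, head SAR %+d%%, max T %+.2f%%\n",
                  nm, names(x$per_phantom)[1],
                  as.integer(cmp$sar10g_pct), as.integer(cmp$head_avg_sar_pct),
                  cmp$max_temp_pct))
    }
  }
  invisible(x)
}

#' Serialize a study report to JSON
#' @param study an `exposure_study`
#' @param path output file
#' @export
write_study_report <- function(study, path) {
  strip <- function(p) p[setdiff(names(p),
                                 c("b1_profile", "max_temperature_trace"))]
  out <- list(per_phantom = lapply(study$per_phantom, strip),
              comparisons = study$comparisons,
              config = list(grid_mm = study$config$grid_mm,
                            freq_hz = study$config$freq_hz,
                            target_b1_t = study$config$target_b1_t,
                            duration_s = study$config$duration_s,
                            seed = study$config$seed,
                            schema = study$config$schema))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
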