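#' Simulation parameters for a synthetic recruitment field
#'
#' Bundles everything needed to render one synthetic field of view: an
#' adherent cell with diffuse protein-of-interest (POI) fluorescence, a
#' micron-scale receptor cluster at the cell edge where the POI is enriched
#' by a known factor, optical blur, shot noise and camera read noise.
#' The enrichment factor `E` is the ground-truth analogue of the
#' recruitment ratio `R` that the analysis recovers.
#'
#' @param field_shape Integer vector `(rows, cols)` of the field in pixels.
#'   256 x 256 is the default working scale; 1024 x 1024 mirrors typical
#'   confocal acquisition.
#' @param cell_center Pixel coordinates `(row, col)`, 0-based, of the cell
#'   centre. `NULL` places the cell at the field centre.
#' @param cell_radius Cell radius in pixels.
#' @param baseline_intensity Mean POI intensity `c` (photons/pixel) inside
#'   the cell before noise.
#' @param enrichment_factor Ground-truth enrichment `E` (dimensionless):
#'   the POI intensity at the attachment site is `E * c` before blur and
#'   noise. Must be >= 0; values below 1 are rendered but invisible to the
#'   max-based statistic.
#' @param cluster_geometry `"microcolony"` (k diffraction-scale spots along
#'   the cell perimeter, emulating a bacterial microcolony) or `"bead"`
#'   (one disk, emulating an antibody-coated bead).
#' @param n_spots Number of spots in the microcolony geometry.
#' @param spot_radius Spot radius in pixels (microcolony geometry).
#' @param bead_radius Bead radius in pixels (bead geometry).
#' @param cluster_angle Attachment angle (radians) of the cluster on the
#'   cell perimeter, or `"random"` to draw it from the field seed.
#' @param cluster_offset Radial offset (pixels) of the attachment point
#'   from the cell perimeter; 0 centres the footprint on the perimeter.
#' @param receptor_gain Receptor-channel concentration at the cluster, as a
#'   multiple of `baseline_intensity`.
#' @param receptor_membrane_frac Fraction of the cluster receptor level
#'   rendered diffusely over the cell footprint (surface receptor pool).
#' @param bacteria_gain Bacteria-channel amplitude on the cluster
#'   footprint, as a multiple of `baseline_intensity`.
#' @param background_level Additive background `b` (photons/pixel) across
#'   the whole field. The analysis contract assumes `b = 0`; with `b > 0`
#'   the recoverable ratio is `(E*c + b) / (c + b)`, not `E`.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels
#'   (0 disables blur).
#' @param poisson Apply Poisson shot noise?
#' @param gaussian_read_sd Standard deviation of additive Gaussian read
#'   noise (0 disables).
#' @param bit_depth Bit depth used when `quantize = TRUE` (8 mirrors the
#'   acquisition setting the simulator emulates).
#' @param quantize Round intensities to `bit_depth` integer levels? Off by
#'   default so analytic test cases stay exact.
#' @param experiment_factor Multiplicative intensity factor used to emulate
#'   a per-experiment batch effect (1 = none).
#' @param seed Integer seed; identical parameters (including the seed)
#'   yield bit-identical fields.
#'
#' @return An object of class `optic_params`.
#' @seealso [simulate_field()], [simulate_cohort()]
#' @export
optic_params <- function(field_shape = c(256L, 256L),
                         cell_center = NULL,
                         cell_radius = 60,
                         baseline_intensity = 60,
                         enrichment_factor = 1,
                         cluster_geometry = c("microcolony", "bead"),
                         n_spots = 4,
                         spot_radius = 4,
                         bead_radius = 6,
                         cluster_angle = "random",
                         cluster_offset = 0,
                         receptor_gain = 6,
                         receptor_membrane_frac = 0.05,
                         bacteria_gain = 2.5,
                         background_level = 0,
                         psf_sigma = 2,
                         poisson = TRUE,
                         gaussian_read_sd = 2,
                         bit_depth = 8,
                         quantize = FALSE,
                         experiment_factor = 1,
                         seed = 1L) {
  cluster_geometry <- match.arg(cluster_geometry)
  if (is.null(cell_center)) {
    cell_center <- (field_shape - 1) / 2
  }
  p <- structure(list(
    field_shape = as.integer(field_shape),
    cell_center = as.numeric(cell_center),
    cell_radius = cell_radius,
    baseline_intensity = baseline_intensity,
    enrichment_factor = enrichment_factor,
    cluster_geometry = cluster_geometry,
    n_spots = as.integer(n_spots),
    spot_radius = spot_radius,
    bead_radius = bead_radius,
    cluster_angle = cluster_angle,
    cluster_offset = cluster_offset,
    receptor_gain = receptor_gain,
    receptor_membrane_frac = receptor_membrane_frac,
    bacteria_gain = bacteria_gain,
    background_level = background_level,
    psf_sigma = psf_sigma,
    poisson = isTRUE(poisson),
    gaussian_read_sd = gaussian_read_sd,
    bit_depth = as.integer(bit_depth),
    quantize = isTRUE(quantize),
    experiment_factor = experiment_factor,
    seed = as.integer(seed)
  ), class = "optic_params")
  validate_optic_params(p)
  p
}

validate_optic_params <- function(p) {
  stopifnot(inherits(p, "optic_params"))
  if (length(p$field_shape) != 2L || any(p$field_shape <= 0L)) {
    stop("`field_shape` must be two positive integers (rows, cols)", call. = FALSE)
  }
  if (p$enrichment_factor < 0) {
    stop("`enrichment_factor` must be >= 0", call. = FALSE)
  }
  if (p$baseline_intensity <= 0) {
    stop("`baseline_intensity` must be > 0", call. = FALSE)
  }
  if (p$cell_radius <= 0) {
    stop("`cell_radius` must be > 0", call. = FALSE)
  }
  if (p$background_level < 0) {
    stop("`background_level` must be >= 0", call. = FALSE)
  }
  if (!identical(p$cluster_angle, "random") && !is.numeric(p$cluster_angle)) {
    stop("`cluster_angle` must be numeric or \"random\"", call. = FALSE)
  }
  invisible(p)
}

#' Modify simulation parameters
#'
#' Returns a copy of `params` with the named fields replaced, re-running
#' validation. Convenient for deriving per-condition parameter sets.
#'
#' @param params An [optic_params()] object.
#' @param ... Named fields to replace.
#' @return A validated `optic_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "optic_params"))
  changes <- list(...)
  unknown <- setdiff(names(changes), names(params))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(changes)) params[[nm]] <- changes[[nm]]
  params$field_shape <- as.integer(params$field_shape)
  params$seed <- as.integer(params$seed)
  validate_optic_params(params)
  params
}
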