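# Parameter objects for the synthetic ENS scene generator.

#' Network specification for synthetic ENS scenes
#'
#' Describes a ganglion lattice connected by interganglionic fibre bundles,
#' the morphology the generator emulates: ganglia (soma clusters) on a
#' jittered grid, connectives between lattice neighbours, and secondary
#' fibres sprouting from connectives.
#'
#' @param grid_rows,grid_cols ganglion lattice dimensions (each >= 2).
#' @param ganglion_radius_px mean soma-cluster radius in pixels (> 0).
#' @param jitter_px positional jitter SD of ganglion centres, pixels.
#' @param connective_prob probability that each pair of lattice neighbours is
#'   connected by a fibre bundle, in `[0, 1]`.
#' @param extra_branch_rate expected number of secondary fibres sprouting per
#'   connective (>= 0); the knob that makes a network "more branched".
#' @param fibre_width_px mean fibre-bundle thickness in pixels (> 0).
#' @param anisotropy bias of connectives toward a preferred axis, 0 (none) to
#'   1 (connectives orthogonal to the axis are suppressed).
#' @param preferred_axis_deg preferred axis in degrees, -90..+90.
#' @return A `NetworkSpec` object.
#' @seealso [ens_control_spec()], [ens_ko_spec()] for calibrated presets.
#' @export
network_spec <- function(grid_rows = 7L, grid_cols = 7L,
                         ganglion_radius_px = 9, jitter_px = 3,
                         connective_prob = 0.9, extra_branch_rate = 1,
                         fibre_width_px = 10, anisotropy = 0,
                         preferred_axis_deg = 0) {
  if (grid_rows < 2L || grid_cols < 2L) stop("lattice must be at least 2x2")
  if (connective_prob < 0 || connective_prob > 1)
    stop("connective_prob must be in [0, 1]")
  if (anisotropy < 0 || anisotropy > 1) stop("anisotropy must be in [0, 1]")
  if (ganglion_radius_px <= 0 || fibre_width_px <= 0)
    stop("radii and widths must be > 0")
  if (extra_branch_rate < 0) stop("extra_branch_rate must be >= 0")
  if (jitter_px < 0) stop("jitter_px must be >= 0")
  if (preferred_axis_deg < -90 || preferred_axis_deg > 90)
    stop("preferred_axis_deg must be in [-90, 90]")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 ganglion_radius_px = ganglion_radius_px,
                 jitter_px = jitter_px, connective_prob = connective_prob,
                 extra_branch_rate = extra_branch_rate,
                 fibre_width_px = fibre_width_px, anisotropy = anisotropy,
                 preferred_axis_deg = preferred_axis_deg),
            class = "NetworkSpec")
}

#' Calibrated control-like network preset
#'
#' Defaults chosen once so that the true projected network density of a
#' default 512 x 512 render falls inside the 25-45 % range observed for
#' healthy distal-colon wholemounts.
#' @return A `NetworkSpec`.
#' @export
ens_control_spec <- function() {
  network_spec(grid_rows = 7L, grid_cols = 7L, ganglion_radius_px = 9,
               jitter_px = 3, connective_prob = 0.9, extra_branch_rate = 1,
               fibre_width_px = 10)
}

#' Knockout-like network preset (denser, more branched)
#'
#' A variant with complete lattice connectivity, doubled sprouting and
#' slightly thicker fibres, calibrated so the true-density contrast against
#' [ens_control_spec()] is approximately 39:29, the contrast reported between
#' Nos1-null and control colon.
#' @return A `NetworkSpec`.
#' @export
ens_ko_spec <- function() {
  network_spec(grid_rows = 8L, grid_cols = 8L, ganglion_radius_px = 9,
               jitter_px = 3, connective_prob = 1, extra_branch_rate = 1.2,
               fibre_width_px = 11)
}

#' Reduced-size power-study conditions
#'
#' The fixed conditions of the package's built-in detection-power
#' demonstration: a control/variant spec pair on a 5 x 5 lattice scaled to
#' 128 x 128 px fields (3 optical sections), with true-density contrast of
#' about 39:29 and a junction-count contrast of about 1.45 -- the direction
#' and rough magnitude of the reported knockout phenotype. Cohorts use 6
#' subjects x 5 fields per group; analysis uses a Gaussian pre-filter and
#' Otsu segmentation with orientation disabled (not a compared metric).
#'
#' @return List with `control`, `variant` ([network_spec()]s), `render`
#'   ([render_params()]), `options` ([analysis_options()]), and `metrics`
#'   (the compared columns).
#' @export
ens_power_specs <- function() {
  list(control = network_spec(5L, 5L, ganglion_radius_px = 5,
                              jitter_px = 1.5, connective_prob = 0.85,
                              extra_branch_rate = 0.7, fibre_width_px = 5.2),
       variant = network_spec(5L, 5L, ganglion_radius_px = 5.5,
                              jitter_px = 1.5, connective_prob = 1,
                              extra_branch_rate = 2, fibre_width_px = 6.3),
       render = render_params(shape = c(3L, 128L, 128L),
                              psf_sigma_px = c(1, 0.6)),
       options = analysis_options(prefilter_method = "gaussian",
                                  do_orientation = FALSE),
       metrics = c("density_percent", "n_junctions",
                   "total_branch_length_px"))
}

#' Ground-truth-recovery validation conditions
#'
#' Fixed conditions for the package's recovery benchmarks at 256 x 256 px
#' (9 optical sections): `recovery` is a 4 x 4 lattice at full fibre scale
#' used for noiseless-exactness, realistic-error and segmentation-quality
#' checks; `ablation` is a denser 6 x 6 lattice used for the graded-loss
#' series, dense enough that the intermediate (half-retained) scene keeps a
#' non-zero junction count and the three scenes order strictly.
#'
#' @return List with `recovery`, `ablation` ([network_spec()]s) and `shape`.
#' @export
ens_validation_specs <- function() {
  list(recovery = network_spec(4L, 4L, ganglion_radius_px = 9, jitter_px = 3,
                               connective_prob = 0.9, extra_branch_rate = 1,
                               fibre_width_px = 10),
       ablation = network_spec(6L, 6L, ganglion_radius_px = 7, jitter_px = 2,
                               connective_prob = 0.9, extra_branch_rate = 1,
                               fibre_width_px = 9),
       shape = c(9L, 256L, 256L))
}

#' Rendering parameters for synthetic stacks
#'
#' @param shape integer vector `(n_slices, height, width)`; default matches
#'   the acquisition protocol (21 slices of 512 x 512 px).
#' @param pixel_size_um lateral calibration (default 0.415 um/px, a 40x field
#'   of ~212 um across 512 px).
#' @param z_step_um axial step (default 1 um).
#' @param psf_sigma_px Gaussian PSF sigma, `c(lateral_px, axial_slices)`.
#' @param photon_scale mean photon count at peak signal (shot noise); `Inf`
#'   disables Poisson noise.
#' @param gauss_noise_sd additive read-noise SD (intensity units).
#' @param background_level constant background offset.
#' @return A `RenderParams` object.
#' @export
render_params <- function(shape = c(21L, 512L, 512L), pixel_size_um = 0.415,
                          z_step_um = 1, psf_sigma_px = c(1, 0.8),
                          photon_scale = 60, gauss_noise_sd = 0.02,
                          background_level = 0.08) {
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (pixel_size_um <= 0 || z_step_um <= 0) stop("calibrations must be > 0")
  if (any(psf_sigma_px < 0) || gauss_noise_sd < 0 || background_level < 0 ||
      photon_scale <= 0)
    stop("noise parameters must be >= 0 (photon_scale > 0)")
  structure(list(shape = as.integer(shape), pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 psf_sigma_px = rep_len(psf_sigma_px, 2L),
                 photon_scale = photon_scale, gauss_noise_sd = gauss_noise_sd,
                 background_level = background_level),
            class = "RenderParams")
}
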