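#' Simulation configuration for virtual TIRF movies
#'
#' Collects every parameter of the virtual microscope and of the molecules it
#' images. Defaults describe the assay geometry the analysis assumes: a
#' 512 x 512 px field at 100 nm/pixel, 100 ms per recorded frame with
#' alternating two-laser excitation (so each emission channel is sampled every
#' 0.2 s after deinterleaving), sparse immobilized multi-subunit "green" spots
#' that photobleach stepwise, and a red-labelled ligand that binds and unbinds
#' each subunit independently.
#'
#' @param field_size_px Integer pair, field dimensions in pixels.
#' @param pixel_nm Pixel size in nm (100 nm/pixel).
#' @param frame_interval_s Time per recorded camera frame in seconds (0.1 s).
#' @param n_frames Number of recorded frames per camera (~500).
#' @param psf_sigma_nm Gaussian PSF sigma in nm. Default `0.21 * 525 / 1.5`
#'   = 73.5 nm (Gaussian approximation at lambda = 525 nm, NA = 1.5).
#' @param n_spots Number of green spots in the field.
#' @param subunits Subunit count S per spot (1, 2, or 12/14 for holoenzymes).
#' @param cam_conc Labelled-ligand concentration in molar.
#' @param kon_per_M_s,koff_s Per-subunit association (M^-1 s^-1) and
#'   dissociation (s^-1) rates.
#' @param kpb_green_s,kpb_red_s Per-fluorophore photobleaching hazards (s^-1)
#'   under illumination.
#' @param dark_fraction Probability that a green fluorescent-protein tag is
#'   never fluorescent (0.20 estimated for GFP-family tags).
#' @param step_mean,step_sd Calibrated single-fluorophore intensity step in
#'   camera ADU (mean and SD).
#' @param noise_sd Per-frame additive trace noise SD in ADU, used by the
#'   staircase generator; matched to the calibration records.
#' @param leak_fraction Green-to-mixed-channel spectral bleed-through
#'   (default 0.10 of the Venus-channel intensity).
#' @param bg_amp1,bg_k1,bg_amp2,bg_k2,bg_offset Autofluorescence decay:
#'   mean per-pixel background `bg_amp1*exp(-bg_k1 t) + bg_amp2*exp(-bg_k2 t)
#'   + bg_offset` (ADU; decays under illumination).
#' @param illum_sigma_frac Width of the Gaussian illumination profile as a
#'   fraction of the field size (multiplicative, peak-normalized to 1).
#' @param emccd_gain EMCCD multiplication gain (ADU/photon scale of the gamma
#'   gain register model).
#' @param read_noise Gaussian read noise SD in ADU.
#' @param fret_per_bound Optional FRET intensity added to the mixed channel
#'   per bound ligand (0 disables FRET simulation).
#' @param min_separation_um Minimum spot center separation in micrometres.
#' @param seed Integer seed for all randomness in the simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(field_size_px = c(512L, 512L),
                       pixel_nm = 100,
                       frame_interval_s = 0.1,
                       n_frames = 500L,
                       psf_sigma_nm = 0.21 * 525 / 1.5,
                       n_spots = 100L,
                       subunits = 14L,
                       cam_conc = 30e-9,
                       kon_per_M_s = 2.3e5,
                       koff_s = 0.03,
                       kpb_green_s = 0.15,
                       kpb_red_s = 0.08,
                       dark_fraction = 0.2,
                       step_mean = 2000,
                       step_sd = 600,
                       noise_sd = 300,
                       leak_fraction = 0.10,
                       bg_amp1 = 40, bg_k1 = 0.08,
                       bg_amp2 = 15, bg_k2 = 0.01,
                       bg_offset = 20,
                       illum_sigma_frac = 1.5,
                       emccd_gain = 30,
                       read_noise = 10,
                       fret_per_bound = 0,
                       min_separation_um = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$field_size_px <- as.integer(rep_len(field_size_px, 2L))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c("kon_per_M_s", "koff_s", "kpb_green_s", "kpb_red_s", "cam_conc",
             "bg_k1", "bg_k2", "emccd_gain", "read_noise", "noise_sd",
             "fret_per_bound")
  for (nm in rates) check_number(cfg[[nm]], nm, min = 0)
  for (nm in c("pixel_nm", "frame_interval_s", "psf_sigma_nm", "step_mean"))
    check_number(cfg[[nm]], nm, min = 0, allow_zero = FALSE)
  if (cfg$leak_fraction < 0 || cfg$leak_fraction >= 1)
    abort("`leak_fraction` must be in [0, 1).")
  if (cfg$dark_fraction < 0 || cfg$dark_fraction >= 1)
    abort("`dark_fraction` must be in [0, 1).")
  if (cfg$subunits < 1L) abort("`subunits` must be >= 1.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %dx%d px, %d frames @ %.3g s, %d spots, S = %d, [CAM] = %.3g M\n",
    x$field_size_px[1], x$field_size_px[2], x$n_frames, x$frame_interval_s,
    x$n_spots, x$subunits, x$cam_conc))
  invisible(x)
}
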