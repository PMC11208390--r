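#' Radionuclide decay parameters
#'
#' @param half_life_h physical half-life in hours (default: Y-90, 64.2 h).
#' @return a `decay_params` object with the half-life and the decay
#'   constant lambda = ln(2) / t_half in 1/s.
#' @export
decay_params <- function(half_life_h = 64.2) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L || half_life_h <= 0)
    stop("`half_life_h` must be a single positive number")
  structure(list(half_life_h = half_life_h,
                 lambda_per_s = decay_constant(half_life_h)),
            class = "decay_params")
}

#' Decay constant from a half-life
#' @param half_life_h half-life in hours (> 0).
#' @return lambda in 1/s.
#' @export
decay_constant <- function(half_life_h) {
  if (any(half_life_h <= 0)) stop("half-life must be positive")
  log(2) / (half_life_h * 3600)
}

#' Self-calibrate a counts image to activity
#'
#' Converts a quantitative SPECT counts map to Becquerel with a single
#' patient-specific calibration factor: the administered activity, decay
#' corrected to the acquisition start time, divided by the total counts in
#' the image. The total calibrated activity therefore equals the
#' decay-corrected administered activity exactly.
#'
#' @param counts `voxel_grid` of counts (role `"counts"` or `"other"`).
#' @param administered_bq administered activity in Bq (> 0).
#' @param interval_h time from administration to acquisition start, hours.
#' @param decay a [decay_params()].
#' @return `voxel_grid` with role `"activity"` (Bq).
#' @export
self_calibrate <- function(counts, administered_bq, interval_h,
                           decay = decay_params()) {
  if (!is_voxel_grid(counts)) stop("`counts` must be a voxel_grid")
  if (administered_bq <= 0) stop("administered activity must be > 0")
  if (interval_h < 0) stop("interval must be >= 0")
  total <- sum(counts$values)
  if (total <= 0) stop("all-zero counts grid cannot be calibrated")
  cf <- administered_bq * exp(-decay$lambda_per_s * interval_h * 3600) / total
  grid_like(counts, counts$values * cf, role = "activity")
}

#' Time-integrated activity map
#'
#' For a permanently trapped source (pure physical decay, no biological
#' clearance) the number of decays in a voxel over all time is
#' `TIA = integral of A(t) dt = A(0) / lambda = A(T) exp(lambda T) / lambda`,
#' where `A(T)` is the measured voxel activity at the acquisition time `T`
#' after administration.
#'
#' @param activity `voxel_grid` of voxel activities at time `T` (Bq).
#' @param interval_h `T` in hours (>= 0).
#' @param decay a [decay_params()].
#' @return `voxel_grid` with role `"tia"` (decays).
#' @export
tia_map <- function(activity, interval_h, decay = decay_params()) {
  if (!is_voxel_grid(activity)) stop("`activity` must be a voxel_grid")
  if (any(activity$values < 0)) stop("activity must be non-negative")
  if (interval_h < 0) stop("interval must be >= 0")
  lam <- decay$lambda_per_s
  vals <- activity$values * exp(lam * interval_h * 3600) / lam
  grid_like(activity, vals, role = "tia")
}
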