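# MR signal model: compartmental R1 under the fast exchange limit (FXL) and
# the spoiled gradient echo (SPGR) steady-state equation, with nearest-sample
# extraction at scan temporal resolutions.

#' Scan parameters for the SPGR signal model
#'
#' Defaults follow a typical 7 T preclinical protocol: TR = 5 ms, flip angle
#' 25 degrees, relaxivity 4.7 /mM/s, and 0.5 /s baseline relaxation rates in
#' all three compartments.
#'
#' @param TR repetition time [s]
#' @param flip_deg flip angle [degrees]
#' @param S0 baseline signal scale (arbitrary units)
#' @param r1 contrast-agent relaxivity [1/mM/s]
#' @param R10_elm baseline R1 of the EES elements [1/s]
#' @param R10_blood baseline R1 of blood [1/s]
#' @param R1_eis (constant) R1 of the intracellular space [1/s]
#' @return a `scan_parameters` list
#' @export
scan_parameters <- function(TR = 0.005, flip_deg = 25, S0 = 1, r1 = 4.7,
                            R10_elm = 0.5, R10_blood = 0.5, R1_eis = 0.5) {
  stopifnot(TR > 0, flip_deg > 0, flip_deg < 90, r1 >= 0)
  structure(list(TR = TR, flip_deg = flip_deg, S0 = S0, r1 = r1,
                 R10_elm = R10_elm, R10_blood = R10_blood, R1_eis = R1_eis),
            class = "scan_parameters")
}

#' Area-weighted elemental relaxation rate
#'
#' Converts an element's EES concentration to its contribution to the voxel
#' R1: `(R10_elm + r1*C) * A_elm / voxel_area`.
#'
#' @param C_elm element concentration [mM]
#' @param A_elm element area [mm^2]
#' @param voxel_area voxel area [mm^2]
#' @param scan a `scan_parameters`
#' @return weighted rate contribution [1/s]
#' @export
elemental_r1 <- function(C_elm, A_elm, voxel_area, scan = scan_parameters()) {
  stopifnot(all(A_elm >= 0), voxel_area > 0)
  (scan$R10_elm + scan$r1 * C_elm) * (A_elm / voxel_area)
}

#' Blood relaxation rate
#'
#' `R10_blood + r1 * Cp`; unweighted — the vp area weighting is applied in
#' [composite_r1()].
#' @param Cp_t plasma concentration [mM]
#' @param scan a `scan_parameters`
#' @return blood R1 [1/s]
#' @export
blood_r1 <- function(Cp_t, scan = scan_parameters()) {
  stopifnot(all(Cp_t >= 0))
  scan$R10_blood + scan$r1 * Cp_t
}

#' Composite voxel relaxation rate under the fast exchange limit
#'
#' Weighted sum of the three compartments: the (already area-weighted)
#' elemental EES rates, the blood rate weighted by `vp`, and the constant
#' intracellular rate weighted by `veis`.
#'
#' @param elemental_rates vector of weighted elemental rates from
#'   [elemental_r1()]; their weights must total `ve`
#' @param vp vascular fraction
#' @param blood_rate blood R1 [1/s]
#' @param veis intracellular fraction
#' @param scan a `scan_parameters`
#' @param ve EES fraction, used to check the partition of unity
#' @return voxel R1 [1/s]
#' @export
composite_r1 <- function(elemental_rates, vp, blood_rate, veis,
                         scan = scan_parameters(), ve = NULL) {
  if (!is.null(ve) && abs(ve + vp + veis - 1) > 1e-6)
    stop("volume fractions do not sum to 1")
  sum(elemental_rates) + vp * blood_rate + veis * scan$R1_eis
}

#' SPGR steady-state signal
#'
#' `S0 * sin(a) * (1 - E) / (1 - cos(a) * E)` with `E = exp(-TR*R1)`; assumes
#' the echo time is much shorter than T2*.
#' @param R1 longitudinal relaxation rate(s) [1/s]
#' @param scan a `scan_parameters`
#' @return signal intensity (same units as `S0`)
#' @export
spgr_signal <- function(R1, scan = scan_parameters()) {
  a <- scan$flip_deg * pi / 180
  E <- exp(-scan$TR * R1)
  scan$S0 * sin(a) * (1 - E) / (1 - cos(a) * E)
}

#' Invert the SPGR signal equation for R1
#' @param SI signal intensity
#' @param scan a `scan_parameters`
#' @return R1 [1/s]
#' @export
invert_spgr <- function(SI, scan = scan_parameters()) {
  a <- scan$flip_deg * pi / 180
  sa <- scan$S0 * sin(a)
  if (any(SI >= sa)) stop("signal at or above the saturation level; cannot invert")
  if (any(SI < 0)) stop("negative signal cannot be inverted")
  E <- (sa - SI) / (sa - SI * cos(a))
  -log(E) / scan$TR
}

#' Voxel R1 time course from a simulation
#'
#' Applies the FXL composite rule at every solver step using the central
#' voxel's area-weighted EES mean (the elemental rates are linear in
#' concentration, so their area-weighted sum reduces to the voxel-mean form).
#' The elemental weights are normalized to total exactly `ve`, so the
#' baseline composite rate is exactly the common `R10` of the compartments.
#'
#' @param tc a `conc_time_course` from [run_simulation()]
#' @param aif the `aif_model` used in the simulation
#' @param scan a `scan_parameters`
#' @return list with `time` [s] and `R1` [1/s]
#' @export
voxel_r1_trajectory <- function(tc, aif, scan = scan_parameters()) {
  fr <- tc$domain_fractions
  Cp <- evaluate_aif(aif, tc$time)
  R1 <- fr["ve"] * (scan$R10_elm + scan$r1 * tc$voxel_mean) +
    fr["vp"] * blood_r1(Cp, scan) +
    fr["veis"] * scan$R1_eis
  list(time = tc$time, R1 = unname(R1))
}

#' Sample a dynamic signal at a scan temporal resolution
#'
#' Evaluates the SPGR signal on the stored R1 trajectory and extracts the
#' nearest stored sample at `t = 0, delta, 2*delta, ...` (point sampling, no
#' interval averaging).
#'
#' @param r1_traj list with `time` and `R1` (from [voxel_r1_trajectory()]),
#'   or a `conc_time_course` plus `aif`
#' @param temporal_resolution sampling interval delta [s]
#' @param scan a `scan_parameters`
#' @param duration total sampled duration [s]; defaults to the trajectory end
#' @return a `signal_time_course` with `time`, `SI`, `temporal_resolution`
#'   and the scan parameters used
#' @export
sample_time_course <- function(r1_traj, temporal_resolution,
                               scan = scan_parameters(), duration = NULL) {
  tt <- r1_traj$time
  if (is.null(duration)) duration <- tt[length(tt)]
  step <- if (length(tt) > 1) tt[2] - tt[1] else Inf
  if (temporal_resolution < step - 1e-12)
    stop("temporal resolution finer than the stored trajectory")
  ts <- seq(0, duration + 1e-9, by = temporal_resolution)
  ts <- ts[ts <= duration + 1e-9]
  idx <- pmin(pmax(round(ts / step) + 1, 1), length(tt))
  structure(list(time = ts, SI = spgr_signal(r1_traj$R1[idx], scan),
                 temporal_resolution = temporal_resolution, scan = scan),
            class = "signal_time_course")
}

#' @export
print.signal_time_course <- function(x, ...) {
  cat(sprintf("<signal_time_course> %d samples at %.3g s resolution\n",
              length(x$time), x$temporal_resolution))
  invisible(x)
}

#' Write a signal time course to CSV
#' @param stc a `signal_time_course`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_signal_csv <- function(stc, path) {
  write.csv(data.frame(t_s = stc$time, SI = stc$SI), path, row.names = FALSE)
  invisible(path)
}
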