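# Experiment orchestration: domains x Ktrans x D x temporal resolution,
# emitting one fit row per grid cell.

#' Experiment configuration
#'
#' The full study grid uses `Ktrans` in \{0.1, 0.4, 0.7\} /min, `ve` in
#' \{0.25, 0.39, 0.55\}, `vp` in \{0.01, 0.03, 0.06\}, `D` log-spaced over
#' `[3e-5, 3e-3]` mm^2/s and temporal resolutions
#' \{1.6, 3.2, 6.4, 12.8, 25.6\} s.  One domain is generated per `(ve, vp)`
#' pair; for each `(domain, Ktrans, D)` the simulation runs once and is
#' re-sampled at every temporal resolution.
#'
#' @param Ktrans vector of transfer constants [1/min]
#' @param ve,vp vectors of target fractions (crossed)
#' @param D vector of diffusion coefficients [mm^2/s]
#' @param temporal_resolutions sampling intervals [s]
#' @param voxel_side voxel side [mm]
#' @param target_edge mesh edge target [mm]
#' @param duration simulated time [s]
#' @param scan a `scan_parameters`
#' @param aif an `aif_model`
#' @param seed base RNG seed; domain `k` uses `seed + k - 1`
#' @return an `experiment_config`
#' @export
experiment_config <- function(Ktrans = c(0.1, 0.4, 0.7),
                              ve = c(0.25, 0.39, 0.55),
                              vp = c(0.01, 0.03, 0.06),
                              D = exp(seq(log(3e-5), log(3e-3),
                                          length.out = 8)),
                              temporal_resolutions = c(1.6, 3.2, 6.4, 12.8,
                                                       25.6),
                              voxel_side = 0.25, target_edge = 0.002,
                              duration = 660,
                              scan = scan_parameters(),
                              aif = aif_parametric(duration_s = duration),
                              seed = 1L) {
  stopifnot(length(Ktrans) > 0, length(ve) > 0, length(vp) > 0,
            length(D) > 0, length(temporal_resolutions) > 0,
            all(Ktrans > 0), all(D > 0), all(temporal_resolutions > 0))
  structure(list(Ktrans = Ktrans, ve = ve, vp = vp, D = D,
                 temporal_resolutions = temporal_resolutions,
                 voxel_side = voxel_side, target_edge = target_edge,
                 duration = duration, scan = scan, aif = aif,
                 seed = as.integer(seed)), class = "experiment_config")
}

#' Reduced demonstration grid
#'
#' A scaled-down version of the study grid sized for quick runs: the
#' reference composition only (`ve = 0.39`, `vp = 0.03`), `Ktrans = 0.4`
#' /min, a 4-point `D` sweep spanning the physiologic-to-well-mixed range,
#' all five temporal resolutions, a coarse 10 um mesh and a 150 um voxel
#' (same cell/vessel sizes and fractions as the 250 um reference, fewer
#' shapes).
#'
#' @param seed base RNG seed
#' @param target_edge mesh edge target [mm]
#' @param voxel_side voxel side [mm]
#' @return an `experiment_config`
#' @export
reduced_grid_config <- function(seed = 1L, target_edge = 0.010,
                                voxel_side = 0.15) {
  experiment_config(Ktrans = 0.4, ve = 0.39, vp = 0.03,
                    D = c(1e-4, 2e-4, 4e-4, 3e-3),
                    target_edge = target_edge, voxel_side = voxel_side,
                    seed = seed)
}

#' Run the experiment grid
#'
#' For each `(ve, vp)` a domain is generated, tiled 3x3 and meshed; for each
#' `(Ktrans, D)` the forward simulation is run once; the signal is then
#' sampled at every temporal resolution, converted to concentration and fit
#' with the extended Tofts model.  Rows are appended to `out_csv` (when
#' given) as they are produced, and per-cell failures are recorded without
#' stopping the grid.
#'
#' @param config an `experiment_config`
#' @param out_csv optional path; rows are flushed incrementally
#' @param verbose print per-cell progress
#' @return data frame with one row per
#'   `(domain, Ktrans, D, temporal resolution)`
#' @export
run_grid <- function(config, out_csv = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  written <- FALSE
  flush_row <- function(row) {
    rows[[length(rows) + 1]] <<- row
    if (!is.null(out_csv)) {
      write.table(row, out_csv, sep = ",", col.names = !written,
                  row.names = FALSE, append = written)
      written <<- TRUE
    }
  }
  dk <- 0L
  for (ve_t in config$ve) for (vp_t in config$vp) {
    dk <- dk + 1L
    dom <- tryCatch(
      generate_domain(config$voxel_side, ve_t, vp_t,
                      seed = config$seed + dk - 1L),
      error = function(e) e)
    if (inherits(dom, "error")) {
      warning(sprintf("domain (ve=%.2f, vp=%.2f) failed: %s", ve_t, vp_t,
                      conditionMessage(dom)))
      next
    }
    ext <- tile_extended_domain(dom)
    mesh <- mesh_ees(ext, target_edge = config$target_edge)
    for (Kt in config$Ktrans) for (Dv in config$D) {
      t0 <- proc.time()[3]
      cell <- tryCatch({
        # dt rule evaluated at the nominal mesh resolution (refined boundary
        # edges drag the realized mean edge well below the target)
        dt <- min(max(config$target_edge^2 / Dv, 1e-3), 0.1, 0.25)
        cfg <- solver_config(D = Dv, Ktrans = Kt, dt = dt,
                             duration = config$duration)
        tc <- run_simulation(dom, mesh, cfg, config$aif)
        r1 <- voxel_r1_trajectory(tc, config$aif, config$scan)
        for (dts in config$temporal_resolutions) {
          stc <- sample_time_course(r1, dts, config$scan)
          ct <- si_to_concentration(stc, config$scan)
          truth <- c(Kt, dom$ve_achieved, dom$vp_achieved)
          fit <- fit_extended_tofts(stc$time, ct, config$aif, truth = truth,
                                    temporal_resolution = dts, D = Dv)
          flush_row(data.frame(
            Ktrans_true_min = Kt, ve_true = dom$ve_achieved,
            vp_true = dom$vp_achieved, D_mm2_s = Dv, dt_sample_s = dts,
            Ktrans_est_min = fit$Ktrans_est, ve_est = fit$ve_est,
            vp_est = fit$vp_est,
            err_Ktrans_pct = fit$percent_errors[["Ktrans"]],
            err_ve_pct = fit$percent_errors[["ve"]],
            err_vp_pct = fit$percent_errors[["vp"]],
            chi2 = fit$chi2, converged = fit$converged))
        }
        TRUE
      }, error = function(e) e)
      if (inherits(cell, "error"))
        warning(sprintf("cell Ktrans=%.2g D=%.2g failed: %s", Kt, Dv,
                        conditionMessage(cell)))
      if (verbose)
        message(sprintf("domain %d Ktrans=%.2g D=%.2g: %.1f s", dk, Kt, Dv,
                        proc.time()[3] - t0))
    }
  }
  if (!length(rows)) stop("no grid cell completed")
  do.call(rbind, rows)
}

#' Per-parameter percent-error extrema over a diffusion range
#'
#' @param table a grid result from [run_grid()]
#' @param D_range inclusive interval of `D` [mm^2/s]
#' @return data frame with rows `Ktrans`, `ve`, `vp` and columns
#'   `min_pct`, `max_pct`
#' @export
summarize_errors <- function(table, D_range = c(1e-4, 4e-4)) {
  stopifnot(nrow(table) > 0)
  sel <- table$D_mm2_s >= D_range[1] - 1e-15 &
    table$D_mm2_s <= D_range[2] + 1e-15
  if (!any(sel)) stop("no rows with D inside the requested range")
  tb <- table[sel, , drop = FALSE]
  data.frame(
    parameter = c("Ktrans", "ve", "vp"),
    min_pct = c(min(tb$err_Ktrans_pct), min(tb$err_ve_pct),
                min(tb$err_vp_pct)),
    max_pct = c(max(tb$err_Ktrans_pct), max(tb$err_ve_pct),
                max(tb$err_vp_pct)))
}

#' Error-versus-diffusion summary panels
#'
#' Base-graphics panels of percent error (and chi-square) against `D` on a
#' log axis, one curve per temporal resolution, mirroring the layout used to
#' report parameterization-error results.
#'
#' @param table a grid result from [run_grid()]
#' @param file optional PNG path
#' @return invisibly, `file` (or `NULL` when plotting to the active device)
#' @export
plot_error_panels <- function(table, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 1200, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::par(mfrow = c(4, 1), mar = c(4, 4, 1.5, 1))
  dts <- sort(unique(table$dt_sample_s))
  cols <- grDevices::hcl.colors(length(dts), "Dark 2")
  panels <- list(c("err_Ktrans_pct", "Ktrans error [%]"),
                 c("err_ve_pct", "ve error [%]"),
                 c("err_vp_pct", "vp error [%]"),
                 c("chi2", "chi^2"))
  for (p in panels) {
    logy <- p[1] == "chi2"
    ylim <- range(table[[p[1]]])
    graphics::plot(NA, xlim = range(table$D_mm2_s), ylim = ylim, log =
                     if (logy) "xy" else "x",
                   xlab = "D [mm^2/s]", ylab = p[2])
    for (i in seq_along(dts)) {
      tb <- table[table$dt_sample_s == dts[i], ]
      tb <- tb[order(tb$D_mm2_s), ]
      graphics::lines(tb$D_mm2_s, tb[[p[1]]], col = cols[i], type = "b",
                      pch = 16)
    }
    if (!logy) graphics::abline(h = 0, lty = 3)
  }
  graphics::legend("topright", legend = sprintf("%.1f s", dts), col = cols,
                   lty = 1, pch = 16, cex = 0.8)
  invisible(file)
}
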