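# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fix, inherits = FALSE))
    assign(name, expr, envir = .fix)
  get(name, envir = .fix, inherits = FALSE)
}

# 100 um voxel with the reference composition (ve 0.39, vp 0.03)
fixture_domain <- function() {
  cached("dom_mini", generate_domain(0.1, 0.39, 0.03, seed = 1))
}

fixture_mesh <- function() {
  cached("mesh_mini", mesh_ees(fixture_domain(), target_edge = 0.005))
}

fixture_aif <- function() {
  cached("aif", aif_parametric())
}

# square voxel with no shapes (pure diffusion test bed), side in mm
empty_domain <- function(side = 0.1) {
  structure(list(
    voxel_side = side, side = side, is_extended = FALSE,
    cells = data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                       b = numeric(0), angle = numeric(0)),
    vessels = data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0)),
    ve_achieved = 1 - 1e-9, vp_achieved = 1e-10, veis_achieved = 9e-10,
    seed = 0L, gap = 0), class = "tissue_domain")
}

# constant-concentration AIF
flat_aif <- function(c0, duration = 660) {
  aif_tabulated(c(0, duration), c(c0, c0))
}

# reduced experiment grid shared by the chi2-monotonicity and ve-bound checks
fixture_grid_table <- function() {
  cached("grid_table", {
    cfg <- reduced_grid_config(seed = 3L)
    run_grid(cfg)
  })
}
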