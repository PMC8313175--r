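# High-level study protocols: the bovine radial-incision experiment and the
# human disc loading pipeline, in both residual-strain modes.
#
# swelling_only: both +/- theta fiber sets present at full modulus from time
#   zero; all annulus residual strain is swelling-induced.
# multigen: the disc swells fiber-free, then the two fiber sets are
#   deposited at opposite twist states (+/- Omega) so the neutral disc
#   carries fiber pre-strain in addition to swelling residual strain.

#' Bovine cylinder incision experiment
#'
#' Builds the bovine cylinder, establishes the requested residual-strain
#' state (swelling at fixed height with gripped ends; multigeneration fiber
#' deposition at twist `Omega` when requested), releases the end grips
#' (statically determinate support, mirroring removal of the disc from the
#' vertebrae), releases the radial cut, re-equilibrates, and measures the
#' opening gap at the outer AF edge.
#'
#' @param mode "multigen" or "swelling_only".
#' @param Omega Deposition twist angle (degrees), multigen mode only.
#' @param spec Bovine `geometry_spec`.
#' @param table Material table.
#' @param env `disc_environment`.
#' @param opts `solver_options`.
#' @param nsub_swell Swelling substeps.
#' @return List: `gap` (mm), `mesh` (cut released), `state` (opened),
#'   `free_state` (pre-incision, free-standing), `swollen_state`.
#' @export
run_bovine_incision <- function(mode = c("multigen", "swelling_only"),
                                Omega = 3,
                                spec = geometry_spec("bovine_cylinder"),
                                table = default_material_table(),
                                env = disc_environment(),
                                opts = solver_options(),
                                nsub_swell = 10) {
  mode <- match.arg(mode)
  mesh <- assign_region_params(build_bovine_cylinder(spec), table)
  st <- model_state(mesh, env)
  if (mode == "swelling_only") {
    st <- activate_time_zero_fibers(mesh, st)
    st <- swell_to_equilibrium(mesh, st, height_change = 0,
                               nsub = nsub_swell, opts = opts)
  } else {
    st <- swell_to_equilibrium(mesh, st, height_change = 0,
                               nsub = nsub_swell, opts = opts)
    st <- run_multigen_deposition(mesh, st, Omega, opts = opts)
  }
  swollen <- st
  st <- release_platens(mesh, st, opts = opts)
  free_state <- st
  cut <- simulate_incision(mesh, st, opts = opts)
  gap <- opening_gap(cut$mesh, cut$state)
  list(gap = gap, mesh = cut$mesh, state = cut$state,
       free_state = free_state, swollen_state = swollen, mode = mode)
}

#' Prepare a human disc model state
#'
#' Builds the parameterized human disc, swells it (fixed height in
#' swelling-only mode; ramped to `H + dH` during swelling in multigen mode),
#' runs the deposition protocol when requested, and applies the axial
#' preload in force control.
#'
#' @param mode "multigen" or "swelling_only".
#' @param Omega Deposition twist angle (degrees).
#' @param dH Axial displacement during multigen swelling (mm).
#' @param preload Axial preload (N); 0 skips the preload stage.
#' @param spec Human `geometry_spec`.
#' @param table Material table.
#' @param env `disc_environment`.
#' @param opts `solver_options`.
#' @param nsub_swell Swelling substeps.
#' @return List: `mesh`, `state` (preloaded), `swollen_state`.
#' @export
prepare_human_disc <- function(mode = c("multigen", "swelling_only"),
                               Omega = 3, dH = 0.5, preload = 270,
                               spec = geometry_spec("human_parametric"),
                               table = default_material_table(),
                               env = disc_environment(),
                               opts = solver_options(),
                               nsub_swell = 10) {
  mode <- match.arg(mode)
  mesh <- assign_region_params(build_human_parametric(spec), table)
  st <- model_state(mesh, env)
  if (mode == "swelling_only") {
    st <- activate_time_zero_fibers(mesh, st)
    st <- swell_to_equilibrium(mesh, st, height_change = 0,
                               nsub = nsub_swell, opts = opts)
  } else {
    st <- swell_to_equilibrium(mesh, st, height_change = dH,
                               nsub = nsub_swell, opts = opts)
    st <- run_multigen_deposition(mesh, st, Omega, opts = opts)
  }
  swollen <- st
  if (preload > 0) st <- apply_preload(mesh, st, preload, opts = opts)
  list(mesh = mesh, state = st, swollen_state = swollen, mode = mode)
}
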