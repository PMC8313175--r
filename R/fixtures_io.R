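# Synthetic experimental fixtures and I/O plumbing: deterministic stand-in
# load-displacement / rotation-torque curves with confidence bands (the
# original organ-scale validation curves are not redistributable), YAML run
# configuration with schema validation, CSV curve writers, JSON metrics
# reports, and a minimal legacy-VTK field writer for visualization.

#' Generate a synthetic experimental curve
#'
#' Deterministic smooth response of the qualitative shape of each test case
#' (monotone power-law-plus-linear for load ramps and rotations, saturating
#' exponential rise for creep, exponential decay for stress relaxation) with
#' a symmetric confidence band and optional seeded noise on the mean.
#'
#' @param kind One of "slow_ramp", "creep", "stress_relaxation",
#'   "axial_compression", "torsion", "bending", "flexion".
#' @param params List of family parameters: `x_max`, `amplitude`, `power`,
#'   `linear`, `tau` (time constant for creep/relaxation), `band` (CI half
#'   width as a fraction of the response scale), `noise` (noise standard
#'   deviation as a fraction of the response scale), `n` (samples).
#' @param seed Integer seed for the noise (the only randomness in the
#'   package).
#' @return Object of class `fixture_curve`: data.frame `x`, `y_expmean`,
#'   `y_ci`, with the generation parameters attached.
#' @export
generate_fixture_curve <- function(kind = c("slow_ramp", "creep",
                                            "stress_relaxation",
                                            "axial_compression", "torsion",
                                            "bending", "flexion"),
                                   params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(x_max = 1, amplitude = 1, power = 2,
                              linear = 0.5, tau = 0.2, band = 0.1,
                              noise = 0, n = 50), params)
  x <- seq(0, p$x_max, length.out = p$n + 1)[-1]
  xr <- x / p$x_max
  y <- switch(kind,
    creep = p$amplitude * (1 - exp(-xr / p$tau)),
    stress_relaxation = p$amplitude * exp(-xr / p$tau),
    p$amplitude * xr^p$power + p$linear * xr  # ramps and rotations
  )
  scale <- max(abs(y))
  if (p$noise > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = p$noise * scale)
  }
  band <- pmax(p$band * scale, 1e-12)
  out <- data.frame(x = x, y_expmean = y, y_ci = y + band)
  attr(out, "params") <- p
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  class(out) <- c("fixture_curve", "data.frame")
  out
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' @param mode "swelling_only" or "multigen".
#' @param shape "bovine_cylinder" or "human_parametric".
#' @return A `run_config` list (geometry spec, material table, environment,
#'   protocol parameters, solver options).
#' @export
default_run_config <- function(mode = "multigen", shape = "bovine_cylinder") {
  structure(list(
    geometry = geometry_spec(shape),
    materials = default_material_table(),
    environment = disc_environment(),
    mode = mode,
    omega = 3,
    dH = if (shape == "human_parametric") 0.5 else 0,
    preload = if (shape == "human_parametric") 270 else 0,
    solver = solver_options(),
    seed = 1L
  ), class = "run_config")
}

.config_check <- function(cfg) {
  if (!cfg$mode %in% c("swelling_only", "multigen"))
    stop("config error at mode: must be swelling_only or multigen")
  if (cfg$mode == "multigen" && (is.null(cfg$omega) || is.null(cfg$dH)))
    stop("config error at omega/dH: multigen mode requires both")
  invisible(cfg)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  .config_check(config)
  mat <- lapply(config$materials, function(p)
    p[c("region_label", "E_m", "nu", "beta_m", "k0", "M", "c0F", "E_f",
        "lambda0", "theta", "beta_f", "phi0_s")])
  lst <- list(
    geometry = unclass(config$geometry),
    materials = mat,
    environment = unclass(config$environment)[
      c("bath_osmolarity", "temperature", "osmotic_coefficient")],
    mode = config$mode, omega = config$omega, dH = config$dH,
    preload = config$preload,
    solver = config$solver, seed = config$seed
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Load and validate a run configuration from YAML
#'
#' Reconstructs typed objects ([geometry_spec()], [material_params()],
#' [disc_environment()], [solver_options()]) with path-precise validation
#' errors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  lst <- yaml::read_yaml(path)
  geom <- tryCatch(do.call(geometry_spec, lst$geometry),
                   error = function(e) stop("config error at geometry: ",
                                            conditionMessage(e)))
  mats <- lapply(names(lst$materials), function(nm) {
    m <- lst$materials[[nm]]
    m <- lapply(m, function(v) if (is.null(v)) NA_real_ else v)
    tryCatch(do.call(material_params, m),
             error = function(e) stop("config error at materials$", nm, ": ",
                                      conditionMessage(e)))
  })
  names(mats) <- names(lst$materials)
  env <- tryCatch(do.call(disc_environment, lst$environment),
                  error = function(e) stop("config error at environment: ",
                                           conditionMessage(e)))
  sol <- do.call(solver_options, lst$solver)
  cfg <- structure(list(geometry = geom, materials = mats, environment = env,
                        mode = lst$mode, omega = lst$omega, dH = lst$dH,
                        preload = lst$preload, solver = sol,
                        seed = lst$seed %||% 1L),
                   class = "run_config")
  .config_check(cfg)
  cfg
}

#' Write a response curve to CSV
#' @param curve A `disc_curve` or data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read a response curve from CSV
#' @param path CSV path with columns x, y_model and optional y_expmean, y_ci.
#' @return A `disc_curve`.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  response_curve(df$x, df$y_model, df$y_expmean, df$y_ci)
}

#' Save run artifacts to a results directory
#'
#' Writes curves as CSV, metrics as JSON, and echoes the configuration.
#'
#' @param dir Output directory (created if absent).
#' @param config A `run_config`.
#' @param curves Named list of curves/data.frames.
#' @param metrics Named list of scalar metrics.
#' @return `dir`, invisibly.
#' @export
save_results <- function(dir, config, curves = list(), metrics = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(curves))
    write_curve_csv(curves[[nm]], file.path(dir, paste0(nm, ".csv")))
  if (length(metrics) > 0)
    jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  save_config(config, file.path(dir, "config_echo.yaml"))
  invisible(dir)
}

#' Write a mesh (with optional fields) as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK writer for visualization of hexahedral meshes with
#' point displacements and per-cell scalar fields.
#'
#' @param mesh A `disc_mesh`.
#' @param path Output .vtk path.
#' @param state Optional `disc_state` (writes displacement vectors and uses
#'   deformed coordinates if `deformed = TRUE`).
#' @param cell_fields Named list of per-element numeric vectors.
#' @param deformed Write deformed node positions.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, state = NULL, cell_fields = list(),
                           deformed = FALSE) {
  nd <- mesh$nodes
  if (!is.null(state) && deformed)
    nd <- nd + matrix(state$u, ncol = 3, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "disc mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  utils::write.table(format(nd, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  ne <- nrow(mesh$elem)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9), con)
  utils::write.table(cbind(8, mesh$elem - 1), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  if (!is.null(state)) {
    writeLines(c(sprintf("POINT_DATA %d", nrow(nd)),
                 "VECTORS displacement double"), con)
    utils::write.table(matrix(format(state$u, digits = 10), ncol = 3,
                              byrow = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  if (length(cell_fields) > 0) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_fields[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}
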