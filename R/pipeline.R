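# End-to-end pipeline: config -> geometry -> mesh -> solve -> reports.

scenario_registry <- function(params) {
  list(
    baseline = scenario("baseline", list(), "calibrated normal upright eye"),
    supine = scenario_supine(params),
    nau_daytime = scenario_nau_daytime(params),
    nocturnal_upright = scenario_nocturnal_nau(params, supine = FALSE),
    nocturnal_supine = scenario_nocturnal_nau(params, supine = TRUE),
    ntg1 = scenario_ntg(params, 1L),
    ntg2 = scenario_ntg(params, 2L),
    tamponade_45 = scenario_tamponade(params, 45),
    tamponade_60 = scenario_tamponade(params, 60),
    tamponade_75 = scenario_tamponade(params, 75),
    tamponade_90 = scenario_tamponade(params, 90),
    schwartz_matsuo_0.148 = scenario_schwartz_matsuo(params, 0.148),
    schwartz_matsuo_0.12 = scenario_schwartz_matsuo(params, 0.12)
  )
}

#' Names of the built-in scenarios
#' @return Character vector of scenario names accepted by [run_pipeline()].
#' @export
list_scenarios <- function() names(scenario_registry(default_normal_eye()))

#' Retrieve a built-in scenario by name
#' @param name A name from [list_scenarios()].
#' @param params Baseline parameters the scenario is defined relative to.
#' @return A [scenario()] object.
#' @export
get_scenario <- function(name, params = default_normal_eye()) {
  reg <- scenario_registry(params)
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; see list_scenarios()", call. = FALSE)
  }
  reg[[name]]
}

#' Full report for one solved scenario
#'
#' @param solution A `flow_solution` on an eye mesh.
#' @param porosity Lamina cribrosa porosity for the true-velocity report.
#' @return A named list: `iop_mmHg`, `tlpg_mmHg_per_mm`, `laminar_fraction`,
#'   `partition_anterior`, `partition_rpe`, `partition_onh`, `v_true_um_s`,
#'   `fos_gradient`, `fos_dynein`.
#' @export
summarise_solution <- function(solution, porosity = 0.70) {
  prof <- extract_axial_profile(solution)
  tl <- compute_tlpg(prof)
  part <- flow_partition(solution)
  vel <- lc_velocities(solution, porosity)
  sf <- safety_factors(tl, vel)
  list(
    iop_mmHg = iop(solution),
    tlpg_mmHg_per_mm = tl$tlpg,
    laminar_fraction = tl$laminar_fraction,
    partition_anterior = part$fraction[part$route == "anterior"],
    partition_rpe = part$fraction[part$route == "rpe"],
    partition_onh = part$fraction[part$route == "onh"],
    v_true_um_s = sf$v_true_um_s,
    fos_gradient = sf$fos_gradient,
    fos_dynein = sf$fos_dynein
  )
}

#' Run the complete modelling pipeline for a named scenario
#'
#' Reads (or defaults) the configuration, builds the geometry and mesh,
#' applies the scenario overrides, solves the Darcy problem and writes the
#' reports: `summary.json`, tidy `reports.csv`, `axial_profile.csv`, a VTK
#' export of the solution, and the config snapshot.
#'
#' @param config_path Optional YAML configuration (see [write_config()]);
#'   defaults to the normal eye.
#' @param scenario_name One of [list_scenarios()], or a [scenario()] object.
#' @param output_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param mesh Optional pre-built mesh (reused across calls).
#' @return A `run_record` list: config snapshot, solver diagnostics, reports,
#'   wall time.
#' @export
run_pipeline <- function(config_path = NULL, scenario_name = "baseline",
                         output_dir = NULL, mesh = NULL) {
  t0 <- Sys.time()
  cfg <- read_config(config_path)
  params <- cfg$params
  sc <- if (inherits(scenario_name, "scenario")) scenario_name
        else {
          reg <- scenario_registry(params)
          if (!scenario_name %in% names(reg)) {
            stop("unknown scenario '", scenario_name, "'; see list_scenarios()",
                 call. = FALSE)
          }
          reg[[scenario_name]]
        }
  params_sc <- apply_scenario(params, sc)
  mesh <- mesh %||% generate_mesh(cfg$geometry, h = cfg$h)
  sol <- solve_eye(params_sc, mesh, control = cfg$control)
  summ <- summarise_solution(sol, porosity = params_sc$porosity_LC)
  prof <- extract_axial_profile(sol)
  record <- list(
    scenario = sc$name,
    config = list(parameters = unclass(params_sc),
                  geometry = unclass(cfg$geometry), h = cfg$h),
    summary = summ,
    diagnostics = list(iterations = sol$iterations,
                       mass_balance_error = mass_balance_error(sol),
                       n_elements = nrow(mesh$triangles),
                       n_nodes = nrow(mesh$nodes)),
    version = as.character(utils::packageVersion("oculoflow")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(record) <- "run_record"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summ, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(tidy_summary(sc$name, summ),
                     file.path(output_dir, "reports.csv"), row.names = FALSE)
    utils::write.csv(prof[, c("z_mm", "p_mmHg")],
                     file.path(output_dir, "axial_profile.csv"),
                     row.names = FALSE)
    write_solution_vtk(sol, file.path(output_dir, "solution.vtk"))
    yaml::write_yaml(record$config, file.path(output_dir, "config.yaml"))
  }
  record
}

tidy_summary <- function(name, summ) {
  tibble::tibble(scenario = name, quantity = names(summ),
                 value = unlist(summ, use.names = FALSE))
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record> scenario '", x$scenario, "' (",
      x$diagnostics$n_elements, " elements, ",
      sprintf("%.1f s", x$wall_time_s), ")\n", sep = "")
  s <- x$summary
  cat(sprintf("  IOP %.2f mmHg | TLPG %.1f mmHg/mm | laminar fraction %.2f\n",
              s$iop_mmHg, s$tlpg_mmHg_per_mm, s$laminar_fraction))
  cat(sprintf("  partition: anterior %.1f%%, RPE %.1f%%, ONH %.2f%%\n",
              100 * s$partition_anterior, 100 * s$partition_rpe,
              100 * s$partition_onh))
  cat(sprintf("  v_true %.2f um/s | FoS gradient %.2f | FoS dynein %.2f\n",
              s$v_true_um_s, s$fos_gradient, s$fos_dynein))
  invisible(x)
}

#' Read / write the pipeline configuration
#'
#' YAML with blocks `parameters`, `geometry`, `solver` (`h`, `tol_Pa`,
#' `max_iter`, `relax`), and a `units` metadata block. Missing blocks fall
#' back to the defaults.
#'
#' @param path Config file path; `NULL` gives the default configuration.
#' @return `read_config`: list with `params`, `geometry`, `h`, `control`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) {
    return(list(params = default_normal_eye(), geometry = eye_geometry(),
                h = 1.7e-4, control = list()))
  }
  y <- yaml::read_yaml(path)
  params <- if (!is.null(y$parameters)) {
    do.call(eye_params, y$parameters[intersect(names(y$parameters),
                                               names(param_units))])
  } else default_normal_eye()
  geometry <- if (!is.null(y$geometry)) {
    do.call(eye_geometry, y$geometry[intersect(names(y$geometry),
                                               names(formals(eye_geometry)))])
  } else eye_geometry()
  list(params = params, geometry = geometry,
       h = y$solver$h %||% 1.7e-4,
       control = y$solver[intersect(names(y$solver),
                                    c("tol_Pa", "max_iter", "relax"))] %||% list())
}

#' @rdname read_config
#' @param params,geometry Objects to serialize.
#' @param h Target mesh edge length (m).
#' @export
write_config <- function(path, params = default_normal_eye(),
                         geometry = eye_geometry(), h = 1.7e-4) {
  yaml::write_yaml(list(parameters = unclass(params),
                        geometry = unclass(geometry),
                        solver = list(h = h),
                        units = as.list(param_units)), path)
  invisible(path)
}

## ---- exports --------------------------------------------------------------

#' Write a mesh or solution to legacy VTK (ASCII)
#'
#' Unstructured-grid export with region labels as cell data; for solutions,
#' nodal pressure (mmHg) as point data and Darcy velocity as cell data.
#'
#' @param mesh An `axisym_mesh`.
#' @param solution A `flow_solution`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  write_vtk_impl(mesh, path, pressure = NULL, velocity = NULL)
}

#' @rdname write_mesh_vtk
#' @export
write_solution_vtk <- function(solution, path) {
  v <- darcy_velocity_field(solution)
  write_vtk_impl(solution$mesh, path,
                 pressure = Pa_to_mmHg(solution$pressure_Pa),
                 velocity = cbind(v$vr, v$vz))
}

write_vtk_impl <- function(mesh, path, pressure, velocity) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "oculoflow axisymmetric mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nn, "double")), con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELLS", nt, 4 * nt), con)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELL_TYPES", nt), con)
  writeLines(as.character(rep(5L, nt)), con)
  writeLines(c(paste("CELL_DATA", nt), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  if (!is.null(velocity)) {
    writeLines("VECTORS darcy_velocity double", con)
    utils::write.table(cbind(velocity, 0), con, row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(pressure)) {
    writeLines(c(paste("POINT_DATA", nn), "SCALARS pressure_mmHg double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(pressure), con)
  }
  invisible(path)
}

#' Dump mesh nodes and elements to CSV
#'
#' @param mesh An `axisym_mesh`.
#' @param node_path,element_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_mesh_csv <- function(mesh, node_path, element_path) {
  utils::write.csv(data.frame(node = seq_len(nrow(mesh$nodes)),
                              r = mesh$nodes[, 1], z = mesh$nodes[, 2]),
                   node_path, row.names = FALSE)
  utils::write.csv(data.frame(element = seq_len(nrow(mesh$triangles)),
                              n1 = mesh$triangles[, 1],
                              n2 = mesh$triangles[, 2],
                              n3 = mesh$triangles[, 3],
                              region = mesh$region),
                   element_path, row.names = FALSE)
  invisible(c(node_path, element_path))
}
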