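# Experiment presets, configuration validation and reproducible runs tying
# the stages together. Each preset corresponds to one published model panel
# and resolves to a full parameter set (KRN, canvas, time window, cells).

preset_registry <- function() {
  base <- list(canvas = list(diameter = 100, wall_thickness = 30,
                             subdivision_level = 4),
               t_start = 96, t_end = 252, dt = 1, cells = NULL)
  mk <- function(krn, ...) utils::modifyList(c(base, list(krn = krn)), list(...))
  list(
    fig4AF = mk("fig4AF"),
    fig4GJ = mk("fig4GJ"),
    fig4KN = mk("fig4KN"),
    fig6AD = mk("fig6AD"),
    fig6EH = mk("fig6EH"),
    fig6IL = mk("fig6IL"),
    fig6MP = mk("fig6MP"),
    fig7_terminal = mk("fig7_terminal"),
    fig7_basal = mk("fig7_basal"),
    s3_thickness = mk("s3_thickness"),
    fig9_integrated_cells = mk("fig6MP",
                               cells = list(target_mean_area = 50,
                                            clone_fraction = NULL)),
    fig11_integrated_clones = mk("fig6MP",
                                 cells = list(target_mean_area = 50,
                                              clone_fraction = 0.4)),
    fig11_directional_clones = mk("fig6IL",
                                  cells = list(target_mean_area = 50,
                                               clone_fraction = 0.4)),
    fig11_areal_clones = mk("fig4KN",
                            cells = list(target_mean_area = 50,
                                         clone_fraction = 0.4))
  )
}

#' List available presets
#' @return character vector of preset names.
#' @export
list_presets <- function() names(preset_registry())

# build and dress the canvas a preset needs
setup_preset_canvas <- function(cfg, params) {
  cv <- build_sphere_canvas(diameter = cfg$canvas$diameter,
                            wall_thickness = cfg$canvas$wall_thickness,
                            subdivision_level = cfg$canvas$subdivision_level)
  setup_trap_factors(cv, with_polarity = params$model_kind != "areal")
}

#' Run a preset experiment
#'
#' Resolves a preset (optionally overridden), builds the canvas and factor
#' fields, runs the simulation (with virtual cells and clones where the
#' preset includes them), measures the section circumferences of the final
#' shape, and writes snapshots, measurement tables and a run manifest when an
#' output directory is given.
#'
#' @param name preset name (see \code{\link{list_presets}}).
#' @param overrides named list overriding resolved fields; KRN parameters can
#'   be overridden directly by name (e.g. \code{list(p_mid = 0)}), and
#'   \code{canvas} sub-fields via \code{list(canvas = list(subdivision_level
#'   = 3))}.
#' @param out_dir optional output directory.
#' @param seed seed controlling cell tiling, clone induction and wall jitter.
#' @param snapshot_every snapshot cadence in steps.
#' @return list with the \code{trajectory}, final-shape \code{measurements},
#'   the final \code{cells} layer (if any) and the run \code{manifest}.
#' @export
run_preset <- function(name, overrides = list(), out_dir = NULL, seed = 1L,
                       snapshot_every = NULL) {
  reg <- preset_registry()
  if (!name %in% names(reg)) stop("unknown preset: ", name)
  cfg <- reg[[name]]
  params <- krn_preset(cfg$krn)
  for (key in names(overrides)) {
    if (key %in% names(params)) params[[key]] <- overrides[[key]]
    else if (key == "canvas")
      cfg$canvas <- utils::modifyList(cfg$canvas, overrides$canvas)
    else if (key %in% names(cfg)) cfg[[key]] <- overrides[[key]]
    else warning("unknown override ignored: ", key)
  }
  validate_params(params)

  t0 <- Sys.time()
  cv <- setup_preset_canvas(cfg, params)
  cells <- NULL
  rule <- division_rule(seed = seed)
  if (!is.null(cfg$cells)) {
    cells <- tile_cells(cv, cfg$cells$target_mean_area, seed = seed)
    if (!is.null(cfg$cells$clone_fraction))
      cells <- induce_clones(cells, cfg$cells$clone_fraction, seed = seed)
  }
  traj <- run_simulation(cv, params, cells = cells, t_start = cfg$t_start,
                         t_end = cfg$t_end,
                         config = solver_config(dt = cfg$dt, seed = seed),
                         rule = rule, snapshot_every = snapshot_every)
  final <- traj$snapshots[[length(traj$snapshots)]]
  measurements <- list(
    circumference = vapply(c("sagittal", "frontal", "transverse"),
                           function(p) extract_circumference(final, p)$length,
                           numeric(1)),
    sagittal_subdomains = extract_circumference(final, "sagittal")$subdomains)
  manifest <- list(preset = name, seed = seed,
                   parameters = unclass(params),
                   canvas = cfg$canvas,
                   t_start = cfg$t_start, t_end = cfg$t_end, dt = cfg$dt,
                   cells = cfg$cells,
                   version = as.character(utils::packageVersion("trapmorph")),
                   wall_time_s = as.numeric(Sys.time() - t0, units = "secs"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, out_dir)
    if (!is.null(traj$cells)) {
      write_cells_csv(traj$cells[[length(traj$cells)]], final,
                      file.path(out_dir, "cells_final.csv"))
    }
    utils::write.csv(
      data.frame(plane = names(measurements$circumference),
                 length_um = measurements$circumference),
      file.path(out_dir, "circumferences.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(trajectory = traj, measurements = measurements,
       cells = if (!is.null(traj$cells)) traj$cells[[length(traj$cells)]],
       manifest = manifest)
}

validate_params <- function(params) {
  errs <- character(0)
  if (params$b_planar <= 0) errs <- c(errs, "b_planar must be positive")
  if (params$b_thickness < 0) errs <- c(errs, "b_thickness must be >= 0")
  for (nm in c("p_mid", "h_stk", "p_ven", "h_ven", "p_th"))
    if (params[[nm]] < 0) errs <- c(errs, paste(nm, "must be >= 0"))
  if (params$t_ven < 0 || params$t_ven > 1)
    errs <- c(errs, "t_ven must lie in [0, 1]")
  if (length(errs)) stop("invalid parameters: ", paste(errs, collapse = "; "))
  invisible(params)
}

#' Write a KRN/solver configuration to JSON
#' @param params a \code{krn_params}.
#' @param path output path.
#' @param solver optional \code{solver_config} stored alongside.
#' @return invisibly, the path.
#' @export
write_config <- function(params, path, solver = NULL) {
  obj <- list(krn = unclass(params))
  if (!is.null(solver)) obj$solver <- unclass(solver)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate and resolve a configuration file
#'
#' Reads a JSON configuration, fills defaults, and either returns the
#' resolved parameter objects or stops with an aggregated report naming every
#' out-of-range field. Unknown keys produce warnings, not errors.
#'
#' @param file path to a JSON configuration with a \code{krn} block and an
#'   optional \code{solver} block.
#' @return list with \code{krn} (\code{krn_params}) and \code{solver}
#'   (\code{solver_config}).
#' @export
validate_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  krn_fields <- names(formals(krn_params))
  solver_fields <- names(formals(solver_config))
  errs <- character(0)
  kr <- obj$krn
  if (is.null(kr)) kr <- obj  # allow a bare KRN object
  unknown <- setdiff(names(kr), c(krn_fields, "use_mid", "use_stk", "use_ven"))
  if (length(unknown))
    warning("unknown configuration keys ignored: ",
            paste(unknown, collapse = ", "))
  kr <- kr[intersect(names(kr), krn_fields)]
  params <- tryCatch(do.call(krn_params, kr), error = function(e) {
    errs <<- c(errs, conditionMessage(e)); NULL
  })
  solver <- solver_config()
  if (!is.null(obj$solver)) {
    sv <- obj$solver[intersect(names(obj$solver), solver_fields)]
    unknown <- setdiff(names(obj$solver), solver_fields)
    if (length(unknown))
      warning("unknown solver keys ignored: ", paste(unknown, collapse = ", "))
    solver <- tryCatch(do.call(solver_config, sv), error = function(e) {
      errs <<- c(errs, conditionMessage(e)); NULL
    })
  }
  if (length(errs)) stop("configuration invalid: ", paste(errs, collapse = "; "))
  list(krn = params, solver = solver)
}

#' Read a configuration written by \code{\link{write_config}}
#' @param path JSON path.
#' @return list with \code{krn} and \code{solver} objects.
#' @export
read_config <- function(path) validate_config(path)
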