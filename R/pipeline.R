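#' Experiment configuration
#'
#' The default grid mirrors the study protocol: the four morphology classes
#' under both rhythm conditions (8 runs), four cardiac cycles each, on
#' desk-scale meshes of a few thousand triangles.
#'
#' @param anatomies named list of [anatomy_spec()]s (defaults to the four
#'   canonical morphologies).
#' @param conditions subset of `c("healthy", "af")`.
#' @param solver a [flow_solver_config()].
#' @param props [fluid_properties()].
#' @param h mesh characteristic length (m).
#' @param n_stations centerline stations.
#' @param out_dir optional output directory for summaries/tables/snapshots.
#' @param write_vtk write VTK snapshots of the final state per case.
#' @param seed integer; reseeds each anatomy spec so the whole experiment is
#'   a deterministic function of the config.
#' @return an object of class `laa_experiment_config`.
#' @export
experiment_config <- function(anatomies = NULL,
                              conditions = c("healthy", "af"),
                              solver = flow_solver_config(),
                              props = fluid_properties(),
                              h = 1.35e-3, n_stations = 24L,
                              out_dir = NULL, write_vtk = FALSE,
                              seed = 1L) {
  if (is.null(anatomies)) anatomies <- default_anatomy_specs(seed = seed)
  classes <- c("chicken_wing", "cactus", "windsock", "cauliflower")
  for (nm in names(anatomies)) {
    sp <- anatomies[[nm]]
    if (!inherits(sp, "laa_anatomy_spec"))
      stop("config-validation error: '", nm, "' is not an anatomy_spec")
    if (!(sp$morphology_class %in% classes))
      stop("config-validation error: unknown morphology '",
           sp$morphology_class, "'")
  }
  if (!all(conditions %in% c("healthy", "af")) || !length(conditions))
    stop("config-validation error: conditions must be within {healthy, af}")
  stopifnot(inherits(solver, "laa_solver_config"),
            inherits(props, "laa_fluid"), h > 0)
  cfg <- list(anatomies = anatomies, conditions = conditions,
              solver = solver, props = props, h = h,
              n_stations = as.integer(n_stations), out_dir = out_dir,
              write_vtk = isTRUE(write_vtk), seed = as.integer(seed))
  cfg$hash <- .config_hash(cfg)
  class(cfg) <- "laa_experiment_config"
  cfg
}

.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(
    cfg[setdiff(names(cfg), c("out_dir", "hash"))], digits.d = 12)), tf)
  unname(tools::md5sum(tf))
}

#' Read an experiment configuration from a YAML file
#'
#' Structured-text front end to [experiment_config()]: top-level keys
#' `anatomies` (name: list of anatomy_spec fields), `conditions`, `solver`,
#' `fluid`, `h`, `n_stations`, `out_dir`, `seed`.
#'
#' @param path YAML file.
#' @return an `laa_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  anats <- NULL
  if (!is.null(y$anatomies))
    anats <- lapply(y$anatomies, function(a) do.call(anatomy_spec, a))
  solver <- do.call(flow_solver_config, y$solver %||% list())
  props <- do.call(fluid_properties, y$fluid %||% list())
  experiment_config(anatomies = anats,
                    conditions = y$conditions %||% c("healthy", "af"),
                    solver = solver, props = props,
                    h = y$h %||% 1.35e-3,
                    n_stations = y$n_stations %||% 24L,
                    out_dir = y$out_dir, seed = y$seed %||% 1L)
}

#' Run one morphology/condition case
#'
#' Generates the anatomy and mesh, extracts the centerline, assembles the
#' boundary conditions and runs the transient washout simulation, returning
#' the stasis summary together with the run artifacts.
#'
#' @param spec an [anatomy_spec()].
#' @param condition `"healthy"` or `"af"`.
#' @param config an [experiment_config()].
#' @param mesh optional pre-built mesh (reused across conditions).
#' @param verbose print per-cycle diagnostics.
#' @return list with `summary`, `run`, `mesh`, `centerline`.
#' @export
run_case <- function(spec, condition, config = experiment_config(),
                     mesh = NULL, verbose = FALSE) {
  if (is.null(mesh)) {
    anatomy <- generate_anatomy(spec)
    mesh <- generate_mesh(anatomy, h = config$h)
  }
  centerline <- extract_centerline(mesh, config$n_stations)
  bcs <- assemble_bcs(mesh, condition)
  run <- run_flow(mesh, bcs, config$props, config$solver, verbose = verbose)
  summary <- summarize_run(run, centerline,
                           morphology_class = spec$morphology_class)
  list(summary = summary, run = run, mesh = mesh, centerline = centerline)
}

#' Run the full experiment grid
#'
#' Executes every (morphology, condition) pair of the configuration. A
#' failing case is logged and skipped; the others continue. Outputs (summary
#' JSON per case, cross-case comparison table, optional VTK snapshots) are
#' written under `config$out_dir` when set, each stamped with the config hash
#' and seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-cycle diagnostics.
#' @return list with `summaries` (named list), `comparison` (data.frame or
#'   NULL), `failures` (named list of error messages).
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "laa_experiment_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  summaries <- list(); failures <- list()
  for (nm in names(config$anatomies)) {
    spec <- config$anatomies[[nm]]
    mesh <- tryCatch({
      generate_mesh(generate_anatomy(spec), h = config$h)
    }, error = function(e) e)
    for (cond in config$conditions) {
      key <- paste(nm, cond, sep = ".")
      res <- tryCatch({
        if (inherits(mesh, "error")) stop(conditionMessage(mesh))
        run_case(spec, cond, config, mesh = mesh, verbose = verbose)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
        message("case ", key, " failed: ", conditionMessage(res))
        next
      }
      summaries[[key]] <- res$summary
      if (!is.null(out_dir)) {
        write_summary_json(res$summary,
                           file.path(out_dir, paste0(key, ".json")),
                           provenance = list(config_hash = config$hash,
                                             seed = config$seed))
        if (config$write_vtk)
          write_mesh_vtk(res$mesh, file.path(out_dir, paste0(key, ".vtk")),
                         point_data = list(u = res$run$state$u,
                                           v = res$run$state$v,
                                           p = res$run$state$p),
                         cell_data = list(c = res$run$state$c,
                                          region = as.integer(
                                            res$mesh$region == "LAA")))
      }
    }
  }
  comparison <- NULL
  if (length(summaries) >= 2L)
    comparison <- tryCatch(compare_conditions(summaries),
                           error = function(e) NULL)
  if (!is.null(out_dir) && !is.null(comparison)) {
    utils::write.csv(cbind(comparison,
                           config_hash = config$hash, seed = config$seed),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  list(summaries = summaries, comparison = comparison, failures = failures)
}

#' Compare rhythm conditions per morphology
#'
#' Per-morphology AF-minus-healthy deltas of the appendage-normalized mean
#' velocity, mean SSR and residual contrast, with flags where a case violates
#' the expected qualitative trends (AF should lower appendage velocity and
#' SSR; AF should retain at least as much contrast except possibly in the
#' chicken-wing analog, where equal residuals are plausible).
#'
#' @param summaries list of `stasis_summary` objects covering both conditions
#'   for at least one morphology.
#' @return data.frame, one row per morphology.
#' @export
compare_conditions <- function(summaries) {
  if (!length(summaries)) stop("pairing error: no summaries")
  cls <- vapply(summaries, function(s) s$morphology_class %||% NA_character_,
                character(1L))
  cond <- vapply(summaries, `[[`, "", "condition")
  morphs <- unique(cls)
  rows <- list()
  for (mc in morphs) {
    ih <- which(cls == mc & cond == "healthy")
    ia <- which(cls == mc & cond == "af")
    if (!length(ih) || !length(ia)) next
    h <- summaries[[ih[1L]]]; a <- summaries[[ia[1L]]]
    rows[[mc]] <- data.frame(
      morphology = mc,
      mean_velocity_healthy = h$mean_velocity_LAA,
      mean_velocity_af = a$mean_velocity_LAA,
      d_mean_velocity = a$mean_velocity_LAA - h$mean_velocity_LAA,
      mean_ssr_healthy = h$mean_ssr_LAA,
      mean_ssr_af = a$mean_ssr_LAA,
      d_mean_ssr = a$mean_ssr_LAA - h$mean_ssr_LAA,
      residual_healthy = h$residual_contrast_domain,
      residual_af = a$residual_contrast_domain,
      d_residual = a$residual_contrast_domain - h$residual_contrast_domain,
      flag_velocity = a$mean_velocity_LAA > h$mean_velocity_LAA,
      flag_ssr = a$mean_ssr_LAA > h$mean_ssr_LAA,
      flag_residual = (mc != "chicken_wing") &&
        (a$residual_contrast_domain < h$residual_contrast_domain),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("pairing error: no morphology has both conditions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
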