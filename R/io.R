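# File formats and run configuration.  One dialect per purpose: CSV for
# tabular traces and profiles, JSON for structured results, YAML for run
# configuration.  Units are fixed at kPa / mm / ml; no unit auto-detection.

#' Read a cavity pressure trace
#'
#' Reads a frame-indexed cavity pressure trace from a CSV file with header
#' `frame,pressure_kpa`, validates it and returns it sorted by frame.
#'
#' @param path CSV file path.
#' @return A tibble with columns `frame` and `pressure_kpa`, sorted by
#'   frame, with attribute `p_min` (the minimum pressure, reported because
#'   the minimum diastolic pressure is conventionally calibrated to zero).
#' @export
load_pressure_trace <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(cnd) abort_validation(
                   sprintf("cannot parse %s: %s", path, conditionMessage(cnd))))
  if (!all(c("frame", "pressure_kpa") %in% names(df)))
    abort_validation("pressure trace must have columns frame, pressure_kpa")
  if (nrow(df) == 0L) abort_validation("pressure trace is empty")
  if (!is.numeric(df$frame) || !is.numeric(df$pressure_kpa) ||
      any(is.na(df$frame)) || any(is.na(df$pressure_kpa)))
    abort_validation("pressure trace columns must be numeric and complete")
  if (anyDuplicated(df$frame))
    abort_validation("duplicate frame indices in the pressure trace")
  if (any(df$pressure_kpa < 0))
    abort_validation("negative pressures are not allowed")
  df <- df[order(df$frame), c("frame", "pressure_kpa")]
  out <- tibble::as_tibble(df)
  attr(out, "p_min") <- min(out$pressure_kpa)
  out
}

#' Write an estimation result to a directory
#'
#' Writes a schema-versioned JSON with the complete result, a CSV of the AT
#' profile, and a short human-readable summary.  [read_result()] reproduces
#' the result object from the JSON.
#'
#' @param result An `lv_estimate` from [run_algorithm1()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "lv_estimate"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  g <- result$params; r <- result$reformulated
  payload <- list(
    schema = "diastolefit-result/1",
    params = list(c1 = g$c1, c2 = g$c2, c3 = g$c3, c4 = g$c4),
    reformulated = list(c1 = r$c1, alpha = r$alpha, r2 = r$r2, r3 = r$r3,
                        r4 = r$r4),
    geometry = list(r_endo = result$x0$r_endo, wall = result$x0$wall,
                    length = result$x0$length, f_base = result$x0$f_base,
                    helix_endo = result$x0$helix_endo,
                    helix_epi = result$x0$helix_epi),
    k = result$k,
    n = result$n,
    at_profile = as.list(result$at_profile[c("frame", "pressure", "t_z",
                                             "j", "rmse")]),
    no_residual_at = result$no_residual_at,
    criterion_relaxed = result$criterion_relaxed
  )
  json_path <- file.path(dir, "result.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv_path <- file.path(dir, "at_profile.csv")
  utils::write.csv(result$at_profile, csv_path, row.names = FALSE)
  sum_path <- file.path(dir, "summary.txt")
  writeLines(utils::capture.output(print(result)), sum_path)
  invisible(c(json = json_path, csv = csv_path, summary = sum_path))
}

#' Read an estimation result written by [write_result()]
#'
#' @param dir Directory containing `result.json`.
#' @return An `lv_estimate` (without the sweep audit trail, which is not
#'   serialized).
#' @export
read_result <- function(dir) {
  path <- file.path(dir, "result.json")
  if (!file.exists(path)) abort_validation(sprintf("no result.json in %s", dir))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "diastolefit-result/1"))
    abort_validation(sprintf("unknown result schema: %s", p$schema))
  params <- guccione_params(p$params$c1, p$params$c2, p$params$c3, p$params$c4)
  ref <- reformulated_params(p$reformulated$c1, p$reformulated$alpha,
                             r2 = p$reformulated$r2, r3 = p$reformulated$r3,
                             r4 = p$reformulated$r4)
  attr(params, "reformulated") <- ref
  structure(list(
    params = params,
    reformulated = ref,
    x0 = lv_geometry(p$geometry$r_endo, p$geometry$wall, p$geometry$length,
                     p$geometry$f_base, p$geometry$helix_endo,
                     p$geometry$helix_epi),
    k = p$k,
    at_profile = tibble::as_tibble(p$at_profile),
    no_residual_at = isTRUE(p$no_residual_at),
    criterion_relaxed = isTRUE(p$criterion_relaxed),
    boundary = NULL, audit = NULL, config = NULL,
    n = p$n
  ), class = "lv_estimate")
}

#' Load or save a run configuration (YAML)
#'
#' A run configuration bundles the sweep settings, the active tension
#' length-dependence coefficient, paths and the seed.  The representation
#' round-trips losslessly through YAML.
#'
#' @param path YAML file path.
#' @param config For [save_run_config()], a list as returned by
#'   [load_run_config()] (fields `sweep` ([sweep_config()] arguments),
#'   `paths`, `seed`, `verbosity`).
#' @return [load_run_config()]: a list with a `sweep_config` in `$sweep`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  sweep <- do.call(sweep_config, y$sweep %||% list())
  list(sweep = sweep, paths = y$paths %||% list(), seed = y$seed %||% 1L,
       verbosity = y$verbosity %||% "info")
}

#' @rdname load_run_config
#' @export
save_run_config <- function(config, path) {
  sw <- config$sweep
  y <- list(
    sweep = list(c1 = sw$c1, alpha_grid = sw$alpha_grid, r_step = sw$r_step,
                 at_range = sw$at_range, at_coarse_step = sw$at_coarse_step,
                 at_refine_step = sw$at_refine_step, max_iter = sw$max_iter,
                 n_refine = sw$n_refine, refine_zoom = sw$refine_zoom,
                 r34_init = sw$r34_init, beta = sw$beta,
                 n_lambda = sw$n_lambda, n_mu = sw$n_mu),
    paths = config$paths, seed = config$seed, verbosity = config$verbosity
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a generated frame series to a directory
#'
#' Writes one CSV per frame (`frame_01.csv`, ... with columns lambda, mu,
#' theta, x, y, z), the pressure trace CSV, and a YAML with the generating
#' configuration (without the truth parameters unless `truth = TRUE`).
#'
#' @param frames A [frames_data()] object.
#' @param dir Output directory.
#' @param truth Also serialize the ground-truth configuration if present.
#' @return Invisibly, `dir`.
#' @export
write_frames <- function(frames, dir, truth = FALSE) {
  stopifnot(inherits(frames, "frames_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(frames$n)) {
    utils::write.csv(frames$points[[i]],
                     file.path(dir, sprintf("frame_%02d.csv", i)),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(frame = seq_len(frames$n),
                              pressure_kpa = frames$pressures),
                   file.path(dir, "pressures.csv"), row.names = FALSE)
  tr <- attr(frames, "truth")
  if (truth && !is.null(tr)) {
    yaml::write_yaml(list(
      params = params_to_list(tr$params),
      geometry = list(r_endo = tr$geometry$r_endo, wall = tr$geometry$wall,
                      length = tr$geometry$length, f_base = tr$geometry$f_base),
      pressures = tr$pressures, at = tr$at, sigma = tr$sigma, seed = tr$seed,
      beta = tr$beta), file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' Read a frame series directory written by [write_frames()]
#'
#' @param dir Directory with `frame_XX.csv` files and `pressures.csv`.
#' @param template Optional [lv_geometry()] template.
#' @return A [frames_data()] object.
#' @export
read_frames <- function(dir, template = NULL) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) abort_validation(sprintf("no frame CSVs in %s", dir))
  pts <- lapply(files, function(f) tibble::as_tibble(utils::read.csv(f)))
  tr <- load_pressure_trace(file.path(dir, "pressures.csv"))
  frames_data(pts, tr$pressure_kpa, template = template)
}
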