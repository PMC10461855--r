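## Declarative run configs (YAML/JSON) and tidy trajectory export.

#' Read a declarative run configuration
#'
#' A config describes one simulation: `model` (name), optional `params`
#' (flat key-value block using the rate-constant symbols), `state0`,
#' `schedules` (list of `{parameter, times, values}` or
#' `{parameter, t_step, from, to}`), and `config`
#' (`t_end`, `t_start`, `dt`, `rtol`, `atol`).
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A list with a ready-to-run `model`, `state0`, `schedules`,
#'   and `config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$model)) stop("config must name a model", call. = FALSE)
  model <- hm_model(cfg$model, params = cfg$params)
  state0 <- if (!is.null(cfg$state0)) unlist(cfg$state0) else NULL
  schedules <- lapply(cfg$schedules, function(s) {
    if (!is.null(s$t_step)) {
      step_schedule(s$parameter, s$t_step, s$from, s$to,
                    t_start = s$t_start %||% 0)
    } else {
      schedule(s$parameter, unlist(s$times), unlist(s$values))
    }
  })
  list(model = model, state0 = state0, schedules = schedules,
       config = cfg$config %||% list())
}

#' Run a simulation described by a config file
#'
#' @param path Config file path (see [read_run_config()]).
#' @return An `hm_trajectory`.
#' @export
run_config <- function(path) {
  rc <- read_run_config(path)
  cf <- rc$config
  if (is.null(rc$state0)) stop("config must provide state0", call. = FALSE)
  args <- list(model = rc$model, state0 = rc$state0,
               schedules = rc$schedules,
               t_end = cf$t_end %||% 100)
  for (nm in c("t_start", "dt", "rtol", "atol")) {
    if (!is.null(cf[[nm]])) args[[nm]] <- cf[[nm]]
  }
  do.call(simulate_model, args)
}

#' Export a trajectory as tidy CSV plus a JSON sidecar
#'
#' Writes `<stem>.csv` (time, one column per species) and
#' `<stem>.json` with the model name, per-phase parameter snapshots,
#' schedules, solver settings and diagnostics.
#'
#' @param trajectory An `hm_trajectory`.
#' @param stem Output path stem (without extension).
#' @return `stem`, invisibly.
#' @export
export_trajectory <- function(trajectory, stem) {
  utils::write.csv(as.data.frame(trajectory), paste0(stem, ".csv"),
                   row.names = FALSE)
  meta <- list(
    model = attr(trajectory, "model"),
    params = lapply(attr(trajectory, "params"), as.list),
    schedules = lapply(attr(trajectory, "schedules"), unclass),
    solver = attr(trajectory, "solver"),
    diagnostics = attr(trajectory, "diagnostics")
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(stem)
}
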