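#' Write a trajectory to CSV
#'
#' Deterministic CSV writer: fixed column order (`time_s`, `a_um`, `c_um`,
#' `V_um3`, `S_um2`, `dr_um`, `dz_um`, `zeta`, `xi`, species concentrations
#' alphabetically, `dP_os_Pa`, `dP_imm_Pa`, then any extra columns such as the
#' classical water fluxes), 12 significant digits, header row, UTF-8, LF line
#' endings.  Two runs with identical configurations produce byte-identical
#' files (the pipeline involves no random numbers).
#'
#' @param traj A non-empty `swelling_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "swelling_trajectory") && !is.data.frame(traj)) {
    abort("`traj` must be a swelling trajectory")
  }
  if (nrow(traj) == 0) abort("refusing to write an empty trajectory")
  fixed <- c(
    "time_s", "a_um", "c_um", "V_um3", "S_um2", "dr_um", "dz_um",
    "zeta", "xi"
  )
  conc <- sort(grep("^C_.*_mM$", names(traj), value = TRUE))
  press <- c("dP_os_Pa", "dP_imm_Pa")
  extra <- setdiff(names(traj), c(fixed, conc, press))
  cols <- c(fixed, conc, press, sort(extra))
  missing <- setdiff(c(fixed, press), names(traj))
  if (length(missing) > 0) {
    abort(paste("trajectory lacks required columns:", paste(missing, collapse = ", ")))
  }
  fmt <- function(x) trimws(formatC(x, digits = 12, format = "g"))
  body <- do.call(paste, c(lapply(cols, function(cl) fmt(traj[[cl]])), sep = ","))
  readr::write_lines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Run manifest
#'
#' Every command-line run emits exactly one manifest next to its outputs,
#' recording the config hash (MD5 of the file), fixture identifiers, solver
#' tolerances, package version and wall-clock start time.
#'
#' @param config_path Path of the configuration file driving the run (or
#'   `NA` for runs configured on the command line).
#' @param config The resolved [swelling_config()] (optional; supplies solver
#'   tolerances and label).
#' @param fixtures Character vector of fixture identifiers used.
#' @param started POSIXct wall-clock start (defaults to now).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config_path = NA_character_, config = NULL,
                         fixtures = character(0), started = Sys.time()) {
  hash <- if (!is.na(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else {
    NA_character_
  }
  structure(
    list(
      config_path = config_path,
      config_hash = hash,
      fixtures = fixtures,
      solver_tolerances = if (!is.null(config)) {
        list(rtol = config$rtol, atol = config$atol)
      } else {
        NULL
      },
      label = if (!is.null(config)) config$label else NULL,
      package_version = as.character(utils::packageVersion("memswell")),
      wall_start = format(started, "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
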