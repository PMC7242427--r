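#' Write parameter fixtures and scenario presets
#'
#' Emits, into `outdir`:
#'
#' * `table1_imm.yaml` -- a complete configuration carrying the
#'   inner-mitochondrial-membrane rigidity preset digit-for-digit
#'   (`n1 = 4`, `gzz0 = 0.008 dyn/nm`, `g00 = 0.0101 dyn/nm`,
#'   `betaz = 1.6e4`, `beta0 = 1.8e4 um^-4`) together with the permeability
#'   as printed in its source (`3.1e2 ul/min/Pa/um^2`; note this converts to
#'   an unphysically large 5.2e3 m/s/Pa -- see the package vignette).
#' * `table2_shapes.csv` -- the six equilibrium oblate shapes
#'   (0--50 mM): concentration, equatorial and polar semi-axes.
#' * `sweep_10mM.yaml` ... `sweep_50mM.yaml` -- reversible-regime swelling
#'   scenarios (internal NaCl 10--50 mM, external 1 mM, zero-strain Table
#'   rigidities with disruption off, self-similar partition, SI permeability
#'   default).
#' * `pathological_50mM.yaml` -- the same 50 mM drive with the full
#'   disruption law active: the irreversible swelling regime.
#'
#' @param outdir Writable output directory (created if missing).
#' @return Invisibly, the character vector of files written.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create directory '%s'", outdir))
  written <- character(0)

  species50 <- function(conc) {
    list(
      Na = list(inside = sprintf("%g mM", conc), outside = "1 mM"),
      Cl = list(inside = sprintf("%g mM", conc), outside = "1 mM")
    )
  }

  table1 <- list(
    label = "table1_imm",
    shape = list(a = "8 um", c = "2 um"),
    medium = list(temperature = "310 K", species = species50(50)),
    rigidity = list(
      n1 = 4L,
      gzz0 = "0.008 dyn/nm",
      g00 = "0.0101 dyn/nm",
      betaz = "1.6e4 um^-4",
      beta0 = "1.8e4 um^-4"
    ),
    p_w = "3.1e2 ul/min/Pa/um^2",
    time_span = "600 s",
    partition_rule = "self-similar"
  )
  f <- file.path(outdir, "table1_imm.yaml")
  yaml::write_yaml(table1, f)
  written <- c(written, f)

  t2 <- c(
    "concentration_mM,a0_um,c_um",
    "0,8.00,2.00",
    "10,8.20,2.06",
    "20,8.32,2.10",
    "30,8.39,2.13",
    "40,8.47,2.15",
    "50,8.53,2.17"
  )
  f <- file.path(outdir, "table2_shapes.csv")
  readr::write_lines(t2, f)
  written <- c(written, f)

  for (conc in c(10, 20, 30, 40, 50)) {
    cfg <- list(
      label = sprintf("sweep_%dmM", conc),
      shape = list(a = "8 um", c = "2 um"),
      medium = list(temperature = "310 K", species = species50(conc)),
      rigidity = list(
        n1 = 4L,
        gzz0 = "0.008 dyn/nm",
        g00 = "0.0101 dyn/nm",
        betaz = "0 um^-4",
        beta0 = "0 um^-4"
      ),
      p_w = "1e-13 m/s/Pa",
      time_span = "600 s",
      partition_rule = "self-similar",
      solver = list(rtol = 1e-8, atol = 1e-10)
    )
    f <- file.path(outdir, sprintf("sweep_%dmM.yaml", conc))
    yaml::write_yaml(cfg, f)
    written <- c(written, f)
  }

  path50 <- table1
  path50$label <- "pathological_50mM"
  path50$p_w <- "1e-13 m/s/Pa"
  path50$time_span <- "3600 s"
  f <- file.path(outdir, "pathological_50mM.yaml")
  yaml::write_yaml(path50, f)
  written <- c(written, f)

  invisible(written)
}

#' Read the equilibrium-shape fixture
#'
#' Convenience reader for `table2_shapes.csv` as written by
#' [make_fixtures()].
#'
#' @param path Path to the CSV.
#' @return Tibble with `concentration_mM`, `a0_um`, `c_um`.
#' @export
read_shape_table <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      concentration_mM = readr::col_double(),
      a0_um = readr::col_double(),
      c_um = readr::col_double()
    )
  )
}
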