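## ---- explicit unit handling -------------------------------------------------
## Source parameters mix CGS, SI and practical units (dyn/nm, erg, mM,
## ul/min/Pa/um^2 ...).  Config values are therefore "value unit" strings,
## parsed against a fixed table per physical kind; every internal computation
## is SI (concentrations in mM = mol/m^3).

.unit_tables <- list(
  length = c( # canonical: um
    "um" = 1, "nm" = 1e-3, "mm" = 1e3, "m" = 1e6, "cm" = 1e4
  ),
  concentration = c( # canonical: mM (= mol/m^3)
    "mM" = 1, "mmol/L" = 1, "mol/m^3" = 1, "M" = 1e3, "mol/L" = 1e3
  ),
  temperature = c("K" = 1),
  time = c("s" = 1, "ms" = 1e-3, "min" = 60, "h" = 3600),
  rigidity = c( # canonical: N/m
    "N/m" = 1, "dyn/nm" = 1e4, "dyn/cm" = 1e-3, "mN/m" = 1e-3
  ),
  permeability = c( # canonical: m s^-1 Pa^-1
    "m/s/Pa" = 1, "m s^-1 Pa^-1" = 1, "um/s/Pa" = 1e-6,
    ## 1 ul = 1e-9 m^3, 1 min = 60 s, 1 um^2 = 1e-12 m^2
    "ul/min/Pa/um^2" = 1e-9 / 60 / 1e-12, "ul min^-1 Pa^-1 um^-2" = 1e-9 / 60 / 1e-12
  ),
  energy = c("erg" = 1, "J" = 1e7), # canonical: erg
  pressure = c("Pa" = 1, "kPa" = 1e3, "MPa" = 1e6),
  curvature = c("um^-1" = 1, "1/um" = 1, "m^-1" = 1e-6)
)

.default_units <- c(
  length = "um", concentration = "mM", temperature = "K", time = "s",
  rigidity = "dyn/nm", permeability = "m/s/Pa", energy = "erg",
  pressure = "Pa", curvature = "um^-1"
)

#' Parse a "value unit" quantity string
#'
#' Converts a quantity to the package's canonical unit for its physical kind
#' (lengths to um, concentrations to mM, rigidities to N/m, permeabilities to
#' m s^-1 Pa^-1, energies to erg, times to s).  Bare numbers are interpreted
#' in the kind's default unit (um, mM, K, s, dyn/nm, m/s/Pa, erg, Pa).
#'
#' @param x A string like `"0.0101 dyn/nm"`, or a bare number.
#' @param kind One of `"length"`, `"concentration"`, `"temperature"`,
#'   `"time"`, `"rigidity"`, `"permeability"`, `"energy"`, `"pressure"`,
#'   `"curvature"`.
#' @param key Config key name used in error messages.
#' @return Numeric value in the canonical unit of `kind`.
#' @examples
#' parse_quantity("0.0101 dyn/nm", "rigidity") # 101 N/m
#' @export
parse_quantity <- function(x, kind, key = kind) {
  tab <- .unit_tables[[kind]]
  if (is.null(tab)) abort(sprintf("unknown quantity kind '%s'", kind))
  if (is.numeric(x)) {
    return(x * unname(tab[.default_units[[kind]]]))
  }
  if (!is.character(x) || length(x) != 1L) {
    abort(sprintf("config key '%s': expected a number or a 'value unit' string", key))
  }
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(.*?)\\s*$", x))[[1]]
  val <- suppressWarnings(as.numeric(m[2]))
  if (length(m) < 3 || is.na(val)) {
    abort(sprintf("config key '%s': cannot parse quantity '%s'", key, x))
  }
  unit <- gsub("µ", "u", m[3]) # micro sign -> u
  unit <- gsub("·", " ", unit) # centre dot -> space
  unit <- gsub("\\s+", " ", unit)
  if (unit == "") {
    return(val * unname(tab[.default_units[[kind]]]))
  }
  if (kind == "dimensionless") {
    abort(sprintf("config key '%s': unexpected unit '%s'", key, unit))
  }
  ## disruption coefficients: any um^-<n> power passes through unchanged
  if (!is.na(match(unit, names(tab)))) {
    return(val * unname(tab[unit]))
  }
  abort(sprintf(
    "config key '%s': unit '%s' is not recognised for kind '%s' (known: %s)",
    key, unit, kind, paste(names(tab), collapse = ", ")
  ))
}

## beta coefficients carry um^-n1 and are dimensionally tied to n1; accept a
## bare number or "<val> um^-<n>" and return the number unchanged.
.parse_beta <- function(x, key) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(um\\^-[0-9]+|um\\^-n1)?\\s*$", x))[[1]]
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val)) abort(sprintf("config key '%s': cannot parse '%s'", key, x))
  val
}

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    abort(sprintf(
      "unknown config key%s %s in '%s'",
      if (length(extra) > 1) "s" else "",
      paste0("'", extra, "'", collapse = ", "), where
    ))
  }
}

#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) configuration, applies defaults (temperature 310 K,
#' partition rule `"energy-min"`, permeability 1e-13 m/s/Pa, time span 600 s,
#' solver tolerances 1e-8/1e-10, Table-style rigidity preset), parses all
#' "value unit" quantity strings to the internal SI convention, and rejects
#' unknown keys by name.
#'
#' Schema (all quantities as `"value unit"` strings or bare numbers in the
#' default unit):
#' ```yaml
#' shape: {a: "8 um", c: "2 um"}
#' medium:
#'   temperature: "310 K"
#'   species:
#'     Na: {inside: "50 mM", outside: "1 mM"}
#'     Cl: {inside: "50 mM", outside: "1 mM"}
#' rigidity: {g00: "0.0101 dyn/nm", gzz0: "0.008 dyn/nm",
#'            beta0: "1.8e4 um^-4", betaz: "1.6e4 um^-4", n1: 4}
#' p_w: "1e-13 m/s/Pa"
#' time_span: "600 s"
#' solver: {rtol: 1.0e-8, atol: 1.0e-10}
#' partition_rule: energy-min
#' saturation_threshold: 1.0e-8
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A fully resolved [swelling_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  .config_from_list(raw, where = path)
}

.config_from_list <- function(raw, where = "config") {
  .check_keys(raw, c(
    "shape", "medium", "rigidity", "p_w", "time_span", "solver",
    "partition_rule", "saturation_threshold", "n_out", "seed", "label"
  ), where)

  if (is.null(raw$shape)) abort("config requires a 'shape' section")
  .check_keys(raw$shape, c("a", "c"), "shape")
  a <- parse_quantity(raw$shape$a, "length", "shape.a")
  cc <- parse_quantity(raw$shape$c, "length", "shape.c")
  if (!is.finite(a) || a <= 0) abort("config key 'shape.a' must be positive")
  if (!is.finite(cc) || cc <= 0) abort("config key 'shape.c' must be positive")
  shape <- ellipsoid_shape(a, cc)

  if (is.null(raw$medium) || is.null(raw$medium$species)) {
    abort("config requires 'medium.species' (per-species inside/outside concentrations)")
  }
  .check_keys(raw$medium, c("temperature", "species"), "medium")
  temperature <- parse_quantity(
    raw$medium$temperature %||% 310, "temperature", "medium.temperature"
  )
  sp <- raw$medium$species
  c_in <- c_out <- setNames(numeric(length(sp)), names(sp))
  for (nm in names(sp)) {
    .check_keys(sp[[nm]], c("inside", "outside"), paste0("medium.species.", nm))
    c_in[nm] <- parse_quantity(
      sp[[nm]]$inside, "concentration", paste0("medium.species.", nm, ".inside")
    )
    c_out[nm] <- parse_quantity(
      sp[[nm]]$outside, "concentration", paste0("medium.species.", nm, ".outside")
    )
  }
  medium <- medium_state(c_in, c_out, temperature)

  rig_raw <- raw$rigidity %||% list()
  .check_keys(rig_raw, c("g00", "gzz0", "beta0", "betaz", "n1"), "rigidity")
  rigidity <- rigidity_params(
    g00 = parse_quantity(rig_raw$g00 %||% "0.0101 dyn/nm", "rigidity", "rigidity.g00"),
    gzz0 = parse_quantity(rig_raw$gzz0 %||% "0.008 dyn/nm", "rigidity", "rigidity.gzz0"),
    beta0 = .parse_beta(rig_raw$beta0 %||% 1.8e4, "rigidity.beta0"),
    betaz = .parse_beta(rig_raw$betaz %||% 1.6e4, "rigidity.betaz"),
    n1 = rig_raw$n1 %||% 4,
    units = "N/m"
  )

  solver <- raw$solver %||% list()
  .check_keys(solver, c("rtol", "atol"), "solver")

  swelling_config(
    shape = shape, medium = medium, rigidity = rigidity,
    p_w = parse_quantity(raw$p_w %||% 1e-13, "permeability", "p_w"),
    t_span = parse_quantity(raw$time_span %||% 600, "time", "time_span"),
    rtol = solver$rtol %||% 1e-8,
    atol = solver$atol %||% 1e-10,
    partition_rule = raw$partition_rule %||% "energy-min",
    saturation_threshold = raw$saturation_threshold %||% 1e-8,
    n_out = raw$n_out %||% 501,
    label = raw$label
  )
}
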