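## Flux datasets: bundled experimental tables, tabular I/O, unit conversion.

# Required columns of the delimited-text schema, in file order.
.SCHEMA_COLS <- c("tmp_bar", "temperature_K", "c_feed_mol_L",
                  "c_permeate_mol_L", "jv_L_m2_h", "jv_sd_L_m2_h", "series")

# Mapping file column -> internal column name.
.COL_MAP <- c(tmp_bar = "tmp", temperature_K = "temperature",
              c_feed_mol_L = "c_feed", c_permeate_mol_L = "c_permeate",
              jv_L_m2_h = "jv", jv_sd_L_m2_h = "jv_sd", series = "series")

#' Construct a flux dataset
#'
#' A `flux_data` object is a data frame of flux observations with one row per
#' steady-state filtration experiment and columns `tmp` (transmembrane
#' pressure, bar), `temperature` (K), `c_feed` and `c_permeate` (mol/L,
#' tyrosol equivalents), `jv` (permeate flux, L/m2/h), `jv_sd` (flux standard
#' deviation, L/m2/h, may be `NA`) and `series` (free-text label).  Extra
#' columns are preserved.
#'
#' @param x data frame with at least the columns above.
#' @param provenance free-text description of where the rows come from.
#' @return `x` with class `flux_data` and a `provenance` attribute.
#' @examples
#' d <- flux_data(data.frame(tmp = 4.5, temperature = 293.15, c_feed = 0,
#'                           c_permeate = 0, jv = 49.1, jv_sd = 1.0,
#'                           series = "water-I"))
#' @export
flux_data <- function(x, provenance = "user-supplied") {
  x <- as.data.frame(x)
  need <- unname(.COL_MAP)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    skm_stop(sprintf("flux_data is missing column(s): %s",
                     paste(miss, collapse = ", ")), "skm_schema_error")
  if (nrow(x) == 0L)
    skm_stop("flux_data must contain at least one observation",
             "skm_schema_error")
  for (col in c("tmp", "temperature", "c_feed", "c_permeate", "jv", "jv_sd"))
    if (!is.numeric(x[[col]]))
      skm_stop(sprintf("column '%s' must be numeric", col), "skm_schema_error")
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L)
      skm_stop(sprintf("%s in row(s) %s", what, paste(i, collapse = ", ")),
               "skm_schema_error")
  }
  bad(!is.finite(x$tmp) | x$tmp <= 0, "non-positive transmembrane pressure")
  bad(!is.finite(x$temperature) | x$temperature <= 0,
      "non-positive temperature")
  bad(is.finite(x$jv) & x$jv < 0, "negative permeate flux")
  both <- is.finite(x$c_feed) & is.finite(x$c_permeate)
  bad(both & (x$c_permeate < 0 | x$c_permeate > x$c_feed),
      "permeate concentration outside [0, feed concentration]")
  structure(x, provenance = provenance,
            class = c("flux_data", "data.frame"))
}

#' @export
print.flux_data <- function(x, ...) {
  cat(sprintf("Flux dataset: %d observation(s) [%s]\n", nrow(x),
              attr(x, "provenance")))
  print(as.data.frame(x), ...)
  invisible(x)
}

# Read a bundled fixture, keeping the CSV column order stable.
.load_fixture <- function(file, provenance) {
  path <- system.file("extdata", file, package = "skmflux", mustWork = TRUE)
  read_flux_table(path, provenance = provenance)
}

#' Pure-water permeate fluxes of the NF270 membrane
#'
#' Steady-state osmotic-water fluxes measured at three temperatures (293.15,
#' 298.15, 303.15 K) and three transmembrane pressures (4.5, 9.5, 14.5 bar).
#' Series `"I"` characterizes the pristine membrane; series `"II"` repeats the
#' measurement after the membrane had processed wine-lees solutions and been
#' water-cleaned, so the series-II fluxes carry the irreversible fouling.
#'
#' @param series `"I"` (before exposure) or `"II"` (after exposure).
#' @return A [flux_data] with 9 observations; both concentration columns are 0.
#' @examples
#' w <- load_water_fluxes("I")
#' nrow(w)  # 9
#' @export
load_water_fluxes <- function(series = c("I", "II")) {
  series <- match.arg(series)
  d <- .load_fixture("nf270_water_flux.csv",
                     sprintf("NF270 osmotic-water fluxes, series %s", series))
  d <- d[d$series == paste0("water-", series), , drop = FALSE]
  rownames(d) <- NULL
  flux_data(d, attr(d, "provenance"))
}

#' Wine-lees permeate fluxes and concentrations on the NF270 membrane
#'
#' Steady-state permeate fluxes, feed and permeate total-polyphenol
#' concentrations (mol/L tyrosol equivalents) for two feed levels: `"C1"`, the
#' raw pre-filtered lees (around 2036 mg tyrosol eq/L as characterized; the
#' source abstract rounds this to 2100), and `"C2"`, the same stream diluted
#' to roughly half.  C1 spans 4 pressures x 4 temperatures (13 rows, one extra
#' 19.5 bar point); C2 spans 3 pressures x 4 temperatures (12 rows).
#'
#' @param solution `"C1"` (concentrated) or `"C2"` (diluted).
#' @return A [flux_data] with 13 (`C1`) or 12 (`C2`) observations.
#' @examples
#' head(load_lees_dataset("C1"))
#' @export
load_lees_dataset <- function(solution = c("C1", "C2")) {
  solution <- match.arg(solution)
  d <- .load_fixture("nf270_lees_flux.csv",
                     sprintf("NF270 wine-lees fluxes, solution %s", solution))
  d <- d[d$series == solution, , drop = FALSE]
  rownames(d) <- NULL
  flux_data(d, attr(d, "provenance"))
}

#' Tyrosol screening fluxes and rejections of the NF90 membrane
#'
#' Membrane-selection screen run with a 1 g/L tyrosol solution: permeate flux
#' and observed rejection at three temperatures and three pressures.  The
#' tyrosol feed/permeate concentrations were not tabulated, so the
#' concentration columns are `NA` and rejection is carried in the auxiliary
#' columns `rejection_pct` and `rejection_sd_pct`.
#'
#' @return A [flux_data] with 9 observations.
#' @export
load_tyrosol_screening <- function() {
  .load_fixture("nf90_tyrosol_screening.csv",
                "NF90 tyrosol screening fluxes and rejections")
}

#' Convert tyrosol-equivalent concentrations between mg/L and mol/L
#'
#' Total polyphenols are assayed as "mg tyrosol equivalents per litre"; the
#' transport model works in mol/L.  The conversion uses the molar mass of
#' tyrosol, 138.16 g/mol.
#'
#' @param x concentration(s); mg tyrosol eq/L for `mg_to_molar`, mol/L for
#'   `molar_to_mg`.  Must be non-negative.
#' @return Converted concentration(s).
#' @examples
#' mg_to_molar(2036)    # 1.47e-2 mol/L
#' molar_to_mg(1e-3)    # 138.16 mg/L
#' @export
mg_to_molar <- function(x) {
  if (any(is.finite(x) & x < 0))
    skm_stop("concentration must be non-negative", "skm_domain_error")
  x / (1000 * .MW_TYROSOL)
}

#' @rdname mg_to_molar
#' @export
molar_to_mg <- function(x) {
  if (any(is.finite(x) & x < 0))
    skm_stop("concentration must be non-negative", "skm_domain_error")
  x * 1000 * .MW_TYROSOL
}

#' Read / write a flux dataset as delimited text
#'
#' The on-disk schema is a UTF-8 CSV with a header row and columns `tmp_bar`,
#' `temperature_K`, `c_feed_mol_L`, `c_permeate_mol_L`, `jv_L_m2_h`,
#' `jv_sd_L_m2_h`, `series`; additional columns are carried through.  Water
#' records use 0 in both concentration columns.  `write_flux_table` followed
#' by `read_flux_table` is the identity on all numeric fields to at least 12
#' significant digits.
#'
#' @param path file path.
#' @param provenance provenance string attached to the returned dataset.
#' @return `read_flux_table` returns a [flux_data]; `write_flux_table`
#'   invisibly returns `path`.
#' @export
read_flux_table <- function(path, provenance = path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  miss <- setdiff(.SCHEMA_COLS, names(raw))
  if (length(miss) > 0L)
    skm_stop(sprintf("'%s' is missing required column(s): %s", path,
                     paste(miss, collapse = ", ")), "skm_schema_error")
  num_cols <- setdiff(.SCHEMA_COLS, "series")
  out <- raw
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "NA" &
                   nzchar(trimws(raw[[col]])) & is.na(v))
    if (length(bad) > 0L)
      skm_stop(sprintf(
        "non-numeric value '%s' in column '%s', row %d of '%s'",
        raw[[col]][bad[1]], col, bad[1], path), "skm_schema_error")
    out[[col]] <- v
  }
  for (col in setdiff(names(out), .SCHEMA_COLS)) {   # auxiliary columns
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (!any(is.na(v) & !is.na(out[[col]]) & out[[col]] != "NA"))
      out[[col]] <- v
  }
  names(out)[match(names(.COL_MAP), names(out))] <- unname(.COL_MAP)
  flux_data(out, provenance)
}

#' @rdname read_flux_table
#' @param x a [flux_data] (or coercible data frame).
#' @export
write_flux_table <- function(x, path) {
  x <- flux_data(x, provenance = attr(x, "provenance") %||% "user-supplied")
  out <- as.data.frame(x)
  names(out)[match(unname(.COL_MAP), names(out))] <- names(.COL_MAP)
  out <- out[, c(.SCHEMA_COLS, setdiff(names(out), .SCHEMA_COLS)),
             drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA, formatC(v, digits = 15, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Resolve a named bundled dataset
#'
#' Fixture names accepted throughout the pipeline layer:
#' `"table5-series-I"`, `"table5-series-II"` (pure-water fluxes),
#' `"table9-C1"`, `"table9-C2"` (wine-lees fluxes), `"table4-tyrosol"`
#' (membrane screening).  Any other string is treated as a file path in the
#' delimited-text schema.
#'
#' @param name fixture name or path.
#' @return A [flux_data].
#' @export
fixture_dataset <- function(name) {
  switch(name,
    "table5-series-I"  = load_water_fluxes("I"),
    "table5-series-II" = load_water_fluxes("II"),
    "table9-C1"        = load_lees_dataset("C1"),
    "table9-C2"        = load_lees_dataset("C2"),
    "table4-tyrosol"   = load_tyrosol_screening(),
    {
      if (!file.exists(name))
        skm_stop(sprintf(
          "unknown dataset '%s' (not a fixture name and not a file)", name),
          "skm_config_error")
      read_flux_table(name)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
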