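# Long-format CSV readers/writers and configuration files.
#
# Native schema (one row per observation): species, replicate, o2, par, ca,
# ci, pn.  A column_map bridges instrument-style exports (e.g. LI-6400
# headers Photo, CO2S, PARi).

native_columns <- function() {
  list(species = c("species", "Species"),
       replicate = c("replicate", "rep", "Obs"),
       o2 = c("o2", "O2", "o2_fraction"),
       par = c("par", "PARi", "PAR"),
       ca = c("ca", "CO2S", "Ca"),
       ci = c("ci", "Ci", "CO2I"),
       pn = c("pn", "Photo", "A", "Pn"))
}

#' Read a long-format gas-exchange CSV
#'
#' Reads, validates and types a gas-exchange table.  Column names are
#' resolved through a built-in alias list (covering common instrument
#' exports, e.g. `Photo` for `pn`, `CO2S` for `ca`, `PARi` for `par`) which
#' `column_map` can extend or override (`column_map = c(pn = "A_net")`
#' means: the file's column `A_net` holds `pn`).  Oxygen given in percent
#' (values > 1) is normalized to a fraction with a warning.  Rows whose
#' flux or CO2 fields are non-numeric are dropped, with their line numbers
#' reported in a warning.  `ci` is optional; all other native columns are
#' required.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector, names = native
#'   columns, values = file column names.
#' @return Data frame of class `gas_exchange` (columns `species`,
#'   `replicate`, `o2`, `par`, `ca`, `ci`, `pn`).
#' @export
read_gas_exchange_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!nrow(raw) || !ncol(raw)) stop_domain("empty gas-exchange file: ", path)

  aliases <- native_columns()
  if (!is.null(column_map)) {
    for (nm in names(column_map)) aliases[[nm]] <- c(column_map[[nm]],
                                                     aliases[[nm]])
  }
  resolve <- function(field) {
    hit <- aliases[[field]][aliases[[field]] %in% names(raw)]
    if (length(hit)) hit[1L] else NA_character_
  }
  found <- vapply(names(aliases), resolve, "")
  required <- setdiff(names(aliases), "ci")
  miss <- required[is.na(found[required])]
  if (length(miss))
    stop_domain("missing required column(s): ",
                paste(sprintf("%s (candidates: %s)", miss,
                              vapply(aliases[miss], paste, "",
                                     collapse = ", ")),
                      collapse = "; "))

  out <- data.frame(species = as.character(raw[[found["species"]]]),
                    replicate = raw[[found["replicate"]]],
                    stringsAsFactors = FALSE)
  numfields <- c("o2", "par", "ca", "pn",
                 if (!is.na(found["ci"])) "ci")
  bad <- rep(FALSE, nrow(raw))
  for (f in numfields) {
    v <- raw[[found[f]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- bad | (!is.na(v) & v != "" & is.na(num))
    out[[f]] <- num
  }
  if (is.na(found["ci"])) out$ci <- NA_real_
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with non-numeric fields (lines ",
            paste(which(bad) + 1L, collapse = ", "), ")")
    out <- out[!bad, , drop = FALSE]
  }
  if (!nrow(out)) stop_domain("no usable rows in ", path)
  if (any(out$o2 > 1, na.rm = TRUE)) {
    warning("'o2' looks like percent; normalizing to a fraction")
    out$o2 <- ifelse(out$o2 > 1, out$o2 / 100, out$o2)
  }
  out <- out[, c("species", "replicate", "o2", "par", "ca", "ci", "pn")]
  rownames(out) <- NULL
  structure(out, class = c("gas_exchange", "data.frame"))
}

#' Write a gas-exchange dataset to CSV at full precision
#'
#' Numeric fields are written with 17 significant digits so a subsequent
#' [read_gas_exchange_csv()] reproduces every value exactly ('.' decimal
#' separator, UTF-8, no locale drift).
#'
#' @param data Gas-exchange data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange_csv <- function(data, path) {
  out <- as.data.frame(data)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file may set any [sim_config()] argument; `species` entries are
#' lists of [species_profile()] arguments.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$species)) {
    cfg$species <- lapply(seq_along(cfg$species), function(i) {
      args <- as.list(cfg$species[[i]])
      if (is.null(args$name)) args$name <- names(cfg$species)[i]
      do.call(species_profile, args)
    })
  }
  if (!is.null(cfg$ca_levels)) cfg$ca_levels <- as.numeric(cfg$ca_levels)
  do.call(sim_config, cfg)
}
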