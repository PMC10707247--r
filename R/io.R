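# Structured-text IO: model configuration (YAML), audiogram and curve CSV
# dialects, scenario serialization. All writers embed a comment header with
# the tool version, config hash and seed so outputs are traceable.

AUDIOGRAM_HEADER <- "frequency_hz,air_db_hl,bone_db_hl,ear"
CURVE_HEADER <- "frequency_hz,value"

#' Path to the shipped calibrated normal-ear configuration
#'
#' @return File path of the frozen, calibration-stamped YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "normal_ear.yaml", package = "earmech", mustWork = TRUE)
}

#' Read and validate a model configuration
#'
#' @param path Path to a YAML model configuration with sections `materials`,
#'   `nodes`, `elements`, `inertias`, `drive`, `footplate`, `cochlea`,
#'   `frequency_grid`.
#' @return The parsed configuration list (attribute `path` records the
#'   source file).
#' @export
read_model_config <- function(path) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    abort_config(sprintf("configuration file not found: '%s'", path))
  }
  config <- yaml::read_yaml(path)
  validate_model_config(config)
  attr(config, "path") <- path
  config
}

#' Validate a model configuration list against the schema
#'
#' Checks the presence and basic shape of every section; detailed physical
#' invariants (positive moduli, connectivity, ...) are enforced when the model
#' is built.
#'
#' @param config A configuration list.
#' @return The configuration, invisibly.
#' @export
validate_model_config <- function(config) {
  if (!is.list(config)) abort_config("configuration must be a list")
  required <- c("materials", "nodes", "elements", "inertias", "drive",
                "footplate", "cochlea")
  for (sec in required) {
    if (is.null(config[[sec]])) {
      abort_config(sprintf("configuration is missing section '%s'", sec))
    }
  }
  sections <- list(
    materials = c("name", "young_modulus", "density"),
    nodes = c("id", "position", "dofs"),
    elements = c("id", "node_a", "node_b", "material", "area", "length"),
    inertias = c("body", "mass", "nodes")
  )
  for (sec in names(sections)) {
    entries <- config[[sec]]
    if (!is.list(entries) || !length(entries)) {
      abort_config(sprintf("section '%s' must be a non-empty list", sec))
    }
    for (j in seq_along(entries)) {
      missing <- setdiff(sections[[sec]], names(entries[[j]]))
      if (length(missing)) {
        abort_config(sprintf("section '%s', entry %d: missing field(s) %s",
                             sec, j, paste(missing, collapse = ", ")))
      }
    }
  }
  if (!is.null(config$frequency_grid) &&
      (!is.numeric(unlist(config$frequency_grid)) ||
       !length(unlist(config$frequency_grid)))) {
    abort_config("'frequency_grid' must be a numeric list of frequencies in Hz")
  }
  invisible(config)
}

#' MD5 hash of a configuration file
#'
#' @param path Configuration file path (or an object with a `path` attribute).
#' @return The hash string, or `NA` when no file backs the configuration.
#' @export
config_hash <- function(path) {
  if (!is.character(path)) path <- attr(path, "path") %||% NA_character_
  if (is.na(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

output_header_lines <- function(seed = NULL, hash = NULL) {
  c(sprintf("# earmech %s", as.character(utils::packageVersion("earmech"))),
    sprintf("# config_hash=%s seed=%s",
            hash %||% NA_character_,
            if (is.null(seed)) "NA" else format(seed)))
}

num_fmt <- function(x) trimws(formatC(x, digits = 12, format = "g"))

#' Read a measured audiogram from CSV
#'
#' The dialect is one row per frequency with header exactly
#' `frequency_hz,air_db_hl,bone_db_hl,ear`; the bone column may be empty;
#' comment lines start with `#`. Frequencies must be strictly increasing
#' (duplicates are reported with their row number).
#'
#' @param path CSV file path.
#' @return An [audiogram()].
#' @export
read_audiogram_csv <- function(path) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    abort_data(sprintf("audiogram file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) abort_format("audiogram file is empty")
  header <- trimws(lines[1])
  if (!identical(header, AUDIOGRAM_HEADER)) {
    abort_format(sprintf("malformed audiogram header: got \"%s\", expected \"%s\"",
                         header, AUDIOGRAM_HEADER))
  }
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  if (!nrow(df)) abort_data("audiogram file has no data rows")
  dup <- which(duplicated(df$frequency_hz))
  if (length(dup)) {
    abort_data(sprintf("duplicated frequency %g Hz at data row %d",
                       df$frequency_hz[dup[1]], dup[1]))
  }
  notinc <- which(diff(df$frequency_hz) <= 0)
  if (length(notinc)) {
    abort_data(sprintf("frequencies not increasing at data row %d", notinc[1] + 1L))
  }
  bone <- df$bone_db_hl
  if (all(is.na(bone))) {
    bone <- NULL
  } else if (anyNA(bone)) {
    abort_data("bone-conduction column must be entirely present or entirely empty")
  }
  ear <- unique(df$ear)
  if (length(ear) != 1L || !ear %in% c("left", "right")) {
    abort_data("'ear' column must be a single value, 'left' or 'right'")
  }
  audiogram(df$frequency_hz, df$air_db_hl, bone, ear = ear)
}

#' Write an audiogram to CSV
#'
#' @param path Output file path.
#' @param aud An [audiogram()].
#' @param seed,hash Optional provenance recorded in the comment header.
#' @return The path, invisibly.
#' @export
write_audiogram_csv <- function(path, aud, seed = NULL, hash = NULL) {
  stopifnot(inherits(aud, "ear_audiogram"))
  bone <- aud$bone_db_hl
  rows <- paste(num_fmt(aud$frequencies), num_fmt(aud$air_db_hl),
                if (is.null(bone)) "" else num_fmt(bone),
                aud$ear, sep = ",")
  writeLines(c(output_header_lines(seed, hash), AUDIOGRAM_HEADER, rows), path)
  invisible(path)
}

#' Write a transmission or loss curve to CSV
#'
#' Curves are written in the dialect `frequency_hz,value` with a comment
#' header recording tool version, config hash and seed.
#'
#' @param path Output file path.
#' @param curve An `ear_loss_curve`, a transmission curve, or any data.frame
#'   with `frequency_hz` plus one value column.
#' @param seed,hash Optional provenance recorded in the comment header.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(path, curve, seed = NULL, hash = NULL) {
  if (is.data.frame(curve) && "vsf_abs" %in% names(curve)) {
    f <- curve$frequency_hz; v <- curve$vsf_abs
  } else {
    cv <- curve_values(curve)
    f <- cv$f; v <- cv$v
  }
  rows <- paste(num_fmt(f), num_fmt(v), sep = ",")
  writeLines(c(output_header_lines(seed, hash), CURVE_HEADER, rows), path)
  invisible(path)
}

#' Read a curve CSV written by [write_curve_csv()]
#'
#' @param path CSV file path.
#' @return Data.frame with `frequency_hz`, `value`.
#' @export
read_curve_csv <- function(path) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    abort_data(sprintf("curve file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines) || !identical(trimws(lines[1]), CURVE_HEADER)) {
    abort_format(sprintf("malformed curve header: got \"%s\", expected \"%s\"",
                         if (length(lines)) trimws(lines[1]) else "",
                         CURVE_HEADER))
  }
  utils::read.csv(text = lines)
}

# -- scenario serialization ---------------------------------------------------

mod_to_list <- function(m) {
  params <- lapply(m$params, function(p) {
    if (inherits(p, "ear_viscoelastic")) {
      list(e_inf = p$e_inf, e = as.list(p$e), tau = as.list(p$tau))
    } else p
  })
  list(variant = m$variant, params = params)
}

mod_from_list <- function(x) {
  params <- x$params %||% list()
  if (identical(x$variant, "monopod_stapes") && is.list(params$crus_spec)) {
    cs <- params$crus_spec
    params$crus_spec <- viscoelastic_spec(cs$e_inf, as.numeric(unlist(cs$e)),
                                          as.numeric(unlist(cs$tau)))
  }
  do.call(modification, c(list(variant = x$variant), params))
}

#' Write a pathology scenario to YAML
#'
#' The scenario dialect is a `scenario:` block with `name`, `provenance` and a
#' `modifications:` list; [read_scenario_yaml()] round-trips it losslessly.
#'
#' @param path Output file path.
#' @param scenario An [pathology_scenario()].
#' @return The path, invisibly.
#' @export
write_scenario_yaml <- function(path, scenario) {
  stopifnot(inherits(scenario, "ear_scenario"))
  obj <- list(scenario = list(
    name = scenario$name,
    provenance = scenario$provenance,
    modifications = lapply(scenario$modifications, mod_to_list)
  ))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a pathology scenario from YAML
#'
#' @param path Scenario YAML path.
#' @return An [pathology_scenario()].
#' @export
read_scenario_yaml <- function(path) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    abort_data(sprintf("scenario file not found: '%s'", path))
  }
  obj <- yaml::read_yaml(path)
  if (!is.list(obj$scenario)) abort_format("scenario file must contain a 'scenario:' block")
  sc <- obj$scenario
  pathology_scenario(sc$name,
                     lapply(sc$modifications, mod_from_list),
                     provenance = sc$provenance %||% "")
}
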