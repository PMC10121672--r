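#' Write and read trial CSVs
#'
#' One CSV per trial with a header row and the column convention
#' `time_s, angle_deg, torque_Nm, emg_sol_mV, emg_gl_mV, emg_ta_mV,
#' fascicle_cm` (units encoded in the column-name suffix; sparse fascicle
#' rows are empty fields, parsed back as missing, not zero).  Metadata is
#' written to a JSON sidecar next to the CSV.
#'
#' @param trial An `invivo_trial`.
#' @param file Path of the CSV file.
#' @return `write_trial_csv()`: the file path, invisibly;
#'   `read_trial_csv()`: the reconstructed `invivo_trial`.
#' @export
write_trial_csv <- function(trial, file) {
  stopifnot(inherits(trial, "invivo_trial"))
  write.csv(trial$data, file, row.names = FALSE, na = "")
  jsonlite::write_json(trial$meta, .sidecar(file), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

.sidecar <- function(file) paste0(sub("\\.csv$", "", file), ".json")

#' @rdname write_trial_csv
#' @param file Path of the CSV file (a `.json` sidecar with the same stem
#'   is read when present).
#' @export
read_trial_csv <- function(file) {
  d <- read.csv(file, check.names = FALSE)
  required <- c("time_s", "angle_deg", "torque_Nm")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("input error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.unsorted(d$time_s, strictly = TRUE)) {
    stop("input error: time must be strictly increasing")
  }
  meta <- if (file.exists(.sidecar(file))) {
    jsonlite::read_json(.sidecar(file), simplifyVector = TRUE)
  } else {
    list(fs = round(1 / median(diff(d$time_s))), kind = "shortening",
         omega_setting = NA_real_)
  }
  structure(list(data = d, meta = meta), class = "invivo_trial")
}

#' Write a table as locale-independent CSV
#'
#' @param x A data.frame.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(x, file) {
  write.csv(x, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Read and validate a run configuration
#'
#' JSON configuration with the recognized top-level blocks
#' `architecture`, `path`, `curves`, `protocol`, `design`, `invivo`,
#' `synth`, `output_dir`, `log_level`, `seed`.  Unknown keys are rejected
#' by name.
#'
#' @param file Path to a JSON configuration file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  known <- c("architecture", "path", "curves", "protocol", "design",
             "invivo", "synth", "output_dir", "log_level", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("schema error: unknown configuration key(s): ",
         paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Write a run manifest
#'
#' Echoes the fully resolved configuration to JSON next to the outputs and
#' records a content hash, so a run is reproducible from its manifest
#' alone.
#'
#' @param config A `run_config` (or plain list).
#' @param file Output path for the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, file) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(tmp)),
                   package = "mtusim",
                   version = as.character(utils::packageVersion("mtusim")))
  unlink(tmp)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
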