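# Readers and writers for the plain-text dialects, flat key=value configs,
# and machine-readable provenance records. Canonical dialect: UTF-8
# comma-separated text with a one-line header, decimal point, no
# locale-dependent formatting.

#' Read a long-format plate tolerance table
#'
#' Columns: `strain, metal, day, conc_g_per_L, replicate, diameter_mm`.
#' Control rows have `conc_g_per_L = 0`.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) ms_stop(paste("no such file:", path), "parse_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   ms_stop(paste("cannot parse plate table:",
                                 conditionMessage(e)), "parse_error")
                 })
  required <- c("strain", "metal", "day", "conc_g_per_L", "replicate",
                "diameter_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    ms_stop(paste("plate table missing columns:",
                  paste(missing_cols, collapse = ", ")), "parse_error")
  }
  bad <- which(!is.finite(df$conc_g_per_L) | df$conc_g_per_L < 0 |
                 !is.finite(df$diameter_mm) | df$diameter_mm < 0)
  if (length(bad) > 0) {
    ms_stop(sprintf("malformed plate rows (line %s): negative or non-numeric values",
                    paste(bad + 1L, collapse = ", ")), "parse_error")
  }
  df[required]
}

#' Write a plate tolerance table
#'
#' @param plates data frame in the [read_plate_table()] layout.
#' @param path destination; refuses to overwrite unless `overwrite = TRUE`.
#' @param overwrite allow replacing an existing file.
#' @export
write_plate_table <- function(plates, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    ms_stop(paste(path, "exists; pass overwrite = TRUE"), "config_error")
  }
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a tolerance dataset to plate-table rows
#'
#' @param dataset a [tolerance_dataset()].
#' @return data frame in the [read_plate_table()] layout (controls at
#'   `conc_g_per_L = 0`).
#' @export
plate_rows <- function(dataset) {
  stopifnot(inherits(dataset, "tolerance_dataset"))
  trt <- data.frame(strain = dataset$strain, metal = dataset$metal,
                    day = dataset$day,
                    conc_g_per_L = dataset$records$conc,
                    replicate = stats::ave(dataset$records$conc,
                                           dataset$records$conc,
                                           FUN = seq_along),
                    diameter_mm = dataset$records$diameter,
                    stringsAsFactors = FALSE)
  ctl <- data.frame(strain = dataset$strain, metal = dataset$metal,
                    day = dataset$day, conc_g_per_L = 0,
                    replicate = seq_along(dataset$control),
                    diameter_mm = dataset$control,
                    stringsAsFactors = FALSE)
  rbind(ctl, trt)
}

#' Write a batch sorption experiment file
#'
#' Metadata header lines (`# key: value` for label, metal, C0_mg_per_L, V_L,
#' Ma_g, detection_limit_mg_per_L) followed by CSV rows
#' `time_min,replicate,ct_mg_per_L,censored`; censored values are written as
#' the literal detection bound with the flag set.
#'
#' @param x a [batch_sorption()] object.
#' @inheritParams write_plate_table
#' @export
write_batch_sorption <- function(x, path, overwrite = FALSE) {
  stopifnot(inherits(x, "batch_sorption"))
  if (file.exists(path) && !overwrite) {
    ms_stop(paste(path, "exists; pass overwrite = TRUE"), "config_error")
  }
  meta <- c(
    sprintf("# label: %s", x$label),
    sprintf("# metal: %s", x$metal),
    sprintf("# C0_mg_per_L: %.15g", x$C0),
    sprintf("# V_L: %.15g", x$V),
    sprintf("# Ma_g: %.15g", x$Ma),
    sprintf("# detection_limit_mg_per_L: %.15g", x$detection_limit),
    "time_min,replicate,ct_mg_per_L,censored"
  )
  rows <- sprintf("%.15g,%s,%.15g,%s", x$data$time, x$data$replicate,
                  x$data$ct, ifelse(x$data$censored, "TRUE", "FALSE"))
  writeLines(c(meta, rows), path)
  invisible(path)
}

#' Read a batch sorption experiment file
#'
#' @param path file written by [write_batch_sorption()].
#' @return a [batch_sorption()] object; `parse(write(x))` equals `x`.
#' @export
read_batch_sorption <- function(path) {
  if (!file.exists(path)) ms_stop(paste("no such file:", path), "parse_error")
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  required <- c("label", "metal", "C0_mg_per_L", "V_L", "Ma_g",
                "detection_limit_mg_per_L")
  if (!all(required %in% names(meta))) {
    ms_stop(paste("batch file missing metadata:",
                  paste(setdiff(required, names(meta)), collapse = ", ")),
            "parse_error")
  }
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) ms_stop(paste("cannot parse batch rows:",
                                      conditionMessage(e)), "parse_error")
  )
  if (!all(c("time_min", "replicate", "ct_mg_per_L", "censored") %in% names(df))) {
    ms_stop("batch file rows must have columns time_min,replicate,ct_mg_per_L,censored",
            "parse_error")
  }
  batch_sorption(
    label = meta$label, metal = meta$metal,
    C0 = as.numeric(meta$C0_mg_per_L), V = as.numeric(meta$V_L),
    Ma = as.numeric(meta$Ma_g),
    time = df$time_min, ct = df$ct_mg_per_L, replicate = df$replicate,
    censored = as.logical(df$censored),
    detection_limit = as.numeric(meta$detection_limit_mg_per_L)
  )
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values parseable as numbers are coerced; `true`/`false` become logical.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ms_stop(paste("no such file:", path), "config_error")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      ms_stop(paste("malformed config line (expected key = value):", ln),
              "config_error")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else val
  }
  out
}

#' Write a machine-readable provenance record
#'
#' JSON record of inputs, seed, tolerances and package version, so every
#' pipeline run can be traced and reproduced.
#'
#' @param path destination `.json` path.
#' @param inputs named list (or character vector) of input identifiers.
#' @param seed the run seed (or NULL for deterministic runs).
#' @param tolerances named list of numeric tolerances in force.
#' @param extra optional named list of further fields.
#' @return the path, invisibly.
#' @export
write_provenance <- function(path, inputs = list(), seed = NULL,
                             tolerances = list(), extra = list()) {
  rec <- c(list(
    package = "mycosorb",
    version = as.character(utils::packageVersion("mycosorb")),
    inputs = inputs,
    seed = seed,
    tolerances = tolerances
  ), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
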