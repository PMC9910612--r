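## Delimited-text I/O: CSV bodies with '#'-prefixed metadata header lines.
## One dialect per dataset kind; columns are matched by name so column
## order never matters.

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

write_meta_csv <- function(df, meta, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta)) {
    v <- meta[[nm]]
    writeLines(sprintf("# %s: %s",
                       nm, if (is.numeric(v)) fmt_num(v) else as.character(v)),
               con)
  }
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, fmt_num), sep = ","))
  writeLines(body, con)
}

read_meta_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop_input(sprintf("parse error in '%s': no data rows found", path))
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e)
      stop_input(sprintf("parse error in '%s': %s", path, conditionMessage(e))))
  list(meta = meta, data = df)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_input(sprintf("file '%s' is missing required column(s): %s",
                       path, paste(missing, collapse = ", ")))
  invisible(df)
}

#' Write a dataset to delimited text
#'
#' Writes Z-spectra, relaxation series and DOSY datasets as CSV with
#' `#`-prefixed metadata header lines. The round trip through
#' [read_table()] is lossless to at least 12 significant digits.
#'
#' @param x A [zspectrum()], [dosy_dataset()], or relaxation series data
#'   frame with columns `temperature_K`, `R1`, `R2`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.zspectrum <- function(x, path) {
  write_meta_csv(data.frame(offset_hz = x$offset_hz, z = x$z),
                 list(kind = "zspectrum",
                      temperature_K = attr(x, "temperature_K"),
                      nutation_hz = attr(x, "nutation_hz"),
                      duration_s = attr(x, "duration_s")),
                 path)
  invisible(path)
}

#' @export
write_table.dosy_dataset <- function(x, path) {
  write_meta_csv(data.frame(gradient_T_per_m = x$gradients,
                            intensity = x$intensities),
                 list(kind = "dosy",
                      gamma = x$gamma,
                      delta_small_s = x$delta_small,
                      delta_big_s = x$delta_big,
                      temperature_K = x$temperature),
                 path)
  invisible(path)
}

#' @export
write_table.data.frame <- function(x, path) {
  require_columns(x, c("temperature_K", "R1", "R2"), "<relaxation series>")
  write_meta_csv(x[c("temperature_K", "R1", "R2")],
                 list(kind = "relaxation"), path)
  invisible(path)
}

#' Read a dataset written by [write_table()]
#'
#' @param path File path.
#' @param kind One of `"zspectrum"`, `"relaxation"`, `"dosy"`.
#' @return The corresponding object: a [zspectrum()], a data frame with
#'   columns `temperature_K`, `R1`, `R2`, or a [dosy_dataset()].
#' @export
read_table <- function(path, kind = c("zspectrum", "relaxation", "dosy")) {
  kind <- match.arg(kind)
  parsed <- read_meta_csv(path)
  df <- parsed$data
  meta <- parsed$meta
  switch(kind,
    zspectrum = {
      require_columns(df, c("offset_hz", "z"), path)
      df <- df[order(df$offset_hz), ]
      zspectrum(df$offset_hz, df$z,
                temperature = meta$temperature_K %||% NA_real_,
                nutation = meta$nutation_hz %||% NA_real_,
                duration = meta$duration_s %||% NA_real_)
    },
    relaxation = {
      require_columns(df, c("temperature_K", "R1", "R2"), path)
      df[order(df$temperature_K), c("temperature_K", "R1", "R2")]
    },
    dosy = {
      require_columns(df, c("gradient_T_per_m", "intensity"), path)
      df <- df[order(df$gradient_T_per_m), ]
      dosy_dataset(df$gradient_T_per_m, df$intensity,
                   gamma = meta$gamma %||% GAMMA_31P,
                   delta_small = meta$delta_small_s,
                   delta_big = meta$delta_big_s,
                   temperature = meta$temperature_K %||% NA_real_)
    })
}
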