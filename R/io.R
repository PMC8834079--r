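#' Read kinetic traces from a delimited text file
#'
#' The expected layout is one sample per row with a time column and a value
#' column, plus optional `channel`, `group` and `replicate` columns that
#' split the file into traces. CSV and TSV are auto-detected from the file
#' extension. The time unit of the file must be declared through `dialect`
#' (`time_unit = "us"` or `"ms"`); times are converted to microseconds
#' internally.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param dialect A list created by [trace_dialect()] declaring the time
#'   unit and column names.
#' @return A list of [kinetic_trace()] objects in file order.
#' @seealso [write_traces()] for the inverse operation.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("t_ms,pf", "0.02,500", "2,1500", "300,2500",
#'              "301,2500", "302,2500", "303,2500", "304,2500",
#'              "305,2500", "306,2500", "307,2500"), f)
#' tr <- read_traces(f, trace_dialect(time_unit = "ms", time_col = "t_ms",
#'                                    value_col = "pf"))
#' tr[[1]]$times[1:3]  # 20, 2000, 300000 us
#' @export
read_traces <- function(path, dialect = trace_dialect()) {
  df <- read_delimited(path)
  for (col in c(dialect$time_col, dialect$value_col)) {
    if (!col %in% names(df)) {
      ojip_abort(sprintf("column '%s' missing from %s", col, path),
                 "ojip_schema_error")
    }
  }
  if (!dialect$channel_col %in% names(df)) {
    ojip_warn(sprintf("no '%s' column in %s; assuming channel %s",
                      dialect$channel_col, path, dialect$default_channel),
              "ojip_missing_channel_warning")
    df[[dialect$channel_col]] <- dialect$default_channel
  }
  if (!dialect$group_col %in% names(df)) df[[dialect$group_col]] <- "NA"
  if (!dialect$replicate_col %in% names(df)) df[[dialect$replicate_col]] <- "r1"

  tfac <- switch(dialect$time_unit, us = 1, ms = 1e3,
                 ojip_abort("time_unit must be 'us' or 'ms'",
                            "ojip_config_error"))
  times <- suppressWarnings(as.numeric(df[[dialect$time_col]]))
  values <- suppressWarnings(as.numeric(df[[dialect$value_col]]))
  if (anyNA(times) || anyNA(values)) {
    row <- which(is.na(times) | is.na(values))[1L]
    ojip_abort(sprintf("non-numeric time or value at data row %d of %s",
                       row, path), "ojip_format_error")
  }

  key <- paste(df[[dialect$channel_col]], df[[dialect$group_col]],
               df[[dialect$replicate_col]], sep = "\r")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    dt <- diff(times[i])
    if (any(dt <= 0)) {
      ojip_abort(sprintf(
        "time column not strictly increasing at data row %d of %s",
        i[which(dt <= 0)[1L] + 1L], path), "ojip_format_error")
    }
    kinetic_trace(times[i] * tfac, values[i],
                  channel = as.character(df[[dialect$channel_col]][i[1L]]),
                  group = df[[dialect$group_col]][i[1L]],
                  replicate = df[[dialect$replicate_col]][i[1L]])
  })
}

#' Trace file dialect
#'
#' Declares how a delimited trace file maps onto [kinetic_trace()] fields.
#' The native dialect written by [write_traces()] is the default:
#' header `time_us,value,channel,group,replicate`, times in microseconds.
#'
#' @param time_unit `"us"` (default) or `"ms"`; unit of the time column.
#' @param time_col,value_col,channel_col,group_col,replicate_col Column
#'   names in the file.
#' @param default_channel Channel assumed when the channel column is
#'   absent; a warning is emitted in that case.
#' @return A named list of dialect settings.
#' @export
trace_dialect <- function(time_unit = c("us", "ms"), time_col = "time_us",
                          value_col = "value", channel_col = "channel",
                          group_col = "group", replicate_col = "replicate",
                          default_channel = "PF") {
  list(time_unit = match.arg(time_unit), time_col = time_col,
       value_col = value_col, channel_col = channel_col,
       group_col = group_col, replicate_col = replicate_col,
       default_channel = default_channel)
}

#' Write kinetic traces to a delimited text file
#'
#' Writes the native dialect (`time_us,value,channel,group,replicate`, UTF-8,
#' `.` decimal separator) with times at full double precision so that
#' `read_traces(write_traces(x))` reproduces `x` exactly.
#'
#' @param traces Non-empty list of [kinetic_trace()] objects.
#' @param path Output path; `.csv` or `.tsv` selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (is_kinetic_trace(traces)) traces <- list(traces)
  if (length(traces) == 0L) {
    ojip_abort("no traces to write", "ojip_validation_error")
  }
  stopifnot(all(vapply(traces, is_kinetic_trace, logical(1))))
  df <- do.call(rbind, lapply(traces, as.data.frame))
  # 17 significant digits round-trips doubles exactly
  df$time_us <- sprintf("%.17g", df$time_us)
  df$value <- sprintf("%.17g", df$value)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pigment-assay absorbance table
#'
#' Expects the header
#' `a_chl_a,a_chl_b,a_470,volume_ml,mass_g,group,replicate`: the two red-peak
#' chlorophyll absorbances (wavelengths depend on the solvent dialect used
#' downstream), the 470 nm carotenoid absorbance, extract volume in mL and
#' fresh mass in g.
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @return A data frame with one validated record per row.
#' @export
read_absorbances <- function(path) {
  df <- read_delimited(path)
  needed <- c("a_chl_a", "a_chl_b", "a_470", "volume_ml", "mass_g")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    ojip_abort(sprintf("column(s) %s missing from %s",
                       paste0("'", missing, "'", collapse = ", "), path),
               "ojip_schema_error")
  }
  if (!"group" %in% names(df)) df$group <- "NA"
  if (!"replicate" %in% names(df)) df$replicate <- as.character(seq_len(nrow(df)))
  for (col in needed) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]])) {
      ojip_abort(sprintf("non-numeric entry in column '%s' of %s", col, path),
                 "ojip_format_error")
    }
  }
  validate_absorbances(df)
  df[, c(needed, "group", "replicate")]
}

validate_absorbances <- function(df) {
  if (any(df$a_chl_a < 0 | df$a_chl_b < 0 | df$a_470 < 0)) {
    ojip_abort("absorbances must be non-negative", "ojip_validation_error")
  }
  if (any(df$volume_ml <= 0)) {
    ojip_abort("extract volume must be positive", "ojip_validation_error")
  }
  if (any(df$mass_g <= 0)) {
    ojip_abort("fresh mass must be positive", "ojip_validation_error")
  }
  invisible(df)
}

#' Write an absorbance table
#'
#' @param records Data frame as returned by [read_absorbances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_absorbances <- function(records, path) {
  validate_absorbances(records)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_delimited <- function(path) {
  if (!file.exists(path)) {
    ojip_abort(sprintf("file not found: %s", path), "ojip_io_error")
  }
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", strip.white = TRUE,
                    fileEncoding = "UTF-8")
}
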