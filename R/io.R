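# Delimited-text readers and writers for trace and current-record tables.
# Comma or tab dialect is auto-detected from the header line. All numeric
# columns carry explicit unit suffixes (time_s, value_au, voltage_mv,
# current_pa) to keep pS/nS and s/min confusions out of configs.

detect_sep <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 50)
  header <- header[!startsWith(header, "#")][1]
  if (is.na(header)) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_checked <- function(path, required) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in required) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                   path, col, bad[1]), call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read fluorescence traces from a delimited table
#'
#' Expects columns `time_s` and `value_au`, with optional `roi` (one trace
#' per ROI, long format) and `genotype`. Comma- or tab-separated, detected
#' from the header; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param background Scalar background fluorescence f0 (a.u.) applied to all
#'   traces in the file (measured in a cell-free region of the recording).
#' @param genotype Group label applied when the table has no `genotype`
#'   column.
#' @return A list of [fluorescence_trace()] objects, named by ROI.
#' @export
read_trace_table <- function(path, background = 0,
                             genotype = NA_character_) {
  df <- read_delim_checked(path, c("time_s", "value_au"))
  if (!"roi" %in% names(df)) df$roi <- "roi1"
  out <- lapply(split(seq_len(nrow(df)), df$roi), function(rows) {
    sub <- df[rows, ]
    if (any(diff(sub$time_s) <= 0)) {
      bad <- rows[which(diff(sub$time_s) <= 0)[1] + 1]
      stop(sprintf("%s: non-increasing time_s at data row %d (roi '%s')",
                   path, bad, sub$roi[1]), call. = FALSE)
    }
    gt <- if ("genotype" %in% names(sub)) sub$genotype[1] else genotype
    fluorescence_trace(sub$time_s, sub$value_au, background = background,
                       label = as.character(sub$roi[1]), genotype = gt)
  })
  out[order(names(out))]
}

#' Write fluorescence traces to a delimited table
#'
#' Long format with columns `roi`, `genotype`, `time_s`, `value_au`.
#'
#' @param traces A [fluorescence_trace()] or list of them.
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path, sep = ",") {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(roi = tr$label, genotype = tr$genotype,
               time_s = tr$times, value_au = tr$values)
  }))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voltage-ramp record
#'
#' Expects columns `time_s`, `voltage_mv`, `current_pa`.
#'
#' @param path File path.
#' @return A [ramp_record()].
#' @export
read_ramp_table <- function(path) {
  df <- read_delim_checked(path, c("time_s", "voltage_mv", "current_pa"))
  if (any(diff(df$time_s) <= 0)) {
    stop(sprintf("%s: non-increasing time_s at data row %d", path,
                 which(diff(df$time_s) <= 0)[1] + 1), call. = FALSE)
  }
  ramp_record(df$time_s, df$voltage_mv, df$current_pa)
}

#' Read a constant-voltage single-channel record
#'
#' Expects columns `time_s` and `current_pa`. The holding voltage is taken
#' from the `holding_mv` argument or, failing that, from a header comment of
#' the form `# holding_mv: -70`.
#'
#' @param path File path.
#' @param holding_mv Holding voltage (mV); overrides any header value.
#' @return A [unitary_record()].
#' @export
read_unitary_table <- function(path, holding_mv = NULL) {
  if (is.null(holding_mv)) {
    hdr <- grep("^#\\s*holding_mv\\s*:", readLines(path, n = 20),
                value = TRUE)
    if (length(hdr)) {
      holding_mv <- as.numeric(sub("^#\\s*holding_mv\\s*:\\s*", "", hdr[1]))
    }
  }
  if (is.null(holding_mv) || is.na(holding_mv)) {
    stop("holding voltage not supplied and not found in header", call. = FALSE)
  }
  df <- read_delim_checked(path, c("time_s", "current_pa"))
  unitary_record(df$time_s, df$current_pa, holding_mv)
}
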