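# Plain-text readers/writers for traces, spike trains, spectra and
# continuation branches (tab-separated; the formats the command-line
# entry point exchanges).

#' Write / read a trace
#'
#' Tab-separated columns `t`, `V` and one per gating variable; spike times
#' are stored in a `# spikes:` header line.
#'
#' @param trace a `stellate_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spikes: %s",
                     paste(sprintf("%.10g", trace$spikes), collapse = " ")), con)
  df <- data.frame(t = trace$t, V = trace$V, trace$gating,
                   check.names = FALSE)
  write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param params the `stellate_params` to attach to the read trace (gate
#'   order must match the stored columns).
#' @export
read_trace <- function(path, params = model_params()) {
  hdr <- readLines(path, n = 1)
  spikes <- if (grepl("^# spikes:", hdr))
    as.numeric(strsplit(trimws(sub("^# spikes:", "", hdr)), "\\s+")[[1]])
  else numeric(0)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  y <- as.matrix(df[, -1])
  new_trace(df$t, y, spikes[!is.na(spikes)], params,
            dt = diff(df$t[1:2]), seed = NA_integer_, scheme = "file")
}

#' Write / read a spike train
#'
#' Single column of spike times (ms); the recording bounds are stored in a
#' comment header.
#'
#' @param train a [spike_train()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(train, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_start: %.10g t_end: %.10g", train$t_start,
                     train$t_end), con)
  writeLines(sprintf("%.10g", train$times), con)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  bounds <- as.numeric(regmatches(
    hdr, gregexpr("-?[0-9]+\\.?[0-9]*([eE][-+]?[0-9]+)?", hdr))[[1]])
  times <- as.numeric(lines[-1])
  times <- times[!is.na(times)]
  spike_train(times, t_start = bounds[1], t_end = bounds[2])
}

#' Write a power spectrum or an equilibrium branch as delimited text
#'
#' @param x a `power_spectrum` or `equilibrium_branch`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_result <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "equilibrium_branch")) {
    f <- attr(x, "folds"); h <- attr(x, "hopf")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# parameter: %s", attr(x, "param_name")),
                 sprintf("# fold: %.10g V=%.6g", f$param, f$V),
                 sprintf("# hopf: %.10g V=%.6g freq=%.6g", h$param, h$V,
                         h$freq_hz)), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
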