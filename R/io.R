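# Text-based exchange formats: decays, traces, correlation curves and
# event lists are tab-delimited tables; images are 16-bit grayscale TIFF;
# run configuration travels as JSON.

#' Read a decay histogram from delimited text
#'
#' Expects columns `time_ns` and `counts` on a uniform grid spanning one
#' repetition period.
#'
#' @param path File path (TSV with header).
#' @param channel Detection channel of the stored decay.
#' @param period Repetition period in ns; default: inferred as the grid
#'   span plus one bin.
#' @return A [decay_histogram()].
#' @export
read_decay <- function(path, channel = "VM", period = NULL) {
  df <- read.delim(path)
  stopifnot(all(c("time_ns", "counts") %in% names(df)))
  dt <- diff(df$time_ns)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("non-uniform time grid")
  if (is.null(period)) period <- nrow(df) * dt[1]
  decay_histogram(df$counts, decay_grid(nrow(df), period), channel)
}

#' Write a decay histogram to delimited text
#' @param decay A [decay_histogram()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_decay <- function(decay, path) {
  write.table(data.frame(time_ns = decay$grid$times, counts = decay$counts),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a photobleaching trace from delimited text
#'
#' Expects columns `bin` and `counts`; bin width and laser power come
#' from a JSON sidecar (`<path>.json`, fields `t_bin`, `p485`) or the
#' arguments.
#'
#' @param path File path.
#' @param t_bin,p485 Metadata overrides.
#' @return A [bleach_trace()].
#' @export
read_bleach_trace <- function(path, t_bin = NULL, p485 = NULL) {
  df <- read.delim(path)
  stopifnot("counts" %in% names(df))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  bleach_trace(df$counts,
               t_bin = t_bin %||% meta$t_bin %||% 0.005,
               p485 = p485 %||% meta$p485 %||% 1.36)
}

#' Read an FCS correlation curve from delimited text
#'
#' Expects columns `lag_s`, `G` and optionally `stderr`; lag times are
#' converted to ms.
#'
#' @param path File path.
#' @return A [correlation_curve()].
#' @export
read_fcs_curve <- function(path) {
  df <- read.delim(path)
  stopifnot(all(c("lag_s", "G") %in% names(df)))
  correlation_curve(df$lag_s * 1000, df$G,
                    stderr = if ("stderr" %in% names(df)) df$stderr)
}

#' Write an FCS correlation curve to delimited text
#' @param curve A [correlation_curve()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fcs_curve <- function(curve, path) {
  write.table(data.frame(lag_s = curve$lag_ms / 1000, G = curve$G,
                         stderr = curve$stderr),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read apoptosis event times from delimited text
#'
#' Expects columns `cell_id` and `death_time_h` (empty/NA marks a
#' censored cell that survived the observation window).
#'
#' @param path File path.
#' @param censor_time Observation end in hours (default: max event time).
#' @return An [apoptosis_series()].
#' @export
read_event_times <- function(path, censor_time = NULL) {
  df <- read.delim(path)
  stopifnot(all(c("cell_id", "death_time_h") %in% names(df)))
  ev <- df$death_time_h[!is.na(df$death_time_h)]
  apoptosis_series(ev, n_total = nrow(df),
                   censor_time = censor_time %||% max(ev, 0))
}

#' Read / write 16-bit grayscale TIFF count images
#'
#' Images are stored as unsigned 16-bit TIFF; counts are clipped to
#' 65535 on write.
#'
#' @param path File path.
#' @return `read_count_image`: an integer count matrix.
#' @export
read_count_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' @rdname read_count_image
#' @param image Count matrix.
#' @export
write_count_image <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
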