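#' Write a stimulus to a RIFF/WAV file with calibration sidecar
#'
#' Writes mono PCM (16-bit integer) or IEEE float (32-bit) WAV.  Physical
#' calibration is preserved through a JSON sidecar (`<path>.json`) holding the
#' pascals-per-full-scale constant, the sampling rate, nominal level and kind,
#' since WAV samples are dimensionless.
#'
#' @param stim a [stimulus()].
#' @param path output file path (`.wav`).
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @param pa_per_fs pascals represented by digital full scale (+/-1.0).
#'   Default scales the waveform peak to 0.5 full scale.
#' @return `path`, invisibly.
#' @export
write_wav <- function(stim, path, bits = 32, pa_per_fs = NULL) {
  stopifnot(inherits(stim, "stimulus"), bits %in% c(16, 32))
  x <- stim$samples
  if (is.null(pa_per_fs)) {
    pk <- max(abs(x), 1e-300)
    pa_per_fs <- 2 * pk
  }
  y <- x / pa_per_fs
  if (max(abs(y)) > 1) stop("pa_per_fs too small: samples clip full scale")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(y)
  bytes_per <- bits / 8
  data_len <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L           # PCM vs IEEE float
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(as.integer(stim$fs), con, size = 4, endian = "little")
  writeBin(as.integer(stim$fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(pmin(y, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(y), con, size = 4, endian = "little")
  }
  jsonlite::write_json(
    list(pa_per_fs = pa_per_fs, fs = stim$fs, level_dB = stim$level_dB,
         kind = stim$kind, bits = bits),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a WAV file written with [write_wav()]
#'
#' Restores physical units (Pa) from the JSON sidecar; without a sidecar the
#' samples are returned at digital full scale with `pa_per_fs = 1`.
#'
#' @param path `.wav` file path.
#' @return a [stimulus()].
#' @export
read_wav <- function(path) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(pa_per_fs = 1, level_dB = NULL, kind = "corpus_item")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt_code <- NULL; fs <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      if (nch != 1) stop("only mono WAV supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (identical(id, "data")) {
      if (bits == 16) {
        x <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little") / 32767
      } else if (bits == 32 && fmt_code == 3) {
        x <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
      } else stop("unsupported WAV format: ", bits, "-bit code ", fmt_code)
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(x)) stop("no data chunk found in ", path)
  stimulus(x * meta$pa_per_fs, fs,
           level_dB = meta$level_dB,
           kind = if (is.null(meta$kind)) "corpus_item" else meta$kind)
}
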