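#' Write a mono WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM, 24-bit PCM and 32-bit
#' IEEE float, mono.
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`; values outside
#'   are clipped for integer formats.
#' @param sample_rate_hz sample rate in Hz.
#' @param path output file path.
#' @param bit_depth 16, 24 or 32 (32 = float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path, bit_depth = 16) {
  if (!bit_depth %in% c(16, 24, 32)) {
    stop_bws("bit_depth must be 16, 24 or 32", class = "bws_wav_error")
  }
  n <- length(samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 32) 3L else 1L  # IEEE float vs PCM
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 32) {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    x <- pmax(-1, pmin(1, samples))
    if (bit_depth == 16) {
      q <- as.integer(round(x * 32767))
      writeBin(q, con, size = 2, endian = "little")
    } else {  # 24-bit: write 3 little-endian bytes per sample
      q <- round(x * 8388607)
      q[q < 0] <- q[q < 0] + 16777216
      raw3 <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
      writeBin(as.raw(raw3), con)
    }
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in `[-1, 1]`) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_bws("not a RIFF file", class = "bws_wav_error")
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop_bws("not a WAVE file", class = "bws_wav_error")
  sample_rate <- NA_integer_; bit_depth <- NA_integer_; fmt_code <- NA_integer_
  n_channels <- 1L
  repeat {
    chunk <- readChar(con, 4)
    if (length(chunk) == 0 || nchar(chunk) < 4) {
      stop_bws("no data chunk found", class = "bws_wav_error")
    }
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (chunk == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      n_channels <- readBin(con, "integer", size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bit_depth <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (chunk == "data") {
      if (n_channels != 1L) {
        stop_bws("only mono WAV supported", class = "bws_wav_error")
      }
      n <- size / (bit_depth / 8)
      samples <- if (fmt_code == 3L && bit_depth == 32) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else if (bit_depth == 16) {
        readBin(con, "integer", n = n, size = 2, endian = "little") / 32767
      } else if (bit_depth == 24) {
        raw <- as.integer(readBin(con, "raw", size))
        dim(raw) <- c(3, n)
        q <- raw[1, ] + 256 * raw[2, ] + 65536 * raw[3, ]
        q[q >= 8388608] <- q[q >= 8388608] - 16777216
        q / 8388607
      } else {
        stop_bws("unsupported WAV format (code %d, %d-bit)", fmt_code, bit_depth,
                 class = "bws_wav_error")
      }
      return(list(samples = samples, sample_rate_hz = sample_rate))
    } else {
      readBin(con, "raw", size)  # skip unknown chunk
    }
  }
}
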