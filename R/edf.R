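# Minimal EDF (European Data Format) writer/reader: fixed-width ASCII
# header + 16-bit little-endian data records. One-second records; the last
# record is zero-padded and the true sample count is carried in the JSON
# annotation sidecar so round trips are exact in length.

pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

#' Write a recording to an EDF file with a JSON annotation sidecar
#'
#' Signals are quantized to 16-bit integers over each channel's physical
#' range (quantization error <= range / 65534). Trial annotations, channel
#' names, the true sample count and subject id go to `<path>.json`.
#'
#' @param recording a [raw_recording()]; `fs` must be a whole number.
#' @param path output EDF path (the sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  data <- recording$data
  ns <- nrow(data)
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad(paste0("subject ", recording$subject_id), 80),
                pad("eegemotion synthetic recording", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8),
                pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, w) writeChar(paste0(vapply(f, pad, "", n = w),
                                           collapse = ""), con, eos = NULL)
  field(recording$layout$name, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- matrix(0, ns, fs)
    valid <- idx <= n
    block[, valid] <- data[, idx[valid], drop = FALSE]
    dig <- round((block - pmin_) / scale) - 32768
    dig[, !valid] <- 0
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  sidecar <- list(subject_id = recording$subject_id, fs = fs, n_samples = n,
                  channels = recording$layout$name,
                  annotations = recording$annotations,
                  blinks = if (is.null(recording$blinks)) numeric(0) else
                    recording$blinks)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path EDF path; `<path>.json` must exist alongside it.
#' @return a [raw_recording()] (channel positions re-attached from the
#'   package montage by name), with `blinks` restored when present.
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such EDF file: ", path)
  if (!file.exists(sidecar_path)) {
    stop("missing annotation sidecar: ", sidecar_path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns <= 0) stop("malformed EDF header at offset 252")
  labels <- trimws(vapply(seq_len(ns), function(i)
    readChar(con, 16, useBytes = TRUE), ""))
  skip <- function(w) invisible(readChar(con, w * ns, useBytes = TRUE))
  skip(80); skip(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  skip(8); skip(8); skip(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  skip(32)
  if (length(sc$channels) != ns) {
    stop("channel-count mismatch: EDF has ", ns, ", sidecar lists ",
         length(sc$channels))
  }
  if (!identical(labels, as.character(sc$channels))) {
    stop("channel labels differ between EDF and sidecar")
  }
  fs <- spr[1]
  scale <- (pmax_ - pmin_) / 65535
  data <- matrix(0, ns, n_rec * fs)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * fs, size = 2, endian = "little")
    data[, ((r - 1) * fs + 1):(r * fs)] <-
      (matrix(raw, ns, fs, byrow = TRUE) + 32768) * scale + pmin_
  }
  data <- data[, seq_len(sc$n_samples), drop = FALSE]
  ann <- as.data.frame(sc$annotations)
  if (nrow(ann) == 0) ann <- empty_annotations()
  rec <- raw_recording(data, fs, channel_layout(labels), ann,
                       subject_id = sc$subject_id)
  if (length(sc$blinks) > 0) rec$blinks <- as.numeric(sc$blinks)
  rec
}
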