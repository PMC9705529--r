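#' Continuous multichannel recordings
#'
#' Container for a raw recording entering the signal-conditioning front
#' end. Sample indices (including event samples) are 1-based throughout
#' the R API.
#'
#' @param data channel x sample numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param labels Optional channel labels.
#' @param events Optional data.frame with columns `sample` (1-based index)
#'   and `code`.
#' @return A `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, labels = NULL, events = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop("fs must be positive")
  if (is.null(labels)) labels <- sprintf("ch%03d", seq_len(nrow(data)))
  if (!is.null(events)) {
    stopifnot(all(c("sample", "code") %in% names(events)))
    if (any(events$sample < 1L | events$sample > ncol(data)))
      stop("event sample index outside record length")
  }
  structure(list(data = data, fs = fs, labels = labels, events = events),
            class = "continuous_recording")
}

# steady-state DF2T state for a unit-level input (suppresses startup
# transients when scaled by the first sample)
biquad_zi <- function(b, a) {
  A <- rbind(c(-a[2], 1), c(-a[3], 0))
  B <- c(b[2] - b[1] * a[2], b[3] - b[1] * a[3])
  solve(diag(2) - A, B)
}

# Butterworth band-pass as cascaded second-order sections, built from the
# analog prototype (poles in closed form, LP-to-BP transform, bilinear
# map). High-order IIR band-passes (10 poles for the order-5 filter) are
# numerically fragile as one direct-form recursion; biquads keep each
# recursion well-conditioned.
butter_sos <- function(order, w, type = "pass") {
  stopifnot(type == "pass", length(w) == 2, w[1] > 0, w[2] < 1)
  W1 <- tan(pi * w[1] / 2)                   # prewarped analog edges
  W2 <- tan(pi * w[2] / 2)
  Bw <- W2 - W1
  W0sq <- W1 * W2
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LP poles
  # LP -> BP: each prototype pole yields two band-pass poles
  disc <- sqrt((Bw * proto)^2 / 4 - W0sq)
  s_poles <- c(Bw * proto / 2 + disc, Bw * proto / 2 - disc)
  z_poles <- (1 + s_poles) / (1 - s_poles)   # bilinear transform
  # group poles into conjugate pairs (plus real poles paired by sorting)
  tol <- 1e-9
  up <- z_poles[Im(z_poles) > tol]
  re <- sort(Re(z_poles[abs(Im(z_poles)) <= tol]))
  pairs <- lapply(up, function(p) c(p, Conj(p)))
  while (length(re) >= 2L) {
    pairs <- c(pairs, list(c(re[1], re[2])))
    re <- re[-(1:2)]
  }
  # Assign each section the zeros nearest its poles (the band-pass has
  # `order` zeros at z = +1 and `order` at z = -1): sections with poles
  # hugging the unit circle get matching-sign zeros, which keeps every
  # section's resonant gain bounded (the usual zpk-to-sos pairing rule).
  pairs <- pairs[order(-vapply(pairs, function(p) max(Mod(p)), numeric(1)))]
  pool <- c(pos = order, neg = order)
  w0 <- 2 * atan(sqrt(W0sq))         # (warped) centre frequency
  z0 <- exp(1i * w0)
  sos <- lapply(pairs, function(p) {
    zer <- vapply(p, function(pk) {
      want <- if (Re(pk) >= 0) "pos" else "neg"
      if (pool[want] == 0L) want <- setdiff(c("pos", "neg"), want)
      pool[want] <<- pool[want] - 1L
      if (want == "pos") 1 else -1
    }, numeric(1))
    b <- c(1, -(zer[1] + zer[2]), zer[1] * zer[2])
    a <- c(1, -Re(p[1] + p[2]), Re(p[1] * p[2]))
    g <- Mod(sum(b * z0^-(0:2)) / sum(a * z0^-(0:2)))
    list(b = b / g, a = a)
  })
  sos
}

# Zero-phase (forward-backward) application of a cascade of second-order
# sections: odd-reflection padding at both ends plus steady-state initial
# conditions per pass, so edge transients stay small even for sections
# with poles very close to the unit circle.
sos_filtfilt <- function(x, sos) {
  zis <- lapply(sos, function(s) biquad_zi(s$b, s$a))
  run <- function(v) {
    n <- length(v)
    p <- min(n - 2L, 3L * (2L * length(sos) + 1L))
    ext <- c(2 * v[1] - v[(p + 1):2], v, 2 * v[n] - v[(n - 1):(n - p)])
    for (i in seq_along(sos)) {
      s <- sos[[i]]
      ext <- cpp_biquad(ext, s$b, s$a, zis[[i]] * ext[1])
      ext <- rev(cpp_biquad(rev(ext), s$b, s$a, zis[[i]] * ext[length(ext)]))
    }
    ext[(p + 1):(p + n)]
  }
  if (is.matrix(x)) t(apply(x, 1L, run)) else run(x)
}

#' Zero-phase Butterworth band-pass
#'
#' Forward-backward (zero-phase) application of an order-`order`
#' Butterworth band-pass per channel, the standard broadband EEG cleanup
#' (defaults 0.3-50 Hz, order 5). Zero-phase filtering leaves phase
#' estimates downstream (WPLI) unbiased; the effective magnitude order is
#' doubled by the two passes.
#'
#' @param rec A `continuous_recording`.
#' @param low_hz,high_hz Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order (per pass).
#' @return The filtered `continuous_recording` (same length).
#' @export
bandpass <- function(rec, low_hz = 0.3, high_hz = 50, order = 5) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$fs / 2
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq) stop("high_hz must be below the Nyquist frequency")
  sos <- butter_sos(order, c(low_hz, high_hz) / nyq, "pass")
  rec$data <- sos_filtfilt(rec$data, sos)
  rec
}

#' Zero-phase line-noise notch
#'
#' Second-order IIR (biquad) notch at `freq_hz` with quality factor `q`,
#' applied forward-backward per channel. The default Q = 30 gives a 3 dB
#' rejection bandwidth of `freq_hz / 30` Hz per pass; raise `q` for a
#' narrower notch.
#'
#' @param rec A `continuous_recording`.
#' @param freq_hz Notch centre frequency (default 60 Hz mains).
#' @param q Quality factor (centre frequency over 3 dB bandwidth).
#' @return The filtered `continuous_recording`.
#' @export
notch <- function(rec, freq_hz = 60, q = 30) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (freq_hz <= 0 || freq_hz >= rec$fs / 2)
    stop("notch frequency must lie in (0, fs/2)")
  w0 <- 2 * pi * freq_hz / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  sos <- list(list(b = b / a[1], a = a / a[1]))
  rec$data <- sos_filtfilt(rec$data, sos)
  rec
}

#' Cut a recording into event-locked epochs
#'
#' One epoch per event, spanning `[tmin, tmax)` seconds around the event
#' sample (the paper-style default is 1 s of pre-stimulus baseline plus
#' the 2 s stimulation period). Each epoch has `round((tmax - tmin) * fs)`
#' samples.
#'
#' @param rec A `continuous_recording` with events.
#' @param tmin,tmax Epoch window in seconds relative to the event.
#' @return An `epoch_set`: list with `data` (channel x sample x trial),
#'   `fs`, `tmin`, `tmax`, `labels`, `codes`.
#' @export
epoch_recording <- function(rec, tmin = -1, tmax = 2) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (tmax <= tmin) stop("tmax must exceed tmin")
  nsamp <- round((tmax - tmin) * rec$fs)
  ev <- rec$events
  nev <- if (is.null(ev)) 0L else nrow(ev)
  out <- array(0, dim = c(nrow(rec$data), nsamp, nev))
  if (nev > 0L) {
    first <- ev$sample + round(tmin * rec$fs)
    bad <- which(first < 1L | first + nsamp - 1L > ncol(rec$data))
    if (length(bad))
      stop("epoch out of record bounds for event(s) ",
           paste(bad, collapse = ", "))
    for (k in seq_len(nev))
      out[, , k] <- rec$data[, first[k]:(first[k] + nsamp - 1L)]
  }
  structure(list(data = out, fs = rec$fs, tmin = tmin, tmax = tmax,
                 labels = rec$labels,
                 codes = if (nev > 0L) ev$code else character(0)),
            class = "epoch_set")
}

#' Select an analysis sub-window of an epoch set
#'
#' Exposes, e.g., the 2 s from stimulus onset (`t_from = 0, t_to = 2`)
#' out of a -1..+2 s epoch.
#'
#' @param epochs An `epoch_set`.
#' @param t_from,t_to Sub-window in seconds relative to the event.
#' @return The trimmed `epoch_set`.
#' @export
analysis_window <- function(epochs, t_from = 0, t_to = 2) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (t_from < epochs$tmin - 1e-9 || t_to > epochs$tmax + 1e-9)
    stop("analysis window outside epoch window")
  a <- round((t_from - epochs$tmin) * epochs$fs) + 1L
  n <- round((t_to - t_from) * epochs$fs)
  epochs$data <- epochs$data[, a:(a + n - 1L), , drop = FALSE]
  epochs$tmin <- t_from
  epochs$tmax <- t_to
  epochs
}

#' Zero-phase band selection on epochs
#'
#' Narrow-band (default alpha, 8-13 Hz) Butterworth band-pass applied
#' forward-backward to every channel of every epoch.
#'
#' @param epochs An `epoch_set`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (per pass).
#' @return The filtered `epoch_set` (same shape).
#' @export
band_select <- function(epochs, low = 8, high = 13, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$fs / 2
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= nyq) stop("high must be below the Nyquist frequency")
  sos <- butter_sos(order, c(low, high) / nyq, "pass")
  for (k in seq_len(dim(epochs$data)[3]))
    epochs$data[, , k] <- sos_filtfilt(epochs$data[, , k], sos)
  epochs
}

#' Convert an epoch set to an ROI time-series set
#'
#' Hook for externally source-localized / cleaned data: an `epoch_set`
#' whose channels already are ROI time courses becomes the pipeline's
#' universal input.
#'
#' @param epochs An `epoch_set`.
#' @param condition Condition tag.
#' @return A `roi_ts`.
#' @export
as_roi_ts <- function(epochs, condition = "data") {
  stopifnot(inherits(epochs, "epoch_set"))
  structure(list(data = epochs$data, fs = epochs$fs,
                 labels = epochs$labels, condition = condition,
                 schedules = NULL,
                 provenance = list(source = "epoch_set")),
            class = "roi_ts")
}

#' Read a 16-bit EDF/EDF+ recording
#'
#' Minimal reader for standard continuous EDF: parses the ASCII header and
#' per-signal headers, decodes the 16-bit little-endian samples, and
#' applies each signal's physical calibration. All kept signals must share
#' one sampling rate; `"EDF Annotations"` channels are skipped (supply
#' events via `events_csv`, a CSV with header `sample,code` and 1-based
#' sample indices).
#'
#' @param path EDF file path.
#' @param events_csv Optional path to a sidecar events CSV.
#' @return A `continuous_recording`.
#' @export
read_edf <- function(path, events_csv = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    trimws(rawToChar(readBin(con, "raw", nchars)))
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)                                  # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- field(16)
  field(80); field(8)                     # transducer, physical dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                               # prefiltering
  spr <- as.integer(field(8))             # samples per record
  field(32)                               # reserved
  stopifnot(seek(con) == header_bytes)
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("no signal channels in EDF file")
  fs <- spr[keep] / record_dur
  if (length(unique(fs)) != 1L)
    stop("channels with differing sampling rates are not supported")
  out <- matrix(0, sum(keep), n_records * spr[which(keep)[1]])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_records)) {
    row <- 0L
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2,
                     endian = "little", signed = TRUE)
      if (keep[s]) {
        row <- row + 1L
        out[row, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
          pmin[s] + (dig - dmin[s]) * scale[s]
      }
    }
  }
  events <- if (!is.null(events_csv)) read.csv(events_csv) else NULL
  continuous_recording(out, fs[1], labels = labels[keep], events = events)
}
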