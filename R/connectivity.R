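#' Sliding-window specification
#'
#' Defaults follow the dynamic-connectivity geometry used throughout the
#' package: 300 ms windows with 50 % overlap, which tile a 2 s trial at
#' 500 Hz into exactly 12 layers.
#'
#' @param window_ms Window length in milliseconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_ms = 300, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (window_ms <= 0) stop("window_ms must be positive")
  structure(list(window_ms = window_ms, overlap = overlap),
            class = "window_spec")
}

#' Enumerate sliding windows
#'
#' Windows are 0-based half-open sample intervals `[start, start +
#' window_samples)`; consecutive starts differ by the step implied by the
#' overlap, and trailing samples that do not fill a complete window are
#' dropped.
#'
#' @param n_samples Trial length in samples.
#' @param fs Sampling rate in Hz.
#' @param spec A [window_spec()].
#' @return Integer matrix with columns `start` and `end` (0-based,
#'   half-open), one row per window.
#' @export
make_windows <- function(n_samples, fs, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  wl <- round(spec$window_ms / 1000 * fs)
  if (wl < 2L) stop("window shorter than 2 samples")
  if (wl > n_samples) stop("window longer than the trial")
  step <- max(1L, round(wl * (1 - spec$overlap)))
  n_win <- floor((n_samples - wl) / step) + 1L
  start <- (seq_len(n_win) - 1L) * step
  cbind(start = as.integer(start), end = as.integer(start + wl))
}

#' Analytic signal via the FFT
#'
#' Standard construction: zero the negative-frequency half of the
#' spectrum, double the positive half, inverse-transform.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

band_filter <- function(x, fs, band, order = 4) {
  sos <- butter_sos(order, band / (fs / 2), "pass")
  sos_filtfilt(x, sos)
}

#' Weighted phase lag index of one signal pair
#'
#' WPLI uses only the lagged (imaginary) part of the cross-spectrum and is
#' therefore insensitive to zero-lag coupling such as volume conduction.
#' With `Sxy` the per-sample cross-spectrum of the analytic signals of the
#' (optionally band-filtered) inputs,
#' `WPLI = |mean(Im Sxy)| / mean(|Im Sxy|)`,
#' and 0 by convention when the denominator vanishes (identical or
#' zero-lag signals: no evidence of lagged interaction). The debiased
#' variant is the squared, sample-size-debiased estimator.
#'
#' @param x,y Equal-length numeric vectors (length >= 2), all finite.
#' @param fs Sampling rate in Hz (needed only when `band` is given).
#' @param band Optional `c(low, high)` band-pass applied to both inputs
#'   before the analytic transform.
#' @param debias If `TRUE`, return the debiased squared WPLI.
#' @return Scalar in `[0, 1]`.
#' @export
wpli <- function(x, y, fs = NULL, band = NULL, debias = FALSE) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 2L) stop("inputs must have length >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (!is.null(band)) {
    if (is.null(fs)) stop("band filtering requires fs")
    x <- band_filter(x, fs, band)
    y <- band_filter(y, fs, band)
    # drop filter startup transients (two cycles of the band's low edge)
    k <- min(floor(length(x) / 4), round(2 * fs / band[1]))
    if (k > 0) {
      keep <- (k + 1):(length(x) - k)
      x <- x[keep]; y <- y[keep]
    }
  }
  im <- Im(analytic_signal(x) * Conj(analytic_signal(y)))
  wpli_from_im(im, debias)
}

wpli_from_im <- function(im, debias = FALSE) {
  if (!debias) {
    den <- mean(abs(im))
    if (den <= .Machine$double.eps) return(0)
    abs(mean(im)) / den
  } else {
    num <- sum(im)^2 - sum(im^2)
    den <- sum(abs(im))^2 - sum(im^2)
    if (den <= .Machine$double.eps) return(0)
    max(0, num / den)
  }
}

#' Layer-indexed WPLI connectivity stack for one trial
#'
#' Band-filters each node's full trial once, takes the analytic signal
#' once (avoiding per-window Hilbert edge transients), then evaluates the
#' WPLI of every unordered node pair within every sliding window. Each
#' layer is a symmetric matrix with zero diagonal and entries in `[0, 1]`
#' - the intralayer weights of the weighted multilayer graph.
#'
#' @param x node x sample numeric matrix (one trial).
#' @param fs Sampling rate in Hz.
#' @param spec A [window_spec()].
#' @param band Optional band in Hz applied before the analytic transform
#'   (pass `NULL` for already narrow-band data).
#' @param debias If `TRUE`, use the debiased squared WPLI.
#' @return A `conn_stack`: numeric array `n_windows x n_nodes x n_nodes`
#'   with attributes `windows`, `fs`, `band`.
#' @export
connectivity_stack <- function(x, fs, spec = window_spec(), band = NULL,
                               debias = FALSE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in trial data")
  win <- make_windows(ncol(x), fs, spec)
  n <- nrow(x)
  if (!is.null(band)) x <- band_filter(x, fs, band)
  Z <- t(apply(x, 1L, analytic_signal))
  if (n == 1L) Z <- matrix(Z, nrow = 1L)
  RZ <- Re(Z); IZ <- Im(Z)
  out <- array(0, dim = c(nrow(win), n, n))
  for (w in seq_len(nrow(win))) {
    idx <- (win[w, "start"] + 1L):win[w, "end"]
    Rw <- RZ[, idx, drop = FALSE]; Iw <- IZ[, idx, drop = FALSE]
    num <- Iw %*% t(Rw) - Rw %*% t(Iw)       # sum over samples of Im(Sxy)
    den <- matrix(0, n, n)
    sq <- matrix(0, n, n)
    for (s in seq_along(idx)) {
      m <- tcrossprod(Iw[, s], Rw[, s]) - tcrossprod(Rw[, s], Iw[, s])
      den <- den + abs(m)
      if (debias) sq <- sq + m^2
    }
    if (!debias) {
      lay <- ifelse(den > .Machine$double.eps, abs(num) / den, 0)
    } else {
      db_den <- den^2 - sq
      lay <- ifelse(db_den > .Machine$double.eps,
                    pmax(0, (num^2 - sq) / db_den), 0)
    }
    diag(lay) <- 0
    out[w, , ] <- (lay + t(lay)) / 2
  }
  structure(out, windows = win, fs = fs, band = band, debias = debias,
            class = "conn_stack")
}

#' Write / read a connectivity stack
#'
#' Binary doubles plus a JSON sidecar; `export_layers` additionally writes
#' each layer as a dense CSV matrix.
#'
#' @param stack A `conn_stack`.
#' @param dir Bundle directory.
#' @param export_layers If `TRUE`, also write `layer_<w>.csv` files.
#' @return The directory (write) or a `conn_stack` (read).
#' @export
write_conn_stack <- function(stack, dir, export_layers = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "stack.bin"), "wb")
  writeBin(as.vector(unclass(stack)), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(stack), windows = attr(stack, "windows"),
               fs = attr(stack, "fs"), band = attr(stack, "band"),
               debias = attr(stack, "debias"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (export_layers)
    for (w in seq_len(dim(stack)[1]))
      write.csv(stack[w, , ], file.path(dir, sprintf("layer_%02d.csv", w)),
                row.names = FALSE)
  invisible(dir)
}

#' @rdname write_conn_stack
#' @export
read_conn_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(file.path(dir, "stack.bin"), "rb")
  v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  close(con)
  win <- as.matrix(meta$windows)
  structure(array(v, dim = d), windows = win, fs = meta$fs,
            band = meta$band, debias = meta$debias, class = "conn_stack")
}
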