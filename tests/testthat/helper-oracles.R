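# Independent oracles and small fixtures shared across tests. Everything
# here recomputes quantities from first principles, separately from the
# package's own code paths.

tiny_map <- function(n_per_system = 2) system_map(make_demo_nodes(n_per_system))

# random symmetric non-negative zero-diagonal weight stack
random_stack <- function(n_layers, n_nodes) {
  st <- array(0, dim = c(n_layers, n_nodes, n_nodes))
  for (l in seq_len(n_layers)) {
    A <- matrix(runif(n_nodes^2), n_nodes)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    st[l, , ] <- A
  }
  st
}

# multilayer modularity matrix and normalization, built independently of
# the package: intralayer Newman-Girvan blocks at resolution gamma plus
# uniform ordinal interlayer coupling omega on the identity
oracle_B <- function(stack, gamma, omega) {
  L <- dim(stack)[1]; n <- dim(stack)[2]
  V <- n * L
  B <- matrix(0, V, V)
  twom <- 0
  for (l in seq_len(L)) {
    A <- stack[l, , ]
    k <- rowSums(A)
    m2 <- sum(k)
    twom <- twom + m2
    idx <- (l - 1L) * n + seq_len(n)
    B[idx, idx] <- if (m2 > 0) A - gamma * (k %o% k) / m2 else A
  }
  if (L > 1L) for (l in seq_len(L - 1L)) {
    i1 <- (l - 1L) * n + seq_len(n); i2 <- l * n + seq_len(n)
    B[cbind(i1, i2)] <- B[cbind(i2, i1)] <- omega
  }
  list(B = B, twomu = twom + 2 * omega * n * (L - 1L))
}

oracle_Q <- function(stack, labels, gamma, omega) {
  ob <- oracle_B(stack, gamma, omega)
  g <- as.vector(labels)
  same <- outer(g, g, "==")
  sum(ob$B[same]) / ob$twomu
}

# all set partitions of n items as restricted-growth strings (rows)
all_partitions <- function(n) {
  G <- matrix(1L, 1L, 1L)
  maxl <- 1L
  for (k in seq_len(n - 1L) + 1L) {
    reps <- maxl + 1L
    rows <- rep.int(seq_len(nrow(G)), reps)
    G <- cbind(G[rows, , drop = FALSE], sequence(reps))
    maxl <- pmax(rep.int(maxl, reps), G[, k])
  }
  G
}

# exhaustive maximum of multilayer modularity over every partition of the
# node-layer vertices
exhaustive_max_Q <- function(stack, gamma, omega) {
  ob <- oracle_B(stack, gamma, omega)
  V <- nrow(ob$B)
  G <- all_partitions(V)
  qs <- rep(sum(diag(ob$B)), nrow(G))
  for (i in seq_len(V - 1L)) for (j in (i + 1L):V) {
    qs <- qs + (2 * ob$B[i, j]) * (G[, i] == G[, j])
  }
  max(qs) / ob$twomu
}

# amplitude ratio of a pure sinusoid through a filtering function
# (broadband RMS over the core, edges dropped)
sine_gain <- function(filter_fun, freq, fs = 500, dur = 4) {
  t <- seq_len(fs * dur) / fs
  x <- sin(2 * pi * freq * t)
  y <- filter_fun(x)
  core <- (fs):(length(t) - fs)        # ignore edge transients
  sqrt(mean(y[core]^2) / mean(x[core]^2))
}

# gain at exactly the probe frequency (lock-in over whole core cycles),
# insensitive to broadband edge-transient leakage
tone_gain <- function(filter_fun, freq, fs = 500, dur = 4) {
  t <- seq_len(fs * dur) / fs
  x <- sin(2 * pi * freq * t)
  y <- filter_fun(x)
  n_cyc <- floor((dur - 2) * freq)
  core <- fs + seq_len(round(n_cyc * fs / freq))
  2 * Mod(mean(y[core] * exp(-2i * pi * freq * t[core])))
}

# minimal single-record-block 16-bit EDF writer for round-trip tests
write_mini_edf <- function(path, data, fs, record_dur = 1) {
  n_ch <- nrow(data)
  spr <- as.integer(fs * record_dur)
  n_rec <- ncol(data) / spr
  stopifnot(n_rec == round(n_rec))
  pmin_ <- -200; pmax_ <- 200; dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- sprintf(paste0("%-", w, "s"), substr(as.character(x), 1, w))
    writeChar(s, con, nchars = w, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.24", 8); pad("00.00.00", 8)
  pad(256 + 256 * n_ch, 8); pad("", 44); pad(n_rec, 8)
  pad(format(record_dur), 8); pad(n_ch, 4)
  for (i in seq_len(n_ch)) pad(sprintf("ch%d", i), 16)
  for (i in seq_len(n_ch)) pad("synthetic", 80)
  for (i in seq_len(n_ch)) pad("uV", 8)
  for (i in seq_len(n_ch)) pad(pmin_, 8)
  for (i in seq_len(n_ch)) pad(pmax_, 8)
  for (i in seq_len(n_ch)) pad(dmin, 8)
  for (i in seq_len(n_ch)) pad(dmax, 8)
  for (i in seq_len(n_ch)) pad("", 80)
  for (i in seq_len(n_ch)) pad(spr, 8)
  for (i in seq_len(n_ch)) pad("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      seg <- data[ch, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - pmin_) * scale + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
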