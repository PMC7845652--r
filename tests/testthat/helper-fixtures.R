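# Shared fixtures, built lazily and cached for the duration of a test run
# so expensive synthetic sessions are generated once.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# compact session design: 3 blocks, compressed breaks
small_design <- function(n_blocks = 3L, trials_per_block = 6L,
                         intensities = c("low", "medium", "high"), ...) {
  session_design(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 intensities = intensities, inter_block = 8, ...)
}

# uniform planted ERD across intensities
gt_uniform <- function(alpha = -40, beta = -20, ...) {
  neural_ground_truth(
    roi_erd = list(low = c(alpha = alpha, beta = beta),
                   medium = c(alpha = alpha, beta = beta),
                   high = c(alpha = alpha, beta = beta)), ...)
}

no_artifacts <- function(...) {
  artifact_model(transient_amplitude = c(low = 0, medium = 0, high = 0),
                 baseline_powerline = 0, ...)
}

# hand-built epoch_set for unit tests of the spectral/dose layers
make_epochs <- function(data, fs = 100, t0 = -4, intensity = "high",
                        blocks = NULL) {
  ntr <- dim(data)[1]
  if (is.null(dimnames(data)[[2]])) {
    dimnames(data)[[2]] <- paste0("ch", seq_len(dim(data)[2]))
  }
  if (is.null(blocks)) blocks <- rep(1L, ntr)
  intensity <- rep(intensity, length.out = ntr)
  structure(list(
    data = data,
    time = t0 + (seq_len(dim(data)[3]) - 1) / fs,
    fs = fs, channels = dimnames(data)[[2]],
    trials = data.frame(block = blocks,
                        trial = stats::ave(seq_len(ntr), blocks, FUN = seq_along),
                        intensity = intensity,
                        onset = seq_len(ntr) * 20),
    mask = matrix(TRUE, ntr, dim(data)[2],
                  dimnames = list(NULL, dimnames(data)[[2]]))),
    class = "epoch_set")
}

# epochs of narrowband ROI oscillations with a known percent power drop
# during (0, +4) s, for ERD recovery at the unit level
make_erd_epochs <- function(ntr = 12, erd = -40, f = 10, fs = 100,
                            channels = c("C3", "C1", "CP3", "CP1"),
                            seed = 42) {
  nt <- 8 * fs
  tt <- -4 + (seq_len(nt) - 1) / fs
  g <- ifelse(tt >= 0, sqrt(1 + erd / 100), 1)
  data <- array(0, c(ntr, length(channels), nt),
                dimnames = list(NULL, channels, NULL))
  with_seed_local(seed, {
    for (k in seq_len(ntr)) {
      for (ci in seq_along(channels)) {
        phase <- stats::runif(1, 0, 2 * pi)
        data[k, ci, ] <- 5 * g * sin(2 * pi * f * tt + phase) +
          stats::rnorm(nt, sd = 0.3)
      }
    }
  })
  make_epochs(data, fs = fs)
}

with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# brute-force sliding median oracle: explicit per-window sort-and-pick
brute_median_filter <- function(x, w, edge = c("shrink", "reflect")) {
  edge <- match.arg(edge)
  n <- length(x)
  left <- w %/% 2
  right <- w - left - 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - left):(i + right)
    if (edge == "shrink") {
      idx <- idx[idx >= 1 & idx <= n]
    } else {
      idx <- vapply(idx, function(k) {
        while (k < 1 || k > n) {
          if (k < 1) k <- 2 - k
          if (k > n) k <- 2 * n - k
        }
        k
      }, numeric(1))
    }
    v <- sort(x[idx])
    m <- length(v)
    out[i] <- if (m %% 2 == 1) v[(m + 1) / 2]
              else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  out
}
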