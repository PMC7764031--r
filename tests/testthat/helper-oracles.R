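# Independent oracles and fixture builders, coded from first principles so
# they share no path with the package implementation.

# Pearson correlation by the textbook formula (explicit sums)
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force greedy selection: at step 1 take the column with the lowest
# mean absolute correlation to all other columns; afterwards, the column
# with the lowest mean absolute correlation to the selected set.  Written
# with explicit loops over pairs and pearson_brute.
oracle_greedy <- function(X, N) {
  p <- ncol(X)
  C <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r <- abs(pearson_brute(X[, i], X[, j]))
    C[i, j] <- r
    C[j, i] <- r
  }
  sel <- integer(0)
  for (step in seq_len(N)) {
    cand <- setdiff(seq_len(p), sel)
    crit <- vapply(cand, function(j) {
      ref <- if (step == 1) setdiff(seq_len(p), j) else sel
      mean(C[j, ref])
    }, 0)
    sel <- c(sel, cand[which.min(crit)])
  }
  colnames(X)[sel]
}

# Welch's two-sample t statistic and two-sided p, textbook formulas
welch_brute <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(t), df)
}

# dominant periodogram frequency of a signal (FFT oracle)
peak_frequency <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))[2:(n %/% 2)]^2
  freqs <- (1:(n %/% 2 - 1)) * fs / n
  freqs[which.max(sp)]
}

# periodogram band power (direct FFT, no filtering)
fft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n^2
  freqs <- (0:(n - 1)) * fs / n
  keep <- (freqs >= lo & freqs <= hi) | (freqs >= fs - hi & freqs <= fs - lo)
  sum(sp[keep])
}

# random matrix with one of several covariance structures, for oracle
# equivalence sweeps
random_structured_matrix <- function(seed) {
  set.seed(seed)
  p <- sample(4:20, 1)
  n <- sample(50:500, 1)
  kind <- seed %% 5
  X <- if (kind == 0) {
    matrix(rnorm(n * p), n)
  } else if (kind == 1) {            # equicorrelated
    rho <- runif(1, 0.2, 0.8)
    f <- rnorm(n)
    sqrt(rho) * matrix(f, n, p) + sqrt(1 - rho) * matrix(rnorm(n * p), n)
  } else if (kind == 2) {            # correlated blocks
    nb <- sample(2:4, 1)
    blk <- sort(rep_len(seq_len(nb), p))
    f <- matrix(rnorm(n * nb), n)
    w <- runif(p, 0.4, 0.95)
    sapply(seq_len(p), function(j)
      w[j] * f[, blk[j]] + sqrt(1 - w[j]^2) * rnorm(n))
  } else if (kind == 3) {            # heavy-tailed
    matrix(exp(rnorm(n * p)), n)
  } else {                           # clones plus independents
    k <- sample(2:(p - 1), 1)
    f <- rnorm(n)
    cbind(matrix(f, n, k) + matrix(rnorm(n * k, sd = 0.3), n),
          matrix(rnorm(n * (p - k)), n))
  }
  colnames(X) <- paste0("f", seq_len(p))
  X
}

# small synthetic study for fast tests
small_synth <- function(seed = 1, trials = 4, secs = 6) {
  synth_config(n_subjects = 1, n_trials_per_subject = trials,
               trial_seconds = secs, baseline_seconds = 1, seed = seed)
}

# single-channel recording holding a pure sinusoid
sine_recording <- function(freq, fs = 128, secs = 4, channels = "Cz",
                           n_trials = 1, amplitude = 1) {
  n <- secs * fs
  t <- (0:(n - 1)) / fs
  x <- amplitude * sin(2 * pi * freq * t)
  dat <- array(rep(x, each = n_trials * length(channels)),
               c(n_trials, length(channels), n))
  for (tr in seq_len(n_trials)) for (ch in seq_along(channels))
    dat[tr, ch, ] <- x
  eeg_recording(dat, channels, fs)
}
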