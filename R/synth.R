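# Seeded synthetic EEG with planted band-power class effects and
# engineered channel redundancy.

#' The default 16-channel synthetic montage
#'
#' A right-lateralized subset of the 10-20 montage that contains every
#' channel referenced by the fixed literature sets ([get_fixed_set()])
#' plus the default planted-effect sites.
#'
#' @return character vector of 16 channel labels.
#' @export
synth_channels <- function() {
  c("Fp1", "AF4", "Fz", "F4", "FC1", "FC2", "FC6", "Cz", "C4", "T8",
    "CP6", "P4", "Pz", "P8", "PO4", "O2")
}

synth_groups_default <- function() {
  list(list(channels = c("Fp1", "AF4", "Fz", "F4"), weight = 0.9),
       list(channels = c("FC1", "FC2", "FC6", "Cz", "C4"), weight = 0.9),
       list(channels = c("T8", "CP6", "P4"), weight = 0.9),
       list(channels = c("Pz", "P8", "PO4", "O2"), weight = 0.9))
}

#' Configuration of the synthetic EEG generator
#'
#' Every channel is a sum over the four analysis bands of band-limited
#' Gaussian noise, plus a 1/f aperiodic background and white sensor
#' noise.  Channels within a redundancy group share one latent source per
#' band (mixing weight `weight`, the remainder being private noise).  All
#' ongoing activity is multiplied by a per-second global log-normal
#' amplitude envelope (vigilance gain).  Each `effect` entry replaces the
#' named band of the named channel with a private evoked source that is
#' only partially coupled to the envelope (`effect_coupling` exponent)
#' and whose amplitude is multiplied by `amplitude_ratio` on trials whose
#' latent `effect_emotion` class is 1 -- the planted, mutually
#' decorrelated class effects the selection pipeline should recover.
#'
#' @param n_subjects number of subjects (default 2).
#' @param n_trials_per_subject trials per subject, split evenly between
#'   the two latent classes (default 30; must be even).
#' @param channel_names montage (default [synth_channels()]).
#' @param fs sampling rate in Hz (default 128).
#' @param trial_seconds stimulus length in seconds (default 60).
#' @param baseline_seconds pre-trial baseline kept at the start of each
#'   trial (default 3).
#' @param band_amplitudes named amplitudes (uV) of the four bands;
#'   defaults theta 6, alpha 10, beta 4, gamma 2.
#' @param background_noise_sd white sensor noise sd in uV (default 1).
#' @param one_over_f_amplitude amplitude (uV) of the aperiodic 1/f
#'   background (default 4).
#' @param one_over_f_exponent spectral exponent of the background
#'   (power ~ f^-exponent, default 1).
#' @param gain_sd log-sd of the per-second global amplitude envelope
#'   (default 0.35).
#' @param redundancy_groups list of `list(channels=, weight=)` groups
#'   sharing latent per-band sources (default four anatomical groups).
#' @param effect list of `list(channel=, band=, amplitude_ratio=)`
#'   planted class effects; default alpha effects of ratio 1.12 at P8,
#'   AF4 and Cz.
#' @param effect_emotion which latent class drives the effect
#'   (`"valence"` default).
#' @param effect_coupling envelope-coupling exponent of evoked planted
#'   sources (default 0.30; ongoing activity has exponent 1).
#' @param rating_low,rating_high ranges the class-0 / class-1 ratings are
#'   drawn from; the gap around the 4.5 threshold makes label recovery
#'   from ratings exact.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 2,
                         n_trials_per_subject = 30,
                         channel_names = synth_channels(),
                         fs = 128,
                         trial_seconds = 60,
                         baseline_seconds = 3,
                         band_amplitudes = c(theta = 6, alpha = 10,
                                             beta = 4, gamma = 2),
                         background_noise_sd = 1,
                         one_over_f_amplitude = 4,
                         one_over_f_exponent = 1,
                         gain_sd = 0.35,
                         redundancy_groups = synth_groups_default(),
                         effect = list(
                           list(channel = "P8", band = "alpha", amplitude_ratio = 1.12),
                           list(channel = "AF4", band = "alpha", amplitude_ratio = 1.12),
                           list(channel = "Cz", band = "alpha", amplitude_ratio = 1.12)),
                         effect_emotion = c("valence", "arousal"),
                         effect_coupling = 0.30,
                         rating_low = c(1, 4.3),
                         rating_high = c(4.7, 9),
                         seed = 1) {
  effect_emotion <- match.arg(effect_emotion)
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (!inherits(cfg, "synth_config")) stopf("not a synth_config")
  assert_scalar_number(cfg$fs, "fs", positive = TRUE)
  assert_scalar_number(cfg$trial_seconds, "trial_seconds", positive = TRUE)
  assert_scalar_number(cfg$baseline_seconds, "baseline_seconds")
  if (cfg$baseline_seconds < 0) stopf("'baseline_seconds' must be non-negative")
  if (cfg$n_trials_per_subject %% 2 != 0)
    stopf("'n_trials_per_subject' must be even (balanced classes)")
  if (anyDuplicated(cfg$channel_names)) stopf("channel names must be unique")
  bands <- names(default_bands())
  miss <- setdiff(bands, names(cfg$band_amplitudes))
  if (length(miss)) stopf("'band_amplitudes' is missing band(s): %s",
                          paste(miss, collapse = ", "))
  for (g in cfg$redundancy_groups) {
    bad <- setdiff(g$channels, cfg$channel_names)
    if (length(bad)) stopf("redundancy group names unknown channel(s): %s",
                           paste(bad, collapse = ", "))
    if (g$weight < 0 || g$weight > 1) stopf("group mixing weight must be in [0, 1]")
  }
  seen <- unlist(lapply(cfg$redundancy_groups, `[[`, "channels"))
  if (anyDuplicated(seen)) stopf("channels may belong to at most one redundancy group")
  for (e in cfg$effect) {
    if (!e$channel %in% cfg$channel_names)
      stopf("effect names unknown channel '%s'", e$channel)
    if (!e$band %in% bands) stopf("effect names unknown band '%s'", e$band)
    if (!is.numeric(e$amplitude_ratio) || e$amplitude_ratio <= 0)
      stopf("effect 'amplitude_ratio' must be positive")
  }
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d subject(s) x %d trials, %d channels, %g s + %g s baseline @ %g Hz (seed %d)\n",
    x$n_subjects, x$n_trials_per_subject, length(x$channel_names),
    x$trial_seconds, x$baseline_seconds, x$fs, x$seed))
  for (e in x$effect)
    cat(sprintf("  effect: %s_%s x %g on %s\n", e$channel, e$band,
                e$amplitude_ratio, x$effect_emotion))
  invisible(x)
}

# unit-variance band-limited Gaussian noise via frequency-domain synthesis
band_limited_noise <- function(n, fs, lo, hi) {
  f <- (0:(n - 1L)) * fs / n
  keep <- (f >= lo & f <= hi) | (f >= fs - hi & f <= fs - lo)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  z[!keep] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# unit-variance aperiodic background with power ~ f^-exponent (>= 0.5 Hz)
one_over_f_noise <- function(n, fs, exponent) {
  f <- (0:(n - 1L)) * fs / n
  f2 <- pmin(f, fs - f)
  mag <- ifelse(f2 < 0.5, 0, f2^(-exponent / 2))
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * mag
  x <- Re(stats::fft(z, inverse = TRUE))
  x / stats::sd(x)
}

#' Generate a synthetic EEG study
#'
#' Produces one [eeg_recording()] per subject plus a ratings table whose
#' binarization at 4.5 recovers the latent classes exactly.  The
#' non-effect emotion receives independent balanced labels with no
#' signal.
#'
#' @param config a [synth_config()].
#' @return list with `recordings` (list of [eeg_recording()]),
#'   `ratings` (data frame `subject`, `trial`, `valence`, `arousal`) and
#'   `labels` (the latent classes, data frame `subject`, `trial`,
#'   `valence`, `arousal`).
#' @examples
#' cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 2,
#'                     trial_seconds = 4, baseline_seconds = 1, seed = 7)
#' out <- synth_generate(cfg)
#' out$recordings[[1]]
#' @export
synth_generate <- function(config) {
  cfg <- validate_synth_config(config)
  bands <- default_bands()
  fs <- cfg$fs
  n <- round((cfg$trial_seconds + cfg$baseline_seconds) * fs)
  S <- ceiling(n / fs)
  nc <- length(cfg$channel_names)
  grp_of <- rep(NA_integer_, nc)
  names(grp_of) <- cfg$channel_names
  for (g in seq_along(cfg$redundancy_groups))
    grp_of[cfg$redundancy_groups[[g]]$channels] <- g
  gwt <- vapply(cfg$redundancy_groups, `[[`, 0, "weight")
  eff_key <- vapply(cfg$effect, function(e) paste(e$channel, e$band, sep = "_"), "")
  eff_ratio <- vapply(cfg$effect, `[[`, 0, "amplitude_ratio")
  names(eff_ratio) <- eff_key

  with_seed(derive_seed(cfg$seed, "synth"), {
    recordings <- vector("list", cfg$n_subjects)
    lab_rows <- list()
    rate_rows <- list()
    for (subj in seq_len(cfg$n_subjects)) {
      sid <- sprintf("synth%02d", subj)
      nt <- cfg$n_trials_per_subject
      # balanced latent classes for both emotions
      lab_eff <- sample(rep(0:1, nt / 2))
      lab_oth <- sample(rep(0:1, nt / 2))
      dat <- array(0, c(nt, nc, n))
      for (tr in seq_len(nt)) {
        g_s <- exp(stats::rnorm(S, 0, cfg$gain_sd))
        env_full <- rep(g_s, each = fs)[seq_len(n)]
        env_evoked <- env_full^cfg$effect_coupling
        for (b in names(bands)) {
          lo <- bands[[b]]$low; hi <- bands[[b]]$high
          lat <- lapply(seq_along(cfg$redundancy_groups), function(g)
            band_limited_noise(n, fs, lo, hi))
          amp <- cfg$band_amplitudes[[b]]
          for (ci in seq_len(nc)) {
            key <- paste(cfg$channel_names[ci], b, sep = "_")
            if (key %in% eff_key) {
              u <- band_limited_noise(n, fs, lo, hi)
              a <- amp * if (lab_eff[tr] == 1) eff_ratio[[key]] else 1
              dat[tr, ci, ] <- dat[tr, ci, ] + a * env_evoked * u
            } else {
              g <- grp_of[ci]
              u <- if (is.na(g)) band_limited_noise(n, fs, lo, hi)
                   else gwt[g] * lat[[g]] +
                        sqrt(1 - gwt[g]^2) * band_limited_noise(n, fs, lo, hi)
              dat[tr, ci, ] <- dat[tr, ci, ] + amp * env_full * u
            }
          }
        }
        for (ci in seq_len(nc)) {
          dat[tr, ci, ] <- dat[tr, ci, ] +
            cfg$one_over_f_amplitude * env_full *
              one_over_f_noise(n, fs, cfg$one_over_f_exponent) +
            stats::rnorm(n, 0, cfg$background_noise_sd)
        }
      }
      recordings[[subj]] <- eeg_recording(dat, cfg$channel_names, fs, sid,
                                          cfg$baseline_seconds)
      val <- if (cfg$effect_emotion == "valence") lab_eff else lab_oth
      aro <- if (cfg$effect_emotion == "arousal") lab_eff else lab_oth
      draw <- function(cls)
        ifelse(cls == 1,
               stats::runif(nt, cfg$rating_high[1], cfg$rating_high[2]),
               stats::runif(nt, cfg$rating_low[1], cfg$rating_low[2]))
      lab_rows[[subj]] <- data.frame(subject = sid, trial = seq_len(nt),
                                     valence = val, arousal = aro)
      rate_rows[[subj]] <- data.frame(subject = sid, trial = seq_len(nt),
                                      valence = draw(val), arousal = draw(aro))
    }
    list(recordings = recordings,
         ratings = do.call(rbind, rate_rows),
         labels = do.call(rbind, lab_rows))
  })
}

#' Planted effect feature names of a configuration
#' @param config a [synth_config()].
#' @return character vector of `"<channel>_<band>"` names.
#' @export
planted_features <- function(config) {
  vapply(config$effect, function(e) paste(e$channel, e$band, sep = "_"), "")
}

#' Build a clone-group fixture matrix for selection tests
#'
#' Constructs a feature matrix with known redundancy ground truth:
#' columns inside a multi-column group are noisy clones of one shared
#' latent draw, while singleton groups are mutually *exactly*
#' sample-decorrelated reference columns (centered and orthogonalized by
#' QR).  Exact orthogonality is what makes the planted ground truth
#' well-defined at finite sample size: with merely independent draws,
#' some clone could by chance be less correlated with a selected
#' reference column than the remaining reference columns are.
#'
#' @param n_rows number of instances.
#' @param groups named list of character vectors of column names;
#'   length-1 groups are the independent reference columns.
#' @param noise_sd sd of the private noise added to each clone (the
#'   shared latent has unit sd).
#' @param seed integer seed.
#' @return a `band_feature_matrix` with synthetic provenance metadata.
#' @examples
#' m <- make_clone_matrix(200, list(g1 = c("a1", "a2", "a3"),
#'                                  ref1 = "x", ref2 = "y"), 0.1, seed = 1)
#' rca_select(m, 2)$selected  # the two reference columns
#' @export
make_clone_matrix <- function(n_rows, groups, noise_sd, seed = 1) {
  if (!length(groups)) stopf("'groups' must be non-empty")
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stopf("'noise_sd' must be non-negative")
  cols <- unname(unlist(groups))
  if (anyDuplicated(cols)) stopf("column names must be unique across groups")
  if (n_rows < length(cols) + 1L)
    stopf("n_rows must exceed the total number of columns")
  with_seed(seed, {
    single <- which(lengths(groups) == 1L)
    X <- matrix(NA_real_, n_rows, length(cols))
    colnames(X) <- cols
    if (length(single)) {
      raw <- matrix(stats::rnorm(n_rows * length(single)), n_rows)
      raw <- scale(raw, center = TRUE, scale = FALSE)
      q <- qr.Q(qr(raw))
      for (i in seq_along(single))
        X[, groups[[single[i]]]] <- q[, i] * sqrt(n_rows)
    }
    for (gi in setdiff(seq_along(groups), single)) {
      latent <- stats::rnorm(n_rows)
      for (nm in groups[[gi]])
        X[, nm] <- latent + stats::rnorm(n_rows, 0, noise_sd)
    }
    structure(list(values = X,
                   meta = data.frame(subject = "synthetic", trial = 1L,
                                     second = seq_len(n_rows)),
                   stat = "synthetic"),
              class = "band_feature_matrix")
  })
}
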