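#' Configuration for synthetic microstate-structured EEG
#'
#' Bundles the parameters of the generative model: `K` latent topographies
#' activated by a first-order Markov label sequence, multiplied by a random
#' positive amplitude and embedded in additive 1/f^alpha noise at a
#' controlled signal-to-noise ratio.
#'
#' @param n_channels Number of electrodes (default 30).
#' @param K Number of latent topographies (default 5).
#' @param transition_matrix K x K row-stochastic matrix of the label chain.
#'   Default: self-transition probability `dwell` on the diagonal (0.95 at
#'   250 Hz, roughly an 80 ms mean dwell) with the remaining mass spread
#'   uniformly over the other states.
#' @param fs Sampling rate in Hz (default 250).
#' @param duration Length of the generated segment in seconds (default 3,
#'   one pre-trigger epoch).
#' @param snr_db Signal-to-noise ratio in dB: total template-signal power
#'   over total noise power (default 20).
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha channel
#'   noise, alpha >= 0 (default 1).
#' @param dwell Diagonal self-transition probability used when
#'   `transition_matrix` is NULL (default 0.95).
#' @param seed Master seed; component streams (sequence, amplitudes, noise)
#'   are derived from it deterministically.
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_channels = 30, K = 5, duration = 3, seed = 1)
#' @export
synth_config <- function(n_channels = 30, K = 5, transition_matrix = NULL,
                         fs = 250, duration = 3, snr_db = 20,
                         noise_exponent = 1, dwell = 0.95, seed = 1) {
  if (K < 1) stopf("K must be >= 1")
  if (fs <= 0) stopf("fs must be positive")
  if (duration <= 0) stopf("duration must be positive")
  if (noise_exponent < 0) stopf("noise_exponent must be >= 0")
  if (is.null(transition_matrix))
    transition_matrix <- dwell_transition_matrix(K, dwell)
  validate_stochastic(transition_matrix, K)
  structure(list(n_channels = as.integer(n_channels), K = as.integer(K),
                 transition_matrix = transition_matrix, fs = fs,
                 duration = duration, snr_db = snr_db,
                 noise_exponent = noise_exponent, seed = seed),
            class = "synth_config")
}

# Diagonal dwell probability, off-diagonal mass weighted by `weights`
# (stationary-distribution skew control); uniform by default.
dwell_transition_matrix <- function(K, dwell = 0.95, weights = NULL) {
  if (dwell < 0 || dwell > 1) stopf("dwell must be in [0, 1]")
  if (K == 1L) return(matrix(1, 1, 1))
  weights <- weights %||% rep(1, K)
  P <- matrix(0, K, K)
  for (i in seq_len(K)) {
    w <- weights
    w[i] <- 0
    P[i, ] <- (1 - dwell) * w / sum(w)
    P[i, i] <- dwell
  }
  P
}

validate_stochastic <- function(P, K, tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    stopf("transition matrix must be %d x %d", K, K)
  if (any(P < -tol)) stopf("transition matrix has negative entries")
  if (any(abs(rowSums(P) - 1) > tol))
    stopf("transition matrix rows must sum to 1 (max deviation %.3g)",
          max(abs(rowSums(P) - 1)))
  invisible(P)
}

#' Generate K random latent topographies
#'
#' Draws `K` zero-mean, unit-norm, mutually orthogonal channel maps
#' (orthonormal basis of a random subspace of the zero-mean hyperplane,
#' via QR of centered Gaussian vectors). Orthogonality makes every pair of
#' maps spatially uncorrelated, trivially satisfying the pairwise
#' `|corr| <= 0.5` requirement of a well-posed recovery problem. Zero-mean
#' maps live in an `(n_channels - 1)`-dimensional subspace, so at most
#' `n_channels - 1` mutually orthogonal maps exist.
#'
#' @param n_channels Number of channels.
#' @param K Number of maps; requires `K < n_channels`.
#' @param seed Seed for the map stream.
#' @return A [template_set()] (GEV/SSE fields unset).
#' @examples
#' ts <- generate_templates(30, 5, seed = 1)
#' max(abs(cor(t(ts$maps))[upper.tri(diag(5))]))  # ~ 0
#' @export
generate_templates <- function(n_channels, K, seed = 1) {
  if (K >= n_channels)
    stopf(paste("cannot build %d mutually orthogonal zero-mean maps on %d",
                "channels (at most %d exist)"),
          K, n_channels, n_channels - 1)
  maps <- with_seed(stream_seed(seed, "templates"), {
    G <- matrix(rnorm(n_channels * K), n_channels, K)
    G <- sweep(G, 2, colMeans(G))      # columns in the zero-mean subspace
    Q <- qr.Q(qr(G))                   # orthonormal, still zero-mean
    t(Q)
  })
  template_set(maps)
}

#' Simulate the first-order Markov microstate label sequence
#'
#' @param config A [synth_config()].
#' @param init_state Either `"stationary"` (sample the first label from the
#'   chain's stationary distribution) or an integer state in `1..K`.
#' @return A [label_sequence()] of length `round(fs * duration)`.
#' @export
generate_label_sequence <- function(config, init_state = "stationary") {
  stopifnot(inherits(config, "synth_config"))
  P <- config$transition_matrix
  K <- config$K
  n <- round(config$fs * config$duration)
  labels <- with_seed(stream_seed(config$seed, "sequence"), {
    x <- integer(n)
    if (identical(init_state, "stationary")) {
      x[1] <- sample.int(K, 1L, prob = stationary_distribution(P))
    } else {
      init_state <- as.integer(init_state)
      if (init_state < 1L || init_state > K) stopf("init_state outside 1..%d", K)
      x[1] <- init_state
    }
    if (n > 1L) {
      u <- runif(n - 1L)
      cumP <- t(apply(P, 1, cumsum))
      for (t in 2:n)
        x[t] <- which(u[t - 1L] <= cumP[x[t - 1L], ])[1L]
    }
    x
  })
  label_sequence(labels, fs = config$fs, K = K)
}

# Left eigenvector of P for eigenvalue 1, normalized to a probability
# vector.
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Synthesize an EEG recording from templates and a label sequence
#'
#' Each sample is the active template scaled by a random positive amplitude
#' drawn from `|N(1, 0.1^2)|`, plus spatially independent 1/f^alpha noise
#' scaled so that the realized signal-to-noise power ratio equals
#' `config$snr_db` exactly.
#'
#' @param templates A [template_set()] with `config$K` maps on
#'   `config$n_channels` channels.
#' @param labels A [label_sequence()] matching `config` in length and
#'   alphabet.
#' @param config A [synth_config()].
#' @return An [eeg_recording()] with attribute `"ground_truth"` holding the
#'   generating labels and amplitudes.
#' @export
generate_eeg <- function(templates, labels, config) {
  stopifnot(inherits(config, "synth_config"))
  maps <- if (inherits(templates, "template_set")) templates$maps else
    normalize_maps(templates)
  if (ncol(maps) != config$n_channels)
    stopf("template channel count (%d) does not match config (%d)",
          ncol(maps), config$n_channels)
  lab <- as_labels(labels)
  if (any(lab < 1L | lab > nrow(maps)))
    stopf("labels outside 1..%d", nrow(maps))
  n <- length(lab)
  amp <- with_seed(stream_seed(config$seed, "amplitudes"),
                   abs(rnorm(n, mean = 1, sd = 0.1)))
  S <- t(maps)[, lab, drop = FALSE] *
    rep(amp, each = config$n_channels)           # channels x samples
  noise <- with_seed(stream_seed(config$seed, "noise"),
                     one_over_f_noise(config$n_channels, n,
                                      config$noise_exponent))
  p_sig <- mean(S^2)
  p_noise <- mean(noise^2)
  scale <- sqrt(p_sig / (p_noise * 10^(config$snr_db / 10)))
  out <- eeg_recording(S + scale * noise, fs = config$fs)
  attr(out, "ground_truth") <- list(labels = lab, amplitudes = amp,
                                    snr_db = config$snr_db)
  out
}

# Spatially independent Gaussian noise with a 1/f^alpha amplitude spectrum,
# built by shaping white noise in the frequency domain.
one_over_f_noise <- function(n_channels, n_samples, alpha) {
  W <- matrix(rnorm(n_channels * n_samples), n_samples, n_channels)
  if (alpha == 0) return(t(W))
  # two-sided frequency magnitude per FFT bin
  f <- pmin(seq_len(n_samples) - 1, n_samples - (seq_len(n_samples) - 1))
  h <- numeric(n_samples)
  h[f > 0] <- f[f > 0]^(-alpha / 2)
  h[f == 0] <- 0                                 # no DC drift
  Fw <- mvfft(W) * h
  t(Re(mvfft(Fw, inverse = TRUE)) / n_samples)
}

#' Design of a multi-subject, multi-condition synthetic study
#'
#' Describes the study layout the statistics layer consumes: subjects
#' measured under several conditions, several pre-trigger epochs per
#' condition. Conditions may shift the randomness of the underlying label
#' chain via a dwell-probability and stationary-skew override, or supply a
#' full transition matrix.
#'
#' @param n_subjects Number of subjects (default 30, two-set pistol study
#'   layout).
#' @param conditions Named list; each element is a (possibly empty) list of
#'   overrides with elements among `dwell`, `skew` (exponential stationary
#'   weighting, 0 = uniform) and `transition_matrix`. Default three
#'   conditions with identical parameters.
#' @param trials_per_condition Epochs per subject and condition
#'   (default 60).
#' @param base_config A [synth_config()] giving the common generation
#'   parameters (default 3 s epochs at 250 Hz, 30 channels, K = 5).
#' @param subject_dwell_sd SD of a per-subject logit-scale jitter on the
#'   dwell probability, shared across conditions (default 0.2); this is the
#'   between-subject variance component the repeated-measures design
#'   removes.
#' @param include_eeg If TRUE (default) each trial carries a synthesized
#'   multichannel epoch; if FALSE only label sequences are generated (the
#'   symbolic pipeline is much cheaper and sufficient for sequence-metric
#'   studies).
#' @param seed Master seed.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 30,
                         conditions = list(normal = list(),
                                           lowlight = list(),
                                           noise = list()),
                         trials_per_condition = 60,
                         base_config = synth_config(),
                         subject_dwell_sd = 0.2,
                         include_eeg = TRUE,
                         seed = 1) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stopf("`conditions` must be a named list")
  if (trials_per_condition < 1) stopf("trials_per_condition must be >= 1")
  stopifnot(inherits(base_config, "synth_config"))
  for (nm in names(conditions)) {
    ov <- conditions[[nm]]
    if (!is.list(ov)) stopf("condition '%s' must be a list of overrides", nm)
    bad <- setdiff(names(ov), c("dwell", "skew", "transition_matrix"))
    if (length(bad))
      stopf("condition '%s': unknown override(s) %s", nm,
            paste(bad, collapse = ", "))
    if (!is.null(ov$transition_matrix))
      validate_stochastic(ov$transition_matrix, base_config$K)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions,
                 trials_per_condition = as.integer(trials_per_condition),
                 base_config = base_config,
                 subject_dwell_sd = subject_dwell_sd,
                 include_eeg = isTRUE(include_eeg),
                 seed = seed),
            class = "study_design")
}

#' Generate a full synthetic study with known ground truth
#'
#' Produces one pre-trigger epoch per (subject, condition, trial) cell,
#' together with a ground-truth table of the sequence parameters actually
#' used in each condition.
#'
#' @param design A [study_design()].
#' @return A list of class `synth_study` with elements
#'   \describe{
#'     \item{trials}{data.frame with columns `subject`, `condition`,
#'       `trial` and list-columns `labels` ([label_sequence()]) and,
#'       when `include_eeg`, `eeg` ([eeg_recording()]).}
#'     \item{ground_truth}{data.frame of per-condition true parameters
#'       (dwell, skew) plus the per-subject realized dwell values.}
#'     \item{templates}{the shared ground-truth [template_set()]
#'       (NULL when `include_eeg = FALSE`).}
#'   }
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  base <- design$base_config
  templates <- if (design$include_eeg)
    generate_templates(base$n_channels, base$K,
                       seed = stream_seed(design$seed, "study-templates"))
  else NULL

  subj_jitter <- with_seed(stream_seed(design$seed, "subject-dwell"),
                           rnorm(design$n_subjects, 0, design$subject_dwell_sd))
  cond_names <- names(design$conditions)
  base_dwell <- base$transition_matrix[1, 1]

  rows <- list()
  idx <- 0L
  for (s in seq_len(design$n_subjects)) {
    for (ci in seq_along(cond_names)) {
      ov <- design$conditions[[ci]]
      for (tr in seq_len(design$trials_per_condition)) {
        idx <- idx + 1L
        trial_seed <- stream_seed(design$seed,
                                  sprintf("s%d-c%d-t%d", s, ci, tr))
        if (!is.null(ov$transition_matrix)) {
          P <- ov$transition_matrix
        } else {
          dw <- ov$dwell %||% base_dwell
          dw <- stats::plogis(stats::qlogis(dw) + subj_jitter[s])
          w <- if (is.null(ov$skew)) rep(1, base$K) else
            exp(-(ov$skew) * (seq_len(base$K) - 1))
          P <- dwell_transition_matrix(base$K, dw, w)
        }
        cfg <- synth_config(n_channels = base$n_channels, K = base$K,
                            transition_matrix = P, fs = base$fs,
                            duration = base$duration, snr_db = base$snr_db,
                            noise_exponent = base$noise_exponent,
                            seed = trial_seed)
        lab <- generate_label_sequence(cfg)
        eeg <- if (design$include_eeg) generate_eeg(templates, lab, cfg)
               else NULL
        rows[[idx]] <- list(subject = s, condition = cond_names[ci],
                            trial = tr, labels = lab, eeg = eeg)
      }
    }
  }
  trials <- data.frame(
    subject = vapply(rows, `[[`, 0, "subject"),
    condition = vapply(rows, `[[`, "", "condition"),
    trial = vapply(rows, `[[`, 0, "trial"),
    stringsAsFactors = FALSE
  )
  trials$labels <- lapply(rows, `[[`, "labels")
  if (design$include_eeg) trials$eeg <- lapply(rows, `[[`, "eeg")

  gt <- data.frame(
    condition = cond_names,
    dwell = vapply(seq_along(cond_names), function(ci) {
      ov <- design$conditions[[ci]]
      if (!is.null(ov$transition_matrix)) NA_real_
      else ov$dwell %||% base_dwell
    }, 0),
    skew = vapply(seq_along(cond_names), function(ci)
      design$conditions[[ci]]$skew %||% 0, 0),
    stringsAsFactors = FALSE
  )
  attr(gt, "subject_dwell_jitter") <- subj_jitter

  structure(list(trials = trials, ground_truth = gt, templates = templates,
                 design = design),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> %d subjects x %d conditions x %d trials (%d epochs)%s\n",
              x$design$n_subjects, length(x$design$conditions),
              x$design$trials_per_condition, nrow(x$trials),
              if (x$design$include_eeg) ", with EEG" else ", labels only"))
  invisible(x)
}

#' Sequence-complexity metrics for every cell of a synthetic study
#'
#' Computes the six microstate-sequence complexity metrics for each trial
#' and averages them within subject and condition, yielding the
#' subject-level table the statistics layer consumes.
#'
#' @param study A `synth_study` from [generate_study()].
#' @param metrics Character subset of
#'   `c("ms_lzc", "ms_mig", "ms_fc", "ms_se", "ms_er", "ms_ee")`.
#' @param n_shuffles Shuffle count for [ms_lzc()] (default 20).
#' @param seed Seed for the shuffle stream.
#' @return Long data.frame with columns `subject`, `condition`, `metric`,
#'   `value` (trial-averaged).
#' @export
study_sequence_metrics <- function(study,
                                   metrics = c("ms_lzc", "ms_mig", "ms_fc",
                                               "ms_se", "ms_er", "ms_ee"),
                                   n_shuffles = 20, seed = 1) {
  stopifnot(inherits(study, "synth_study"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  tr <- study$trials
  per_trial <- lapply(seq_len(nrow(tr)), function(i) {
    sequence_complexity(tr$labels[[i]], metrics = metrics,
                        n_shuffles = n_shuffles,
                        seed = stream_seed(seed, sprintf("trial-%d", i)))
  })
  vals <- do.call(rbind, per_trial)
  long <- data.frame(
    subject = rep(tr$subject, times = length(metrics)),
    condition = rep(tr$condition, times = length(metrics)),
    metric = rep(metrics, each = nrow(tr)),
    value = as.vector(vals),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(value ~ subject + condition + metric, data = long,
                          FUN = mean)
  agg[order(agg$metric, agg$subject, agg$condition), , drop = FALSE]
}
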