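#' Specification of a synthetic sustained vowel
#'
#' Harmonic pulse model of sustained phonation: `n_harmonics` sinusoids with
#' 1/h amplitude roll-off, cycle-by-cycle fundamental-frequency perturbation
#' (jitter), cycle amplitude perturbation (shimmer) and additive white noise
#' scaled to a requested harmonics-to-noise ratio. Not a physiological
#' vocal-tract model; it controls exactly the periodicity properties CPP
#' responds to.
#'
#' @param f0 fundamental frequency in Hz; a warning is issued when it falls
#'   outside the quefrency band of the default CPP configuration
#'   (`rate/400` to `rate/22`, i.e. 40-727 Hz at 16 kHz).
#' @param duration seconds; below the 500 ms phonation minimum a warning is
#'   issued.
#' @param n_harmonics number of harmonics.
#' @param hnr_db harmonics-to-noise ratio in dB; `Inf` means noiseless.
#' @param jitter_pct cycle-to-cycle f0 perturbation, percent.
#' @param shimmer_pct cycle amplitude perturbation, percent.
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @return An object of class `vowel_spec`.
#' @export
vowel_spec <- function(f0 = 200, duration = 1, n_harmonics = 10, hnr_db = Inf,
                       jitter_pct = 0, shimmer_pct = 0, rate = 16000, seed = 1L) {
  if (f0 <= 0 || duration <= 0 || n_harmonics < 1) {
    stop_input("f0, duration and n_harmonics must be positive")
  }
  if (f0 < rate / 400 || f0 > rate / 22) {
    warning(sprintf("f0 = %g Hz is outside the default quefrency band (%.0f-%.0f Hz at %g Hz); the cepstral peak will fall outside [tmin, tmax]",
                    f0, rate / 400, rate / 22, rate), call. = FALSE)
  }
  if (duration < 0.5) {
    warning("duration below the 500 ms phonation minimum", call. = FALSE)
  }
  structure(list(f0 = f0, duration = duration, n_harmonics = n_harmonics,
                 hnr_db = hnr_db, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, rate = rate, seed = as.integer(seed)),
            class = "vowel_spec")
}

#' Synthesize a sustained vowel
#'
#' Cycles are generated one fundamental period at a time (each starting at
#' zero phase, so the waveform is continuous), with per-cycle jitter on f0
#' and shimmer on amplitude; white Gaussian noise is added at the requested
#' HNR and the result is peak-normalized to 0.9.
#'
#' @param spec a [vowel_spec()].
#' @return An [audio_signal()] of `round(duration * rate)` samples.
#' @export
synth_vowel <- function(spec) {
  stopifnot(inherits(spec, "vowel_spec"))
  n <- round(spec$duration * spec$rate)
  with_seed(spec$seed, {
    out <- numeric(0)
    while (length(out) < n) {
      f0c <- spec$f0 * (1 + spec$jitter_pct / 100 * stats::rnorm(1))
      period <- max(8L, round(spec$rate / max(f0c, 1)))
      amp <- max(0, 1 + spec$shimmer_pct / 100 * stats::rnorm(1))
      phase <- 2 * pi * seq_len(period) / period
      cyc <- rowSums(vapply(seq_len(spec$n_harmonics),
                            function(h) sin(h * phase) / h,
                            numeric(period)))
      out <- c(out, amp * cyc)
    }
    out <- out[seq_len(n)]
    if (is.finite(spec$hnr_db)) {
      p_harm <- mean(out^2)
      p_noise <- p_harm / 10^(spec$hnr_db / 10)
      out <- out + stats::rnorm(n, sd = sqrt(p_noise))
    }
    audio_signal(0.9 * out / max(abs(out)), spec$rate)
  })
}

#' Specification of a synthetic CPP cohort
#'
#' Per-cell Gaussian CPP distributions for each label x sex x age-group
#' cell, mirroring the study design: 24 speakers, 12 per class, 3 per cell,
#' with the affected (SMS) cells shifted to lower CPP and two cells
#' configured for greater class overlap (young girls, older boys). Default
#' magnitudes (~0.05) match linear log-magnitude CPP units.
#'
#' @param cells data frame with columns `label`, `sex`, `age_group`,
#'   `mean`, `sd` covering all 8 cells; every SMS cell mean must be below
#'   its matched normative cell mean and all sds positive.
#' @param speakers_per_cell speakers per cell.
#' @param samples_range inclusive range the per-speaker CPP count is drawn
#'   from uniformly.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = default_cohort_cells(), speakers_per_cell = 3,
                        samples_range = c(90, 130), seed = 1L) {
  need <- c("label", "sex", "age_group", "mean", "sd")
  if (!all(need %in% names(cells))) {
    stop_input("cells must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(cells$sd <= 0)) stop_input("cell sd values must be positive")
  for (sx in SEX_LEVELS) for (g in GROUP_LEVELS) {
    m_n <- cells$mean[cells$label == "N" & cells$sex == sx & cells$age_group == g]
    m_s <- cells$mean[cells$label == "SMS" & cells$sex == sx & cells$age_group == g]
    if (length(m_n) != 1L || length(m_s) != 1L) {
      stop_input("cells must cover each label x sex x age_group cell exactly once")
    }
    if (m_s >= m_n) {
      stop_input("SMS cell mean must be below the matched normative mean (%s/%s)", sx, g)
    }
  }
  if (!is_count(speakers_per_cell) || speakers_per_cell < 1) {
    stop_input("speakers_per_cell must be a positive integer")
  }
  if (length(samples_range) != 2L || samples_range[1] > samples_range[2] ||
      samples_range[1] < 1) {
    stop_input("samples_range must be an increasing pair of positive counts")
  }
  structure(list(cells = cells, speakers_per_cell = as.integer(speakers_per_cell),
                 samples_range = as.integer(samples_range), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort cell parameters
#'
#' Normative cells at mean 0.050; SMS cells at 0.030 except the two
#' greater-overlap cells (young females 0.040, older males 0.038); common
#' sd 0.004.
#'
#' @return Data frame of 8 cells.
#' @export
default_cohort_cells <- function() {
  cells <- expand.grid(label = LABEL_LEVELS, sex = SEX_LEVELS,
                       age_group = GROUP_LEVELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$mean <- ifelse(cells$label == "N", 0.050, 0.030)
  cells$mean[cells$label == "SMS" & cells$sex == "female" & cells$age_group == "young"] <- 0.040
  cells$mean[cells$label == "SMS" & cells$sex == "male" & cells$age_group == "older"] <- 0.038
  cells$sd <- 0.004
  cells
}

#' Draw a synthetic cohort of CPP streams
#'
#' Per-speaker CPP sequences are sampled i.i.d. from the speaker's cell
#' distribution, with per-speaker counts drawn uniformly from
#' `samples_range`. Ages are drawn within the group's range (young 5-7,
#' older 8-12).
#'
#' @param spec a [cohort_spec()].
#' @return A [cohort()]; with the defaults, 24 speakers (12 SMS, 12 N).
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    records <- list()
    for (ci in seq_len(nrow(spec$cells))) {
      cell <- spec$cells[ci, ]
      for (k in seq_len(spec$speakers_per_cell)) {
        id <- sprintf("%s_%s_%s_%d", cell$label, substr(cell$sex, 1, 1),
                      substr(cell$age_group, 1, 1), k)
        count <- sample(spec$samples_range[1]:spec$samples_range[2], 1)
        age <- if (cell$age_group == "young") sample(5:7, 1) else sample(8:12, 1)
        records[[length(records) + 1L]] <-
          speaker_record(id, cell$sex, age, cell$age_group, cell$label,
                         stats::rnorm(count, cell$mean, cell$sd))
      }
    }
    cohort(records)
  })
}

#' Three-speaker toy cohort for windowing demonstrations
#'
#' Per-speaker CPP counts 14, 21 and 24 — small enough to trace the prime
#' candidate list and loss map by hand.
#'
#' @param seed integer seed for the CPP draws.
#' @return A [cohort()] of 3 speakers (counts 14, 21, 24).
#' @export
toy_windowing_cohort <- function(seed = 42L) {
  with_seed(seed, {
    cohort(list(
      speaker_record("N1", "female", 9, "older", "N", stats::rnorm(14, 0.050, 0.004)),
      speaker_record("N2", "male", 6, "young", "N", stats::rnorm(21, 0.050, 0.004)),
      speaker_record("SMS3", "male", 6, "young", "SMS", stats::rnorm(24, 0.030, 0.004))
    ))
  })
}

#' Build a cohort from synthetic audio
#'
#' End-to-end fixture path: one synthetic vowel per speaker (high HNR for
#' normative voices, low HNR plus jitter for SMS voices), CPP extracted with
#' the standard chain. Slower than direct CPP sampling; used to check that
#' the signal-level and table-level generators agree on class ordering.
#'
#' @param n_per_class speakers per class.
#' @param duration seconds of phonation per speaker.
#' @param hnr_n,hnr_sms class HNR levels in dB.
#' @param jitter_sms SMS jitter, percent.
#' @param seed integer seed.
#' @return A [cohort()].
#' @export
synth_audio_cohort <- function(n_per_class = 2, duration = 0.6,
                               hnr_n = 30, hnr_sms = 2, jitter_sms = 2,
                               seed = 1L) {
  records <- list()
  for (i in seq_len(n_per_class)) {
    for (lab in LABEL_LEVELS) {
      vs <- vowel_spec(f0 = 220 + 10 * i, duration = duration,
                       hnr_db = if (lab == "N") hnr_n else hnr_sms,
                       jitter_pct = if (lab == "N") 0.2 else jitter_sms,
                       shimmer_pct = if (lab == "N") 0.5 else 3,
                       seed = seed + 7L * i + (lab == "SMS"))
      series <- extract_cpp(synth_vowel(vs))
      records[[length(records) + 1L]] <-
        speaker_record(sprintf("%s_audio_%d", lab, i), "female", 6, "young",
                       lab, series$smoothed)
    }
  }
  cohort(records)
}

#' Boxplot of cohort CPP by class and sex
#'
#' Unstyled descriptive plot: CPP distributions split by sex, affected vs
#' normative side by side.
#'
#' @param x a [cohort()].
#' @return Invisibly, the long data frame plotted.
#' @export
plot_cohort_cpp <- function(x) {
  stopifnot(inherits(x, "cohort"))
  df <- do.call(rbind, lapply(x$records, function(r) {
    data.frame(cpp = r$cpp_values, label = r$label, sex = r$sex,
               stringsAsFactors = FALSE)
  }))
  graphics::boxplot(cpp ~ label + sex, data = df, horizontal = TRUE,
                    las = 1, xlab = "CPP", ylab = "",
                    col = c("orange", "lightblue"))
  invisible(df)
}

#' Barplot of per-speaker mean CPP
#'
#' @param x a [cohort()].
#' @return Invisibly, the named vector of per-speaker means.
#' @export
plot_speaker_means <- function(x) {
  stopifnot(inherits(x, "cohort"))
  s <- cohort_summary(x)
  means <- vapply(x$records, function(r) mean(r$cpp_values), numeric(1))
  names(means) <- s$speaker_id
  graphics::barplot(means, las = 2, ylab = "mean CPP",
                    col = ifelse(s$label == "SMS", "orange", "lightblue"))
  invisible(means)
}
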