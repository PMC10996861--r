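test_that("framing covers the signal with hop-spaced frames and no padding", {
  cfg <- framing_config()
  one <- frame_signal(audio_signal(seq_len(1024) / 1024, 16000), cfg)
  expect_equal(dim(one), c(1, 1024))

  sig <- audio_signal(rnorm(8000), 16000)  # 500 ms at 16 kHz
  fr <- frame_signal(sig, cfg)
  expect_equal(nrow(fr), 55)  # floor((8000 - 1024) / 128) + 1
  # frame i covers samples [i*hop, i*hop + frame_len)
  expect_equal(fr[3, ], sig$samples[(2 * 128 + 1):(2 * 128 + 1024)])

  expect_error(frame_signal(audio_signal(rnorm(1023), 16000), cfg), "1024")
})

test_that("the cepstrum of silence is a log-floor impulse at quefrency zero", {
  ccfg <- cepstral_config()
  cep <- compute_cepstrum(numeric(1024), framing_config(), ccfg)
  expect_equal(cep[1], log(ccfg$log_floor))
  expect_equal(cep[-1], numeric(1023), tolerance = 1e-9)
})

test_that("a harmonic frame peaks at the fundamental period and is finite", {
  for (f0 in c(100, 200, 320)) {
    sig <- synth_vowel(vowel_spec(f0 = f0, duration = 0.5))
    cep <- compute_cepstrum(frame_signal(sig)[1, ])
    expect_true(all(is.finite(cep)))
    # brute-force band argmax oracle
    band <- 22:400
    oracle <- band[which.max(cep[band + 1])]
    expect_equal(band_argmax(cep), oracle)
    expect_lte(abs(oracle - round(16000 / f0)), 1)
  }
  expect_error(compute_cepstrum(c(NaN, numeric(1023))), "non-finite")
})

test_that("both smoothers preserve constants exactly, including edges", {
  ccfg <- cepstral_config()
  expect_equal(smooth_cepstrum(rep(2.5, 500), ccfg), rep(2.5, 500))
  expect_equal(smooth_cpp_series(rep(-1.2, 40), ccfg), rep(-1.2, 40))
  expect_equal(smooth_cpp_series(numeric(0), ccfg), numeric(0))
})

test_that("smoothing an interior impulse yields the coefficient sequence", {
  ccfg <- cepstral_config()
  x <- numeric(100)
  x[50] <- 1
  y <- smooth_cepstrum(x, ccfg)
  a <- signal::hamming(7) / sum(signal::hamming(7))
  expect_equal(y[50:56], as.numeric(a))
  expect_lt(max(y), 1)
  # an isolated peak's band argmax moves by at most l - 1 samples
  set.seed(3)
  for (rep in 1:5) {
    cf <- rnorm(1024, sd = 0.001)
    at <- sample(60:380, 1)
    cf[at + 1] <- 1
    expect_lte(abs(band_argmax(smooth_cepstrum(cf)) - at), 6)
  }
})

test_that("peak prominence is max minus mean-of-rest over the band", {
  ccfg <- cepstral_config()
  cf <- numeric(1024)
  cf[(22:400) + 1] <- 3.7
  expect_equal(cpp_of_frame(cf, ccfg), 0)

  cf[(22:400) + 1] <- 0.2
  cf[101] <- 0.2 + 0.9  # spike of height h on constant baseline
  expect_equal(cpp_of_frame(cf, ccfg), 0.9)

  expect_error(cpp_of_frame(numeric(300), ccfg), "band")
})

test_that("prominence agrees with the brute-force loop and is non-negative", {
  set.seed(11)
  for (i in 1:100) {
    cf <- rnorm(1024)
    v <- cpp_of_frame(cf)
    expect_equal(v, brute_cpp(cf), tolerance = 1e-12)
    expect_gte(v, 0)
    expect_true(is.finite(v))
  }
})

test_that("a harmonic frame scores higher CPP than equal-power noise", {
  harm <- frame_signal(synth_vowel(vowel_spec(f0 = 200, duration = 0.5)))[5, ]
  set.seed(2)
  noise <- rnorm(1024)
  noise <- noise * sqrt(mean(harm^2) / mean(noise^2))
  cpp_h <- brute_cpp(smooth_cepstrum(compute_cepstrum(harm)))
  cpp_n <- brute_cpp(smooth_cepstrum(compute_cepstrum(noise)))
  expect_gt(cpp_h, cpp_n)
})

test_that("extract_cpp yields one raw and one smoothed value per frame", {
  sig <- synth_vowel(vowel_spec(f0 = 220, duration = 0.5))
  cs <- extract_cpp(sig)
  expect_s3_class(cs, "cpp_series")
  expect_length(cs$raw, 55)
  expect_length(cs$smoothed, 55)
  expect_equal(cs$hop_seconds, 128 / 16000)

  df <- as.data.frame(cs)
  expect_named(df, c("frame_index", "time_s", "cpp_raw", "cpp_smoothed"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_cpp_csv(cs, p)
  expect_equal(nrow(read.csv(p)), 55)
})

test_that("non-16 kHz input is accepted with a calibration warning", {
  sig <- audio_signal(rnorm(6000), 8000)
  expect_warning(extract_cpp(sig), "16 kHz")
})

test_that("mean smoothed CPP decreases as noise drowns the harmonics", {
  sweep <- c(30, 20, 10, 0)
  means <- vapply(sweep, function(hnr) {
    sig <- synth_vowel(vowel_spec(f0 = 200, duration = 0.5, hnr_db = hnr,
                                  jitter_pct = 0.5, seed = 99))
    mean(suppressWarnings(extract_cpp(sig))$smoothed)
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
  expect_gt(means[1], means[length(means)])
})
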