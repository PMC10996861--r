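# Independent oracles and fixture builders, kept deliberately naive.

# Brute-force CPP: explicit loop over the quefrency band, no vector tricks.
brute_cpp <- function(cf, tmin = 22, tmax = 400) {
  peak <- -Inf
  peak_at <- NA
  for (q in tmin:tmax) {
    v <- cf[q + 1]
    if (v > peak) { peak <- v; peak_at <- q }
  }
  rest <- 0
  for (q in tmin:tmax) {
    if (q != peak_at) rest <- rest + cf[q + 1]
  }
  # remove exactly one copy of the maximum; if duplicated, drop the first hit
  peak - rest / (tmax - tmin)
}

# Independent rank-sum oracle: U counted as concordant pairs (x_i > y_j gets
# 1, ties get 1/2), p by enumerating every assignment of pooled values.
enum_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
  }
  u
}

enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  obs <- abs(enum_u(x, y) - mu)
  sets <- utils::combn(n, n1, simplify = FALSE)
  hits <- vapply(sets, function(s) {
    abs(enum_u(pooled[s], pooled[-s]) - mu) >= obs - 1e-9
  }, logical(1))
  mean(hits)
}

# Windowed-table builder with synthetic class separation.
make_windowed_table <- function(n_sms, n_n, nprime = 3,
                                sms_mean = 0.03, n_mean = 0.05, sd = 0.004,
                                seed = 1, speakers_per_class = 1) {
  set.seed(seed)
  mk <- function(label, n_rows, mu, sp_id) {
    feats <- matrix(rnorm(n_rows * nprime, mu, sd), n_rows)
    colnames(feats) <- paste0("CPP", seq_len(nprime))
    data.frame(Name = paste0(sp_id, ".", seq_len(n_rows)), feats,
               Target = label, Sex = "Female", Group = "Young",
               stringsAsFactors = FALSE)
  }
  parts <- list()
  for (s in seq_len(speakers_per_class)) {
    parts[[length(parts) + 1]] <- mk("SMS", n_sms, sms_mean, paste0("SMS", s))
    parts[[length(parts) + 1]] <- mk("N", n_n, n_mean, paste0("CTL", s))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, nprime = nprime)
}

# Small fast cohort for protocol tests.
small_cohort_spec <- function(seed = 7) {
  cohort_spec(speakers_per_cell = 1, samples_range = c(12, 18), seed = seed)
}
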