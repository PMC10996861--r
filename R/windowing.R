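is_prime <- function(p) {
  if (p < 2) return(FALSE)
  if (p < 4) return(TRUE)
  if (p %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= p) {
    if (p %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

#' Candidate subgroup sizes for windowing
#'
#' All primes `p` with `3 <= p <= nmin`, ascending, where `nmin` is the
#' smallest per-speaker CPP count in the cohort.
#'
#' @param nmin smallest per-speaker count; must be at least 3.
#' @return Integer vector of primes.
#' @export
candidate_primes <- function(nmin) {
  if (!is_count(nmin)) stop_input("nmin must be a single integer")
  if (nmin < 3) {
    stop_input("cohort too small to window: nmin = %d, need at least 3 CPP values per speaker",
               nmin)
  }
  cand <- 3:nmin
  cand[vapply(cand, is_prime, logical(1))]
}

#' Samples lost when windowing at a given subgroup size
#'
#' Each speaker with `s` values contributes `s mod p` discarded samples.
#'
#' @param counts per-speaker CPP counts (all >= 1).
#' @param p subgroup size.
#' @return Total discarded sample count.
#' @export
total_loss <- function(counts, p) {
  if (!is.numeric(counts) || length(counts) < 1L || any(counts < 1)) {
    stop_input("counts must be a non-empty vector of positive integers")
  }
  sum(counts %% p)
}

#' Choose the prime subgroup size that minimizes discarded samples
#'
#' Searches all primes in `[3, min(counts)]` and picks the one whose total
#' loss (sum of per-speaker remainders) is smallest. Ties are broken toward
#' the larger prime, which yields richer feature rows per sample; a message
#' is emitted whenever the tie-break fires.
#'
#' @param counts per-speaker CPP counts; `min(counts) >= 3`.
#' @return A `windowing_plan`: list with `nprime`, `nmin`, `candidates`,
#'   `loss_by_candidate` (named integer vector) and `counts`.
#' @export
select_nprime <- function(counts) {
  nmin <- min(counts)
  cand <- candidate_primes(nmin)
  losses <- vapply(cand, function(p) total_loss(counts, p), numeric(1))
  best_loss <- min(losses)
  winners <- cand[losses == best_loss]
  if (length(winners) > 1L) {
    message(sprintf("windowing tie at loss %d between primes {%s}; choosing the larger (%d)",
                    best_loss, paste(winners, collapse = ", "), max(winners)))
  }
  structure(list(nprime = max(winners),
                 nmin = as.integer(nmin),
                 candidates = as.integer(cand),
                 loss_by_candidate = stats::setNames(as.integer(losses), cand),
                 counts = as.integer(counts)),
            class = "windowing_plan")
}

#' Build a windowing plan with a caller-forced subgroup size
#'
#' Bypasses loss minimization; used to mirror a published configuration
#' (e.g. a fixed `nprime = 7`). The forced size must still be a prime no
#' larger than the smallest per-speaker count.
#'
#' @param counts per-speaker CPP counts.
#' @param nprime forced prime subgroup size.
#' @return A `windowing_plan`.
#' @export
force_nprime <- function(counts, nprime) {
  nmin <- min(counts)
  cand <- candidate_primes(nmin)
  if (!nprime %in% cand) {
    stop_input("forced nprime = %d is not a prime in [3, nmin = %d]", nprime, nmin)
  }
  losses <- vapply(cand, function(p) total_loss(counts, p), numeric(1))
  structure(list(nprime = as.integer(nprime),
                 nmin = as.integer(nmin),
                 candidates = as.integer(cand),
                 loss_by_candidate = stats::setNames(as.integer(losses), cand),
                 counts = as.integer(counts)),
            class = "windowing_plan")
}

#' @export
print.windowing_plan <- function(x, ...) {
  cat(sprintf("<windowing_plan: nprime = %d (nmin = %d, loss = %d of %d values)>\n",
              x$nprime, x$nmin, x$loss_by_candidate[[as.character(x$nprime)]],
              sum(x$counts)))
  cat("  candidate losses:",
      paste(sprintf("%s:%d", names(x$loss_by_candidate), x$loss_by_candidate),
            collapse = "  "), "\n")
  invisible(x)
}

#' Serialize a windowing plan as JSON
#'
#' @param plan a `windowing_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "windowing_plan"))
  jsonlite::write_json(list(nmin = plan$nmin,
                            candidates = plan$candidates,
                            loss_by_candidate = as.list(plan$loss_by_candidate),
                            nprime = plan$nprime),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Partition each speaker's CPP stream into fixed-width rows
#'
#' Each speaker with `s` values yields `floor(s / nprime)` rows of `nprime`
#' consecutive values taken in original temporal order; the final
#' `s mod nprime` values are discarded. Row names append a 1-based subgroup
#' index to the speaker id (`"SMS3.1"`, `"SMS3.2"`, ...). No values are ever
#' mixed across speakers.
#'
#' @param x a [cohort()].
#' @param plan a `windowing_plan` (from [select_nprime()] or
#'   [force_nprime()]), or a single prime size.
#' @return A windowed table: data frame with columns `Name`,
#'   `CPP1..CPPnprime`, `Target`, `Sex`, `Group` and attributes `nprime` and
#'   `discarded` (named per-speaker discard counts).
#' @export
apply_windowing <- function(x, plan) {
  stopifnot(inherits(x, "cohort"))
  if (is.numeric(plan)) plan <- force_nprime(speaker_counts(x), plan)
  stopifnot(inherits(plan, "windowing_plan"))
  np <- plan$nprime
  counts <- speaker_counts(x)
  if (np > min(counts)) {
    stop_input("nprime = %d exceeds the smallest per-speaker count (%d)",
               np, min(counts))
  }
  rows <- lapply(x$records, function(r) {
    s <- length(r$cpp_values)
    k <- s %/% np
    if (k == 0L) return(NULL)
    feats <- matrix(r$cpp_values[seq_len(k * np)], nrow = k, byrow = TRUE)
    colnames(feats) <- windowed_feature_cols(np)
    df <- data.frame(Name = paste0(r$speaker_id, ".", seq_len(k)),
                     feats,
                     Target = r$label,
                     Sex = c(female = "Female", male = "Male")[[r$sex]],
                     Group = c(young = "Young", older = "Older")[[r$age_group]],
                     stringsAsFactors = FALSE, row.names = NULL)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            nprime = np,
            discarded = counts %% np)
}
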