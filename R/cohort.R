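SEX_LEVELS <- c("female", "male")
GROUP_LEVELS <- c("young", "older")
LABEL_LEVELS <- c("N", "SMS")

canon_token <- function(x, levels, what, where = NULL) {
  m <- levels[match(tolower(x), tolower(levels))]
  bad <- which(is.na(m))
  if (length(bad)) {
    ctx <- if (is.null(where)) "" else sprintf(" (row %s)", paste(where[bad], collapse = ", "))
    stop_input("unknown %s token '%s'%s; expected one of: %s",
               what, x[bad[1]], ctx, paste(levels, collapse = ", "))
  }
  m
}

#' One speaker's pooled CPP values plus metadata
#'
#' @param speaker_id opaque identifier, unique within a cohort.
#' @param sex `"female"` or `"male"`.
#' @param age years.
#' @param age_group `"young"` (5-7 years) or `"older"` (8-12 years).
#' @param label `"SMS"` (affected) or `"N"` (normative).
#' @param cpp_values non-empty numeric vector of per-window CPP values, in
#'   temporal order.
#' @return An object of class `speaker_record`.
#' @export
speaker_record <- function(speaker_id, sex, age, age_group, label, cpp_values) {
  if (!is.character(speaker_id) || length(speaker_id) != 1L || !nzchar(speaker_id)) {
    stop_input("speaker_id must be a non-empty string")
  }
  if (!is.numeric(cpp_values) || length(cpp_values) < 1L || !all(is.finite(cpp_values))) {
    stop_input("cpp_values must be a non-empty finite numeric vector (speaker %s)",
               speaker_id)
  }
  structure(list(speaker_id = speaker_id,
                 sex = canon_token(sex, SEX_LEVELS, "sex"),
                 age = as.numeric(age),
                 age_group = canon_token(age_group, GROUP_LEVELS, "age_group"),
                 label = canon_token(label, LABEL_LEVELS, "label"),
                 cpp_values = as.numeric(cpp_values)),
            class = "speaker_record")
}

#' A cohort of speakers
#'
#' @param records list of [speaker_record()] objects; at least two speakers
#'   with unique identifiers.
#' @return An object of class `cohort`.
#' @export
cohort <- function(records) {
  if (!is.list(records) || length(records) < 2L) {
    stop_input("a cohort needs at least 2 speakers")
  }
  ok <- vapply(records, inherits, logical(1), "speaker_record")
  if (!all(ok)) stop_input("all cohort elements must be speaker_record objects")
  ids <- vapply(records, `[[`, character(1), "speaker_id")
  if (anyDuplicated(ids)) {
    stop_input("duplicate speaker_id in cohort: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(records = records), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf("<cohort: %d speakers (%d SMS / %d N), %d CPP values>\n",
              nrow(s), sum(s$label == "SMS"), sum(s$label == "N"), sum(s$n_values)))
  invisible(x)
}

#' Per-speaker cohort summary
#'
#' @param x a [cohort()].
#' @return A data frame with one row per speaker: `speaker_id`, `sex`, `age`,
#'   `age_group`, `label`, `n_values`.
#' @export
cohort_summary <- function(x) {
  stopifnot(inherits(x, "cohort"))
  do.call(rbind, lapply(x$records, function(r) {
    data.frame(speaker_id = r$speaker_id, sex = r$sex, age = r$age,
               age_group = r$age_group, label = r$label,
               n_values = length(r$cpp_values), stringsAsFactors = FALSE)
  }))
}

#' Named per-speaker CPP counts
#'
#' @param x a [cohort()].
#' @return Integer vector named by speaker id; the input the windowing
#'   planner works on.
#' @export
speaker_counts <- function(x) {
  s <- cohort_summary(x)
  stats::setNames(s$n_values, s$speaker_id)
}

#' Read a long-format cohort CSV
#'
#' Interchange format with one row per CPP value and columns `speaker_id`,
#' `sex`, `age`, `age_group`, `label`, `cpp`. Rows are grouped by
#' `speaker_id` (by key, not adjacency), preserving the within-speaker row
#' order.
#'
#' @param path CSV path.
#' @return A [cohort()].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_input("cohort CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("speaker_id", "sex", "age", "age_group", "label", "cpp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_input("cohort CSV %s is missing columns: %s", path,
               paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_input("cohort CSV %s contains no rows", path)
  rows <- seq_len(nrow(df))
  df$sex <- canon_token(df$sex, SEX_LEVELS, "sex", rows)
  df$age_group <- canon_token(df$age_group, GROUP_LEVELS, "age_group", rows)
  df$label <- canon_token(df$label, LABEL_LEVELS, "label", rows)
  ids <- unique(df$speaker_id)
  records <- lapply(ids, function(id) {
    sub <- df[df$speaker_id == id, , drop = FALSE]
    for (col in c("sex", "age", "age_group", "label")) {
      if (length(unique(sub[[col]])) != 1L) {
        stop_input("inconsistent %s for speaker %s in %s", col, id, path)
      }
    }
    speaker_record(id, sub$sex[1], sub$age[1], sub$age_group[1], sub$label[1],
                   sub$cpp)
  })
  cohort(records)
}

#' Write a cohort as a long-format CSV
#'
#' @param x a [cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- do.call(rbind, lapply(x$records, function(r) {
    data.frame(speaker_id = r$speaker_id, sex = r$sex, age = r$age,
               age_group = r$age_group, label = r$label, cpp = r$cpp_values,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- windowed-table dialect -------------------------------------------------

windowed_feature_cols <- function(nprime) paste0("CPP", seq_len(nprime))

windowed_dialect_cols <- function(nprime) {
  c("Name", windowed_feature_cols(nprime), "Target", "Sex", "Group")
}

#' Speaker identifiers of windowed rows
#'
#' Row names carry a dotted subgroup suffix (`"SMS3.3"` is the third
#' fixed-width subgroup of speaker `SMS3`); this strips it.
#'
#' @param table a windowed table.
#' @return Character vector of speaker ids, one per row.
#' @export
windowed_speakers <- function(table) {
  sub("\\.[0-9]+$", "", table$Name)
}

#' Write a windowed table in the fixed-width dialect
#'
#' Header is exactly `Name,CPP1,...,CPPn,Target,Sex,Group`. Any bookkeeping
#' columns (e.g. the synthetic flag added by SMOTE balancing) are dropped.
#'
#' @param table a windowed table as produced by [apply_windowing()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windowed_csv <- function(table, path) {
  nprime <- attr(table, "nprime")
  if (is.null(nprime)) stop_input("not a windowed table (missing nprime attribute)")
  out <- table[, windowed_dialect_cols(nprime), drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_input("failed writing windowed CSV to %s: %s",
                              path, conditionMessage(ok))
  invisible(path)
}

#' Read a windowed table from the fixed-width dialect
#'
#' @param path CSV path written by [write_windowed_csv()].
#' @return A windowed table (data frame with an `nprime` attribute).
#' @export
read_windowed_csv <- function(path) {
  if (!file.exists(path)) stop_input("windowed CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feat <- grep("^CPP[0-9]+$", names(df), value = TRUE)
  nprime <- length(feat)
  need <- windowed_dialect_cols(nprime)
  if (nprime == 0L || !identical(names(df)[seq_along(need)], need)) {
    stop_input("%s is not in the windowed-table dialect (Name,CPP1..CPPn,Target,Sex,Group)",
               path)
  }
  df$Target <- canon_token(df$Target, LABEL_LEVELS, "label", seq_len(nrow(df)))
  structure(df, nprime = nprime)
}
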