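## Long-format cohort container for dyadic Symptom Questionnaire data.
## One row per (dyad, parent role, time point); columns are the 8 SQ
## subscales plus the child's sex. Column order is fixed package-wide.

#' Symptom Questionnaire subscale names
#'
#' The eight subscales, in the fixed column order used by every matrix and
#' network in the package: the four symptom scales (Anxiety, Depression,
#' Somatisation, Hostility) followed by the four well-being scales
#' (Relaxation, Contentedness, PhysicalWellBeing, Friendliness).
#'
#' @return Character vector of length 8.
#' @export
sq_subscales <- function() {
  c("Anxiety", "Depression", "Somatisation", "Hostility",
    "Relaxation", "Contentedness", "PhysicalWellBeing", "Friendliness")
}

#' Default subscale score ranges
#'
#' Maximum attainable score per subscale: 17 for the symptom scales and 6
#' for the well-being scales, reflecting the SQ item counts. The instrument
#' manual is the authority for any deviating administration, so every
#' reader/generator accepts an explicit `scale_ranges` override.
#'
#' @return Named integer vector, one entry per subscale.
#' @export
default_scale_ranges <- function() {
  setNames(c(17L, 17L, 17L, 17L, 6L, 6L, 6L, 6L), sq_subscales())
}

parent_roles <- function() c("mother", "father")
time_points  <- function() c("T1", "T2", "T3")
child_sexes  <- function() c("female", "male")

#' Node labels of a stratum network
#'
#' The 8 continuous subscale nodes followed by the dichotomous `child_sex`
#' node.
#'
#' @return Character vector of length 9.
#' @export
network_node_labels <- function() c(sq_subscales(), "child_sex")

cohort_columns <- function() {
  c("dyad_id", "parent_role", "time_point", sq_subscales(), "child_sex")
}

#' Construct a validated cohort table
#'
#' @param records Data frame with columns `dyad_id`, `parent_role`
#'   (`"mother"`/`"father"`), `time_point` (`"T1"`/`"T2"`/`"T3"`), the 8
#'   subscale integer scores, and `child_sex` (`"female"`/`"male"`).
#' @param scale_ranges Named vector of per-subscale maxima
#'   (default [default_scale_ranges()]).
#' @return A `cohort_table`: the data frame with a `scale_ranges` attribute.
#' @export
cohort_table <- function(records, scale_ranges = default_scale_ranges()) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, cohort_columns(), drop = FALSE]
  if (!setequal(names(scale_ranges), sq_subscales())) {
    stop("scale_ranges must name exactly the 8 SQ subscales")
  }
  scale_ranges <- scale_ranges[sq_subscales()]
  records$dyad_id <- as.character(records$dyad_id)
  records$parent_role <- as.character(records$parent_role)
  records$time_point <- as.character(records$time_point)
  records$child_sex <- as.character(records$child_sex)
  validate_cohort_records(records, scale_ranges)
  structure(records, scale_ranges = scale_ranges,
            class = c("cohort_table", "data.frame"))
}

validate_cohort_records <- function(records, scale_ranges) {
  n <- nrow(records)
  if (n == 0) return(invisible(TRUE))
  bad <- function(col, ok) {
    if (any(!ok)) {
      stop("row ", which(!ok)[1], ": invalid value in field '", col, "'",
           call. = FALSE)
    }
  }
  bad("parent_role", records$parent_role %in% parent_roles())
  bad("time_point", records$time_point %in% time_points())
  bad("child_sex", records$child_sex %in% child_sexes())
  for (s in sq_subscales()) {
    v <- records[[s]]
    if (!is.numeric(v) || any(is.na(v))) {
      stop("row ", which(!is.numeric(v) | is.na(v))[1],
           ": non-numeric or missing score in field '", s, "'", call. = FALSE)
    }
    if (any(v != round(v))) {
      stop("row ", which(v != round(v))[1],
           ": non-integer score in field '", s, "'", call. = FALSE)
    }
    out <- v < 0 | v > scale_ranges[[s]]
    if (any(out)) {
      stop("row ", which(out)[1], ": score out of range [0, ",
           scale_ranges[[s]], "] in field '", s, "'", call. = FALSE)
    }
    records[[s]] <- as.integer(v)
  }
  key <- paste(records$dyad_id, records$parent_role, records$time_point)
  if (anyDuplicated(key)) {
    stop("row ", which(duplicated(key))[1],
         ": duplicate (dyad_id, parent_role, time_point) key", call. = FALSE)
  }
  sex_per_dyad <- tapply(records$child_sex, records$dyad_id,
                         function(x) length(unique(x)))
  if (any(sex_per_dyad > 1)) {
    dy <- names(sex_per_dyad)[sex_per_dyad > 1][1]
    stop("row ", which(records$dyad_id == dy)[1],
         ": inconsistent field 'child_sex' within dyad '", dy, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Scale ranges of a cohort
#' @param cohort A `cohort_table`.
#' @return Named integer vector of per-subscale maxima.
#' @export
scale_ranges <- function(cohort) attr(cohort, "scale_ranges")

#' Read a cohort from a long-format CSV file
#'
#' The file must be comma-separated UTF-8 with a single header row naming,
#' in any order, `dyad_id`, `parent_role`, `time_point`, the 8 subscales and
#' `child_sex`; role/time/sex are stored as lowercase tokens (`mother`,
#' `father`, `T1`..`T3`, `female`, `male`). Row order is preserved.
#'
#' @param path CSV file path.
#' @param scale_ranges Per-subscale maxima used for validation.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, scale_ranges = default_scale_ranges()) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  extra_cols <- setdiff(names(df), cohort_columns())
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    stop("malformed header in ", path,
         if (length(missing_cols)) paste0("; missing: ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; unexpected: ",
                                        paste(extra_cols, collapse = ", ")))
  }
  for (s in sq_subscales()) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    if (nrow(df) > 0 && any(is.na(v))) {
      stop("row ", which(is.na(v))[1], ": non-numeric score in field '",
           s, "'")
    }
    df[[s]] <- v
  }
  cohort_table(df, scale_ranges)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]; the dialect is byte-stable, so
#' write-read-write reproduces the file exactly.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns(), drop = FALSE]
  for (s in sq_subscales()) df[[s]] <- as.integer(df[[s]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only dyads observed at every role and time point
#'
#' A dyad is complete when all 6 records (2 roles x 3 times) are present.
#' This mirrors the study design in which father dropout after baseline
#' forces the exclusion of the paired mother, leaving matched pairs only.
#' Idempotent.
#'
#' @param cohort A `cohort_table`.
#' @return List with `cohort` (complete-case `cohort_table`) and `report`
#'   (list: `n_enrolled`, `n_complete`, `n_dropped`, `dropped_dyads`).
#' @export
complete_case_filter <- function(cohort) {
  need <- expand.grid(parent_role = parent_roles(),
                      time_point = time_points(),
                      stringsAsFactors = FALSE)
  dyads <- unique(cohort$dyad_id)
  complete <- vapply(dyads, function(d) {
    sub <- cohort[cohort$dyad_id == d, c("parent_role", "time_point")]
    all(paste(need$parent_role, need$time_point) %in%
          paste(sub$parent_role, sub$time_point))
  }, logical(1))
  keep <- dyads[complete]
  out <- cohort[cohort$dyad_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  list(
    cohort = cohort_table(out, scale_ranges(cohort)),
    report = list(
      n_enrolled = length(dyads),
      n_complete = length(keep),
      n_dropped = length(dyads) - length(keep),
      dropped_dyads = sort(setdiff(dyads, keep))
    )
  )
}

#' Split a complete-case cohort into the six role-by-time strata
#'
#' @param cohort A complete-case `cohort_table` (see
#'   [complete_case_filter()]); anything else is an error.
#' @return Named list of 6 `stratum` objects (`mother_T1`, ..,
#'   `father_T3`), each holding an `n x 9` data matrix whose columns are the
#'   subscales in [sq_subscales()] order followed by `child_sex` coded
#'   0 = female, 1 = male; rows are dyads in sorted `dyad_id` order.
#' @export
stratify <- function(cohort) {
  cc <- complete_case_filter(cohort)
  if (cc$report$n_dropped > 0) {
    stop("stratify() requires a complete-case cohort; ",
         cc$report$n_dropped, " dyad(s) are incomplete")
  }
  dyads <- sort(unique(cohort$dyad_id))
  out <- list()
  for (role in parent_roles()) {
    for (tp in time_points()) {
      sub <- cohort[cohort$parent_role == role & cohort$time_point == tp, ,
                    drop = FALSE]
      sub <- sub[match(dyads, sub$dyad_id), , drop = FALSE]
      m <- as.matrix(sub[, sq_subscales(), drop = FALSE])
      sex <- as.integer(sub$child_sex == "male")
      dat <- cbind(m, child_sex = sex)
      rownames(dat) <- dyads
      colnames(dat) <- network_node_labels()
      out[[paste(role, tp, sep = "_")]] <- structure(
        list(parent_role = role, time_point = tp, data = dat,
             n = nrow(dat), scale_ranges = scale_ranges(cohort)),
        class = "stratum")
    }
  }
  out
}

#' @export
print.stratum <- function(x, ...) {
  cat("<stratum> ", x$parent_role, " ", x$time_point, ", n = ", x$n, "\n",
      sep = "")
  invisible(x)
}
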