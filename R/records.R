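#' Concentration records
#'
#' A concentration record table holds one row per (subject, scheduled time)
#' cell of a sparse-sampling study: subject id, time in hours post dose,
#' plasma concentration in ug/mL, and a status flag distinguishing observed
#' measurements from cells where the subject was not sampled ("NS").
#'
#' @param subject character or factor subject identifiers.
#' @param time numeric, hours post dose (>= 0).
#' @param conc numeric, ug/mL; `NA` for cells that were not sampled.
#' @param status optional character, "observed" or "not_sampled"; inferred
#'   from `conc` when missing.
#' @return a `data.frame` of class `conc_records` with columns
#'   `subject`, `time`, `conc`, `status`.
#' @export
concentration_records <- function(subject, time, conc, status = NULL) {
  subject <- as.character(subject)
  time <- as.numeric(time)
  conc <- as.numeric(conc)
  if (is.null(status)) status <- ifelse(is.na(conc), "not_sampled", "observed")
  status <- as.character(status)
  n <- length(subject)
  if (length(time) != n || length(conc) != n || length(status) != n)
    stop_validation("subject, time, conc, status must have equal length")
  if (any(!status %in% c("observed", "not_sampled")))
    stop_validation("status must be 'observed' or 'not_sampled'")
  if (any(time < 0, na.rm = TRUE)) stop_validation("times must be non-negative")
  bad <- (status == "observed" & is.na(conc)) | (status == "not_sampled" & !is.na(conc))
  if (any(bad))
    stop_validation("concentration must be present iff status is 'observed'")
  if (any(conc < 0, na.rm = TRUE)) stop_validation("concentrations must be non-negative")
  key <- paste(subject, time)
  if (anyDuplicated(key))
    stop_validation("duplicate (subject, time) cell: %s", key[duplicated(key)][1])
  structure(
    data.frame(subject = subject, time = time, conc = conc, status = status,
               stringsAsFactors = FALSE),
    class = c("conc_records", "data.frame")
  )
}

#' Read a concentration-time table from CSV
#'
#' Two dialects are supported and auto-detected from the header: long format
#' (columns `subject`, `time_h`, `conc_ug_ml`) and wide format (first column
#' `time_h`, one column per subject, rows = sampling times). Cells equal to
#' the not-sampled token (default `"NS"`) or left blank become
#' `status = "not_sampled"`.
#'
#' @param path path to a CSV file.
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @param ns_token token marking a cell where the subject was not sampled.
#' @return a [concentration_records()] table.
#' @export
read_concentration_table <- function(path, format = c("auto", "long", "wide"),
                                     ns_token = "NS") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  names(df) <- trimws(names(df))
  if (format == "auto") {
    format <- if (any(tolower(names(df)) %in% c("subject", "subject_id", "id")))
      "long" else "wide"
  }
  parse_cell <- function(x, row, col) {
    x <- trimws(x)
    if (!nzchar(x) || identical(x, ns_token)) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop_input("malformed numeric cell '%s' at row %d, column '%s'", x, row, col)
    v
  }
  if (format == "long") {
    pick <- function(cands) {
      hit <- which(tolower(names(df)) %in% cands)
      if (!length(hit)) stop_input("long format needs one of columns: %s",
                                   paste(cands, collapse = ", "))
      hit[1]
    }
    si <- pick(c("subject", "subject_id", "id"))
    ti <- pick(c("time_h", "time", "time_hr"))
    ci <- pick(c("conc_ug_ml", "conc", "concentration"))
    if (nrow(df) == 0)
      return(concentration_records(character(), numeric(), numeric()))
    time <- vapply(seq_len(nrow(df)), function(i)
      parse_cell(df[i, ti], i, names(df)[ti]), numeric(1))
    conc <- vapply(seq_len(nrow(df)), function(i)
      parse_cell(df[i, ci], i, names(df)[ci]), numeric(1))
    concentration_records(df[[si]], time, conc)
  } else {
    if (ncol(df) < 2) stop_input("wide format needs a time column plus subjects")
    if (nrow(df) == 0)
      return(concentration_records(character(), numeric(), numeric()))
    times <- vapply(seq_len(nrow(df)), function(i)
      parse_cell(df[i, 1], i, names(df)[1]), numeric(1))
    subjects <- names(df)[-1]
    long <- do.call(rbind, lapply(seq_along(subjects), function(j) {
      conc <- vapply(seq_len(nrow(df)), function(i)
        parse_cell(df[i, j + 1], i, subjects[j]), numeric(1))
      data.frame(subject = subjects[j], time = times, conc = conc,
                 stringsAsFactors = FALSE)
    }))
    concentration_records(long$subject, long$time, long$conc)
  }
}

#' Write a concentration-time table to CSV
#'
#' Inverse of [read_concentration_table()]; `read -> write -> read`
#' round-trips losslessly, including not-sampled markers.
#'
#' @param records a [concentration_records()] table.
#' @param path output path.
#' @param format `"long"` or `"wide"`.
#' @param ns_token token written for not-sampled cells.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(records, path, format = c("long", "wide"),
                                      ns_token = "NS") {
  format <- match.arg(format)
  fmt <- function(x) ifelse(is.na(x), ns_token, format(x, trim = TRUE, scientific = FALSE))
  if (format == "long") {
    out <- data.frame(subject = records$subject,
                      time_h = format(records$time, trim = TRUE, scientific = FALSE),
                      conc_ug_ml = fmt(records$conc))
  } else {
    times <- sort(unique(records$time))
    subjects <- unique(records$subject)
    out <- data.frame(time_h = format(times, trim = TRUE, scientific = FALSE))
    for (s in subjects) {
      col <- rep(NA_real_, length(times))
      rows <- records[records$subject == s, ]
      col[match(rows$time, times)] <- rows$conc
      # a subject absent at a time is an NS cell in the wide grid
      col[match(rows$time[rows$status == "not_sampled"], times)] <- NA_real_
      out[[s]] <- fmt(col)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The pooled feline enrofloxacin study dataset
#'
#' Concentration records for 14 adult cats given a single 10 mg/kg oral dose
#' of enrofloxacin as dried alginate beads, sampled under a sparse design:
#' a baseline draw for every cat plus 2-3 post-dose draws each, giving 5
#' observations at each of 1, 2, 4, 8, 12 and 24 h. Ships with the package
#' as a wide-format CSV.
#'
#' @return a [concentration_records()] table (98 cells, 44 observed).
#' @export
enro_cats <- function() {
  read_concentration_table(
    system.file("extdata", "enro_cats_table1.csv", package = "pooledPK"),
    format = "wide")
}

#' Study design descriptor
#'
#' @param scheduled_times strictly increasing post-dose sampling times (h).
#' @param n_per_time target number of observations per scheduled time.
#' @param max_draws_per_subject cap on post-dose draws per subject.
#' @param dose_mg_per_kg administered dose (mg/kg).
#' @return an object of class `study_design`.
#' @export
study_design <- function(scheduled_times, n_per_time, max_draws_per_subject,
                         dose_mg_per_kg = 10) {
  if (any(diff(scheduled_times) <= 0))
    stop_validation("scheduled_times must be strictly increasing")
  if (n_per_time < 1 || max_draws_per_subject < 1 || dose_mg_per_kg <= 0)
    stop_validation("n_per_time, max_draws_per_subject, dose must be positive")
  structure(list(scheduled_times = as.numeric(scheduled_times),
                 n_per_time = as.integer(n_per_time),
                 max_draws_per_subject = as.integer(max_draws_per_subject),
                 dose_mg_per_kg = dose_mg_per_kg),
            class = "study_design")
}

#' Design used by the feline enrofloxacin study
#'
#' Six post-dose times (1, 2, 4, 8, 12, 24 h), 5 observations per time,
#' at most 3 draws per cat, 10 mg/kg single oral dose.
#' @return a [study_design()].
#' @export
enro_design <- function() {
  study_design(c(1, 2, 4, 8, 12, 24), n_per_time = 5,
               max_draws_per_subject = 3, dose_mg_per_kg = 10)
}

#' Naive pooling of sparse records
#'
#' Merges all subjects' observed points and treats them as if they came from
#' a single individual, the naive pooled-sample estimator for sparse designs.
#' Per-time summaries (n, mean, sample SD with the n-1 denominator) are
#' computed for every distinct observed time.
#'
#' @param records a [concentration_records()] table.
#' @return an object of class `pooled_profile` with elements `points`
#'   (time-sorted data.frame of time, conc, subject) and `summary`
#'   (data.frame of time, n, mean, sd; sd is `NA` when n = 1).
#' @export
pool <- function(records) {
  obs <- records[records$status == "observed", , drop = FALSE]
  if (nrow(obs) == 0) stop_input("no observed records to pool")
  ord <- order(obs$time, obs$subject)
  points <- data.frame(time = obs$time[ord], conc = obs$conc[ord],
                       subject = obs$subject[ord], stringsAsFactors = FALSE)
  times <- sort(unique(points$time))
  summ <- data.frame(
    time = times,
    n = vapply(times, function(t) sum(points$time == t), integer(1)),
    mean = vapply(times, function(t) mean(points$conc[points$time == t]), numeric(1)),
    sd = vapply(times, function(t) {
      x <- points$conc[points$time == t]
      if (length(x) < 2) NA_real_ else stats::sd(x)
    }, numeric(1))
  )
  structure(list(points = points, summary = summ), class = "pooled_profile")
}

#' @export
print.pooled_profile <- function(x, ...) {
  cat(sprintf("Naive pooled profile: %d points from %d subjects at %d times\n",
              nrow(x$points), length(unique(x$points$subject)), nrow(x$summary)))
  print(summary_table(x), row.names = FALSE)
  invisible(x)
}

#' Per-time summary table of a pooled profile
#'
#' One row per time with n, mean and sample SD, display-rounded half away
#' from zero to the requested decimals (internal values stay full precision).
#'
#' @param profile a [pool()]ed profile.
#' @param decimals decimal places for mean and SD.
#' @return data.frame with columns `time`, `n`, `mean`, `sd`.
#' @export
summary_table <- function(profile, decimals = 1) {
  s <- profile$summary
  data.frame(time = s$time, n = s$n,
             mean = round_half_away(s$mean, decimals),
             sd = round_half_away(s$sd, decimals))
}

#' Check records against the sparse design constraints
#'
#' Reports per-time observed counts against the design target and per-subject
#' post-dose draw counts against the cap, listing violations without raising.
#'
#' @param records a [concentration_records()] table.
#' @param design a [study_design()].
#' @return an object of class `design_report`: `per_time` (time, n_observed,
#'   target), `per_subject` (subject, draws, max), and `violations`
#'   (type, where, detail; zero rows when the design is satisfied).
#' @export
validate_design <- function(records, design) {
  obs <- records[records$status == "observed" & records$time > 0, , drop = FALSE]
  per_time <- data.frame(
    time = design$scheduled_times,
    n_observed = vapply(design$scheduled_times,
                        function(t) sum(obs$time == t), integer(1)),
    target = design$n_per_time)
  subjects <- unique(records$subject)
  per_subject <- data.frame(
    subject = subjects,
    draws = vapply(subjects, function(s) sum(obs$subject == s), integer(1)),
    max = design$max_draws_per_subject, row.names = NULL)
  v <- list()
  for (i in seq_len(nrow(per_time))) {
    if (per_time$n_observed[i] < per_time$target[i])
      v[[length(v) + 1]] <- data.frame(type = "under_count",
        where = paste0("t=", per_time$time[i]),
        detail = sprintf("%d observed, %d required",
                         per_time$n_observed[i], per_time$target[i]))
    else if (per_time$n_observed[i] > per_time$target[i])
      v[[length(v) + 1]] <- data.frame(type = "over_count",
        where = paste0("t=", per_time$time[i]),
        detail = sprintf("%d observed, %d required",
                         per_time$n_observed[i], per_time$target[i]))
  }
  for (i in seq_len(nrow(per_subject))) {
    if (per_subject$draws[i] > per_subject$max[i])
      v[[length(v) + 1]] <- data.frame(type = "excess_draws",
        where = per_subject$subject[i],
        detail = sprintf("%d draws, max %d",
                         per_subject$draws[i], per_subject$max[i]))
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(), where = character(), detail = character())
  structure(list(per_time = per_time, per_subject = per_subject,
                 violations = violations), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design check\n  per-time observed counts:\n")
  print(x$per_time, row.names = FALSE)
  if (nrow(x$violations) == 0) cat("  no violations\n")
  else { cat(sprintf("  %d violation(s):\n", nrow(x$violations)))
         print(x$violations, row.names = FALSE) }
  invisible(x)
}

#' Beads needed to deliver a dose
#'
#' Number of fixed-strength drug beads required for a subject of the given
#' weight: `ceiling(weight * dose / bead_strength)`. With 2.5 mg of drug per
#' bead, a 4 kg cat at 10 mg/kg needs 16 beads.
#'
#' @param weight_kg body weight (kg).
#' @param dose_mg_per_kg dose (mg/kg).
#' @param bead_strength_mg drug content of one bead (mg).
#' @return integer bead count.
#' @export
beads_required <- function(weight_kg, dose_mg_per_kg, bead_strength_mg) {
  if (any(c(weight_kg, dose_mg_per_kg, bead_strength_mg) <= 0))
    stop_domain("weight, dose and bead strength must all be positive")
  as.integer(ceiling(weight_kg * dose_mg_per_kg / bead_strength_mg - 1e-9))
}
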