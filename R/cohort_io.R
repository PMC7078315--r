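# Data model and sample-inclusion rules for nested case-control screening
# cohorts of serial serum biomarker measurements.

COHORT_COLUMNS <- c("subject_id", "group", "tumour_type", "age_years",
                    "months_to_dx", "sample_kind", "marker", "value")
TUMOUR_TYPES <- c("TypeI", "TypeII", "Borderline", "none")
SAMPLE_KINDS <- c("annual_screen", "other")

#' Construct a screening cohort object
#'
#' A `cohort_set` holds one nested case-control screening cohort in long
#' format: one row per (subject, visit, marker) measurement, plus the ordered
#' marker panel and a flag recording whether concentrations are on the raw
#' assay scale or already log10-transformed.
#'
#' @param data data.frame with columns `subject_id`, `group` ("case" or
#'   "control"), `tumour_type` ("TypeI", "TypeII", "Borderline" or "none"),
#'   `age_years`, `months_to_dx` (NA for controls), `sample_kind`
#'   ("annual_screen" or "other"), `marker`, `value`.
#' @param markers character vector giving the ordered marker panel; defaults
#'   to the markers present in `data`.
#' @param log_scale logical; `TRUE` if `value` holds log10 concentrations.
#' @param provenance free-text metadata string.
#' @param validate run [validate_cohort()] on the result (default `TRUE`).
#'
#' @return An object of class `cohort_set`.
#' @export
cohort_set <- function(data, markers = NULL, log_scale = FALSE,
                       provenance = "", validate = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(COHORT_COLUMNS, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort data is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- data[, COHORT_COLUMNS]
  data$subject_id <- as.character(data$subject_id)
  data$marker <- as.character(data$marker)
  data$group <- as.character(data$group)
  data$tumour_type <- as.character(data$tumour_type)
  data$sample_kind <- as.character(data$sample_kind)
  data$age_years <- as.numeric(data$age_years)
  data$months_to_dx <- as.numeric(data$months_to_dx)
  data$value <- as.numeric(data$value)
  if (is.null(markers)) markers <- unique(data$marker)
  obj <- structure(
    list(data = data, markers = as.character(markers),
         log_scale = isTRUE(log_scale), provenance = provenance),
    class = "cohort_set"
  )
  if (validate) validate_cohort(obj)
  obj
}

#' Validate a cohort_set against its structural invariants
#'
#' Checks: positive concentrations (on the raw scale), no duplicate
#' (subject, age, marker) measurement, diagnosis timing present for every
#' case row and absent for every control row, tumour type consistent with
#' group, strictly increasing visit ages within subject, a fixed implied
#' diagnosis date per case (age + months_to_dx/12 constant within 0.1 yr),
#' and marker names within the declared panel.
#'
#' @param cohort a `cohort_set`.
#' @return `cohort`, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_set"))
  d <- cohort$data
  if (nrow(d) == 0) return(invisible(cohort))

  bad_group <- !d$group %in% c("case", "control")
  if (any(bad_group)) {
    stop("unknown group at row ", which(bad_group)[1], ": ", d$group[which(bad_group)[1]])
  }
  bad_type <- !d$tumour_type %in% TUMOUR_TYPES
  if (any(bad_type)) {
    stop("unknown tumour_type at row ", which(bad_type)[1])
  }
  bad_kind <- !d$sample_kind %in% SAMPLE_KINDS
  if (any(bad_kind)) {
    stop("unknown sample_kind at row ", which(bad_kind)[1])
  }
  if (!cohort$log_scale) {
    bad <- !is.finite(d$value) | d$value <= 0
    if (any(bad)) {
      stop("non-positive or missing concentration at row ", which(bad)[1],
           " (subject ", d$subject_id[which(bad)[1]], ", marker ",
           d$marker[which(bad)[1]], ", value ", d$value[which(bad)[1]], ")")
    }
  }
  key <- paste(d$subject_id, format(d$age_years, digits = 12), d$marker, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate measurement for subject ", d$subject_id[i],
         ", age ", d$age_years[i], ", marker ", d$marker[i])
  }
  is_case <- d$group == "case"
  if (any(is_case & is.na(d$months_to_dx))) {
    i <- which(is_case & is.na(d$months_to_dx))[1]
    stop("case row without months_to_dx at row ", i,
         " (subject ", d$subject_id[i], ")")
  }
  if (any(!is_case & !is.na(d$months_to_dx))) {
    i <- which(!is_case & !is.na(d$months_to_dx))[1]
    stop("control row carries months_to_dx at row ", i,
         " (subject ", d$subject_id[i], ")")
  }
  if (any(is_case & d$months_to_dx < 0, na.rm = TRUE)) {
    stop("negative months_to_dx")
  }
  if (any(is_case & d$tumour_type == "none")) {
    stop("case subject with tumour_type 'none'")
  }
  if (any(!is_case & d$tumour_type != "none")) {
    stop("control subject with tumour_type other than 'none'")
  }
  bad_marker <- !d$marker %in% cohort$markers
  if (any(bad_marker)) {
    stop("marker outside declared panel at row ", which(bad_marker)[1],
         ": ", d$marker[which(bad_marker)[1]])
  }
  for (sid in unique(d$subject_id)) {
    rows <- d[d$subject_id == sid, ]
    if (length(unique(rows$group)) > 1 || length(unique(rows$tumour_type)) > 1) {
      stop("subject ", sid, " has inconsistent group or tumour_type")
    }
    ages <- sort(unique(rows$age_years))
    if (any(diff(ages) <= 0)) stop("subject ", sid, " has non-increasing visit ages")
    if (rows$group[1] == "case") {
      dx_age <- rows$age_years + rows$months_to_dx / 12
      if (diff(range(dx_age)) > 0.1) {
        stop("subject ", sid, " has inconsistent implied diagnosis age (spread ",
             signif(diff(range(dx_age)), 3), " yr > 0.1 yr)")
      }
    }
  }
  invisible(cohort)
}

#' @export
print.cohort_set <- function(x, ...) {
  d <- x$data
  n_sub <- length(unique(d$subject_id))
  n_case <- length(unique(d$subject_id[d$group == "case"]))
  cat("cohort_set:", n_sub, "subjects (", n_case, "cases,",
      n_sub - n_case, "controls ),", nrow(d), "measurements\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat("  scale:", if (x$log_scale) "log10" else "raw", "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Per-subject summary of a cohort
#'
#' @param cohort a `cohort_set`.
#' @return data.frame with one row per subject: id, group, tumour type,
#'   number of visits, and (for cases) months from last visit to diagnosis.
#' @export
cohort_subjects <- function(cohort) {
  d <- cohort$data
  if (nrow(d) == 0) {
    return(data.frame(subject_id = character(), group = character(),
                      tumour_type = character(), n_visits = integer(),
                      last_months_to_dx = numeric()))
  }
  sids <- unique(d$subject_id)
  out <- lapply(sids, function(sid) {
    rows <- d[d$subject_id == sid, ]
    ages <- sort(unique(rows$age_years))
    last <- rows[rows$age_years == max(ages), ]
    data.frame(subject_id = sid, group = rows$group[1],
               tumour_type = rows$tumour_type[1],
               n_visits = length(ages),
               last_months_to_dx = last$months_to_dx[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a cohort from a long-format CSV file
#'
#' The expected schema is one row per measurement with header
#' `subject_id,group,tumour_type,age_years,months_to_dx,sample_kind,marker,value`
#' (comma separator, "." decimal, UTF-8). Empty `months_to_dx` cells denote
#' controls. The file is validated on read; duplicate measurements,
#' non-positive concentrations and cases lacking diagnosis timing are errors
#' naming the offending row.
#'
#' @param path CSV file path.
#' @param markers optional explicit marker panel (default: order of first
#'   appearance in the file).
#' @return A validated `cohort_set` (raw scale).
#' @export
read_cohort <- function(path, markers = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(subject_id = "character", marker = "character"))
  cohort_set(d, markers = markers, log_scale = FALSE,
             provenance = paste0("read from ", basename(path)))
}

#' Write a cohort to a long-format CSV file
#'
#' Emits the same schema [read_cohort()] consumes, so
#' `read_cohort(write_cohort(x, f))` reproduces `x`'s data. Only raw-scale
#' cohorts round-trip (the file format has no scale flag).
#'
#' @param cohort a `cohort_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_set"))
  write.csv(cohort$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a cohort to the samples eligible for model building
#'
#' Applies the modelling inclusion rules: keep only annual screening samples
#' (dropping repeat samples triggered by elevated risk scores, which would
#' bias the case series toward rising trajectories), drop case samples taken
#' more than 5 years (60 months) before diagnosis, exclude Borderline
#' subjects entirely, and drop any subject left with no visits. Controls are
#' never excluded by the time rule. The numbers of dropped visits and
#' subjects are reported as messages; the operation is idempotent.
#'
#' @param cohort a validated `cohort_set`.
#' @return The filtered `cohort_set`, with attribute `"modelling_filtered"`
#'   set so downstream steps can check the precondition.
#' @export
modelling_filter <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_set"))
  d <- cohort$data
  n_rows0 <- nrow(d)
  sub0 <- unique(d$subject_id)

  bl_subjects <- unique(d$subject_id[d$tumour_type == "Borderline"])
  d <- d[!d$subject_id %in% bl_subjects, , drop = FALSE]
  d <- d[d$sample_kind == "annual_screen", , drop = FALSE]
  late <- d$group == "case" & d$months_to_dx > 60
  d <- d[!late, , drop = FALSE]

  kept_subjects <- unique(d$subject_id)
  message("modelling_filter: dropped ", length(bl_subjects),
          " Borderline subject(s), ", n_rows0 - nrow(d),
          " measurement row(s); ",
          length(sub0) - length(kept_subjects), " subject(s) removed in total")
  if (nrow(d) == 0) warning("modelling_filter left an empty cohort")

  out <- cohort_set(d, markers = cohort$markers, log_scale = cohort$log_scale,
                    provenance = cohort$provenance, validate = FALSE)
  attr(out, "modelling_filtered") <- TRUE
  out
}

#' Select the evaluation window of a filtered cohort
#'
#' Two evaluation windows are defined relative to diagnosis. `within_1yr`
#' keeps cases whose final retained annual sample falls within 12 months of
#' diagnosis (their full retained series is kept). `yr1_to_2` first removes
#' every case sample taken within 12 months of diagnosis, then keeps cases
#' whose new final sample falls within 24 months of diagnosis. Controls are
#' always retained in both windows.
#'
#' @param cohort a `cohort_set` that has been through [modelling_filter()].
#' @param window `"within_1yr"` or `"yr1_to_2"`.
#' @return The subset `cohort_set`; dropped case counts are reported.
#' @export
evaluation_subset <- function(cohort, window = c("within_1yr", "yr1_to_2")) {
  stopifnot(inherits(cohort, "cohort_set"))
  window <- match.arg(window)
  if (!isTRUE(attr(cohort, "modelling_filtered"))) {
    stop("evaluation_subset requires a cohort processed by modelling_filter()")
  }
  d <- cohort$data
  ctrl <- d[d$group == "control", , drop = FALSE]
  cases <- d[d$group == "case", , drop = FALSE]
  case_ids <- unique(cases$subject_id)

  if (window == "yr1_to_2") {
    cases <- cases[cases$months_to_dx > 12, , drop = FALSE]
    limit <- 24
  } else {
    limit <- 12
  }
  keep_ids <- character()
  for (sid in unique(cases$subject_id)) {
    rows <- cases[cases$subject_id == sid, ]
    final_m <- rows$months_to_dx[which.max(rows$age_years)]
    if (final_m <= limit) keep_ids <- c(keep_ids, sid)
  }
  cases <- cases[cases$subject_id %in% keep_ids, , drop = FALSE]
  message("evaluation_subset(", window, "): kept ", length(keep_ids), " of ",
          length(case_ids), " case subject(s); all ",
          length(unique(ctrl$subject_id)), " control(s) retained")

  out <- cohort_set(rbind(cases, ctrl), markers = cohort$markers,
                    log_scale = cohort$log_scale,
                    provenance = cohort$provenance, validate = FALSE)
  attr(out, "modelling_filtered") <- TRUE
  attr(out, "evaluation_window") <- window
  out
}

#' Log10-transform all concentrations in a cohort
#'
#' Marker concentrations are replaced by their base-10 logarithms prior to
#' feature extraction and model fitting. The cohort is tagged as log-scale;
#' applying the transform twice is an error, not a silent no-op.
#'
#' @param cohort a raw-scale `cohort_set` with strictly positive values.
#' @return The log-scale `cohort_set`.
#' @export
log10_transform <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_set"))
  if (cohort$log_scale) {
    stop("cohort is already on the log10 scale; refusing to transform twice")
  }
  if (any(cohort$data$value <= 0, na.rm = TRUE)) {
    stop("cannot log10-transform non-positive concentrations")
  }
  d <- cohort$data
  d$value <- log10(d$value)
  out <- cohort_set(d, markers = cohort$markers, log_scale = TRUE,
                    provenance = cohort$provenance, validate = FALSE)
  for (a in c("modelling_filtered", "evaluation_window")) {
    attr(out, a) <- attr(cohort, a)
  }
  out
}

#' Restrict a cohort to one case stratum
#'
#' Keeps all controls and only the cases of the requested tumour type;
#' used to evaluate performance on Type II (mostly high-grade serous)
#' cases separately from all cases.
#'
#' @param cohort a `cohort_set`.
#' @param stratum `"all"` or one of the tumour types (e.g. `"TypeII"`).
#' @return The subset `cohort_set`.
#' @export
case_stratum <- function(cohort, stratum = "all") {
  stopifnot(inherits(cohort, "cohort_set"))
  if (identical(stratum, "all")) return(cohort)
  if (!stratum %in% TUMOUR_TYPES) stop("unknown stratum: ", stratum)
  d <- cohort$data
  d <- d[d$group == "control" | d$tumour_type == stratum, , drop = FALSE]
  out <- cohort_set(d, markers = cohort$markers, log_scale = cohort$log_scale,
                    provenance = cohort$provenance, validate = FALSE)
  for (a in c("modelling_filtered", "evaluation_window")) {
    attr(out, a) <- attr(cohort, a)
  }
  out
}
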