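#' Framewise displacement from motion parameters
#'
#' Backward-difference framewise displacement (FD): the sum of absolute
#' volume-to-volume changes in the three translations (mm) plus the three
#' rotations (radians) converted to arc length on a 50 mm sphere. The first
#' volume has FD 0 by convention.
#'
#' @param motion Volumes-by-6 numeric matrix or data frame: columns 1-3
#'   translations in mm, columns 4-6 rotations in radians.
#' @param radius Rotational radius in mm.
#' @return Numeric vector of per-volume FD (mm), length = number of volumes.
#' @examples
#' m <- matrix(0, 10, 6); m[6, 1] <- 0.3
#' framewise_displacement(m)[6:7]   # 0.3 at the step, 0.3 stepping back
#' @export
framewise_displacement <- function(motion, radius = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) {
    abort("Motion table must have 6 columns (3 translations, 3 rotations).")
  }
  if (nrow(m) < 2L) abort("Need at least 2 volumes.")
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' High-motion subject flag
#'
#' Flags a subject whose proportion of volumes with FD strictly above
#' `fd_thresh` strictly exceeds `prop_thresh`.
#'
#' @param fd Numeric FD series (mm).
#' @param fd_thresh FD threshold in mm.
#' @param prop_thresh Proportion-of-volumes threshold.
#' @return Logical scalar.
#' @export
high_motion_flag <- function(fd, fd_thresh = 0.5, prop_thresh = 0.5) {
  if (!length(fd)) abort("Empty FD series.")
  mean(fd > fd_thresh) > prop_thresh
}

#' Robust amplitude-outlier flags (scaled-MAD rule)
#'
#' Flags values deviating from the sample median by more than
#' `k * 1.4826 * MAD`, where MAD is the median absolute deviation from the
#' median and 1.4826 makes it a consistent estimate of the standard
#' deviation under normality. With a degenerate sample (MAD = 0) only values
#' strictly away from the median would be flagged; an all-equal sample flags
#' nobody.
#'
#' @param values Numeric vector of per-subject summaries (e.g., mean BOLD
#'   response), length >= 3.
#' @param k Deviation multiplier.
#' @return Logical vector, `TRUE` for outliers.
#' @export
mad_outlier_flags <- function(values, k = 3) {
  if (length(values) < 3L) abort("Need at least 3 values for the MAD rule.")
  med <- median(values)
  abs(values - med) > k * mad(values)   # stats::mad includes the 1.4826 scale
}

#' Apply twin-aware subject exclusions
#'
#' Applies the exclusion cascade of a twin imaging study: (1) high-motion
#' subjects, (2) robust amplitude outliers among the remaining subjects
#' together with their co-twins, (3) subjects with missing data; finally any
#' subject whose co-twin was removed at an earlier stage (or was never
#' present in the roster) is dropped so that only intact pairs remain.
#' Subjects are counted at the first stage that triggers.
#'
#' @param cohort Recruitment roster (cohort tibble; incomplete pairs
#'   tolerated — the widowed twin is removed at the missing-data stage).
#' @param qc Tibble with one row per roster subject: `subject_id`,
#'   `high_motion` (logical), `bold_mean` (numeric outlier summary, NAs
#'   allowed when missing), `missing` (logical).
#' @param mad_k Multiplier for [mad_outlier_flags()].
#' @param motion_removes_cotwin Should the co-twin of a high-motion subject
#'   also be excluded (counted at the motion stage)? Defaults to `TRUE` to
#'   keep stage counts aligned with the intact-pair rule.
#' @return List with `cohort` (the filtered tibble, complete pairs only) and
#'   `report` (a `qc_report`: per-stage subject lists and counts).
#' @examples
#' co <- simulate_cohort(5, 5, seed = 1)
#' qc <- tibble::tibble(subject_id = co$subject_id, high_motion = FALSE,
#'                      bold_mean = rnorm(20), missing = FALSE)
#' apply_exclusions(co, qc)$report
#' @export
apply_exclusions <- function(cohort, qc, mad_k = 3,
                             motion_removes_cotwin = TRUE) {
  validate_cohort(cohort, allow_incomplete = TRUE)
  need <- c("subject_id", "high_motion", "bold_mean", "missing")
  if (!all(need %in% names(qc))) {
    abort(paste("qc needs columns:", paste(need, collapse = ", ")))
  }
  extra <- setdiff(qc$subject_id, cohort$subject_id)
  if (length(extra)) {
    abort(paste0("qc lists subjects not in the cohort: ",
                 paste(head(extra, 3), collapse = ", ")))
  }
  qc <- qc[match(cohort$subject_id, qc$subject_id), ]
  if (anyNA(qc$subject_id)) abort("qc must cover every cohort subject.")

  cotwins_of <- function(ids) {
    pid <- cohort$pair_id[cohort$subject_id %in% ids]
    setdiff(cohort$subject_id[cohort$pair_id %in% pid], ids)
  }

  # stage 1: head motion
  excl_motion <- cohort$subject_id[qc$high_motion]
  if (motion_removes_cotwin) {
    excl_motion <- union(excl_motion, cotwins_of(excl_motion))
  }
  alive <- setdiff(cohort$subject_id, excl_motion)

  # stage 2: amplitude outliers among survivors, plus co-twins
  vals <- qc$bold_mean[match(alive, qc$subject_id)]
  ok <- !is.na(vals)
  out_flag <- rep(FALSE, length(alive))
  if (sum(ok) >= 3L) out_flag[ok] <- mad_outlier_flags(vals[ok], k = mad_k)
  excl_outlier <- alive[out_flag]
  excl_outlier <- union(excl_outlier,
                        intersect(cotwins_of(excl_outlier), alive))
  alive <- setdiff(alive, excl_outlier)

  # stage 3: missing / incomplete data
  excl_missing <- intersect(cohort$subject_id[qc$missing], alive)
  alive <- setdiff(alive, excl_missing)

  # intact-pair sweep: a subject whose co-twin is gone (for any reason,
  # including never having been recruited) cannot contribute a pair
  pair_n <- table(cohort$pair_id[cohort$subject_id %in% alive])
  widowed <- cohort$subject_id[cohort$subject_id %in% alive &
                                 cohort$pair_id %in% names(pair_n)[pair_n < 2]]
  excl_missing <- union(excl_missing, widowed)
  alive <- setdiff(alive, widowed)

  final <- cohort[cohort$subject_id %in% alive, ]
  report <- structure(
    list(excluded_motion = excl_motion,
         excluded_outlier = excl_outlier,
         excluded_missing = excl_missing,
         n_recruited = nrow(cohort),
         n_final = nrow(final)),
    class = "qc_report")
  stopifnot(report$n_final ==
              report$n_recruited - length(unique(c(excl_motion, excl_outlier,
                                                   excl_missing))))
  list(cohort = final, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> recruited %d -> final %d (motion %d, outlier %d, missing %d)\n",
    x$n_recruited, x$n_final, length(x$excluded_motion),
    length(x$excluded_outlier), length(x$excluded_missing)))
  invisible(x)
}

#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  bind_rows(
    tibble(subject_id = x$excluded_motion, stage = "motion"),
    tibble(subject_id = x$excluded_outlier, stage = "outlier"),
    tibble(subject_id = x$excluded_missing, stage = "missing")
  )
}

#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_recruited = x$n_recruited,
         n_motion = length(x$excluded_motion),
         n_outlier = length(x$excluded_outlier),
         n_missing = length(x$excluded_missing),
         n_final = x$n_final)
}

#' Serialize an exclusion report to JSON
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
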