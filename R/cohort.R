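#' Simulate a twin cohort
#'
#' Builds a cohort table of monozygotic (MZ) and dizygotic (DZ) twin pairs.
#' Each pair contributes two subjects sharing a `pair_id` and a zygosity
#' label; sex is assigned per pair (same-sex pairs only, as in typical
#' registry-based designs) and age per pair, as optional covariates.
#'
#' @param n_mz Number of MZ pairs (non-negative integer).
#' @param n_dz Number of DZ pairs (non-negative integer).
#' @param seed Optional integer seed; fixed seed gives a bit-identical cohort.
#' @param age_range Numeric length-2 vector, uniform sampling range for pair
#'   age in years.
#'
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `pair_id`, `zygosity` (factor, levels `MZ`/`DZ`), `sex` (factor `F`/`M`),
#'   `age` (years).
#' @examples
#' cohort <- simulate_cohort(56, 67, seed = 1)
#' dplyr::count(cohort, zygosity)
#' @export
simulate_cohort <- function(n_mz, n_dz, seed = NULL, age_range = c(20, 60)) {
  if (length(n_mz) != 1L || length(n_dz) != 1L ||
      is.na(n_mz) || is.na(n_dz) || n_mz < 0 || n_dz < 0) {
    abort("`n_mz` and `n_dz` must be single non-negative counts.")
  }
  n_mz <- as.integer(n_mz); n_dz <- as.integer(n_dz)
  if (n_mz + n_dz < 1L) abort("Need at least one twin pair.")
  n_pairs <- n_mz + n_dz
  with_seed_or_current(seed, {
    pair_id <- sprintf("P%03d", seq_len(n_pairs))
    zyg <- factor(rep(c("MZ", "DZ"), c(n_mz, n_dz)), levels = c("MZ", "DZ"))
    sex <- factor(sample(c("F", "M"), n_pairs, replace = TRUE),
                  levels = c("F", "M"))
    age <- round(runif(n_pairs, age_range[1], age_range[2]))
    tibble(
      subject_id = sprintf("S%03d-%d", rep(seq_len(n_pairs), each = 2L),
                           rep(1:2, n_pairs)),
      pair_id    = rep(pair_id, each = 2L),
      zygosity   = rep(zyg, each = 2L),
      sex        = rep(sex, each = 2L),
      age        = rep(age, each = 2L)
    )
  })
}

#' Validate a twin cohort table
#'
#' Checks the structural invariants of a cohort table: required columns,
#' two subjects per pair (unless `allow_incomplete`), consistent zygosity
#' within pairs, and unique subject ids.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param allow_incomplete Allow pairs with a single present member (used for
#'   recruitment rosters before quality control).
#' @return The cohort, invisibly, with `zygosity` coerced to the standard
#'   factor levels.
#' @export
validate_cohort <- function(cohort, allow_incomplete = FALSE) {
  need <- c("subject_id", "pair_id", "zygosity")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cohort$subject_id)) abort("Duplicated subject_id.")
  zyg <- as.character(cohort$zygosity)
  if (!all(zyg %in% c("MZ", "DZ"))) abort("zygosity must be 'MZ' or 'DZ'.")
  cohort$zygosity <- factor(zyg, levels = c("MZ", "DZ"))
  sizes <- table(cohort$pair_id)
  if (!allow_incomplete && any(sizes != 2L)) {
    abort("Every pair_id must map to exactly 2 subjects.")
  }
  if (any(sizes > 2L)) abort("A pair_id maps to more than 2 subjects.")
  nz <- tapply(zyg, cohort$pair_id, function(z) length(unique(z)))
  if (any(nz != 1L)) abort("Both members of a pair must share zygosity.")
  invisible(cohort)
}

#' Per-pair view of a cohort
#'
#' @param cohort A cohort tibble.
#' @return A tibble with one row per complete pair: `pair_id`, `zygosity`,
#'   `twin1`, `twin2` (subject ids in table order).
#' @export
cohort_pairs <- function(cohort) {
  validate_cohort(cohort)
  cohort %>%
    group_by(.data$pair_id) %>%
    summarise(zygosity = .data$zygosity[1],
              twin1 = .data$subject_id[1],
              twin2 = .data$subject_id[2],
              .groups = "drop") %>%
    arrange(.data$pair_id)
}

#' Count MZ and DZ pairs
#'
#' @param cohort A cohort tibble.
#' @return Named integer vector with elements `MZ` and `DZ`.
#' @export
zygosity_counts <- function(cohort) {
  p <- cohort_pairs(cohort)
  c(MZ = sum(p$zygosity == "MZ"), DZ = sum(p$zygosity == "DZ"))
}

#' Read / write a cohort table
#'
#' Cohorts are stored as tab-separated text with columns `subject_id`,
#' `pair_id`, `zygosity` and optional covariates.
#'
#' @param path File path.
#' @param cohort A cohort tibble.
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(x, allow_incomplete = TRUE)
  x$zygosity <- factor(as.character(x$zygosity), levels = c("MZ", "DZ"))
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}
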