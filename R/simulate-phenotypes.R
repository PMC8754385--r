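#' Simulate ACE-structured twin phenotypes
#'
#' Generates one phenotype value per subject and element under the classical
#' twin model: `y = sqrt(A) a + sqrt(C) c + sqrt(E) e`, where the additive-
#' genetic score `a` is shared perfectly within MZ pairs and correlates 0.5
#' within DZ pairs (latent construction
#' `a_DZ = sqrt(0.5) a_pair + sqrt(0.5) a_individual`), the shared-environment
#' score `c` is common to both twins of every pair, and `e` is independent
#' noise. Marginal variance is 1 for every element, so the implied twin
#' correlations are `r_MZ = A + C` and `r_DZ = A/2 + C`.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param params ACE fractions for the elements: an [ace_params()] object
#'   (recycled), a data frame with columns `A`, `C`, `E` (one row per
#'   element), or a list of `ace_params`.
#' @param n_elements Number of phenotype elements; defaults to the number of
#'   parameter rows.
#' @param seed Optional integer seed.
#'
#' @return A tibble with `subject_id` plus one numeric column per element
#'   (`e001`, `e002`, ...), ordered as the cohort.
#' @examples
#' co <- simulate_cohort(100, 100, seed = 1)
#' ph <- simulate_ace_phenotypes(co, ace_params(0.5, 0.2), seed = 2)
#' @export
simulate_ace_phenotypes <- function(cohort, params, n_elements = NULL,
                                    seed = NULL) {
  validate_cohort(cohort)
  if (is.null(n_elements)) {
    pm <- as_ace_matrix(params)
    n_elements <- nrow(pm)
  }
  pm <- as_ace_matrix(params, n_elements)
  pairs <- cohort_pairs(cohort)
  n_pairs <- nrow(pairs)
  is_dz <- pairs$zygosity == "DZ"

  with_seed_or_current(seed, {
    a_pair <- matrix(rnorm(n_pairs * n_elements), n_pairs)
    a_ind1 <- matrix(rnorm(n_pairs * n_elements), n_pairs)
    a_ind2 <- matrix(rnorm(n_pairs * n_elements), n_pairs)
    c_pair <- matrix(rnorm(n_pairs * n_elements), n_pairs)
    e1     <- matrix(rnorm(n_pairs * n_elements), n_pairs)
    e2     <- matrix(rnorm(n_pairs * n_elements), n_pairs)

    # MZ twins take the pair-level genetic score untouched; DZ twins split it
    # with an individual component so cor(a1, a2) = 0.5 exactly by construction
    s <- sqrt(0.5)
    a1 <- a_pair; a2 <- a_pair
    a1[is_dz, ] <- s * a_pair[is_dz, , drop = FALSE] +
      s * a_ind1[is_dz, , drop = FALSE]
    a2[is_dz, ] <- s * a_pair[is_dz, , drop = FALSE] +
      s * a_ind2[is_dz, , drop = FALSE]

    sa <- sqrt(pm[, "A"]); sc <- sqrt(pm[, "C"]); se <- sqrt(pm[, "E"])
    y1 <- sweep(a1, 2, sa, `*`) + sweep(c_pair, 2, sc, `*`) +
      sweep(e1, 2, se, `*`)
    y2 <- sweep(a2, 2, sa, `*`) + sweep(c_pair, 2, sc, `*`) +
      sweep(e2, 2, se, `*`)

    y <- matrix(0, 2L * n_pairs, n_elements)
    y[seq(1, 2 * n_pairs, by = 2), ] <- y1
    y[seq(2, 2 * n_pairs, by = 2), ] <- y2
    colnames(y) <- sprintf("e%03d", seq_len(n_elements))

    ids <- c(rbind(pairs$twin1, pairs$twin2))
    out <- bind_cols(tibble(subject_id = ids), as_tibble(y))
    # return in cohort order
    out[match(cohort$subject_id, out$subject_id), ]
  })
}

#' Phenotype tibble to subjects-by-elements matrix
#'
#' @param pheno A tibble with a `subject_id` column and numeric element
#'   columns, as returned by [simulate_ace_phenotypes()].
#' @return Numeric matrix with subject ids as row names.
#' @export
pheno_matrix <- function(pheno) {
  if (!"subject_id" %in% names(pheno)) abort("Need a subject_id column.")
  m <- as.matrix(pheno[, setdiff(names(pheno), "subject_id"), drop = FALSE])
  if (!is.numeric(m)) abort("Element columns must be numeric.")
  rownames(m) <- pheno$subject_id
  m
}

#' Empirical within-pair correlations by zygosity
#'
#' Pearson correlation between the two members of a pair, computed
#' separately for MZ and DZ pairs with double entry disabled (each pair
#' contributes one (twin1, twin2) point in cohort order; the generator's
#' exchangeability makes the ordering immaterial up to sampling noise).
#'
#' @param pheno Phenotype tibble.
#' @param cohort Cohort tibble.
#' @return A tibble with columns `element`, `r_mz`, `r_dz`.
#' @export
twin_correlations <- function(pheno, cohort) {
  pairs <- cohort_pairs(cohort)
  y <- pheno_matrix(pheno)
  y1 <- y[pairs$twin1, , drop = FALSE]
  y2 <- y[pairs$twin2, , drop = FALSE]
  mz <- pairs$zygosity == "MZ"
  r_for <- function(sel) {
    vapply(seq_len(ncol(y)), function(j)
      cor(y1[sel, j], y2[sel, j]), numeric(1))
  }
  tibble(element = colnames(y), r_mz = r_for(mz), r_dz = r_for(!mz))
}
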