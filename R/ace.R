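#' Falconer's ACE estimate from twin correlations
#'
#' The classical contrast of monozygotic and dizygotic twin-pair
#' correlations: `A = 2 (r_MZ - r_DZ)`, `C = 2 r_DZ - r_MZ`,
#' `E = 1 - r_MZ`. Raw estimates are reported alongside non-negativity-
#' constrained ones (A and C truncated at 0, no renormalization);
#' heritability `h2 = A / (A + C + E)` is computed from the constrained
#' values.
#'
#' @param r_mz,r_dz Twin-pair correlations, each in `[-1, 1]`.
#' @return Object of class `falconer_ace` with components `raw`,
#'   `constrained` (named A/C/E vectors) and `h2`.
#' @examples
#' falconer_ace(0.18, 0.09)   # h2 = 0.18
#' @export
falconer_ace <- function(r_mz, r_dz) {
  if (any(abs(c(r_mz, r_dz)) > 1) || anyNA(c(r_mz, r_dz))) {
    abort("Correlations must lie in [-1, 1].")
  }
  raw <- c(A = 2 * (r_mz - r_dz), C = 2 * r_dz - r_mz, E = 1 - r_mz)
  con <- c(A = max(raw["A"], 0), C = max(raw["C"], 0), E = raw["E"])
  names(con) <- c("A", "C", "E")
  h2 <- if (sum(con) > 0) unname(con["A"] / sum(con)) else NA_real_
  structure(list(r_mz = r_mz, r_dz = r_dz, raw = raw, constrained = con,
                 h2 = h2),
            class = "falconer_ace")
}

#' @export
print.falconer_ace <- function(x, ...) {
  cat(sprintf("<falconer_ace> r_MZ = %.3f, r_DZ = %.3f\n", x$r_mz, x$r_dz))
  cat(sprintf("  A = %.3f, C = %.3f, E = %.3f (constrained); h2 = %.3f\n",
              x$constrained["A"], x$constrained["C"], x$constrained["E"],
              x$h2))
  invisible(x)
}

#' @method tidy falconer_ace
#' @export
tidy.falconer_ace <- function(x, ...) {
  tibble(component = c("A", "C", "E"),
         raw = unname(x$raw),
         constrained = unname(x$constrained))
}

#' @method glance falconer_ace
#' @export
glance.falconer_ace <- function(x, ...) {
  tibble(r_mz = x$r_mz, r_dz = x$r_dz, h2 = x$h2)
}

# ---- squared-pair-differences engine ---------------------------------------

# phenotype matrix + cohort -> squared within-pair differences (pairs x
# elements), pair zygosity, and pooled per-element total variance
pair_sq_diffs <- function(y, cohort) {
  pairs <- cohort_pairs(cohort)
  d <- (y[pairs$twin1, , drop = FALSE] - y[pairs$twin2, , drop = FALSE])^2
  list(d = d, is_dz = pairs$zygosity == "DZ",
       var_p = apply(y[cohort$subject_id, , drop = FALSE], 2, var))
}

# moment estimates from group means of squared differences:
#   E[d | MZ] = 2 sigma2_E            -> E = mean_MZ / 2
#   E[d | DZ] = 2 sigma2_E + sigma2_A -> A = mean_DZ - mean_MZ (the slope on
#                                        a 0/1 zygosity regressor)
#   C = total variance - A - E
# Constraints: A truncated at 0 first, then C; A and E additionally capped at
# the total variance so every component lies in [0, var_p].
ace_from_moments <- function(m_mz, m_dz, var_p) {
  a_raw <- m_dz - m_mz
  e_hat <- pmin(m_mz / 2, var_p)
  a_hat <- pmin(pmax(a_raw, 0), var_p)
  c_hat <- pmax(var_p - a_hat - e_hat, 0)
  tot <- a_hat + c_hat + e_hat
  h2 <- ifelse(var_p > 0 & tot > 0, a_hat / tot, NA_real_)
  list(A = a_hat, C = c_hat, E = e_hat, h2 = h2, slope = a_raw)
}

# vectorized two-group slope t-statistics for the d ~ zygosity regression
# (equal-variance pooling); returns the signed t per element
lrsd_t <- function(d, is_dz) {
  n1 <- sum(!is_dz); n2 <- sum(is_dz)
  if (n1 < 2L || n2 < 2L) abort("Need at least 2 MZ and 2 DZ pairs.")
  dmz <- d[!is_dz, , drop = FALSE]; ddz <- d[is_dz, , drop = FALSE]
  m1 <- colMeans(dmz); m2 <- colMeans(ddz)
  v1 <- (colSums(dmz^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(ddz^2) - n2 * m2^2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  t[se == 0] <- 0
  list(t = t, m_mz = m1, m_dz = m2, df = n1 + n2 - 2)
}

# one-sided p from the boundary null 1/2 delta_0 + 1/2 chi^2_1 applied to the
# squared statistic; slope < 0 maps to the mass point with p = 1, slope = 0
# to p = 0.5
boundary_p <- function(t) {
  p <- 0.5 * pchisq(t^2, df = 1, lower.tail = FALSE)
  p[t < 0] <- 1
  p[t == 0] <- 0.5
  p
}

#' ACE estimates per element by squared-pair-differences regression
#'
#' Non-iterative variance-component estimation for every phenotype element:
#' per twin pair, the squared within-pair difference `d = (y1 - y2)^2` is
#' regressed on a 0/1 dizygosity indicator. The MZ group mean identifies
#' `2 sigma2_E`, the slope identifies `sigma2_A`, and the shared-environment
#' component is recovered from the pooled total variance across all
#' subjects. Negative estimates are truncated (A first, then C) and
#' `h2 = A / (A + C + E)` is computed from the constrained values; elements
#' with zero total variance are returned with `h2 = NA`.
#'
#' The test for A > 0 is the one-sided slope statistic (`stat_A`, the
#' regression t truncated at 0) with a parametric p-value from the boundary
#' mixture `1/2 delta_0 + 1/2 chi^2_1`.
#'
#' @param pheno Phenotype tibble (`subject_id` + element columns) or a
#'   subjects-by-elements matrix with subject-id row names.
#' @param cohort Cohort tibble; at least 2 MZ and 2 DZ complete pairs.
#' @param covariates Optional character vector of cohort column names (e.g.
#'   `c("age", "sex")`) residualized out of every element by ordinary least
#'   squares before fitting.
#' @return A tibble of class `ace_fit`: one row per element with columns
#'   `element`, `A`, `C`, `E`, `h2`, `stat_A`, `p_A`.
#' @examples
#' co <- simulate_cohort(200, 200, seed = 1)
#' ph <- simulate_ace_phenotypes(co, ace_params(0.5, 0.2), seed = 2)
#' lrsd_ace(ph, co)
#' @export
lrsd_ace <- function(pheno, cohort, covariates = NULL) {
  validate_cohort(cohort)
  y <- if (is.matrix(pheno)) pheno else pheno_matrix(pheno)
  missing_ids <- setdiff(cohort$subject_id, rownames(y))
  if (length(missing_ids)) {
    abort(paste0("Phenotypes missing for subject(s): ",
                 paste(head(missing_ids, 3), collapse = ", ")))
  }
  y <- y[cohort$subject_id, , drop = FALSE]
  if (!is.null(covariates)) {
    x <- stats::model.matrix(~., data = cohort[, covariates, drop = FALSE])
    y <- qr.resid(qr(x), y)
    rownames(y) <- cohort$subject_id
  }
  sq <- pair_sq_diffs(y, cohort)
  st <- lrsd_t(sq$d, sq$is_dz)
  est <- ace_from_moments(st$m_mz, st$m_dz, sq$var_p)
  degenerate <- sq$var_p <= 0
  if (any(degenerate)) {
    warn(paste0("Element(s) with zero total variance: ",
                paste(colnames(y)[degenerate], collapse = ", ")))
  }
  stat <- pmax(st$t, 0)
  p <- boundary_p(st$t)
  stat[degenerate] <- NA_real_; p[degenerate] <- NA_real_
  out <- tibble(element = colnames(y),
                A = unname(est$A), C = unname(est$C), E = unname(est$E),
                h2 = unname(est$h2),
                stat_A = unname(stat), p_A = unname(p))
  class(out) <- c("ace_fit", class(out))
  attr(out, "n_pairs") <- c(MZ = sum(!sq$is_dz), DZ = sum(sq$is_dz))
  out
}

#' One-sided test for additive-genetic variance on a single element
#'
#' @param values Numeric phenotype vector named by subject id, or a one-
#'   column matrix.
#' @param cohort Cohort tibble.
#' @return Named numeric `c(stat_A, p_A)`.
#' @export
a_test_statistic <- function(values, cohort) {
  y <- if (is.matrix(values)) values else matrix(values, ncol = 1,
                                                 dimnames = list(names(values)))
  if (is.null(rownames(y))) abort("Values must be named by subject id.")
  colnames(y) <- "e001"
  fit <- lrsd_ace(y, cohort)
  c(stat_A = fit$stat_A[1], p_A = fit$p_A[1])
}

#' @method glance ace_fit
#' @export
glance.ace_fit <- function(x, ...) {
  np <- attr(x, "n_pairs")
  tibble(n_elements = nrow(x),
         n_mz_pairs = unname(np["MZ"]), n_dz_pairs = unname(np["DZ"]),
         mean_h2 = mean(x$h2, na.rm = TRUE),
         n_sig_05 = sum(x$p_A < 0.05, na.rm = TRUE))
}

#' @method tidy ace_fit
#' @export
tidy.ace_fit <- function(x, ...) {
  as_tibble(x)
}
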