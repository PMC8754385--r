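#' ACE variance-fraction parameters
#'
#' Bundle of additive-genetic (A), shared-environment (C) and unique-
#' environment (E) variance fractions used by the synthetic generators.
#' The generator convention is A + C + E = 1 so simulated phenotypes have
#' unit marginal variance; E must be strictly positive.
#'
#' @param A,C Variance fractions in `[0, 1]`.
#' @param E Variance fraction in `(0, 1]`. Defaults to `1 - A - C`.
#' @return An object of class `ace_params`: a named numeric vector
#'   `c(A, C, E)`.
#' @examples
#' ace_params(0.5, 0.2)        # E = 0.3 implied
#' @export
ace_params <- function(A, C = 0, E = 1 - A - C) {
  x <- c(A = as.numeric(A), C = as.numeric(C), E = as.numeric(E))
  if (anyNA(x)) abort("ACE fractions must be numeric.")
  if (x["A"] < 0 || x["A"] > 1 || x["C"] < 0 || x["C"] > 1) {
    abort("A and C must lie in [0, 1].")
  }
  if (x["E"] <= 0 || x["E"] > 1) abort("E must lie in (0, 1].")
  if (abs(sum(x) - 1) > 1e-8) {
    abort("Generator convention requires A + C + E = 1.")
  }
  structure(x, class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  cat(sprintf("<ace_params> A = %.3g, C = %.3g, E = %.3g\n",
              x["A"], x["C"], x["E"]))
  invisible(x)
}

# normalize user input (ace_params, plain vector, data.frame row set) into an
# n_elements x 3 matrix of A, C, E fractions
as_ace_matrix <- function(params, n_elements = NULL) {
  if (inherits(params, "ace_params")) {
    m <- matrix(unclass(params), nrow = 1,
                dimnames = list(NULL, c("A", "C", "E")))
  } else if (is.data.frame(params)) {
    if (!all(c("A", "C", "E") %in% names(params))) {
      abort("Parameter table must have columns A, C, E.")
    }
    m <- as.matrix(params[, c("A", "C", "E")])
  } else if (is.list(params)) {
    m <- do.call(rbind, lapply(params, function(p)
      unclass(ace_params(p[["A"]], p[["C"]], p[["E"]]))))
  } else if (is.numeric(params) && length(params) == 3L) {
    m <- matrix(unclass(ace_params(params[1], params[2], params[3])), nrow = 1,
                dimnames = list(NULL, c("A", "C", "E")))
  } else {
    abort("Cannot interpret `params` as ACE fractions.")
  }
  apply(m, 1, function(r) ace_params(r[1], r[2], r[3]))  # validate each row
  if (!is.null(n_elements)) {
    if (nrow(m) == 1L) m <- m[rep(1L, n_elements), , drop = FALSE]
    if (nrow(m) != n_elements) {
      abort("Number of parameter rows must be 1 or match the element count.")
    }
  }
  m
}
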