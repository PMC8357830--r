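#' Monomial basis specifications for gaze regression
#'
#' A gaze model spec names a fixed, ordered set of monomials over the 4D eye
#' feature vector `(x, y, m, n)` — relative pupil coordinates `(x, y)` and
#' inner eye-corner coordinates `(m, n)`, both in camera pixels. Each screen
#' coordinate of the gaze point is modelled as a linear combination of these
#' monomials, so a spec with `N` terms has `N` coefficients per gaze
#' coordinate (`2N` unknowns in total).
#'
#' Monomials are written as products of the variable names with optional
#' integer powers, e.g. `"x"`, `"x*y"`, `"x^2"`, `"x^2*y"`; the constant term
#' is `"1"`. Every spec must include the constant term.
#'
#' @param terms Character vector of monomials, evaluated in the given order.
#' @param name Optional label used in printouts and comparison tables.
#' @return An object of class `gaze_model_spec`.
#' @examples
#' spec <- gaze_model_spec(c("x", "y", "x*y", "x^2", "y^2", "m", "n", "1"),
#'                         name = "quadratic pupil + linear corner")
#' n_coefficients(spec)
#' basis_row(c(x = 2, y = 3, m = 10, n = 20), spec)
#' @export
gaze_model_spec <- function(terms, name = NULL) {
  if (!is.character(terms) || length(terms) < 1) {
    rlang::abort("`terms` must be a non-empty character vector of monomials.")
  }
  powers <- t(vapply(terms, parse_monomial, numeric(4)))
  colnames(powers) <- c("x", "y", "m", "n")
  if (!any(rowSums(powers) == 0)) {
    rlang::abort("The basis must include the constant term \"1\".")
  }
  if (anyDuplicated(powers)) {
    rlang::abort("Duplicate monomials in `terms`.")
  }
  structure(
    list(
      name = name %||% paste0(length(terms), "-term"),
      terms = unname(terms),
      powers = unname(powers)
    ),
    class = "gaze_model_spec"
  )
}

# "x^2*y" -> c(2, 1, 0, 0); "1" -> c(0, 0, 0, 0)
parse_monomial <- function(term) {
  p <- c(x = 0, y = 0, m = 0, n = 0)
  term <- gsub(" ", "", term)
  if (term == "1") return(p)
  for (fac in strsplit(term, "*", fixed = TRUE)[[1]]) {
    parts <- strsplit(fac, "^", fixed = TRUE)[[1]]
    var <- parts[1]
    if (!var %in% names(p)) {
      rlang::abort(sprintf("Unknown variable '%s' in monomial '%s'.", var, term))
    }
    k <- if (length(parts) == 2) suppressWarnings(as.numeric(parts[2])) else 1
    if (is.na(k) || k < 1 || k != round(k)) {
      rlang::abort(sprintf("Invalid power in monomial '%s'.", term))
    }
    p[var] <- p[var] + k
  }
  p
}

#' @export
print.gaze_model_spec <- function(x, ...) {
  cat(sprintf("<gaze_model_spec> %s (%d terms)\n", x$name, length(x$terms)))
  cat("  [", paste(x$terms, collapse = ", "), "]\n")
  invisible(x)
}

#' Number of basis terms (coefficients per gaze coordinate)
#'
#' Each gaze coordinate has one coefficient per basis term, so the full
#' least-squares solve has `2 * n_coefficients(spec)` unknowns.
#'
#' @param spec A [gaze_model_spec()].
#' @return Integer count of basis terms.
#' @export
n_coefficients <- function(spec) {
  stopifnot(inherits(spec, "gaze_model_spec"))
  length(spec$terms)
}

#' Evaluate the monomial basis for one feature vector
#'
#' @param e Numeric feature vector `(x, y, m, n)`, optionally named, or a
#'   one-row data frame with columns `x`, `y`, `m`, `n`.
#' @param spec A [gaze_model_spec()].
#' @return Numeric vector of length `n_coefficients(spec)` with the monomials
#'   evaluated in the spec's fixed order.
#' @export
basis_row <- function(e, spec) {
  drop(basis_matrix(e, spec))
}

#' Evaluate the monomial basis for many feature vectors
#'
#' @param features A data frame with columns `x`, `y`, `m`, `n` (one row per
#'   sample), or a numeric vector for a single sample.
#' @param spec A [gaze_model_spec()].
#' @return A numeric matrix with one row per sample and one column per term.
#' @export
basis_matrix <- function(features, spec) {
  stopifnot(inherits(spec, "gaze_model_spec"))
  if (is.data.frame(features)) {
    vars <- as.matrix(features[, c("x", "y", "m", "n")])
  } else {
    v <- as.numeric(features)
    if (length(v) != 4) rlang::abort("A feature vector has 4 components (x, y, m, n).")
    vars <- matrix(v, nrow = 1, dimnames = list(NULL, c("x", "y", "m", "n")))
  }
  P <- spec$powers
  V <- matrix(1, nrow = nrow(vars), ncol = nrow(P))
  for (j in seq_len(nrow(P))) {
    for (k in 1:4) {
      if (P[j, k] > 0) V[, j] <- V[, j] * vars[, k]^P[j, k]
    }
  }
  colnames(V) <- spec$terms
  V
}

#' The model library: the candidate regression families
#'
#' Four named specs cover the families compared when selecting the deployed
#' model:
#' \describe{
#'   \item{`quadratic_pupil`}{Quadratic in `(x, y)` only; 6 terms. No head
#'     motion terms, so it degrades when the eye corner moves.}
#'   \item{`quadratic_pupil_linear_corner`}{Quadratic in `(x, y)` plus linear
#'     `m`, `n` head-motion terms; 8 terms. The adopted default.}
#'   \item{`cubic_pupil_linear_corner`}{Full cubic in `(x, y)` plus linear
#'     `m`, `n`; 12 terms.}
#'   \item{`full_quadratic_4var`}{Every monomial of total degree at most 2 in
#'     all four variables; 15 terms, the most complex candidate.}
#' }
#'
#' @return A named list of [gaze_model_spec()] objects.
#' @examples
#' vapply(gaze_model_library(), n_coefficients, integer(1) + 0)
#' @export
gaze_model_library <- function() {
  list(
    quadratic_pupil = gaze_model_spec(
      c("x", "y", "x*y", "x^2", "y^2", "1"),
      name = "quadratic_pupil"
    ),
    quadratic_pupil_linear_corner = default_gaze_spec(),
    cubic_pupil_linear_corner = gaze_model_spec(
      c("x", "y", "x*y", "x^2", "y^2", "x^2*y", "x*y^2", "x^3", "y^3",
        "m", "n", "1"),
      name = "cubic_pupil_linear_corner"
    ),
    full_quadratic_4var = full_quadratic_spec()
  )
}

#' The adopted 8-term gaze model spec
#'
#' Quadratic in the relative pupil coordinates with linear eye-corner terms:
#' `x, y, x*y, x^2, y^2, m, n, 1`.
#'
#' @return A [gaze_model_spec()] with 8 terms.
#' @export
default_gaze_spec <- function() {
  gaze_model_spec(
    c("x", "y", "x*y", "x^2", "y^2", "m", "n", "1"),
    name = "quadratic_pupil_linear_corner"
  )
}

#' The full degree-<= 2 basis in four variables (15 terms)
#'
#' All monomials of total degree at most two in `(x, y, m, n)`: the constant,
#' 4 linear terms, 6 pairwise products and 4 squares.
#'
#' @return A [gaze_model_spec()] with 15 terms.
#' @export
full_quadratic_spec <- function() {
  vars <- c("x", "y", "m", "n")
  cross <- utils::combn(vars, 2, function(v) paste(v, collapse = "*"))
  gaze_model_spec(
    c(vars, cross, paste0(vars, "^2"), "1"),
    name = "full_quadratic_4var"
  )
}
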