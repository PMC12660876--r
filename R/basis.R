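#' Construct an equally spaced basis set over an estimate domain
#'
#' Centers are placed with equal spacing between consecutive centers and
#' between each domain bound and its nearest center, i.e.
#' `mu_i = a + i * (b - a) / (K + 1)` for `i = 1..K`.
#'
#' @param kind `"gaussian"` (`f_i(x) = c exp(-(x - mu_i)^2 / (2 sigma^2))`)
#'   or `"sigmoid"` (`f_i(x) = c / (1 + exp(-(x - mu_i) / width))`).
#' @param K Number of basis functions.
#' @param domain Interval `c(a, b)` of the encoded estimate.
#' @param width Gaussian dispersion `sigma`, or sigmoid slope scale. The
#'   default scales the width with the center spacing so that the sum of
#'   the Gaussian basis functions is approximately constant over the domain
#'   (0.04 for `K = 10` on `[0, 1]`, 0.06 for `K = 10` on `[1.1, 2.6]`).
#' @param amplitude Common amplitude `c` (absorbed by the regression fit).
#'
#' @return An object of class `basis_set`.
#' @export
make_basis <- function(kind = c("gaussian", "sigmoid"), K = 10L,
                       domain = c(0, 1), width = NULL, amplitude = 1) {
  kind <- match.arg(kind)
  K <- as.integer(K)
  if (K < 1L) stop("make_basis: `K` must be >= 1", call. = FALSE)
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    stop("make_basis: `domain` must be an interval c(a, b) with a < b",
         call. = FALSE)
  }
  spacing <- diff(domain) / (K + 1)
  if (is.null(width)) width <- 0.44 * spacing
  if (width <= 0) stop("make_basis: `width` must be > 0", call. = FALSE)
  centers <- domain[1] + seq_len(K) * spacing
  structure(list(kind = kind, K = K, domain = domain, centers = centers,
                 width = width, amplitude = amplitude, spacing = spacing),
            class = "basis_set")
}

#' Evaluate a basis set
#'
#' @param basis A [make_basis()] object.
#' @param x Numeric vector of estimate values.
#' @return A `length(x) x K` matrix with `f_i(x)` in column `i`.
#' @export
eval_basis <- function(basis, x) {
  x <- as.numeric(x)
  out <- matrix(NA_real_, length(x), basis$K)
  for (i in seq_len(basis$K)) {
    mu <- basis$centers[i]
    out[, i] <- switch(basis$kind,
      gaussian = basis$amplitude *
        exp(-(x - mu)^2 / (2 * basis$width^2)),
      sigmoid = basis$amplitude / (1 + exp(-(x - mu) / basis$width))
    )
  }
  colnames(out) <- sprintf("f%02d", seq_len(basis$K))
  out
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("%s basis set: K = %d on [%g, %g], width = %g\n",
              x$kind, x$K, x$domain[1], x$domain[2], x$width))
  invisible(x)
}

#' Encoding-model specification
#'
#' Couples a model class (linear, versatile, or posterior-expectation
#' versatile) with the encoded estimate and, where needed, a basis set.
#' Default domains and widths follow the study design: probability on
#' `[0, 1]` with `sigma = 0.04`, confidence (log precision) on `[1.1, 2.6]`
#' with `sigma = 0.06`, `K = 10` Gaussian basis functions.
#'
#' @param model `"linear"`, `"versatile"` or `"posterior_expectation"`.
#' @param estimate `"probability"`, `"confidence"` or `"entropy"`.
#' @param K Number of basis functions (versatile classes).
#' @param width Basis width; defaults to the study value for `K = 10`
#'   (0.04 probability, 0.06 confidence) and otherwise scales with spacing.
#' @param domain Estimate domain; defaults per estimate type.
#' @param kind Basis kind, `"gaussian"` or `"sigmoid"`.
#'
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(model = c("versatile", "linear",
                                    "posterior_expectation"),
                          estimate = c("probability", "confidence",
                                       "entropy"),
                          K = 10L, width = NULL, domain = NULL,
                          kind = c("gaussian", "sigmoid")) {
  model <- match.arg(model)
  estimate <- match.arg(estimate)
  kind <- match.arg(kind)
  if (is.null(domain)) {
    domain <- switch(estimate,
                     probability = c(0, 1),
                     confidence = c(1.1, 2.6),
                     entropy = c(0, log(2)))
  }
  basis <- NULL
  if (model != "linear") {
    if (is.null(width) && K == 10L && kind == "gaussian") {
      width <- switch(estimate, probability = 0.04, confidence = 0.06,
                      NULL)
    }
    basis <- make_basis(kind, K, domain, width)
  }
  structure(list(model = model, estimate = estimate, basis = basis,
                 domain = domain),
            class = "encoding_spec")
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat(sprintf("encoding spec: %s model of %s on [%g, %g]",
              x$model, x$estimate, x$domain[1], x$domain[2]))
  if (!is.null(x$basis)) {
    cat(sprintf(" (%s basis, K = %d, width = %g)",
                x$basis$kind, x$basis$K, x$basis$width))
  }
  cat("\n")
  invisible(x)
}

spec_label <- function(spec) paste(spec$model, spec$estimate, sep = "-")
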