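#' Kernel (covariance function) constructors
#'
#' Covariance functions for the Gaussian-process models. All hyperparameters
#' are strictly positive and are optimised internally in log space. Available
#' kinds:
#'
#' * `kernel_linear_bias(l, b)`: \eqn{k(x_i, x_j) = x_i x_j^T / l^2 + b^2},
#'   a linear kernel plus bias — the predictive function is a linear model of
#'   the features.
#' * `kernel_ard_linear(l)`: linear automatic-relevance-determination kernel
#'   \eqn{k(x_i, x_j) = \sum_m x_{im} x_{jm} / l_m^2}; one scale per input
#'   column, controlling that column's contribution.
#' * `kernel_bias(b)`: constant \eqn{b^2}; input-independent, used to model a
#'   target's marginal distribution.
#' * `kernel_sum(...)`: entrywise sum of child kernels, each of which may be
#'   restricted to a column block via its `cols` field (e.g. linear-plus-bias
#'   on the features plus ARD on appended confounds).
#' * `kernel_ard_se(l)`: ARD squared-exponential, provided as an optional kind
#'   for one-hot encodings of discrete confounds with more than two levels.
#'
#' @param l Positive scale (scalar for `kernel_linear_bias`; vector with one
#'   entry per input column for the ARD kinds).
#' @param b Positive bias hyperparameter (enters the kernel squared).
#' @param cols Optional integer vector: the columns of the input matrix this
#'   kernel applies to (default: all).
#' @param ... For `kernel_sum`, two or more kernel specs.
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- kernel_linear_bias(l = 2, b = 1)
#' gram(k, matrix(c(1, 2, 3, -1), 2, 2, byrow = TRUE))
#' @name kernels
NULL

new_kernel <- function(kind, hyper, cols = NULL, children = NULL) {
  if (length(hyper) && any(hyper <= 0))
    abort(sprintf("%s: hyperparameters must be strictly positive", kind),
          class = "deconfound_domain_error")
  structure(list(kind = kind, hyper = hyper, cols = cols, children = children),
            class = "kernel_spec")
}

#' @rdname kernels
#' @export
kernel_linear_bias <- function(l = 1, b = 1, cols = NULL)
  new_kernel("linear_bias", c(l = unname(l), b = unname(b)), cols)

#' @rdname kernels
#' @export
kernel_ard_linear <- function(l = 1, cols = NULL)
  new_kernel("ard_linear", setNames(l, paste0("l", seq_along(l))), cols)

#' @rdname kernels
#' @export
kernel_bias <- function(b = 1) new_kernel("bias_only", c(b = unname(b)))

#' @rdname kernels
#' @export
kernel_sum <- function(...) {
  children <- list(...)
  if (length(children) < 2)
    abort("a sum kernel needs at least two children", class = "deconfound_domain_error")
  stopifnot(all(vapply(children, inherits, TRUE, "kernel_spec")))
  new_kernel("sum", numeric(0), children = children)
}

#' @rdname kernels
#' @export
kernel_ard_se <- function(l = 1, cols = NULL)
  new_kernel("ard_se", setNames(l, paste0("l", seq_along(l))), cols)

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$kind == "sum") {
    cat("<kernel_spec> sum of", length(x$children), "kernels:\n")
    for (ch in x$children)
      cat("  -", ch$kind, paste(sprintf("%s=%.4g", names(ch$hyper), ch$hyper),
                                collapse = ", "),
          if (!is.null(ch$cols)) sprintf("[cols %d..%d]", min(ch$cols), max(ch$cols)) else "",
          "\n")
  } else {
    cat(sprintf("<kernel_spec> %s (%s)\n", x$kind,
                paste(sprintf("%s=%.4g", names(x$hyper), x$hyper), collapse = ", ")))
  }
  invisible(x)
}

# flat named vector of hyperparameters (natural scale)
kernel_params <- function(spec) {
  if (spec$kind == "sum") {
    out <- numeric(0)
    for (i in seq_along(spec$children)) {
      p <- kernel_params(spec$children[[i]])
      names(p) <- paste0("k", i, ".", names(p))
      out <- c(out, p)
    }
    out
  } else spec$hyper
}

# counterpart setter; `theta` ordered as kernel_params()
kernel_set_params <- function(spec, theta) {
  if (spec$kind == "sum") {
    pos <- 1
    for (i in seq_along(spec$children)) {
      np <- length(kernel_params(spec$children[[i]]))
      spec$children[[i]] <- kernel_set_params(spec$children[[i]],
                                              theta[seq(pos, length.out = np)])
      pos <- pos + np
    }
  } else {
    stopifnot(length(theta) == length(spec$hyper))
    spec$hyper[] <- as.numeric(theta)
    if (any(spec$hyper <= 0))
      abort("hyperparameters must remain positive", class = "deconfound_domain_error")
  }
  spec
}

sel_cols <- function(spec, X) {
  if (is.null(spec$cols)) X else X[, spec$cols, drop = FALSE]
}

check_dims <- function(spec, X) {
  if (!is.null(spec$cols) && max(spec$cols) > ncol(X))
    abort("kernel column selection exceeds input width", class = "deconfound_shape_error")
  d <- if (is.null(spec$cols)) ncol(X) else length(spec$cols)
  nl <- length(grep("^l", names(spec$hyper)))
  if (spec$kind %in% c("ard_linear", "ard_se") && nl != d)
    abort(sprintf("%s kernel has %d scales but input has %d columns", spec$kind, nl, d),
          class = "deconfound_shape_error")
  invisible(TRUE)
}

#' Evaluate a kernel Gram matrix
#'
#' Computes the `n x m` matrix of covariances `k(x_i, x2_j)` between the rows
#' of `X` and `X2` under a kernel specification.
#'
#' @param spec A [kernel_spec][kernels].
#' @param X Numeric matrix (`n x d`).
#' @param X2 Numeric matrix (`m x d`); defaults to `X`.
#' @return An `n x m` matrix.
#' @export
gram <- function(spec, X, X2 = X) {
  X <- as.matrix(X); X2 <- as.matrix(X2)
  if (ncol(X) != ncol(X2))
    abort("X and X2 column counts differ", class = "deconfound_shape_error")
  switch(spec$kind,
    linear_bias = {
      check_dims(spec, X)
      tcrossprod(sel_cols(spec, X), sel_cols(spec, X2)) / spec$hyper[["l"]]^2 +
        spec$hyper[["b"]]^2
    },
    ard_linear = {
      check_dims(spec, X)
      A <- sel_cols(spec, X); B <- sel_cols(spec, X2)
      l <- spec$hyper[grep("^l", names(spec$hyper))]
      tcrossprod(sweep(A, 2, l, "/"), sweep(B, 2, l, "/"))
    },
    bias_only = matrix(spec$hyper[["b"]]^2, nrow(X), nrow(X2)),
    ard_se = {
      check_dims(spec, X)
      A <- sel_cols(spec, X); B <- sel_cols(spec, X2)
      l <- spec$hyper[grep("^l", names(spec$hyper))]
      A <- sweep(A, 2, l, "/"); B <- sweep(B, 2, l, "/")
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      exp(-0.5 * pmax(d2, 0))
    },
    sum = Reduce(`+`, lapply(spec$children, function(ch) gram(ch, X, X2))),
    abort(sprintf("unknown kernel kind '%s'", spec$kind))
  )
}

#' Gradients of a Gram matrix in log-hyperparameter space
#'
#' Returns one matrix per hyperparameter `h`, containing
#' \eqn{\partial K / \partial \log h}, in the order of the flattened
#' hyperparameter vector. Used by the marginal-likelihood optimiser; matches
#' central finite differences of [gram()].
#'
#' @inheritParams gram
#' @return A named list of `n x m` matrices.
#' @export
gram_gradients <- function(spec, X, X2 = X) {
  X <- as.matrix(X); X2 <- as.matrix(X2)
  switch(spec$kind,
    linear_bias = {
      check_dims(spec, X)
      S <- tcrossprod(sel_cols(spec, X), sel_cols(spec, X2))
      list(l = -2 * S / spec$hyper[["l"]]^2,
           b = matrix(2 * spec$hyper[["b"]]^2, nrow(X), nrow(X2)))
    },
    ard_linear = {
      check_dims(spec, X)
      A <- sel_cols(spec, X); B <- sel_cols(spec, X2)
      l <- spec$hyper[grep("^l", names(spec$hyper))]
      out <- lapply(seq_along(l), function(m)
        -2 * tcrossprod(A[, m, drop = FALSE], B[, m, drop = FALSE]) / l[m]^2)
      setNames(out, names(l))
    },
    bias_only = list(b = matrix(2 * spec$hyper[["b"]]^2, nrow(X), nrow(X2))),
    ard_se = {
      A <- sel_cols(spec, X); B <- sel_cols(spec, X2)
      l <- spec$hyper[grep("^l", names(spec$hyper))]
      K <- gram(spec, X, X2)
      out <- lapply(seq_along(l), function(m) {
        d2m <- outer(A[, m]^2, B[, m]^2, "+") - 2 * tcrossprod(A[, m], B[, m])
        K * d2m / l[m]^2
      })
      setNames(out, names(l))
    },
    sum = {
      out <- list()
      for (i in seq_along(spec$children)) {
        g <- gram_gradients(spec$children[[i]], X, X2)
        names(g) <- paste0("k", i, ".", names(g))
        out <- c(out, g)
      }
      out
    },
    abort(sprintf("unknown kernel kind '%s'", spec$kind))
  )
}
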