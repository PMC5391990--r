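# Feature adjustment ("regressing out" confounds): per-feature least-squares
# fits on the intercept-augmented confounds, applied as residual-forming.

#' Fit a confound-adjustment model
#'
#' Fits, for every feature column simultaneously, the ordinary-least-squares
#' regression of the feature on the intercept-augmented confounds
#' \eqn{\hat C}, i.e. \eqn{\beta = (\hat C_S^T \hat C_S)^{-1} \hat C_S^T G_S}
#' where `S` is an optional subset of rows used for the fit (default: all).
#'
#' @param G Feature matrix (`n x dG`).
#' @param C_hat Intercept-augmented confound matrix, from
#'   [augment_confounds()].
#' @param subset Optional integer vector of rows used to fit the model
#'   (e.g. training subjects only); default all rows.
#' @return An object of class `adjustment_model` with fields `beta`
#'   (`(dC + 1) x dG`) and `fit_subset`.
#' @export
fit_adjustment <- function(G, C_hat, subset = NULL) {
  G <- as.matrix(G); C_hat <- as.matrix(C_hat)
  if (nrow(G) != nrow(C_hat))
    abort("G and C_hat row counts differ", class = "deconfound_shape_error")
  if (is.null(subset)) subset <- seq_len(nrow(G))
  Cs <- C_hat[subset, , drop = FALSE]
  qrC <- qr(Cs)
  if (qrC$rank < ncol(Cs)) {
    bad <- setdiff(seq_len(ncol(Cs)), sort(qrC$pivot[seq_len(qrC$rank)]))
    abort(sprintf("augmented confound matrix is rank deficient (columns: %s)",
                  paste(colnames(Cs)[bad] %||% bad, collapse = ", ")),
          class = "deconfound_singularity_error")
  }
  beta <- qr.coef(qrC, G[subset, , drop = FALSE])
  structure(list(beta = beta, fit_subset = subset), class = "adjustment_model")
}

#' Apply a confound-adjustment model
#'
#' Returns the adjusted features \eqn{G^A = G - \hat C \beta}. When the model
#' was fit on all rows, the residual columns are orthogonal to every column
#' of \eqn{\hat C}; rows outside the fitting subset are adjusted with the
#' subset-estimated coefficients and need not be orthogonal.
#'
#' @inheritParams fit_adjustment
#' @param model An [fit_adjustment()] result.
#' @return The adjusted feature matrix, same shape as `G`.
#' @export
apply_adjustment <- function(G, C_hat, model) {
  G <- as.matrix(G); C_hat <- as.matrix(C_hat)
  if (ncol(C_hat) != nrow(model$beta) || ncol(G) != ncol(model$beta))
    abort("shapes inconsistent with adjustment model", class = "deconfound_shape_error")
  G - C_hat %*% model$beta
}

#' Adjust features for confounds in one step
#'
#' Convenience wrapper: augments `C` with an intercept, fits the per-feature
#' regressions on `subset` (default all rows) and returns the residualised
#' features.
#'
#' @param G Feature matrix.
#' @param C Confound matrix (not yet augmented).
#' @param subset Optional fitting rows, as in [fit_adjustment()].
#' @return The adjusted feature matrix \eqn{G^A}.
#' @export
adjust_features <- function(G, C, subset = NULL) {
  C_hat <- augment_confounds(C)
  apply_adjustment(G, C_hat, fit_adjustment(G, C_hat, subset))
}
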