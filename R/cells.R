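#' Estimate blood cell-type proportions by constrained projection
#'
#' Reference-based deconvolution in the Houseman tradition: each sample's
#' beta profile over the shared probes is projected onto the flow-sorted
#' reference profiles by constrained least squares,
#' `min ||x - R w||^2` subject to `w >= 0` and `sum(w) <= 1`, solved as a
#' quadratic program. The inequality (rather than equality) sum
#' constraint tolerates references that do not span every cell type in
#' the sample; the returned proportions are renormalized to sum to 1.
#'
#' @param betas probes x samples beta matrix.
#' @param reference probes x cell-types matrix of reference mean betas;
#'   at least as many shared probes as cell types are required.
#' @return samples x cell-types matrix of proportions, rows summing to 1.
#' @export
estimate_cell_proportions <- function(betas, reference) {
  validate_beta_matrix(betas)
  shared <- intersect(rownames(betas), rownames(reference))
  k <- ncol(reference)
  if (length(shared) < k) {
    stop("need at least ", k, " probes shared with the reference; found ",
         length(shared))
  }
  R <- reference[shared, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < k) {
    bad <- colnames(R)[qrR$pivot[(qrR$rank + 1):k]]
    stop("reference is rank deficient; collinear cell types: ",
         paste(bad, collapse = ", "))
  }
  D <- crossprod(R)
  Amat <- cbind(diag(k), -1)               # w >= 0 ; -sum(w) >= -1
  bvec <- c(rep(0, k), -1)
  props <- t(vapply(colnames(betas), function(s) {
    d <- crossprod(R, betas[shared, s])
    w <- quadprog::solve.QP(D, d, Amat, bvec)$solution
    w <- pmax(w, 0)
    if (sum(w) < 1e-8) stop("degenerate projection for sample ", s)
    w / sum(w)
  }, numeric(k)))
  colnames(props) <- colnames(reference)
  props
}

#' Correct betas for cell composition
#'
#' Removes between-sample variation attributable to blood cell mixture:
#' per probe, betas are regressed on the estimated cell proportions
#' (ordinary least squares across samples, intercept included; one
#' proportion column is dropped since proportions sum to 1), and the
#' corrected value is the residual plus the fitted value at the
#' cohort-mean proportions. This keeps corrected values on the beta scale
#' — a sample with exactly average composition is unchanged — and the
#' result is clamped to `[0, 1]`.
#'
#' @param betas probes x samples beta matrix.
#' @param proportions samples x cell-types matrix (rows aligned with
#'   `colnames(betas)`), e.g. from [estimate_cell_proportions()].
#' @param pass_through return `betas` unchanged instead of erroring when
#'   there are too few samples for a stable regression.
#' @return Corrected beta matrix, same shape and dimnames.
#' @export
celltype_correct <- function(betas, proportions, pass_through = FALSE) {
  validate_beta_matrix(betas)
  if (!is.matrix(proportions)) proportions <- as.matrix(proportions)
  if (nrow(proportions) != ncol(betas)) {
    stop("proportions must have one row per sample")
  }
  k <- ncol(proportions)
  n <- ncol(betas)
  if (n < k + 2) {
    if (pass_through) return(betas)
    stop("need at least ", k + 2, " samples to regress on ", k,
         " cell types; set pass_through = TRUE to skip correction")
  }
  X <- cbind(1, proportions[, -k, drop = FALSE])   # drop one: rows sum to 1
  qx <- qr(X)
  coefs <- qr.coef(qx, t(betas))
  coefs[is.na(coefs)] <- 0                 # aliased columns contribute 0
  fitted <- X %*% coefs
  resid <- t(betas) - fitted
  at_mean <- drop(colMeans(X) %*% coefs)   # fitted value at cohort-mean mix
  corrected <- t(resid + rep(at_mean, each = n))
  corrected <- pmin(pmax(corrected, 0), 1)
  dimnames(corrected) <- dimnames(betas)
  corrected
}
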