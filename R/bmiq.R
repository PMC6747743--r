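#' Fit a three-state beta mixture to methylation values
#'
#' Methylation beta values are well described by a mixture of three beta
#' distributions for the unmethylated (U), hemimethylated (H) and
#' methylated (M) states. The fit is by expectation-maximization: the
#' E-step computes state responsibilities, the M-step re-estimates the
#' mixture weights in closed form and improves each state's shape
#' parameters by bounded quasi-Newton ascent from the current values
#' (a generalized EM step, so the observed-data log-likelihood is
#' non-decreasing across iterations). Initialization is deterministic,
#' from the empirical terciles of the data, so repeated fits are
#' bit-identical.
#'
#' @param values numeric vector of beta values; clamped into
#'   `[1e-6, 1 - 1e-6]` before fitting. At least 30 values and at least
#'   `n_states` distinct values are required.
#' @param n_states number of mixture components (default 3: U, H, M).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param shape_bounds lower/upper bounds for the beta shape parameters.
#' @return A `beta_mixture` list: `weights` (sums to 1), `shape1`,
#'   `shape2`, state `means` sorted increasing so state 1 is U and state
#'   `n_states` is M, per-point `responsibilities` (rows sum to 1),
#'   `loglik` trace, and `converged`.
#' @export
fit_beta_mixture <- function(values, n_states = 3L, max_iter = 500L,
                             tol = 1e-6, shape_bounds = c(0.1, 1e4)) {
  x <- pmin(pmax(as.numeric(values), 1e-6), 1 - 1e-6)
  if (length(x) < 30) stop("need at least 30 values to fit a beta mixture")
  if (length(unique(x)) < n_states) {
    stop("degenerate input: fewer than ", n_states, " distinct values")
  }
  n <- length(x)
  # tercile (quantile-block) initialization: deterministic
  ord <- order(x)
  block <- cut(seq_len(n), n_states, labels = FALSE)
  a <- b <- numeric(n_states)
  for (k in seq_len(n_states)) {
    xk <- x[ord[block == k]]
    m <- mean(xk); v <- max(stats::var(xk), 1e-6)
    phi <- max(m * (1 - m) / v - 1, 0.2)
    a[k] <- min(max(m * phi, shape_bounds[1]), shape_bounds[2])
    b[k] <- min(max((1 - m) * phi, shape_bounds[1]), shape_bounds[2])
  }
  w <- rep(1 / n_states, n_states)

  comp_logdens <- function(a, b) {
    vapply(seq_len(n_states),
           function(k) stats::dbeta(x, a[k], b[k], log = TRUE),
           numeric(n))
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  r <- NULL
  for (it in seq_len(max_iter)) {
    ld <- sweep(comp_logdens(a, b), 2, log(w), "+")
    mx <- apply(ld, 1, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    r <- exp(ld - lse)                      # responsibilities, rows sum to 1
    ll_trace <- c(ll_trace, sum(lse))
    if (it > 1) {
      rel <- abs(diff(utils::tail(ll_trace, 2))) /
        (abs(ll_trace[length(ll_trace) - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    w <- colMeans(r)
    for (k in seq_len(n_states)) {
      rk <- r[, k]
      if (sum(rk) < 1e-8) next
      nll <- function(par) -sum(rk * stats::dbeta(x, par[1], par[2],
                                                  log = TRUE))
      fit <- stats::optim(c(a[k], b[k]), nll, method = "L-BFGS-B",
                          lower = shape_bounds[1], upper = shape_bounds[2],
                          control = list(maxit = 25))
      a[k] <- fit$par[1]; b[k] <- fit$par[2]
    }
  }
  if (!converged) {
    warning("beta-mixture EM did not converge in ", max_iter,
            " iterations; returning best-so-far fit")
  }
  o <- order(a / (a + b))                   # relabel U < H < M by state mean
  structure(list(weights = w[o], shape1 = a[o], shape2 = b[o],
                 means = (a / (a + b))[o],
                 responsibilities = r[, o, drop = FALSE],
                 loglik = ll_trace, converged = converged),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat("beta mixture:", length(x$weights), "states\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat("  means:  ", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  invisible(x)
}

bmiq_transform_sample <- function(x, type, params) {
  i1 <- which(type == "I"); i2 <- which(type == "II")
  if (length(i1) == 0 || length(i2) == 0) {
    if (isTRUE(params$pass_through_single_type)) return(x)
    stop("both probe design types must be present (or allow pass-through)")
  }
  fit1 <- fit_beta_mixture(x[i1], max_iter = params$max_iter,
                           tol = params$tol)
  fit2 <- fit_beta_mixture(x[i2], max_iter = params$max_iter,
                           tol = params$tol)
  state <- max.col(fit2$responsibilities)   # 1 = U, 2 = H, 3 = M
  x2 <- pmin(pmax(x[i2], 1e-6), 1 - 1e-6)
  y2 <- x2
  iU <- which(state == 1); iH <- which(state == 2); iM <- which(state == 3)
  if (length(iU) > 0) {
    p <- stats::pbeta(x2[iU], fit2$shape1[1], fit2$shape2[1])
    y2[iU] <- stats::qbeta(p, fit1$shape1[1], fit1$shape2[1])
  }
  if (length(iM) > 0) {
    p <- stats::pbeta(x2[iM], fit2$shape1[3], fit2$shape2[3],
                      lower.tail = FALSE)
    y2[iM] <- stats::qbeta(p, fit1$shape1[3], fit1$shape2[3],
                           lower.tail = FALSE)
  }
  if (length(iH) > 0 && length(iU) > 0 && length(iM) > 0) {
    # dilate the hemimethylated block into the gap between the transformed
    # U and M regions, preserving the original gaps at either end
    minH <- min(x2[iH]); maxH <- max(x2[iH])
    deltaH <- maxH - minH
    nminH <- max(y2[iU]) + (minH - max(x2[iU]))
    nmaxH <- min(y2[iM]) - (min(x2[iM]) - maxH)
    if (deltaH > 0 && nmaxH > nminH) {
      y2[iH] <- nminH + (nmaxH - nminH) * (x2[iH] - minH) / deltaH
    } else {
      y2[iH] <- (nminH + nmaxH) / 2
    }
  }
  out <- x
  out[i2] <- pmin(pmax(y2, 0), 1)
  out
}

#' BMIQ parameters
#'
#' @param max_iter,tol EM controls for the per-sample mixture fits.
#' @param pass_through_single_type if a sample's matrix carries only one
#'   probe design type, return it unchanged instead of erroring.
#' @return Parameter list for [bmiq_normalize()].
#' @export
bmiq_params <- function(max_iter = 500L, tol = 1e-6,
                        pass_through_single_type = TRUE) {
  list(max_iter = max_iter, tol = tol,
       pass_through_single_type = pass_through_single_type)
}

#' BMIQ beta-mixture quantile normalization
#'
#' The two Infinium probe chemistries report systematically different
#' beta distributions: type II betas are compressed toward 0.5. BMIQ fits
#' a three-state (U/H/M) beta mixture separately to each sample's type I
#' and type II probes, assigns each type II probe to the state with
#' maximal responsibility, and maps type II U- and M-state probes onto
#' the corresponding type I state distribution by quantile transformation
#' (state CDF under the type II fit, inverse CDF under the type I fit).
#' Hemimethylated probes are linearly dilated into the gap left between
#' the transformed U and M regions. Type I probes are never altered, and
#' the maps are monotone within state, so within-state rank order of type
#' II probes is preserved.
#'
#' @param betas probes x samples matrix (see [validate_beta_matrix()]).
#' @param annotation named design-type vector covering every probe (see
#'   [read_probe_annotation()]).
#' @param params a [bmiq_params()] list.
#' @return Normalized beta matrix, same shape and dimnames, values in
#'   `[0, 1]`.
#' @export
bmiq_normalize <- function(betas, annotation, params = bmiq_params()) {
  validate_beta_matrix(betas)
  if (!all(rownames(betas) %in% names(annotation))) {
    stop("annotation must cover every probe in the beta matrix")
  }
  type <- unname(annotation[rownames(betas)])
  out <- betas
  for (s in colnames(betas)) {
    out[, s] <- tryCatch(
      bmiq_transform_sample(betas[, s], type, params),
      error = function(e) stop("BMIQ failed for sample ", s, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}
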