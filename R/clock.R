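#' The piecewise log/linear age transformation
#'
#' Epigenetic clocks of the Horvath family are trained on a transformed
#' age scale that is logarithmic through development and linear in
#' adulthood, with the branch at `adult_age`:
#' `m = log(age + 1) - log(adult_age + 1)` for `age <= adult_age`, and
#' `m = (age - adult_age) / (adult_age + 1)` above it. The map is
#' continuous and strictly increasing; [age_inverse()] is its exact
#' inverse.
#'
#' @param age chronological age in years, `> -1`.
#' @param m transformed age.
#' @param adult_age branch point in years (default 20).
#' @return `age_forward` returns the transformed age; `age_inverse`
#'   returns years.
#' @examples
#' age_forward(20)          # 0 at the branch point
#' age_forward(41)          # 1 on the linear branch
#' age_inverse(age_forward(7.5))
#' @export
age_forward <- function(age, adult_age = 20) {
  if (any(age <= -1)) stop("age must exceed -1 year")
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_forward
#' @export
age_inverse <- function(m, adult_age = 20) {
  ifelse(m <= 0,
         exp(m + log(adult_age + 1)) - 1,
         m * (adult_age + 1) + adult_age)
}

#' Score epigenetic age from a beta matrix
#'
#' Applies a coefficient-driven clock: for each sample, the weighted sum
#' of the clock probes' betas plus the intercept gives the transformed
#' age, which [age_inverse()] maps back to years. Every weighted probe
#' must be present in the matrix.
#'
#' @param betas probes x samples beta matrix (normalized and corrected
#'   upstream as desired — scoring itself is a dot product).
#' @param clock a [clock_model()].
#' @return Named numeric vector of epigenetic ages (years), one per
#'   sample.
#' @export
clock_age <- function(betas, clock) {
  validate_beta_matrix(betas)
  absent <- setdiff(names(clock$weights), rownames(betas))
  if (length(absent) > 0) {
    stop("clock probes missing from the beta matrix: ",
         paste(absent, collapse = ", "))
  }
  m <- clock$intercept +
    drop(crossprod(betas[names(clock$weights), , drop = FALSE],
                   clock$weights))
  stats::setNames(age_inverse(m, clock$adult_age), colnames(betas))
}

#' Run the full clock chain on a beta matrix
#'
#' Convenience wrapper: optional BMIQ normalization, optional
#' cell-composition estimation and correction, then clock scoring.
#'
#' @param betas probes x samples beta matrix.
#' @param clock a [clock_model()].
#' @param annotation probe design types (required when `bmiq = TRUE`).
#' @param cell_reference probes x cell-types reference (required when
#'   `cell_correct = TRUE`).
#' @param bmiq,cell_correct stage switches.
#' @param params [bmiq_params()].
#' @return List with `ages` (named vector), `betas` (the matrix actually
#'   scored), and `cell_proportions` (or `NULL`).
#' @export
clock_chain <- function(betas, clock, annotation = NULL,
                        cell_reference = NULL, bmiq = FALSE,
                        cell_correct = FALSE, params = bmiq_params()) {
  b <- validate_beta_matrix(betas)
  props <- NULL
  if (bmiq) {
    if (is.null(annotation)) stop("BMIQ requires a probe annotation")
    b <- bmiq_normalize(b, annotation, params)
  }
  if (cell_correct) {
    if (is.null(cell_reference)) {
      stop("cell correction requires a cell-type reference")
    }
    props <- estimate_cell_proportions(b, cell_reference)
    b <- celltype_correct(b, props)
  }
  list(ages = clock_age(b, clock), betas = b, cell_proportions = props)
}
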