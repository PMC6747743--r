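#' Validate a methylation beta matrix
#'
#' Beta values are methylation fractions, probes in rows and samples in
#' columns. Values must lie in `[0, 1]` with no missing entries and no
#' duplicated probe or sample ids; imputation is upstream's problem.
#'
#' @param betas numeric matrix with probe rownames and sample colnames.
#' @return The matrix, invisibly checked.
#' @export
validate_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop("betas must be a numeric matrix")
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop("betas must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(betas))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(betas))) stop("duplicate sample ids")
  if (anyNA(betas)) stop("missing beta values are not allowed")
  if (any(betas < 0 | betas > 1)) stop("beta values must lie in [0, 1]")
  betas
}

#' Read / write beta matrices as TSV
#'
#' Probes x samples, tab-separated, header row of sample ids, first column
#' of probe ids. The same layout is used for cell-type reference profiles
#' (columns are cell types).
#'
#' @param path TSV file.
#' @param betas matrix to write.
#' @return `read_beta_tsv` returns a validated numeric matrix.
#' @export
read_beta_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  validate_beta_matrix(m)
}

#' @rdname read_beta_tsv
#' @export
write_beta_tsv <- function(betas, path) {
  d <- data.frame(probe_id = rownames(betas), betas,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe design annotation
#'
#' CSV with columns `probe_id, design_type`, design type `"I"` or `"II"`
#' (the two Infinium assay chemistries; BMIQ maps type II onto the type I
#' distribution).
#'
#' @param path CSV file.
#' @return Named character vector, probe id to design type.
#' @export
read_probe_annotation <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(d$design_type %in% c("I", "II"))) {
    stop("design_type must be 'I' or 'II'")
  }
  stats::setNames(d$design_type, d$probe_id)
}

#' Read an epigenetic-clock coefficient table
#'
#' CSV with columns `probe_id, weight`; the reserved rows `(Intercept)`
#' and `(AdultAge)` carry the model intercept and the branch point of the
#' age transformation. Coefficients are runtime data, never hard-coded, so
#' any published clock in this layout can be dropped in.
#'
#' @param path CSV file.
#' @return A `clock_model` list: `intercept`, `adult_age`, and `weights`
#'   (named numeric vector over probes).
#' @export
read_clock_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  clock_model(
    intercept = d$weight[d$probe_id == "(Intercept)"],
    weights = stats::setNames(
      d$weight[!d$probe_id %in% c("(Intercept)", "(AdultAge)")],
      d$probe_id[!d$probe_id %in% c("(Intercept)", "(AdultAge)")]),
    adult_age = if (any(d$probe_id == "(AdultAge)"))
      d$weight[d$probe_id == "(AdultAge)"] else 20
  )
}

#' @rdname read_clock_csv
#' @param clock a `clock_model`.
#' @export
write_clock_csv <- function(clock, path) {
  d <- data.frame(
    probe_id = c("(Intercept)", "(AdultAge)", names(clock$weights)),
    weight = c(clock$intercept, clock$adult_age, unname(clock$weights)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a clock model
#'
#' @param intercept model intercept on the transformed-age scale.
#' @param weights named numeric vector of per-probe coefficients (sparse:
#'   only weighted probes appear).
#' @param adult_age branch point of the age transformation, years.
#' @return A `clock_model` list.
#' @export
clock_model <- function(intercept, weights, adult_age = 20) {
  if (length(weights) < 1) stop("a clock needs at least one weighted probe")
  if (is.null(names(weights)) || anyDuplicated(names(weights))) {
    stop("weights must be uniquely named by probe id")
  }
  structure(list(intercept = as.numeric(intercept),
                 weights = weights,
                 adult_age = as.numeric(adult_age)),
            class = "clock_model")
}
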