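#' Analysis arms of the simulation design
#'
#' Each continuous sample is analyzed five ways: as continuous data with
#' Pearson correlations, and after dichotomization at a 50-50 split
#' (`delta = 0`) or a 75-25 split (`delta = qnorm(0.75)`), each with Pearson
#' and with tetrachoric correlations.
#'
#' @param ids optional subset of arm ids.
#' @return named list of arm descriptors with fields `id`, `delta`
#'   (`NA` for the continuous arm) and `corr_kind`.
#' @export
analysis_arms <- function(ids = NULL) {
  arms <- list(
    cont_pearson = list(id = "cont_pearson", delta = NA_real_,
                        corr_kind = "pearson"),
    d50_pearson = list(id = "d50_pearson", delta = 0,
                       corr_kind = "pearson"),
    d50_tetra = list(id = "d50_tetra", delta = 0,
                     corr_kind = "tetrachoric"),
    d75_pearson = list(id = "d75_pearson", delta = stats::qnorm(0.75),
                       corr_kind = "pearson"),
    d75_tetra = list(id = "d75_tetra", delta = stats::qnorm(0.75),
                     corr_kind = "tetrachoric"))
  if (is.null(ids)) return(arms)
  missing <- setdiff(ids, names(arms))
  if (length(missing)) stop("unknown arm id(s): ", paste(missing, collapse = ", "))
  arms[ids]
}

#' Push data through an arm's pipeline
#'
#' `arm_transform` applies the arm's dichotomization (identity for the
#' continuous arm); `arm_correlation` additionally computes the arm's
#' correlation matrix. Comparison data inside parallel-analysis style criteria
#' go through the same two steps so the null reference matches the observed
#' pipeline.
#'
#' @param X numeric matrix of continuous draws (or already-transformed data
#'   for `arm_correlation`, see `transformed`).
#' @param arm one element of [analysis_arms()].
#' @param transformed set to `TRUE` when `X` has already been through
#'   `arm_transform` (e.g. the observed binary data of a dichotomized arm).
#' @return `arm_transform`: a matrix; `arm_correlation`: a
#'   `correlation_estimate`.
#' @export
arm_transform <- function(X, arm) {
  if (is.na(arm$delta)) X else dichotomize(X, arm$delta)
}

#' @rdname arm_transform
#' @export
arm_correlation <- function(X, arm, transformed = TRUE) {
  if (!transformed) X <- arm_transform(X, arm)
  if (arm$corr_kind == "tetrachoric") tetrachoric_matrix(X) else pearson_matrix(X)
}

# fast degeneracy check for simulated comparison data: continuous normal
# draws cannot produce constant columns; binary data can (all 0s or all 1s)
.arm_data_ok <- function(D, arm) {
  if (is.na(arm$delta)) return(TRUE)
  s <- colSums(D)
  all(s > 0L & s < nrow(D))
}
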