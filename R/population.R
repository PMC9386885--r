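#' Specify a population factor model with minor-factor contamination
#'
#' Describes a population in which `n_major` factors with perfect simple
#' structure drive `n_items` standardized items, contaminated by `n_minor`
#' weak "minor" factors whose loadings decay geometrically across columns.
#' Minor factors emulate the lack of fit of the common-factor model to real
#' data: the population correlation matrix is not exactly a rank-`n_major`
#' plus diagonal structure.
#'
#' @param n_items number of manifest variables J.
#' @param n_major number of major factors M1 (each item loads on exactly one).
#' @param n_minor number of minor factors M2; `0` gives a clean factor model.
#' @param communality_levels set of admissible major-factor communalities
#'   (squared loadings); each item's value is sampled uniformly from this set.
#' @param interfactor_corr common correlation among all major-factor pairs,
#'   in `[0, 1)`.
#' @param common_ratio multiplier of the geometric decay of minor-factor
#'   loading columns, in `(0, 1]`.
#' @param minor_share_rule how the minor-factor communality of an item derives
#'   from its major communality. `"half_sqrt_norm"` sets the minor-loading row
#'   norm to `0.5 * sqrt(1 - h2_major)`, i.e. `h2_minor = 0.25 * (1 - h2_major)`,
#'   which keeps every uniqueness positive for communalities up to 0.8.
#' @param seed integer seed fixing the population draw.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_items = 20L, n_major = 3L, n_minor = 200L,
                            communality_levels = c(0.2, 0.3, 0.4),
                            interfactor_corr = 0,
                            common_ratio = 0.8,
                            minor_share_rule = "half_sqrt_norm",
                            seed = 1L) {
  n_items <- as.integer(n_items)
  n_major <- as.integer(n_major)
  n_minor <- as.integer(n_minor)
  if (n_items < 1L || n_major < 1L || n_minor < 0L)
    stop("invalid spec: counts must be positive (n_minor may be zero)")
  if (n_items < n_major)
    stop("invalid spec: n_items must be >= n_major")
  if (any(communality_levels <= 0) || any(communality_levels >= 1))
    stop("invalid spec: communality levels must lie strictly in (0, 1)")
  if (interfactor_corr < 0 || interfactor_corr >= 1)
    stop("invalid spec: interfactor_corr must lie in [0, 1)")
  if (common_ratio <= 0 || common_ratio > 1)
    stop("invalid spec: common_ratio must lie in (0, 1]")
  minor_share_rule <- match.arg(minor_share_rule, "half_sqrt_norm")
  structure(
    list(n_items = n_items, n_major = n_major, n_minor = n_minor,
         communality_levels = communality_levels,
         interfactor_corr = interfactor_corr,
         common_ratio = common_ratio,
         minor_share_rule = minor_share_rule,
         seed = as.integer(seed)),
    class = "population_spec")
}

#' Major-factor loading matrix with perfect simple structure
#'
#' Items are partitioned into `n_major` contiguous blocks, as equal in size as
#' possible (earlier blocks take the remainder: 20 items over 3 factors gives
#' 7/7/6). The item assigned to factor m receives loading `sqrt(h2)` with `h2`
#' drawn uniformly from the spec's communality levels; all other entries are 0.
#'
#' @param spec a [population_spec()].
#' @return list with `Lambda` (J x M1 loading matrix) and `h2` (length-J
#'   major-factor communalities).
#' @export
build_major_loadings <- function(spec) {
  J <- spec$n_items; M1 <- spec$n_major
  sizes <- rep(J %/% M1, M1)
  rem <- J %% M1
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  block <- rep(seq_len(M1), times = sizes)
  h2 <- sample(spec$communality_levels, J, replace = TRUE)
  Lambda <- matrix(0, J, M1)
  Lambda[cbind(seq_len(J), block)] <- sqrt(h2)
  list(Lambda = Lambda, h2 = h2, block = block)
}

#' Minor-factor loading matrix with geometric column decay
#'
#' Entries are drawn standard normal, column m is multiplied by
#' `common_ratio^(m-1)`, and each row is rescaled so its squared norm equals
#' the item's minor-factor communality `0.25 * (1 - h2_major)`.
#'
#' @param spec a [population_spec()].
#' @param h2_major length-J major-factor communalities.
#' @return list with `Lambda` (J x M2) and `h2` (length-J minor communalities).
#' @export
build_minor_loadings <- function(spec, h2_major) {
  J <- spec$n_items; M2 <- spec$n_minor
  if (any(h2_major <= 0) || any(h2_major >= 1))
    stop("invalid spec: major communalities must lie in (0, 1)")
  h2_minor <- 0.25 * (1 - h2_major)
  if (any(h2_major + h2_minor >= 1))
    stop("invalid spec: negative uniqueness implied by minor-share rule")
  if (M2 == 0L)
    return(list(Lambda = matrix(0, J, 0), h2 = rep(0, J)))
  G <- matrix(stats::rnorm(J * M2), J, M2)
  G <- sweep(G, 2L, spec$common_ratio^(seq_len(M2) - 1L), `*`)
  norms <- sqrt(rowSums(G^2))
  Lambda <- G * (sqrt(h2_minor) / norms)
  list(Lambda = Lambda, h2 = h2_minor)
}

#' Assemble the population correlation matrix
#'
#' Builds the full population model
#' `R = Lambda_major Phi Lambda_major' + Lambda_minor Lambda_minor' + diag(psi)`
#' where `Phi` has unit diagonal and the spec's interfactor correlation on all
#' off-diagonal entries, and `psi` completes each item's variance to 1. The
#' draw of communalities and minor loadings is fixed by the spec's seed, so
#' one spec defines one population reusable across replications.
#'
#' @param spec a [population_spec()].
#' @return an object of class `population_model` with fields `Lambda_major`,
#'   `Lambda_minor`, `Phi`, `psi`, `R`, `h2_major`, `h2_minor`, `spec`.
#' @export
assemble_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  J <- spec$n_items; M1 <- spec$n_major
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  maj <- build_major_loadings(spec)
  mino <- build_minor_loadings(spec, maj$h2)
  Phi <- matrix(spec$interfactor_corr, M1, M1)
  diag(Phi) <- 1
  psi <- 1 - maj$h2 - mino$h2
  R <- maj$Lambda %*% Phi %*% t(maj$Lambda) +
    mino$Lambda %*% t(mino$Lambda) + diag(psi)
  # loadings are exact; tiny asymmetry can only come from round-off
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("population correlation matrix not positive definite (min eigenvalue %.3e)",
                 min(ev)))
  if (max(abs(diag(R) - 1)) > 1e-10)
    stop("population correlation matrix diagonal deviates from 1")
  structure(
    list(Lambda_major = maj$Lambda, Lambda_minor = mino$Lambda,
         Phi = Phi, psi = psi, R = R,
         h2_major = maj$h2, h2_minor = mino$h2,
         block = maj$block, spec = spec),
    class = "population_model")
}

#' Serialize / restore a population model as JSON
#'
#' @param model a `population_model`.
#' @param path file path.
#' @return `population_to_json` invisibly returns `path`;
#'   `population_from_json` returns the restored `population_model`.
#' @export
population_to_json <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  obj <- list(Lambda_major = model$Lambda_major,
              Lambda_minor = model$Lambda_minor,
              Phi = model$Phi, psi = model$psi, R = model$R,
              h2_major = model$h2_major, h2_minor = model$h2_minor,
              block = model$block,
              spec = unclass(model$spec))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname population_to_json
#' @export
population_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$spec <- structure(obj$spec, class = "population_spec")
  obj$Lambda_major <- as.matrix(obj$Lambda_major)
  obj$Lambda_minor <- as.matrix(obj$Lambda_minor)
  obj$Phi <- as.matrix(obj$Phi)
  obj$R <- as.matrix(obj$R)
  structure(obj, class = "population_model")
}

# save/restore the global RNG state so seeded constructors do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
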