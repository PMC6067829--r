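#' Negative log-model evidence for a fitted hierarchical model
#'
#' The marginal likelihood of the hierarchical model is approximated by
#' marginalizing individual parameters with a Laplace approximation and the
#' 2m group parameters (mean and variance) with a Bayesian-information
#' penalty, giving
#' \deqn{NLME \approx -\sum_n \log P(D^n|\theta^n)
#'   - \sum_n \log N(\theta^n|\Theta,\Sigma)
#'   - \tfrac{1}{2} m N \log 2\pi
#'   + \tfrac{1}{2} \sum_n \log |H_n| + m \log N}
#' where \eqn{m} is the number of free parameters per unit (3 full, 2
#' reduced), \eqn{N} the number of units, and \eqn{|H_n|} the determinant
#' of the Hessian of the negative log-posterior at the MAP. Lower is
#' better.
#'
#' @param fits List of `subject_fit` objects from the converged
#'   hierarchical fit (or a `hier_fit`, in which case `prior` defaults to
#'   its prior).
#' @param prior The [group_prior()] the fits were obtained under.
#' @param m Number of free parameters per unit; defaults from the variant.
#' @param n_units Number of units `N`; defaults to `length(fits)`.
#' @return A `model_evidence` list: `nlme`, `m`, `n_units`, and
#'   `per_unit_terms` (tibble of log-likelihood, log prior density and
#'   `log|H_n|` per unit, for audit).
#' @export
compute_nlme <- function(fits, prior = NULL, m = NULL, n_units = NULL) {
  if (inherits(fits, "hier_fit")) {
    if (is.null(prior)) prior <- fits$prior
    fits <- fits$fits
  }
  stopifnot(length(fits) >= 1, !is.null(prior))
  if (is.null(m)) m <- length(fits[[1]]$theta)
  if (is.null(n_units)) n_units <- length(fits)

  terms <- dplyr::bind_rows(lapply(fits, function(f) {
    det_h <- det(f$hessian)
    if (det_h <= 0 && !isTRUE(f$at_boundary)) {
      stop("non-positive-definite Hessian for interior unit ",
           f$subject_id, "/", f$session)
    }
    tibble::tibble(
      subject_id = f$subject_id,
      session = f$session,
      log_lik = f$log_lik,
      log_prior = log_prior_density(f$theta, prior),
      log_det_h = log(det_h)
    )
  }))

  nlme <- -sum(terms$log_lik) - sum(terms$log_prior) -
    0.5 * m * n_units * log(2 * pi) + 0.5 * sum(terms$log_det_h) +
    m * log(n_units)

  structure(list(nlme = nlme, m = m, n_units = n_units,
                 per_unit_terms = terms),
            class = "model_evidence")
}

#' Select between the full and the no-bias model variant
#'
#' The variant with the lower negative log-model evidence wins; an exact
#' tie goes to the reduced model on parsimony grounds (with a message).
#'
#' @param evidence_full,evidence_reduced `model_evidence` objects for the
#'   full and the `c = 0` model computed on the same data.
#' @return `"full"` or `"no_bias"`.
#' @export
select_model <- function(evidence_full, evidence_reduced) {
  nf <- if (inherits(evidence_full, "model_evidence")) evidence_full$nlme else evidence_full
  nr <- if (inherits(evidence_reduced, "model_evidence")) evidence_reduced$nlme else evidence_reduced
  if (nf == nr) {
    message("exact NLME tie; selecting the reduced model on parsimony")
    return("no_bias")
  }
  if (nf < nr) "full" else "no_bias"
}
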