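#' Assumed observation model for age inference from length
#'
#' Bundles the growth curve, measurement-error standard deviation, survival
#' and maximum age that the estimator *assumes* when converting measured
#' lengths into an age distribution. In a misspecification study the curve
#' and sigma may deliberately differ from the values used to simulate the
#' data; survival and maximum age are taken as known.
#'
#' @param vbgf A [vbgf_params()] object (possibly shifted).
#' @param sigma Assumed SD (cm) of length measurement error; must be > 0.
#' @param phi Annual survival probability (defines the stable age prior).
#' @param a_max Maximum age; posterior support is integer ages `0..a_max`.
#'
#' @return An object of class `ckmr_age_model`.
#' @examples
#' sp <- species_simple()
#' m <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)
#' colSums(age_posterior(c(80, 120), m)) # both columns sum to 1
#' @export
age_model <- function(vbgf, sigma, phi, a_max) {
  stopifnot(inherits(vbgf, "vbgf_params"), sigma > 0, phi > 0, phi < 1,
            a_max >= 0)
  structure(list(vbgf = vbgf, sigma = sigma, phi = phi,
                 a_max = as.integer(a_max),
                 mu = vbgf_length(0:a_max, vbgf),
                 prior = stable_age_pmf(phi, a_max)),
            class = "ckmr_age_model")
}

#' @export
print.ckmr_age_model <- function(x, ...) {
  cat(sprintf("Age-from-length model: sigma = %g cm, phi = %.4f, ages 0..%d\n",
              x$sigma, x$phi, x$a_max))
  print(x$vbgf)
  invisible(x)
}

#' Probability of a measured (integer) length given age
#'
#' Measured length is the true length-at-age plus Gaussian error, rounded to
#' the nearest centimetre, i.e. a discretised Normal:
#' \deqn{f(\ell^* \mid a) = \Phi\!\left(\frac{\ell^* - \mu_a + 0.5}{\sigma}\right)
#'   - \Phi\!\left(\frac{\ell^* - \mu_a - 0.5}{\sigma}\right)}
#' with \eqn{\mu_a} the VBGF expectation. The mass integrates the Normal
#' density over the centimetre bin, so it is non-negative and sums to one
#' over all integers.
#'
#' @param l_star Measured length(s), integer cm.
#' @param age Age(s) in years, each in `0..a_max`. `l_star` and `age` are
#'   recycled against each other.
#' @param model A [age_model()] object.
#' @return Numeric vector of probabilities.
#' @export
length_pmf <- function(l_star, age, model) {
  stopifnot(inherits(model, "ckmr_age_model"))
  if (any(age < 0 | age > model$a_max)) stop("`age` must lie in 0..a_max")
  mu <- model$mu[age + 1L]
  pmax(pnorm((l_star - mu + 0.5) / model$sigma) -
         pnorm((l_star - mu - 0.5) / model$sigma), 0)
}

#' Stable-age prior probability
#'
#' Truncated-geometric prior on age implied by constant survival and a
#' maximum age (see [stable_age_pmf()]); zero outside `0..a_max`.
#'
#' @param age Integer age(s).
#' @param model A [age_model()] object.
#' @return Numeric vector of prior probabilities.
#' @export
age_prior <- function(age, model) {
  stopifnot(inherits(model, "ckmr_age_model"))
  out <- numeric(length(age))
  ok <- age >= 0 & age <= model$a_max
  out[ok] <- model$prior[age[ok] + 1L]
  out
}

#' Posterior distribution of age given measured length
#'
#' Applies Bayes' rule: the posterior over integer ages `0..a_max` is
#' proportional to the discretised-Normal length likelihood times the
#' stable-age prior, normalized by the marginal probability of the measured
#' length. A length whose marginal probability underflows to zero is
#' incompatible with the assumed observation model; its posterior column is
#' set to `NA` and flagged, which downstream propagates to a fit failure
#' rather than an error.
#'
#' @param l_star Vector of measured lengths (integer cm).
#' @param model A [age_model()] object.
#' @return A `(a_max + 1) x length(l_star)` matrix; column `k` is the
#'   posterior pmf of age for `l_star[k]`. Attribute `marginal` holds
#'   `f(l*)` per column; attribute `incompatible` marks zero-marginal
#'   columns.
#' @export
age_posterior <- function(l_star, model) {
  stopifnot(inherits(model, "ckmr_age_model"))
  ages <- 0:model$a_max
  lik <- vapply(l_star, function(l) length_pmf(l, ages, model),
                numeric(length(ages)))
  lik <- matrix(lik, nrow = length(ages))
  joint <- lik * model$prior
  marg <- colSums(joint)
  bad <- marg <= 0
  post <- sweep(joint, 2L, ifelse(bad, NA_real_, marg), "/")
  dimnames(post) <- list(age = ages, l_star = l_star)
  attr(post, "marginal") <- marg
  attr(post, "incompatible") <- bad
  post
}
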