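#' Exponential-family terms and derivatives
#'
#' Evaluates the building blocks of the phenotype density
#' \deqn{p(y | \eta, \phi) = \exp\{ (y\eta - b(\eta))/a(\phi) + c(y, \phi) \}}
#' and every derivative the score and observed-information formulas need:
#' b, b', b'', a, a', a'' and the first two phi-derivatives of c. The three
#' families are: gaussian with \eqn{a(\phi)=\phi}, \eqn{b(\eta)=\eta^2/2},
#' \eqn{c(y,\phi)=-y^2/(2\phi)-\log(2\pi\phi)/2}; logistic with \eqn{a=1},
#' \eqn{b(\eta)=\log(1+e^\eta)}, \eqn{c=0}; Poisson with \eqn{a=1},
#' \eqn{b(\eta)=e^\eta}, \eqn{c(y,\phi)=-\log(y!)}. b' is the mean function
#' of the family and b'' its variance function, both convex-consistent
#' (b'' >= 0 everywhere).
#'
#' @param family a [GLMFamily-class].
#' @param eta linear predictor value(s).
#' @param y observed phenotype value(s); only used through c(y, phi) terms.
#' @param phi dispersion, required (and positive) for gaussian, forbidden
#'   otherwise.
#' @return a list with components \code{b}, \code{b1}, \code{b2}, \code{a},
#'   \code{a1}, \code{a2}, \code{dc_dphi}, \code{d2c_dphi2}, vectorized over
#'   \code{eta} / \code{y}.
#' @examples
#' familyTerms(glmFamily("logistic"), eta = 0)$b1   # 0.5
#' familyTerms(glmFamily("poisson"), eta = 0)$b2    # 1
#' @export
familyTerms <- function(family, eta, y = NULL, phi = NULL) {
  stopifnot(is(family, "GLMFamily"))
  if (family@hasDispersion) {
    if (is.null(phi)) stop("gaussian family requires a dispersion phi")
    if (phi <= 0) stop("phi must be positive")
  } else if (!is.null(phi)) {
    stop("phi supplied for a dispersion-free family (", family@name, ")")
  }
  switch(family@name,
    gaussian = {
      if (is.null(y)) y <- NA_real_
      list(b = eta^2 / 2, b1 = eta, b2 = rep(1, length(eta)),
           a = phi, a1 = 1, a2 = 0,
           dc_dphi = y^2 / (2 * phi^2) - 1 / (2 * phi),
           d2c_dphi2 = -y^2 / phi^3 + 1 / (2 * phi^2))
    },
    logistic = {
      # log(1 + e^eta) via its overflow-stable form
      b <- pmax(eta, 0) + log1p(exp(-abs(eta)))
      mu <- stats::plogis(eta)
      list(b = b, b1 = mu, b2 = mu * (1 - mu),
           a = 1, a1 = 0, a2 = 0, dc_dphi = 0, d2c_dphi2 = 0)
    },
    poisson = {
      mu <- exp(eta)
      list(b = mu, b1 = mu, b2 = mu,
           a = 1, a1 = 0, a2 = 0, dc_dphi = 0, d2c_dphi2 = 0)
    })
}

# Null log-likelihood (constants in y included so that likelihood-ratio
# comparator tests and the latent-genotype brute-force oracle agree).
nullLogLikelihood <- function(y, eta, family, phi = NULL) {
  switch(family@name,
    gaussian = sum(stats::dnorm(y, mean = eta, sd = sqrt(phi), log = TRUE)),
    logistic = sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE)),
    poisson  = sum(stats::dpois(y, exp(eta), log = TRUE)))
}

#' Fit the null model (phenotype on covariates only)
#'
#' Computes the constrained maximum-likelihood estimate under H0: beta = 0 by
#' iteratively reweighted least squares, i.e. the GLM of y on the covariate
#' matrix alone. The returned fit satisfies the first-order condition to high
#' precision (max-abs score in alpha below 1e-8), which the score tests rely
#' on: the alpha (and phi) components of the full score vanish at this point
#' and only the beta component survives. For the gaussian family the
#' dispersion is the MLE \eqn{\tilde\phi} = RSS / N.
#'
#' @param y numeric response vector of length N. Binary 0/1 for logistic;
#'   non-negative integers for Poisson.
#' @param x N x (dx+1) covariate matrix including an intercept column.
#' @param family a [GLMFamily-class].
#' @param maxIter,tol IRLS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return a [NullFit-class].
#' @examples
#' f <- fitNull(c(1, 2, 3), matrix(1, 3, 1), glmFamily("gaussian"))
#' nullCoef(f)        # 2
#' nullDispersion(f)  # 2/3  (MLE: divide by N)
#' @export
fitNull <- function(y, x, family, maxIter = 100L, tol = 1e-10) {
  stopifnot(is(family, "GLMFamily"))
  x <- as.matrix(x)
  N <- length(y)
  if (nrow(x) != N) stop("nrow(x) must equal length(y)")
  p <- ncol(x)
  if (N <= p) stop("need more observations than covariate columns")
  if (qr(x)$rank < p) stop("covariate matrix is rank deficient")
  if (family@name == "logistic" && !all(y %in% c(0, 1)))
    stop("logistic family requires a 0/1 response")
  if (family@name == "poisson" && (any(y < 0) || any(y != round(y))))
    stop("poisson family requires non-negative integer response")

  if (family@name == "gaussian") {
    fit <- stats::lm.fit(x, y)
    alpha <- fit$coefficients
    eta <- drop(x %*% alpha)
    phi <- sum((y - eta)^2) / N          # MLE denominator N, not N - p
    ll <- nullLogLikelihood(y, eta, family, phi)
    return(new("NullFit", alpha = unname(alpha), phi = phi, logLik = ll,
               family = family, eta = eta, mu = eta))
  }

  glmfam <- if (family@name == "logistic") stats::binomial() else
    stats::poisson()
  fit <- stats::glm.fit(x, y, family = glmfam,
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = maxIter))
  if (!fit$converged)
    stop("null-model IRLS did not converge in ", maxIter, " iterations")
  alpha <- unname(fit$coefficients)

  # Newton polish so the alpha-score condition holds to 1e-10, tighter than
  # the deviance-based IRLS stop.
  for (it in seq_len(10L)) {
    eta <- drop(x %*% alpha)
    tm <- familyTerms(family, eta)
    sc <- drop(crossprod(x, y - tm$b1))
    if (max(abs(sc)) < 1e-10) break
    H <- crossprod(x * tm$b2, x)
    alpha <- alpha + drop(solve(H, sc))
  }
  eta <- drop(x %*% alpha)
  tm <- familyTerms(family, eta)
  mu <- tm$b1
  if (max(abs(drop(crossprod(x, y - mu)))) > 1e-8)
    stop("null fit failed the score condition (non-convergence)")
  if (family@name == "logistic" && any(mu > 1 - 1e-10 | mu < 1e-10))
    warning("fitted probabilities pinned at 0/1: possible separation")
  ll <- nullLogLikelihood(y, eta, family)
  new("NullFit", alpha = alpha, phi = numeric(0), logLik = ll,
      family = family, eta = eta, mu = mu)
}
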