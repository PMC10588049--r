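#' Empirical-Bayes adaptive shrinkage of effect estimates
#'
#' Implements the adaptive-shrinkage model: observed estimates are
#' `beta_hat_j ~ N(b_j, s_j^2)` and the true effects follow a zero-mode
#' scale mixture, `b_j ~ sum_m w_m component(scale_m)`, with the component
#' family either zero-centered normals or zero-centered symmetric uniforms.
#' The mixture weights are estimated by (penalized) maximum marginal
#' likelihood via EM on a fixed grid of scales; posterior summaries per test
#' follow in closed form.
#'
#' @name shrinkage
NULL

#' Fit the mixture prior
#'
#' The scale grid is geometric with ratio sqrt(2) from `min(se)/10` to
#' `2 * max(|beta|)`; when all estimates are zero the prior collapses to a
#' single near-zero scale with weight 1. The weights maximize the penalized
#' marginal likelihood, the penalty being a Dirichlet prior on the weights
#' (default Dirichlet(1, ..., 1), i.e. no penalty).
#'
#' @param beta Effect estimates.
#' @param se Standard errors (> 0; entries with `se <= 0` are excluded from
#'   the fit and handled at shrinkage time).
#' @param family `"normal"` or `"uniform"` components.
#' @param weights_prior Optional vector of Dirichlet parameters, one per
#'   grid scale (values >= 1).
#' @param scales Optional fixed scale grid (strictly increasing); overrides
#'   the automatic grid, e.g. to reuse a previously fitted grid.
#' @param pointmass Prepend an exact point mass at zero (scale 0) to the
#'   grid. Off by default (the shrinkage applied to LFC estimates uses a
#'   continuous prior); a point mass makes the lfsr account for
#'   exactly-null effects and tightens false-discovery control against
#'   exact nulls.
#' @param tol Relative EM convergence tolerance (default 1e-7).
#' @param maxiter Maximum EM iterations (default 5000).
#' @return An object of class `shrink_prior`: list with `family`, `scales`,
#'   `weights`, `loglik` (penalty excluded), `niter`.
#' @export
fit_mixture_prior <- function(beta, se, family = c("normal", "uniform"),
                              weights_prior = NULL, scales = NULL,
                              pointmass = FALSE, tol = 1e-7,
                              maxiter = 5000) {
  family <- match.arg(family)
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  usable <- is.finite(beta) & is.finite(se) & se > 0
  if (!any(usable))
    stop("no estimates with positive standard errors to fit the prior")
  b <- beta[usable]
  s <- se[usable]
  if (is.null(scales)) {
    if (max(abs(b)) == 0) {
      scales <- min(s) / 10
    } else {
      lo <- min(s) / 10
      hi <- 2 * max(abs(b))
      if (hi <= lo) {
        scales <- lo
      } else {
        nsc <- ceiling(log(hi / lo) / log(sqrt(2)))
        scales <- lo * sqrt(2)^(0:nsc)
      }
    }
  }
  if (pointmass && scales[1] > 0)
    scales <- c(0, scales)
  M <- length(scales)
  if (is.null(weights_prior))
    weights_prior <- rep(1, M)
  stopifnot(length(weights_prior) == M, all(weights_prior >= 1))
  lik <- component_lik(b, s, scales, family)  # n x M
  w <- rep(1 / M, M)
  a0 <- weights_prior - 1
  ll_old <- -Inf
  niter <- 0
  for (it in seq_len(maxiter)) {
    niter <- it
    f <- drop(lik %*% w)
    f <- pmax(f, .Machine$double.xmin)
    R <- lik * rep(w, each = length(b)) / f   # responsibilities
    cw <- colSums(R) + a0
    w <- cw / sum(cw)
    ll <- sum(log(f)) + sum(a0 * log(pmax(w, .Machine$double.xmin)))
    if (is.finite(ll_old) && abs(ll - ll_old) <=
          tol * (abs(ll_old) + .Machine$double.eps)) break
    ll_old <- ll
  }
  f <- pmax(drop(lik %*% w), .Machine$double.xmin)
  structure(list(family = family, scales = scales, weights = w,
                 loglik = sum(log(f)), niter = niter),
            class = "shrink_prior")
}

#' @export
print.shrink_prior <- function(x, ...) {
  cat(sprintf("shrink_prior: %s mixture, %d components, loglik %.4g\n",
              x$family, length(x$scales), x$loglik))
  invisible(x)
}

# Marginal likelihood of beta_hat under each mixture component:
# normal:  N(beta; 0, se^2 + scale^2)
# uniform: integral of N(beta; b, se^2) over b ~ U(-a, a); the a -> 0 limit
#          is N(beta; 0, se^2), used for near-degenerate scales.
component_lik <- function(beta, se, scales, family) {
  n <- length(beta)
  M <- length(scales)
  out <- matrix(0, n, M)
  for (mm in seq_len(M)) {
    a <- scales[mm]
    if (family == "normal") {
      out[, mm] <- stats::dnorm(beta, 0, sqrt(se^2 + a^2))
    } else {
      if (a < 1e-12 * max(se)) {
        out[, mm] <- stats::dnorm(beta, 0, se)
      } else {
        out[, mm] <- (stats::pnorm((a - beta) / se) -
                      stats::pnorm((-a - beta) / se)) / (2 * a)
      }
    }
  }
  out
}

#' Posterior summaries under a fitted mixture prior
#'
#' For each test, forms the mixture posterior over the true effect `b` and
#' returns its mean and sd, the local false sign rate
#' `lfsr = min{P(b >= 0 | data), P(b <= 0 | data)}`, and the posterior
#' z-score `postmean / postsd`. Tests with `se = 0` are passed through
#' unshrunk: `postmean = beta`, `postsd = 0`, and `lfsr = 0` when
#' `beta != 0` (the sign is certain) or 1 when `beta = 0` (the effect is
#' exactly null, so calling any sign is an error).
#'
#' @param beta Effect estimates.
#' @param se Standard errors (>= 0).
#' @param prior A fitted `shrink_prior`.
#' @return A data frame with columns `postmean`, `postsd`, `lfsr`,
#'   `svalue`, `zscore`.
#' @export
shrink_estimates <- function(beta, se, prior) {
  stopifnot(inherits(prior, "shrink_prior"), length(beta) == length(se))
  n <- length(beta)
  postmean <- postsd <- lfsr <- numeric(n)
  zero_se <- !(se > 0)
  if (any(zero_se)) {
    postmean[zero_se] <- beta[zero_se]
    postsd[zero_se] <- 0
    lfsr[zero_se] <- ifelse(beta[zero_se] == 0, 1, 0)
  }
  idx <- which(!zero_se)
  if (length(idx) > 0) {
    b <- beta[idx]
    s <- se[idx]
    scales <- prior$scales
    M <- length(scales)
    lik <- component_lik(b, s, scales, prior$family)
    R <- lik * rep(prior$weights, each = length(b))
    R <- R / pmax(rowSums(R), .Machine$double.xmin)
    m1 <- m2 <- pneg <- ppos <- matrix(0, length(b), M)
    for (mm in seq_len(M)) {
      a <- scales[mm]
      if (a == 0) {
        # point mass at zero: b = 0 with certainty, so b <= 0 and b >= 0
        # both hold and the component feeds both sign-tail probabilities
        pneg[, mm] <- 1
        ppos[, mm] <- 1
      } else if (prior$family == "normal") {
        shr <- a^2 / (a^2 + s^2)
        mu <- b * shr
        tau2 <- s^2 * shr
        m1[, mm] <- mu
        m2[, mm] <- tau2 + mu^2
        pneg[, mm] <- stats::pnorm(0, mu, sqrt(tau2))
        ppos[, mm] <- 1 - pneg[, mm]
      } else {
        tn <- truncnorm_moments(b, s, -a, a)
        m1[, mm] <- tn$mean
        m2[, mm] <- tn$m2
        pneg[, mm] <- tn$cdf0
        ppos[, mm] <- 1 - tn$cdf0
      }
    }
    pm <- rowSums(R * m1)
    pv <- rowSums(R * m2) - pm^2
    postmean[idx] <- pm
    postsd[idx] <- sqrt(pmax(pv, 0))
    pr_neg <- rowSums(R * pneg)   # P(b <= 0 | data)
    pr_pos <- rowSums(R * ppos)   # P(b >= 0 | data)
    lfsr[idx] <- pmin(1, pmin(pr_neg, pr_pos))
  }
  zscore <- ifelse(postsd > 0, postmean / postsd,
                   ifelse(postmean == 0, 0, sign(postmean) * Inf))
  data.frame(postmean = postmean, postsd = postsd, lfsr = lfsr,
             svalue = compute_svalues(lfsr), zscore = zscore)
}

# First and second moments and CDF at 0 of N(mu, s^2) truncated to [lo, hi].
truncnorm_moments <- function(mu, s, lo, hi) {
  alpha <- (lo - mu) / s
  beta_ <- (hi - mu) / s
  Z <- pmax(stats::pnorm(beta_) - stats::pnorm(alpha),
            .Machine$double.xmin)
  da <- stats::dnorm(alpha)
  db <- stats::dnorm(beta_)
  mean_ <- mu + s * (da - db) / Z
  var_ <- s^2 * (1 + (alpha * da - beta_ * db) / Z - ((da - db) / Z)^2)
  cdf0 <- pmin(1, pmax(0, (stats::pnorm((0 - mu) / s) -
                             stats::pnorm(alpha)) / Z))
  list(mean = mean_, m2 = pmax(var_, 0) + mean_^2, cdf0 = cdf0)
}

#' s-values from local false sign rates
#'
#' The s-value of a test is the average lfsr over all tests at least as
#' significant (lfsr less than or equal to its own); ties share a value.
#' An FDR-like cumulative error measure: calling all tests with s-value
#' below t yields an expected sign-error rate of about t.
#'
#' @param lfsr Vector of local false sign rates in `[0, 1]`.
#' @return Vector of s-values, same length and order as `lfsr`.
#' @export
compute_svalues <- function(lfsr) {
  stopifnot(all(is.na(lfsr) | (lfsr >= 0 & lfsr <= 1)))
  out <- rep(NA_real_, length(lfsr))
  ok <- !is.na(lfsr)
  v <- lfsr[ok]
  o <- order(v)
  cm <- cumsum(v[o]) / seq_along(v)
  # ties share the value at the last index of the tie group, so every test
  # averages over all tests with lfsr <= its own
  r <- rank(v, ties.method = "max")
  out[ok] <- cm[r]
  out
}

#' Log likelihood-ratio (log Bayes factor) for a set of tests
#'
#' Compares the marginal likelihood of the estimates under the fitted
#' mixture prior against the all-null model in which every true effect is
#' exactly zero (`beta_hat_j ~ N(0, s_j^2)`). Positive values support the
#' presence of nonzero effects.
#'
#' @param beta Effect estimates.
#' @param se Standard errors (> 0).
#' @param prior A fitted `shrink_prior`.
#' @return Scalar log likelihood-ratio (natural log).
#' @export
log_lr <- function(beta, se, prior) {
  stopifnot(inherits(prior, "shrink_prior"))
  ok <- se > 0
  b <- beta[ok]
  s <- se[ok]
  if (length(b) == 0) return(0)
  lik <- component_lik(b, s, prior$scales, prior$family)
  f <- pmax(drop(lik %*% prior$weights), .Machine$double.xmin)
  f0 <- pmax(stats::dnorm(b, 0, s), .Machine$double.xmin)
  sum(log(f)) - sum(log(f0))
}
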