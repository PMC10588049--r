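#' Grade-of-membership differential expression
#'
#' The GoM DE model for one feature j is a Poisson model that allows cells
#' partial membership in K topics:
#' `x_ij ~ Poisson(s_i * theta_ij)`, `theta_ij = sum_k l_ik p_jk`,
#' where the membership proportions `l_ik` are treated as known and the
#' unknown topic rates `p_j1, ..., p_jK` are estimated per feature. The
#' standard two-group Poisson model is the special case K = 2 with hard
#' (0/1) memberships.
#'
#' @name gom_de
NULL

#' MCMC and estimation options for the GoM DE analysis
#'
#' @param ns Chain length (number of MCMC states), default 10,000.
#' @param sigma Standard deviation of the Gaussian random-walk proposal on
#'   the log rates, default 0.3.
#' @param eps Pseudocount implementing a Gamma(1 + eps, 1) prior on each
#'   topic rate, default 0.1 (0.01 is used in the simulation study settings).
#' @param seed Integer seed; per-feature RNG streams are derived from
#'   (seed, feature index) so results do not depend on processing order.
#' @param hpd_level Mass of the highest-posterior-density interval used for
#'   the asymmetric standard error, default 0.68 (approximately +-1 sd for a
#'   normal posterior).
#' @return A list of class `mcmc_options`.
#' @export
mcmc_options <- function(ns = 10000, sigma = 0.3, eps = 0.1, seed = 1,
                         hpd_level = 0.68) {
  stopifnot(ns >= 1, sigma > 0, eps >= 0, hpd_level > 0, hpd_level < 1)
  structure(list(ns = as.integer(ns), sigma = sigma, eps = eps,
                 seed = as.integer(seed), hpd_level = hpd_level),
            class = "mcmc_options")
}

#' Null-model rate for one feature
#'
#' Under the null model the rate is shared by all cells,
#' `x_ij ~ Poisson(s_i p_j0)`; the MLE is the ratio of total count to total
#' size factor.
#'
#' @param x_j Count vector over cells for one feature.
#' @param s Size factors (same length).
#' @return The scalar MLE `sum(x_j) / sum(s)`.
#' @export
fit_null_rate <- function(x_j, s) {
  stopifnot(length(x_j) == length(s), sum(s) > 0)
  sum(x_j) / sum(s)
}

# Data augmentation implementing the Gamma(1 + eps, 1) prior: K extra
# "cells" with count eps, membership block I_K, and unit size factors.
# eps = 0 means no prior at all (plain maximum likelihood / flat prior),
# so no rows are added.
augment_gene_data <- function(x_j, L, s, eps) {
  if (eps == 0)
    return(list(x = x_j, L = L, s = s))
  K <- ncol(L)
  list(x = c(x_j, rep(eps, K)),
       L = rbind(L, diag(K)),
       s = c(s, rep(1, K)))
}

#' MAP topic rates for one feature
#'
#' Computes the maximum a posteriori estimate of the topic rates
#' `p_j1, ..., p_jK` under the GoM DE model with a Gamma(1 + eps, 1) prior
#' on each rate, implemented as maximum likelihood on the augmented problem
#' (counts extended by K pseudocount rows of value `eps`, membership block
#' `I_K`, unit size factors). Fitting uses multiplicative (EM) coordinate
#' updates, which are monotone in the augmented likelihood.
#'
#' @param x_j Count vector over cells for one feature.
#' @param L n x K membership matrix; rows must lie on the simplex.
#' @param s Size factors.
#' @param eps Pseudocount (>= 0).
#' @param numiter Number of update sweeps (default 40).
#' @return An object of class `gene_rates`: list with topic rates `p`
#'   (length K), null rate `p0`, and log rates `g` (NA where `p` is 0).
#' @export
fit_gene_rates_map <- function(x_j, L, s, eps = 0.1, numiter = 40) {
  stopifnot(length(x_j) == length(s), nrow(L) == length(s), eps >= 0)
  check_simplex_rows(L)
  a <- augment_gene_data(x_j, L, s, eps)
  K <- ncol(L)
  p0 <- fit_null_rate(x_j, s)
  p <- rep(max(p0, 1e-8), K)
  denom <- colSums(a$s * a$L)
  for (it in seq_len(numiter)) {
    theta <- drop(a$L %*% p)
    r <- ifelse(a$x > 0, a$x / pmax(theta, .Machine$double.xmin), 0)
    p <- p * drop(crossprod(a$L, r)) / pmax(denom, 1e-15)
    if (any(!is.finite(p)))
      stop("numerical error in MAP fit at topic ",
           which(!is.finite(p))[1])
  }
  gene_rates(p, p0)
}

#' Construct a gene_rates object
#'
#' @param p Vector of K non-negative topic rates.
#' @param p0 Null-model rate.
#' @return An object of class `gene_rates`.
#' @export
gene_rates <- function(p, p0 = NA_real_) {
  stopifnot(all(p >= 0))
  g <- ifelse(p > 0, log(p), NA_real_)
  structure(list(p = as.numeric(p), p0 = p0, g = g), class = "gene_rates")
}

#' Pairwise log-fold change between two topics
#'
#' `LFC_{k,l} = log2(p_k / p_l)`. Zero rates are handled explicitly: one
#' zero rate yields a signed infinity and both zero yields 0; either case
#' carries a `degenerate` attribute flag.
#'
#' @param p A `gene_rates` object (or bare non-negative vector).
#' @param k,l Topic indices.
#' @return Scalar LFC in log2 units.
#' @export
pairwise_lfc <- function(p, k, l) {
  pv <- if (inherits(p, "gene_rates")) p$p else p
  stopifnot(k >= 1, l >= 1, k <= length(pv), l <= length(pv))
  if (pv[k] == 0 && pv[l] == 0)
    return(structure(0, degenerate = TRUE))
  if (pv[k] == 0)
    return(structure(-Inf, degenerate = TRUE))
  if (pv[l] == 0)
    return(structure(Inf, degenerate = TRUE))
  log2(pv[k] / pv[l])
}

#' Least extreme log-fold change for one topic
#'
#' The l.e. LFC for topic k is the pairwise LFC against whichever other
#' topic minimizes its absolute value; a feature is "distinctive" for a
#' topic only if its rate differs from that in every other topic. Ties in
#' the argmin are broken by the smallest competitor index. Reduces to the
#' standard two-group LFC when K = 2. Invariant to scaling all rates by a
#' positive constant.
#'
#' @param p A `gene_rates` object (or bare non-negative vector).
#' @param k Topic index.
#' @return Scalar l.e. LFC in log2 units.
#' @export
le_lfc <- function(p, k) {
  pv <- if (inherits(p, "gene_rates")) p$p else p
  K <- length(pv)
  if (K < 2)
    stop("undefined statistic: the least extreme LFC requires K >= 2")
  others <- setdiff(seq_len(K), k)
  lfcs <- vapply(others, function(l) as.numeric(pairwise_lfc(pv, k, l)),
                 numeric(1))
  best <- others[which.min(abs(lfcs))] # which.min takes the first = lowest l
  as.numeric(pairwise_lfc(pv, k, best))
}

#' Log-fold change against the null model
#'
#' `LFC_k^null = log2(p_k / p0)`, comparing topic k's rate with the single
#' shared rate of the null model.
#'
#' @param p A `gene_rates` object with `p0` set.
#' @param k Topic index.
#' @return Scalar LFC in log2 units.
#' @export
null_lfc <- function(p, k) {
  stopifnot(inherits(p, "gene_rates"))
  if (is.na(p$p0) || p$p0 == 0)
    stop("undefined: null rate p0 is zero or missing")
  log2(p$p[k] / p$p0)
}

#' Random-walk Metropolis sampling of log topic rates
#'
#' Simulates the posterior of `g = log(p)` for one feature under the GoM DE
#' model with a flat improper prior on `p` (any Gamma pseudocount prior is
#' expressed through the augmented inputs). Per step, one topic is chosen
#' uniformly at random and its log rate perturbed by a N(0, sigma^2)
#' increment; the proposal is accepted with probability
#' `min{1, likelihood ratio x p*_k/p_k}` (the second factor is the Jacobian
#' of the log transform). Rejections copy the previous state. No burn-in is
#' discarded; initialize at the MAP estimate. Deterministic given
#' `opts$seed`.
#'
#' @param x_j Count vector (already augmented with pseudocounts if a prior
#'   is wanted). Fractional values are allowed.
#' @param L Membership matrix matching `x_j` (augmented accordingly).
#' @param s Size factors matching `x_j`.
#' @param init A `gene_rates` object giving the initial state; rates are
#'   floored at 1e-15 before taking logs.
#' @param opts An [mcmc_options()] object.
#' @return An `ns` x K matrix of sampled `g` vectors.
#' @export
mcmc_sample_rates <- function(x_j, L, s, init, opts) {
  stopifnot(inherits(opts, "mcmc_options"),
            length(x_j) == nrow(L), length(s) == nrow(L))
  p <- pmax(if (inherits(init, "gene_rates")) init$p else init, 1e-15)
  K <- ncol(L)
  stopifnot(length(p) == K)
  nz <- which(x_j > 0)
  theta_nz <- drop(L[nz, , drop = FALSE] %*% p)
  if (any(theta_nz <= 0))
    stop("invalid initialization: zero rate at cells with positive counts")
  sum_sl <- colSums(s * L)
  old_seed <- local_seed(opts$seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  G <- .mcmc_rates_cpp(as.integer(nz - 1), as.numeric(x_j[nz]),
                       as.matrix(L), sum_sl, log(p), opts$ns, opts$sigma)
  colnames(G) <- colnames(L)
  G
}

# Per-sample LFC statistics from an ns x K matrix of sampled log rates.
# Returns an ns x K matrix of the statistic for each topic. For "le_lfc"
# the competitor topic may differ between samples (argmin of |LFC|, ties to
# the lowest index). "null_lfc" compares against a fixed log2 null rate;
# "pairwise" compares every topic against a fixed reference topic (the
# reference column is 0 by convention).
lfc_sample_stats <- function(G, stat = c("le_lfc", "null_lfc", "pairwise"),
                             p0 = NULL, ref_topic = NULL) {
  stat <- match.arg(stat)
  K <- ncol(G)
  ns <- nrow(G)
  B <- G / log(2)
  if (stat == "null_lfc") {
    stopifnot(!is.null(p0), p0 > 0)
    return(B - log2(p0))
  }
  if (stat == "pairwise") {
    stopifnot(!is.null(ref_topic), ref_topic >= 1, ref_topic <= K)
    return(B - B[, ref_topic])
  }
  if (K < 2)
    stop("undefined statistic: the least extreme LFC requires K >= 2")
  out <- matrix(0, ns, K, dimnames = dimnames(G))
  for (k in seq_len(K)) {
    others <- setdiff(seq_len(K), k)
    diffs <- B[, k] - B[, others, drop = FALSE]
    pick <- max.col(-abs(diffs), ties.method = "first")
    out[, k] <- diffs[cbind(seq_len(ns), pick)]
  }
  out
}

#' Posterior summaries of per-sample LFC statistics
#'
#' Evaluates the chosen LFC statistic on every MCMC sample, then summarizes
#' per topic: the posterior mean, the shortest (highest-posterior-density)
#' interval containing `ceiling(hpd_level * ns)` samples, and an asymmetric
#' standard error `se = hpd_hi - mean` when the mean is negative and
#' `mean - hpd_lo` otherwise, which guards against overshrinking estimates
#' whose posterior is wide but bounded away from zero.
#'
#' @param samples An ns x K matrix of sampled log rates (`g`), as returned
#'   by [mcmc_sample_rates()].
#' @param stat One of `"le_lfc"`, `"null_lfc"`, `"pairwise"`.
#' @param hpd_level HPD interval mass in (0, 1).
#' @param p0 Null rate (required for `stat = "null_lfc"`).
#' @param ref_topic Reference topic (required for `stat = "pairwise"`).
#' @return A data frame with one row per topic: `postmean`, `hpd_lo`,
#'   `hpd_hi`, `se`.
#' @export
summarize_posterior <- function(samples, stat = c("le_lfc", "null_lfc",
                                                  "pairwise"),
                                hpd_level = 0.68, p0 = NULL,
                                ref_topic = NULL) {
  stat <- match.arg(stat)
  if (nrow(samples) < 100)
    stop("need at least ns = 100 samples to summarize a posterior")
  S <- lfc_sample_stats(samples, stat, p0 = p0, ref_topic = ref_topic)
  summarize_stat_samples(S, hpd_level)
}

summarize_stat_samples <- function(S, hpd_level) {
  K <- ncol(S)
  out <- data.frame(topic = seq_len(K), postmean = colMeans(S),
                    hpd_lo = NA_real_, hpd_hi = NA_real_, se = NA_real_)
  for (k in seq_len(K)) {
    h <- hpd_interval(S[, k], hpd_level)
    out$hpd_lo[k] <- h[1]
    out$hpd_hi[k] <- h[2]
    out$se[k] <- if (out$postmean[k] < 0) h[2] - out$postmean[k]
                 else out$postmean[k] - h[1]
  }
  out$se <- pmax(out$se, 0)
  out
}

# Shortest window over the sorted samples containing ceiling(level * ns)
# of them.
hpd_interval <- function(v, level) {
  ns <- length(v)
  w <- min(ns, max(1, ceiling(level * ns)))
  sv <- sort(v)
  if (w == ns)
    return(c(sv[1], sv[ns]))
  widths <- sv[w:ns] - sv[1:(ns - w + 1)]
  i <- which.min(widths)
  c(sv[i], sv[i + w - 1])
}

check_simplex_rows <- function(L, tol = 1e-6) {
  if (any(L < -1e-12))
    stop("membership matrix has negative entries")
  rs <- rowSums(L)
  if (any(abs(rs - 1) > tol))
    stop("membership matrix rows must sum to 1 (max deviation ",
         signif(max(abs(rs - 1)), 3), ")")
  invisible(TRUE)
}

#' Differential expression analysis allowing for grades of membership
#'
#' Orchestrates the full per-feature analysis: MAP rate estimation,
#' random-walk MCMC over the log rates, per-sample evaluation of the chosen
#' LFC statistic, posterior mean / HPD / asymmetric-SE summaries, optional
#' empirical-Bayes adaptive shrinkage, and derived test statistics
#' (posterior z-scores, local false sign rates, s-values; two-sided normal
#' p-values when shrinkage is off). Features are processed independently
#' with per-feature RNG streams derived from `(opts$seed, feature index)`,
#' so results do not depend on processing order. Per-feature failures are
#' recorded and flagged rather than aborting the run.
#'
#' @param x A [counts_matrix()].
#' @param L n x K membership matrix (rows on the simplex), e.g. the `L`
#'   matrix of a [poisson2multinom()] fit.
#' @param opts An [mcmc_options()] object.
#' @param lfc_mode `"le"` (least extreme, default), `"null"` (compare
#'   against the null-model rate), or `"reference"` (compare against
#'   `ref_topic`; that topic's own rows are 0 by convention).
#' @param shrink Apply adaptive shrinkage to the posterior mean LFCs
#'   (default `TRUE`).
#' @param ref_topic Reference topic for `lfc_mode = "reference"`.
#' @param map_numiter Update sweeps for the vectorized MAP fit.
#' @param shrink_family Mixture family passed to [fit_mixture_prior()].
#' @param verbose Print progress.
#'
#' @return A `de_table` (data frame) with one row per (feature, topic):
#'   `feature_id`, `topic`, `map` (MAP-estimate LFC), `postmean_mcmc`
#'   (pre-shrinkage posterior mean), `postmean` (post-shrinkage when
#'   `shrink`, otherwise equal to `postmean_mcmc`), `hpd_lo`, `hpd_hi`, `se`,
#'   `z`, `lfsr`, `svalue`, `pval` (only meaningful when `shrink = FALSE`),
#'   and `p0` (the feature's null rate). Attributes: `lfc_mode`, `opts`,
#'   `failed_features`, `shrink_prior` (when shrinkage was applied).
#' @export
de_analysis <- function(x, L, opts = mcmc_options(),
                        lfc_mode = c("le", "null", "reference"),
                        shrink = TRUE, ref_topic = NULL, map_numiter = 40,
                        shrink_family = "normal", verbose = FALSE) {
  lfc_mode <- match.arg(lfc_mode)
  stopifnot(inherits(x, "counts_matrix"), inherits(opts, "mcmc_options"))
  L <- as.matrix(L)
  v <- x$values
  n <- nrow(v)
  m <- ncol(v)
  K <- ncol(L)
  if (nrow(L) != n)
    stop("dimension error: L has ", nrow(L), " rows for ", n, " cells")
  check_simplex_rows(L)
  if (lfc_mode == "reference") {
    if (is.null(ref_topic))
      stop("lfc_mode = 'reference' requires ref_topic")
    stopifnot(ref_topic >= 1, ref_topic <= K)
  }
  if (lfc_mode == "le" && K < 2)
    stop("undefined statistic: the least extreme LFC requires K >= 2")
  s <- compute_size_factors(x)
  p0 <- Matrix::colSums(v) / sum(s)

  # Vectorized MAP fit: MLE on the augmented Poisson NMF problem with H
  # fixed (H = [diag(s) L; I_K], X extended by K rows of eps).
  P <- fit_rates_map_all(v, L, s, opts$eps, map_numiter)

  stat <- switch(lfc_mode, le = "le_lfc", null = "null_lfc",
                 reference = "pairwise")
  map_lfc <- matrix(NA_real_, m, K)
  for (j in seq_len(m)) {
    gr <- gene_rates(P[j, ], p0[j])
    map_lfc[j, ] <- switch(lfc_mode,
      le = vapply(seq_len(K), function(k) le_lfc(gr, k), numeric(1)),
      null = vapply(seq_len(K), function(k) null_lfc(gr, k), numeric(1)),
      reference = log2(pmax(gr$p, 1e-15)) -
        log2(max(gr$p[ref_topic], 1e-15)))
  }

  # Augmented data shared across features (eps = 0: no augmentation)
  if (opts$eps > 0) {
    La <- rbind(L, diag(K))
    sa <- c(s, rep(1, K))
  } else {
    La <- L
    sa <- s
  }
  sum_sl <- colSums(sa * La)
  nz_all <- Matrix::summary(v)
  by_col <- split(seq_along(nz_all$i),
                  factor(nz_all$j, levels = seq_len(m)))

  postmean <- hpd_lo <- hpd_hi <- se <- matrix(NA_real_, m, K)
  failed <- character(0)
  base_seed <- abs(opts$seed) %% 1000000000
  for (j in seq_len(m)) {
    res <- tryCatch({
      ent <- by_col[[j]]
      nzj <- nz_all$i[ent]
      xj <- nz_all$x[ent]
      if (opts$eps > 0) {                     # pseudocount rows
        idx <- c(nzj, n + seq_len(K))
        xv <- c(xj, rep(opts$eps, K))
      } else {
        idx <- nzj
        xv <- xj
      }
      keep <- xv > 0
      pj <- pmax(P[j, ], 1e-15)
      seed_j <- (base_seed + 7919 * j) %% 2147483647
      old_seed <- local_seed(seed_j)
      G <- .mcmc_rates_cpp(as.integer(idx[keep] - 1), as.numeric(xv[keep]),
                           La, sum_sl, log(pj), opts$ns, opts$sigma)
      restore_seed(old_seed)
      S <- lfc_sample_stats(G, stat, p0 = if (p0[j] > 0) p0[j] else NULL,
                            ref_topic = ref_topic)
      summarize_stat_samples(S, opts$hpd_level)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, feature_ids(x)[j])
      next
    }
    postmean[j, ] <- res$postmean
    hpd_lo[j, ] <- res$hpd_lo
    hpd_hi[j, ] <- res$hpd_hi
    se[j, ] <- res$se
    if (verbose && j %% 200 == 0)
      message("de_analysis: feature ", j, " of ", m)
  }

  out <- data.frame(
    feature_id = rep(feature_ids(x), times = K),
    topic = rep(seq_len(K), each = m),
    map = as.vector(map_lfc),
    postmean_mcmc = as.vector(postmean),
    postmean = as.vector(postmean),
    hpd_lo = as.vector(hpd_lo),
    hpd_hi = as.vector(hpd_hi),
    se = as.vector(se),
    z = NA_real_, lfsr = NA_real_, svalue = NA_real_, pval = NA_real_,
    p0 = rep(as.numeric(p0), times = K),
    stringsAsFactors = FALSE)

  ok <- !is.na(out$postmean_mcmc)
  prior <- NULL
  if (shrink) {
    beta <- out$postmean_mcmc[ok]
    sehat <- out$se[ok]  # exact zeros are passed through unshrunk by
                         # shrink_estimates and excluded from the prior fit
    prior <- fit_mixture_prior(beta, sehat, family = shrink_family)
    sr <- shrink_estimates(beta, sehat, prior)
    out$postmean[ok] <- sr$postmean
    out$z[ok] <- sr$zscore
    out$lfsr[ok] <- sr$lfsr
    out$svalue[ok] <- compute_svalues(sr$lfsr)
  } else {
    pos_se <- ok & out$se > 0
    out$z[pos_se] <- out$postmean_mcmc[pos_se] / out$se[pos_se]
    out$z[ok & out$se == 0] <- 0
    out$pval[ok] <- 2 * stats::pnorm(-abs(ifelse(is.na(out$z[ok]), 0,
                                                 out$z[ok])))
  }

  structure(out, class = c("de_table", "data.frame"), lfc_mode = lfc_mode,
            opts = opts, failed_features = unique(failed),
            shrink_prior = prior)
}

# MAP rates for all features at once: 'numiter' multiplicative EM updates
# of the feature factor W with the cell factor H = [diag(s) L; I_K] held
# fixed, on the eps-augmented count matrix. Equivalent to running
# fit_gene_rates_map feature by feature, but vectorized.
fit_rates_map_all <- function(v, L, s, eps, numiter = 40) {
  n <- nrow(v)
  m <- ncol(v)
  K <- ncol(L)
  e <- Matrix::summary(v)
  if (eps > 0) {
    H <- rbind(s * L, diag(K))
    ei <- c(e$i, rep(n + seq_len(K), each = m))
    ej <- c(e$j, rep(seq_len(m), times = K))
    ex <- c(e$x, rep(eps, K * m))
  } else {
    H <- s * L
    ei <- e$i
    ej <- e$j
    ex <- e$x
  }
  keep <- ex > 0
  e_aug <- data.frame(i = ei[keep], j = ej[keep], x = ex[keep])
  p0 <- as.numeric(Matrix::colSums(v)) / sum(s)
  W <- matrix(pmax(p0, 1e-8), m, K)
  denom <- colSums(H)
  for (it in seq_len(numiter)) {
    lam <- lambda_at(H, W, e_aug$i, e_aug$j)
    ratio <- e_aug$x / pmax(lam, .Machine$double.xmin)
    num <- crossprod_entries(e_aug$j, e_aug$i, ratio, H, m)
    W <- W * sweep(num, 2, pmax(denom, 1e-15), "/")
    W[W < 1e-15] <- 1e-15
  }
  W
}
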