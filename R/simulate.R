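#' Synthetic single-cell UMI count data with known topic structure
#'
#' The generator emulates UMI counts from droplet scRNA-seq experiments:
#' log-normal library sizes, sparse Dirichlet grades of membership over K
#' topics, log-normal per-feature expression rates with (for about half the
#' features) a planted rate difference in exactly one topic, and Poisson
#' sampling of the counts from the rank-K rate matrix. Draw order is fixed
#' (sizes, then memberships, then rates, then counts) with sub-seeds derived
#' from the scenario seed, so presets are reproducible.
#'
#' @name simulate
NULL

#' Simulate per-cell size factors
#'
#' Total counts are log-normal on the base-10 scale:
#' `s_i = 10^u_i`, `u_i ~ N(0, sd = 1/5)`, giving a median of 1 and the
#' wide spread of library sizes typical of scRNA-seq.
#'
#' @param n Number of cells.
#' @param seed Integer seed.
#' @return Numeric vector of n positive size factors.
#' @export
simulate_size_factors <- function(n, seed = 1) {
  stopifnot(n >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  10^stats::rnorm(n, 0, 1 / 5)
}

#' Simulate sparse grades of membership
#'
#' Per cell, the number of topics with nonzero membership K' in 1..K is
#' drawn with probability proportional to `2^-K'`; the K' topics are chosen
#' uniformly without replacement; the memberships on the chosen topics are 1
#' when K' = 1 and Dirichlet (with the corresponding shape parameters)
#' otherwise. Unchosen topics get exactly 0.
#'
#' @param n Number of cells.
#' @param K Number of topics.
#' @param alpha Length-K vector of Dirichlet shape parameters.
#' @param seed Integer seed.
#' @return An n x K membership matrix whose rows sum to 1.
#' @export
simulate_memberships <- function(n, K, alpha, seed = 1) {
  stopifnot(K >= 1, length(alpha) == K, all(alpha > 0))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  pk <- 2^-(1:K)
  pk <- pk / sum(pk)
  L <- matrix(0, n, K)
  for (i in seq_len(n)) {
    kp <- sample.int(K, 1, prob = pk)
    topics <- if (K == 1) 1L else sample.int(K, kp)
    if (kp == 1) {
      L[i, topics] <- 1
    } else {
      g <- stats::rgamma(kp, shape = alpha[topics], rate = 1)
      while (sum(g) == 0) # numerically possible for tiny shapes
        g <- stats::rgamma(kp, shape = alpha[topics], rate = 1)
      L[i, topics] <- g / sum(g)
    }
  }
  L
}

#' Simulate per-feature topic expression rates
#'
#' With probability 0.5 a feature's rate is shared by all topics,
#' `2^v_j` with `v_j ~ N(-4, sd = 2)`; otherwise one topic `k'` (uniform) is
#' planted with rate `2^(v_j + e_j)`, `e_j ~ N(0, 1)`, the others keeping
#' `2^v_j`. All planted differences are truth-flagged, however small
#' `|e_j|`: power measured against this truth reflects the burden of small
#' effects.
#'
#' @param m Number of features.
#' @param K Number of topics (>= 2 for differences to exist).
#' @param seed Integer seed.
#' @return A list with `F` (m x K positive rate matrix), `diff_topic`
#'   (integer vector, NA where no difference was planted), and the latent
#'   draws `v` and `e` (`e` is NA for no-difference features).
#' @export
simulate_gene_rates <- function(m, K, seed = 1) {
  stopifnot(m >= 1, K >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  v <- stats::rnorm(m, -4, 2)
  has_diff <- stats::runif(m) < 0.5
  kprime <- ifelse(has_diff, sample.int(K, m, replace = TRUE), NA_integer_)
  e <- ifelse(has_diff, stats::rnorm(m, 0, 1), NA_real_)
  F_ <- matrix(2^v, m, K)
  idx <- which(has_diff)
  F_[cbind(idx, kprime[idx])] <- 2^(v[idx] + e[idx])
  list(F = F_, diff_topic = kprime, v = v, e = e)
}

#' Simulate counts from the rank-K Poisson model
#'
#' `x_ij ~ Poisson(lambda_ij)` with `Lambda = H W'`, `h_ik = s_i l_ik` and
#' `w_jk = f_jk`: the Poisson NMF model whose multinomial reparameterization
#' is the topic model.
#'
#' @param truth A `sim_truth` list with elements `L`, `s`, `F` (see
#'   [simulate_dataset()]), or any list providing them.
#' @param seed Integer seed.
#' @return A [counts_matrix()] of simulated UMI counts.
#' @export
simulate_counts <- function(truth, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  H <- truth$s * truth$L
  lambda <- H %*% t(truth$F)
  n <- nrow(lambda)
  m <- ncol(lambda)
  xs <- stats::rpois(n * m, as.vector(lambda))
  x <- matrix(xs, n, m)
  counts_matrix(x, cell_ids = paste0("cell_", seq_len(n)),
                feature_ids = paste0("gene_", seq_len(m)))
}

#' Simulation scenario presets
#'
#' `"discrete2"`: K = 2, alpha = (0.01, 0.01), n = 200 — memberships are
#' essentially hard, so cells split into two groups.
#' `"mixed2"`: K = 2, alpha = (1, 1), n = 200 — a full range of mixed
#' memberships. `"mixed6"`: K = 6, alpha = (1, ..., 1), n = 1000.
#' All presets default to m = 10,000 features.
#'
#' @param preset Preset name, or `NULL` to pass `n`, `K`, `alpha` directly.
#' @param n,K,alpha,m Scenario parameters (overridable; `m` may be reduced
#'   for scaled-down runs).
#' @param seed Integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(preset = NULL, n = NULL, K = NULL, alpha = NULL,
                         m = 10000, seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("discrete2", "mixed2", "mixed6"))
    def <- switch(preset,
      discrete2 = list(n = 200, K = 2, alpha = c(0.01, 0.01)),
      mixed2    = list(n = 200, K = 2, alpha = c(1, 1)),
      mixed6    = list(n = 1000, K = 6, alpha = rep(1, 6)))
    if (is.null(n)) n <- def$n
    if (is.null(K)) K <- def$K
    if (is.null(alpha)) alpha <- def$alpha
  }
  stopifnot(n >= 1, m >= 1, K >= 1, length(alpha) == K, all(alpha > 0))
  structure(list(preset = preset, n = n, m = m, K = K, alpha = alpha,
                 seed = as.integer(seed)), class = "sim_scenario")
}

#' Simulate a complete data set with ground truth
#'
#' Composes [simulate_size_factors()], [simulate_memberships()],
#' [simulate_gene_rates()] and [simulate_counts()] under one scenario, with
#' sub-seeds `seed + 1 ... seed + 4` in that order.
#'
#' @param scenario A [sim_scenario()], or a preset name (then `...` is
#'   passed to [sim_scenario()]).
#' @param ... Scenario overrides when `scenario` is a preset name.
#' @return A list with `counts` (a [counts_matrix()]) and `truth` (class
#'   `sim_truth`: `L`, `s`, `F`, `diff_topic`, `v`, `e`, `scenario`).
#' @export
simulate_dataset <- function(scenario, ...) {
  if (is.character(scenario))
    scenario <- sim_scenario(preset = scenario, ...)
  stopifnot(inherits(scenario, "sim_scenario"))
  seed <- scenario$seed
  s <- simulate_size_factors(scenario$n, seed + 1)
  L <- simulate_memberships(scenario$n, scenario$K, scenario$alpha,
                            seed + 2)
  gr <- simulate_gene_rates(scenario$m, scenario$K, seed + 3)
  truth <- structure(list(L = L, s = s, F = gr$F,
                          diff_topic = gr$diff_topic, v = gr$v, e = gr$e,
                          scenario = scenario), class = "sim_truth")
  counts <- simulate_counts(truth, seed + 4)
  # guard against (rare) all-zero cells in tiny scaled-down runs: resample
  # their counts with a deterministic follow-on seed
  tries <- 0
  while (any(Matrix::rowSums(counts$values) == 0) && tries < 20) {
    tries <- tries + 1
    bad <- which(Matrix::rowSums(counts$values) == 0)
    old <- local_seed(seed + 100 + tries)
    sub <- truth
    sub$L <- truth$L[bad, , drop = FALSE]
    sub$s <- truth$s[bad]
    lam <- (sub$s * sub$L) %*% t(sub$F)
    counts$values[bad, ] <- matrix(stats::rpois(length(lam),
                                                as.vector(lam)),
                                   nrow = length(bad))
    restore_seed(old)
  }
  list(counts = counts, truth = truth)
}

#' True LFC effects implied by simulation truth
#'
#' For each (feature, topic) pair, the true least-extreme LFC computed from
#' the planted rate matrix; exactly zero for features without a planted
#' difference and, when K > 2, for topics other than the planted one.
#'
#' @param truth A `sim_truth`.
#' @return An m x K matrix of true l.e. LFCs (log2 units).
#' @export
true_le_lfc <- function(truth) {
  F_ <- truth$F
  m <- nrow(F_)
  K <- ncol(F_)
  out <- matrix(0, m, K)
  lf <- log2(F_)
  for (k in seq_len(K)) {
    others <- setdiff(seq_len(K), k)
    d <- lf[, k] - lf[, others, drop = FALSE]
    pick <- max.col(-abs(d), ties.method = "first")
    out[, k] <- d[cbind(seq_len(m), pick)]
  }
  out
}
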