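test_that("poisson_nmf_loglik matches closed forms and the dense oracle", {
  x1 <- counts_matrix(matrix(2, 1, 1))
  f1 <- topicDE:::new_poisson_nmf_fit(W = matrix(3, 1, 1),
                                      H = matrix(1, 1, 1))
  expect_equal(poisson_nmf_loglik(x1, f1), 2 * log(3) - 3)
  # Poisson MLE at the mean: lambda = x is maximal over scalings c * lambda
  x2 <- counts_matrix(rbind(c(2, 1), c(4, 3)))
  ll_scaled <- function(cc) poisson_nmf_loglik(
    x2, topicDE:::new_poisson_nmf_fit(
      W = cc * t(as.matrix(x2$values)), H = diag(2)))
  expect_true(all(ll_scaled(1) >= sapply(c(0.5, 0.9, 1.1, 2), ll_scaled)))
  # random 5 x 4, K = 2: dense elementwise oracle
  x <- random_counts(5, 4, lambda = 3, seed = 11)
  fit <- random_nmf_fit(5, 4, 2, seed = 12)
  expect_equal(poisson_nmf_loglik(x, fit),
               dense_poisson_loglik(x, fit$H, fit$W))
  # lambda = 0 where x > 0 gives -Inf, not an error
  f0 <- topicDE:::new_poisson_nmf_fit(W = matrix(0, 1, 1),
                                      H = matrix(1, 1, 1))
  expect_warning(ll0 <- poisson_nmf_loglik(x1, f0), "-Inf")
  expect_identical(ll0, -Inf)
})

test_that("EM updates solve K = 1 in closed form and never decrease the loglik", {
  # K = 1: updating W with H fixed converges to w_j = sum_i x_ij / sum_i h_i
  x <- random_counts(6, 5, lambda = 4, seed = 21)
  h <- matrix(rowSums(as.matrix(x$values)), 6, 1)
  fit <- topicDE:::new_poisson_nmf_fit(W = matrix(1, 5, 1), H = h)
  fit <- update_factors(x, fit, "W", "em", numiter = 50)
  expect_equal(drop(fit$W), colSums(as.matrix(x$values)) / sum(h),
               tolerance = 1e-8, ignore_attr = TRUE)
  # monotonicity of EM on random instances, both factors, via the loglik
  for (seed in 1:5) {
    x <- random_counts(8, 7, lambda = 2, seed = seed)
    fit <- random_nmf_fit(8, 7, 3, seed = seed + 50)
    ll <- poisson_nmf_loglik(x, fit)
    for (it in 1:10) {
      fit <- update_factors(x, fit, if (it %% 2) "W" else "H", "em")
      ll2 <- poisson_nmf_loglik(x, fit)
      expect_gte(ll2, ll - 1e-8 * abs(ll))
      ll <- ll2
    }
  }
  # zero data column drives the corresponding W row to the floor
  xm <- as.matrix(random_counts(6, 4, lambda = 3, seed = 31)$values)
  xm[, 2] <- 0
  x <- counts_matrix(xm)
  fit <- random_nmf_fit(6, 4, 2, seed = 32)
  fit <- update_factors(x, fit, "W", "em", numiter = 5)
  expect_true(all(fit$W[2, ] <= 1e-15 + 1e-20))
})

test_that("CD updates improve the fit and keep entries positive", {
  x <- random_counts(10, 8, lambda = 2, seed = 41)
  fit <- random_nmf_fit(10, 8, 2, seed = 42)
  ll0 <- poisson_nmf_loglik(x, fit)
  fit <- update_factors(x, fit, "W", "cd", numiter = 5)
  fit <- update_factors(x, fit, "H", "cd", numiter = 5)
  expect_gt(poisson_nmf_loglik(x, fit), ll0)
  expect_true(all(fit$W > 0) && all(fit$H > 0))
})

test_that("fit_poisson_nmf solves K = 1 exactly, is deterministic, and validates K", {
  x <- random_counts(12, 9, lambda = 5, seed = 51)
  fit <- fit_poisson_nmf(x, K = 1, prefit_iters = 60, refine_iters = 40,
                         seed = 3)
  lam <- fit$H %*% t(fit$W)
  xm <- as.matrix(x$values)
  lam_mle <- outer(rowSums(xm), colSums(xm)) / sum(xm)
  expect_lt(max(abs(lam - lam_mle) / pmax(lam_mle, 1e-8)), 1e-4)
  fit2 <- fit_poisson_nmf(x, K = 1, prefit_iters = 60, refine_iters = 40,
                          seed = 3)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$H, fit2$H)
  expect_error(fit_poisson_nmf(x, K = 50), "configuration error")
})

test_that("two-phase fit recovers a planted 2-topic structure", {
  # Statistical limit: at n = 200, m = 500 the MLE itself sits well away
  # from the planted truth (Poisson noise at ~0.2 counts per entry), so the
  # fit is checked (a) to reach at least the truth's likelihood and (b) to
  # land within a realistic Frobenius distance of the truth.
  sim <- simulate_dataset("mixed2", m = 500, seed = 41)
  x <- sim$counts
  tr <- sim$truth
  fit <- fit_poisson_nmf(x, K = 2, prefit_iters = 150, refine_iters = 150,
                         seed = 7)
  truth_fit <- topicDE:::new_poisson_nmf_fit(W = tr$F, H = tr$s * tr$L)
  expect_gte(poisson_nmf_loglik(x, fit), poisson_nmf_loglik(x, truth_fit))
  Pi_hat <- fit$H %*% t(fit$W)
  Pi_true <- (tr$s * tr$L) %*% t(tr$F)
  expect_lt(norm(Pi_hat - Pi_true, "F") / norm(Pi_true, "F"), 0.25)
})

test_that("poisson2multinom matches the stated formulas and identities", {
  # unit column sums: F = W, memberships proportional to H
  W <- cbind(c(0.3, 0.7), c(0.9, 0.1))
  H <- matrix(c(2, 1, 1, 3), 2, 2)
  tm <- poisson2multinom(topicDE:::new_poisson_nmf_fit(W = W, H = H))
  expect_equal(tm$F, W)
  expect_equal(tm$L, H / rowSums(H))
  # forced small example
  W <- rbind(c(1, 0), c(1, 2))
  H <- matrix(c(1, 1), 1, 2)
  tm <- poisson2multinom(topicDE:::new_poisson_nmf_fit(W = W, H = H))
  expect_equal(tm$F, rbind(c(0.5, 0), c(0.5, 1)))
  expect_equal(drop(tm$L), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(tm$s, 4, ignore_attr = TRUE)
  # random fits: reconstruction identity and simplex constraints
  for (seed in 1:10) {
    fit <- random_nmf_fit(7, 6, 3, seed = seed)
    tm <- poisson2multinom(fit)
    lhs <- fit$H %*% t(fit$W)
    rhs <- (tm$s * tm$L) %*% t(tm$F)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-10)
    expect_lt(max(abs(rowSums(tm$L) - 1)), 1e-12)
    expect_lt(max(abs(colSums(tm$F) - 1)), 1e-12)
  }
  bad <- topicDE:::new_poisson_nmf_fit(W = cbind(c(1, 1), c(0, 0)),
                                       H = matrix(1, 2, 2))
  expect_error(poisson2multinom(bad), "degenerate topic")
})

test_that("compare_fits tabulates likelihoods by K", {
  x <- random_counts(15, 10, lambda = 3, seed = 61)
  f2 <- fit_poisson_nmf(x, 2, prefit_iters = 40, refine_iters = 30,
                        seed = 1)
  tab1 <- compare_fits(x, f2)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$loglik, poisson_nmf_loglik(x, f2))
  tab2 <- compare_fits(x, list(f2, f2))
  expect_equal(tab2$loglik[1], tab2$loglik[2])
  fits <- lapply(1:3, function(k)
    fit_poisson_nmf(x, k, prefit_iters = 40, refine_iters = 30, seed = 1))
  tab <- compare_fits(x, fits[c(2, 1, 3)])
  expect_equal(tab$K, c(1, 2, 3))
  # soft nested-likelihood check: allow a small slack for local optima
  expect_true(all(diff(tab$loglik) > -0.005 * abs(tab$loglik[1])))
})

test_that("EM updates commute with feature permutation", {
  x <- random_counts(9, 7, lambda = 2, seed = 71)
  fit <- random_nmf_fit(9, 7, 2, seed = 72)
  perm <- sample(7)
  xp <- counts_matrix(as.matrix(x$values)[, perm])
  fitp <- topicDE:::new_poisson_nmf_fit(W = fit$W[perm, ], H = fit$H)
  up <- update_factors(x, fit, "W", "em")
  upp <- update_factors(xp, fitp, "W", "em")
  expect_equal(upp$W, up$W[perm, ])
})
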