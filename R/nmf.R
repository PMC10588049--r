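#' Poisson non-negative matrix factorization of count data
#'
#' The Poisson NMF model is `x_ij ~ Poisson(lambda_ij)` with
#' `Lambda = H W'`, where `H` is n x K (cells) and `W` is m x K (features),
#' all entries non-negative. A multinomial topic model is an equivalent
#' reparameterization (see [poisson2multinom()]): topic proportions are
#' recovered from `H` and per-topic feature frequencies from `W`.
#'
#' @name poisson_nmf
NULL

new_poisson_nmf_fit <- function(W, H, loglik_trace = numeric(0)) {
  stopifnot(ncol(W) == ncol(H))
  structure(list(W = W, H = H, K = ncol(W), loglik_trace = loglik_trace),
            class = "poisson_nmf_fit")
}

#' @export
print.poisson_nmf_fit <- function(x, ...) {
  cat(sprintf("poisson_nmf_fit: K = %d, W %d x %d, H %d x %d\n",
              x$K, nrow(x$W), ncol(x$W), nrow(x$H), ncol(x$H)))
  if (length(x$loglik_trace) > 0)
    cat(sprintf("  final log-likelihood: %.6g (%d recorded updates)\n",
                utils::tail(x$loglik_trace, 1), length(x$loglik_trace)))
  invisible(x)
}

#' Poisson NMF log-likelihood
#'
#' Computes `sum_ij [x_ij log(lambda_ij) - lambda_ij]` with
#' `Lambda = H W'`. The constant `-log(x_ij!)` terms are omitted, so values
#' are comparable across fits of the same data but are not absolute
#' log-probabilities. Terms with `x_ij = 0` and `lambda_ij = 0` contribute 0;
#' `lambda_ij = 0` with `x_ij > 0` yields `-Inf` (with a warning), not an
#' error.
#'
#' @param x A [counts_matrix()].
#' @param fit A `poisson_nmf_fit` with dimensions matching `x`.
#' @return A scalar log-likelihood (up to the additive constant).
#' @export
poisson_nmf_loglik <- function(x, fit) {
  stopifnot(inherits(x, "counts_matrix"), inherits(fit, "poisson_nmf_fit"))
  v <- x$values
  if (nrow(v) != nrow(fit$H) || ncol(v) != nrow(fit$W))
    stop("dimension error: counts are ", nrow(v), " x ", ncol(v),
         " but fit implies ", nrow(fit$H), " x ", nrow(fit$W))
  # sum of lambda over all entries factorizes over topics
  total_lambda <- sum(colSums(fit$H) * colSums(fit$W))
  e <- Matrix::summary(v)
  lam <- lambda_at(fit$H, fit$W, e$i, e$j)
  bad <- lam == 0 & e$x > 0
  if (any(bad)) {
    warning("lambda = 0 at ", sum(bad), " entries with positive counts; ",
            "log-likelihood is -Inf")
    return(-Inf)
  }
  pos <- e$x > 0
  sum(e$x[pos] * log(lam[pos])) - total_lambda
}

# Poisson rates at a set of (i, j) entries: lambda_ij = sum_k H[i,k] W[j,k].
lambda_at <- function(H, W, i, j) {
  rowSums(H[i, , drop = FALSE] * W[j, , drop = FALSE])
}

#' One or more updates of a single Poisson NMF factor
#'
#' Updates either `W` (features) or `H` (cells) holding the other factor
#' fixed. `method = "em"` applies the classical multiplicative updates for
#' the Poisson/KL objective, which never decrease the likelihood.
#' `method = "cd"` applies cyclic Newton-style coordinate updates, one topic
#' column at a time, with rates refreshed after each column; these typically
#' converge faster but carry no monotonicity guarantee. All entries are
#' clamped at a small positive floor (1e-15) so that zeros are never
#' absorbing.
#'
#' @param x A [counts_matrix()].
#' @param fit A `poisson_nmf_fit`.
#' @param which `"W"` or `"H"`: the factor to update.
#' @param method `"em"` or `"cd"`.
#' @param numiter Number of full update sweeps (>= 1).
#' @return The updated `poisson_nmf_fit`.
#' @export
update_factors <- function(x, fit, which = c("W", "H"),
                           method = c("em", "cd"), numiter = 1) {
  which <- match.arg(which)
  method <- match.arg(method)
  stopifnot(numiter >= 1)
  v <- x$values
  e <- Matrix::summary(v)
  W <- fit$W
  H <- fit$H
  for (iter in seq_len(numiter)) {
    if (which == "W")
      W <- update_one_factor(e, H, W, nrow(v), ncol(v), method,
                             transposed = FALSE)
    else
      H <- update_one_factor(data.frame(i = e$j, j = e$i, x = e$x), W, H,
                             ncol(v), nrow(v), method, transposed = TRUE)
    if (!all(is.finite(if (which == "W") W else H)))
      stop("numerical failure (non-finite factor entries) at iteration ",
           iter)
  }
  new_poisson_nmf_fit(W, H, fit$loglik_trace)
}

# Update factor B (rows indexed by j) given fixed factor A (rows indexed by
# i), for entries e = (i, j, x) of the count matrix. For the W update, A = H
# and B = W; for the H update the entry table is transposed by the caller.
update_one_factor <- function(e, A, B, n, m, method, transposed) {
  floor_val <- 1e-15
  K <- ncol(A)
  colsums_A <- colSums(A)
  if (method == "em") {
    lam <- lambda_at(A, B, e$i, e$j)
    ratio <- e$x / pmax(lam, .Machine$double.xmin)
    # numerator: for each j, sum_i ratio_ij * A[i, k]
    num <- crossprod_entries(e$j, e$i, ratio, A, m)
    B <- B * sweep(num, 2, pmax(colsums_A, floor_val), "/")
    B[B < floor_val] <- floor_val
  } else {
    # cyclic Newton coordinate updates, one topic column at a time
    lam <- lambda_at(A, B, e$i, e$j)
    for (k in seq_len(K)) {
      a <- A[e$i, k]
      r1 <- e$x * a / pmax(lam, .Machine$double.xmin)
      r2 <- e$x * a^2 / pmax(lam, .Machine$double.xmin)^2
      g1 <- accum_by(e$j, r1, m)          # sum_i x a / lam
      g2 <- accum_by(e$j, r2, m)          # sum_i x a^2 / lam^2
      grad <- colsums_A[k] - g1           # d(-loglik)/dB[,k]
      newB <- B[, k] - grad / pmax(g2, floor_val)
      newB[g2 <= floor_val & grad > 0] <- floor_val
      newB[newB < floor_val] <- floor_val
      lam <- lam + a * (newB[e$j] - B[e$j, k])
      B[, k] <- newB
    }
  }
  B
}

# For each group g in 1..m, sum_i w_i A[i, k] restricted to rows with
# group index g: returns an m x K matrix.
crossprod_entries <- function(groups, rows, w, A, m) {
  out <- matrix(0, m, ncol(A))
  for (k in seq_len(ncol(A)))
    out[, k] <- accum_by(groups, w * A[rows, k], m)
  out
}

accum_by <- function(groups, values, m) {
  out <- numeric(m)
  sums <- rowsum(values, groups, reorder = FALSE)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out
}

#' Fit a Poisson NMF model by a two-phase schedule
#'
#' Fits the rank-K Poisson NMF by (1) seeded random initialization of `W` and
#' `H`, scaled so the total fitted rate equals the total count; (2) 10 CD
#' updates of `H` with `W` fixed; (3) a "prefitting" phase of EM updates of
#' both factors; (4) a "refinement" phase of CD updates of both factors. The
#' fixed iteration schedule (defaults 1000 + 1000) is the convergence
#' criterion; an optional early stop triggers when the log-likelihood changes
#' by less than `tol` over one refinement update. Deterministic given `seed`.
#'
#' @param x A [counts_matrix()].
#' @param K Number of topics (1 <= K <= min(n, m)).
#' @param prefit_iters Number of EM prefit updates.
#' @param refine_iters Number of CD refinement updates.
#' @param seed Integer seed for the random initialization.
#' @param tol Optional absolute early-stop tolerance on the log-likelihood
#'   change per refinement update (default `1e-6 * n`); set to 0 to disable.
#' @param verbose Print progress.
#' @return A `poisson_nmf_fit` with the per-update `loglik_trace`.
#' @export
fit_poisson_nmf <- function(x, K, prefit_iters = 1000, refine_iters = 1000,
                            seed = 1, tol = NULL, verbose = FALSE) {
  stopifnot(inherits(x, "counts_matrix"), K >= 1)
  v <- x$values
  n <- nrow(v)
  m <- ncol(v)
  if (K > min(n, m))
    stop("configuration error: K = ", K, " exceeds min(n, m) = ", min(n, m))
  if (length(v@x) == 0)
    stop("configuration error: count matrix has no nonzero entries")
  if (is.null(tol))
    tol <- 1e-6 * n
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  W <- matrix(stats::runif(m * K), m, K)
  H <- matrix(stats::runif(n * K), n, K)
  total <- sum(colSums(H) * colSums(W))
  sc <- sqrt(sum(v@x) / total)
  W <- W * sc
  H <- H * sc
  fit <- new_poisson_nmf_fit(W, H)
  fit <- update_factors(x, fit, which = "H", method = "cd", numiter = 10)
  trace <- poisson_nmf_loglik(x, fit)
  for (it in seq_len(prefit_iters)) {
    fit <- update_factors(x, fit, which = "W", method = "em")
    fit <- update_factors(x, fit, which = "H", method = "em")
    trace <- c(trace, poisson_nmf_loglik(x, fit))
    if (verbose && it %% 100 == 0)
      message("prefit ", it, ": loglik = ", utils::tail(trace, 1))
  }
  for (it in seq_len(refine_iters)) {
    fit <- update_factors(x, fit, which = "W", method = "cd")
    fit <- update_factors(x, fit, which = "H", method = "cd")
    trace <- c(trace, poisson_nmf_loglik(x, fit))
    if (verbose && it %% 100 == 0)
      message("refine ", it, ": loglik = ", utils::tail(trace, 1))
    nt <- length(trace)
    if (tol > 0 && abs(trace[nt] - trace[nt - 1]) < tol)
      break
  }
  fit$loglik_trace <- trace
  fit
}

#' Recover the multinomial topic model from a Poisson NMF fit
#'
#' The reparameterization sets `c_k = sum_j W[j,k]`, topic frequencies
#' `F[j,k] = W[j,k] / c_k` (columns sum to 1), memberships
#' `L[i,k] = H[i,k] c_k / sum_k' H[i,k'] c_k'` (rows sum to 1), and size
#' factors `s_i = sum_k H[i,k] c_k`, so that `H W' = diag(s) L F'` exactly.
#'
#' @param fit A `poisson_nmf_fit`.
#' @return An object of class `topic_model_fit` with elements `L` (n x K),
#'   `F` (m x K) and `s` (length n).
#' @export
poisson2multinom <- function(fit) {
  stopifnot(inherits(fit, "poisson_nmf_fit"))
  ck <- colSums(fit$W)
  if (any(ck == 0))
    stop("degenerate topic: column ", which(ck == 0)[1],
         " of W sums to zero")
  rs <- rowSums(fit$H)
  if (any(rs == 0))
    stop("degenerate cell: row ", which(rs == 0)[1], " of H sums to zero")
  F_ <- sweep(fit$W, 2, ck, "/")
  Hs <- sweep(fit$H, 2, ck, "*")
  s <- rowSums(Hs)
  L <- Hs / s
  structure(list(L = L, F = F_, s = s, K = fit$K),
            class = "topic_model_fit")
}

#' @export
print.topic_model_fit <- function(x, ...) {
  cat(sprintf("topic_model_fit: K = %d, %d cells, %d features\n",
              x$K, nrow(x$L), nrow(x$F)))
  invisible(x)
}

#' Compare Poisson NMF fits by log-likelihood
#'
#' @param x A [counts_matrix()].
#' @param fits A list of `poisson_nmf_fit` objects (typically one per K).
#' @return A data frame with columns `K` and `loglik`, sorted by `K`.
#' @export
compare_fits <- function(x, fits) {
  if (inherits(fits, "poisson_nmf_fit"))
    fits <- list(fits)
  stopifnot(length(fits) >= 1)
  out <- data.frame(K = vapply(fits, function(f) f$K, numeric(1)),
                    loglik = vapply(fits, function(f)
                      poisson_nmf_loglik(x, f), numeric(1)))
  out[order(out$K), , drop = FALSE]
}

# Scoped seeding: set the RNG to a known state, returning the previous state
# so callers can restore it (keeps library functions from clobbering the
# user's RNG stream).
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_seed <- function(old) {
  if (is.null(old))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  else
    assign(".Random.seed", old, envir = globalenv())
}
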