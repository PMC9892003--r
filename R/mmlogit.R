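## Multinomial mixed-effects logistic regression with a per-tomogram random
## intercept for each non-reference outcome category.
##
## Model: log-odds(outcome = k vs reference | state s, tomogram t)
##            = beta[k, s] + u[k, t],   u[k, t] ~ N(0, sigma_k^2)
## independent across tomograms and categories. With a purely categorical
## predictor the likelihood depends on the data only through the per-tomogram
## state-by-outcome counts, which keeps the marginal likelihood cheap: one
## small Newton problem per tomogram inside a Laplace (or, for two outcome
## categories, adaptive Gauss-Hermite) approximation of the integral over u.

# Gauss-Hermite nodes/weights (weight exp(-x^2)) via Golub-Welsch
gh_rule <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# counts: T x S x K array (reference category first); beta: (K-1) x S
# per-tomogram penalized Newton maximization of the joint log density in u
mml_inner_newton <- function(Cts, beta, sigma2, max_iter = 50, tol = 1e-10) {
  K1 <- nrow(beta)
  u <- numeric(K1)
  n_s <- rowSums(Cts)                    # per-state totals, length S
  obj <- function(u) {
    eta <- beta + u                      # (K-1) x S
    lse <- log1p(colSums(exp(eta)))      # length S
    sum(Cts[, -1, drop = FALSE] * t(eta)) - sum(n_s * lse) -
      sum(u^2 / (2 * sigma2))
  }
  f <- obj(u)
  for (it in seq_len(max_iter)) {
    eta <- beta + u
    expeta <- exp(eta)
    denom <- 1 + colSums(expeta)
    P <- sweep(expeta, 2, denom, "/")    # (K-1) x S, non-reference probs
    g <- rowSums(t(Cts[, -1, drop = FALSE])) - as.numeric(P %*% n_s) -
      u / sigma2
    W <- -tcrossprod(sweep(P, 2, sqrt(n_s), "*"))
    diag(W) <- diag(W) + as.numeric(P %*% n_s)
    H <- W + diag(1 / sigma2, K1)
    step <- solve(H, g)
    # step halving for robustness
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      f_new <- obj(u_new)
      if (f_new >= f - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    moved <- max(abs(u_new - u))
    u <- u_new; f <- f_new
    if (moved < tol) break
  }
  # curvature of the unpenalized log-likelihood at the mode
  eta <- beta + u
  expeta <- exp(eta)
  denom <- 1 + colSums(expeta)
  P <- sweep(expeta, 2, denom, "/")
  W <- -tcrossprod(sweep(P, 2, sqrt(n_s), "*"))
  diag(W) <- diag(W) + as.numeric(P %*% n_s)
  list(u = u, logf = f + sum(u^2 / (2 * sigma2)), penalized = f, W = W)
}

# negative marginal log-likelihood, general K, Laplace approximation
mml_negll_laplace <- function(theta, counts, K, S, fixed_sigma = NULL) {
  K1 <- K - 1L
  beta <- matrix(theta[seq_len(K1 * S)], K1, S)
  sigma2 <- if (is.null(fixed_sigma)) exp(2 * theta[K1 * S + seq_len(K1)])
            else rep(fixed_sigma^2, K1)
  Tn <- dim(counts)[1]
  if (all(sigma2 < 1e-12)) {
    # degenerate limit: pooled multinomial logit
    C <- apply(counts, c(2, 3), sum)
    n_s <- rowSums(C)
    eta <- beta
    lse <- log1p(colSums(exp(eta)))
    return(-(sum(C[, -1, drop = FALSE] * t(eta)) - sum(n_s * lse)))
  }
  ll <- 0
  for (t in seq_len(Tn)) {
    Cts <- matrix(counts[t, , ], S, K)
    inner <- mml_inner_newton(Cts, beta, sigma2)
    A <- inner$W + diag(1 / sigma2, K1)
    ld <- determinant(diag(sigma2, K1) %*% A, logarithm = TRUE)$modulus
    ll <- ll + inner$penalized - 0.5 * as.numeric(ld)
  }
  -ll
}

# negative marginal log-likelihood, K = 2, vectorized over tomograms;
# nagq = 1 gives the Laplace approximation, nagq > 1 adaptive Gauss-Hermite
mml_negll_binary <- function(theta, Y, N, fixed_sigma = NULL, nagq = 1,
                             gh = NULL) {
  S <- ncol(Y)
  beta <- theta[seq_len(S)]
  sigma2 <- if (is.null(fixed_sigma)) exp(2 * theta[S + 1]) else fixed_sigma^2
  Tn <- nrow(Y)
  eta0 <- matrix(beta, Tn, S, byrow = TRUE)
  ll_given_u <- function(u) {
    eta <- eta0 + u                      # T x S
    rowSums(Y * eta - N * log1p(exp(eta)))
  }
  if (sigma2 < 1e-12) return(-sum(ll_given_u(0)))
  u <- numeric(Tn)
  f <- ll_given_u(u) - u^2 / (2 * sigma2)
  for (it in 1:100) {
    eta <- eta0 + u
    p <- 1 / (1 + exp(-eta))
    g <- rowSums(Y - N * p) - u / sigma2
    W <- rowSums(N * p * (1 - p))
    step <- g / (W + 1 / sigma2)
    lambda <- rep(1, Tn)
    repeat {
      u_new <- u + lambda * step
      f_new <- ll_given_u(u_new) - u_new^2 / (2 * sigma2)
      worse <- f_new < f - 1e-12 & lambda > 1e-4
      if (!any(worse)) break
      lambda[worse] <- lambda[worse] / 2
    }
    moved <- max(abs(u_new - u))
    u <- u_new; f <- f_new
    if (moved < 1e-10) break
  }
  eta <- eta0 + u
  p <- 1 / (1 + exp(-eta))
  W <- rowSums(N * p * (1 - p))
  A <- W + 1 / sigma2
  if (nagq <= 1) {
    return(-sum(f - 0.5 * log(sigma2 * A)))
  }
  # adaptive GH centred at the mode with scale 1/sqrt(A)
  tau <- 1 / sqrt(A)
  h <- function(uu) ll_given_u(uu) - uu^2 / (2 * sigma2)
  M <- matrix(NA_real_, Tn, nagq)
  for (m in seq_len(nagq)) {
    x <- gh$nodes[m]
    uu <- u + sqrt(2) * tau * x
    M[, m] <- log(gh$weights[m]) + x^2 + h(uu)
  }
  mx <- apply(M, 1, max)
  lint <- mx + log(rowSums(exp(M - mx))) + log(sqrt(2) * tau)
  -sum(lint - log(sqrt(2 * pi * sigma2)))
}

# robust symmetric inverse with SVD fallback (near-singular under separation)
sym_inverse <- function(H) {
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd((H + t(H)) / 2)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
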