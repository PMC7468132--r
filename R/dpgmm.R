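# Variational Dirichlet-process Gaussian mixture with diagonal covariance.
#
# Truncated stick-breaking representation (truncation level `max_components`)
# with Beta(1, alpha) sticks and independent Normal-Gamma priors per
# dimension. Mean-field updates follow the standard conjugate derivation;
# responsibilities are initialized from a k-means partition and the fit with
# the best variational score over random restarts is kept.

dpgmm_fit <- function(X, max_components = 50, alpha = 0.01, restarts = 10,
                      iterations = 200, tol = 1e-6, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  K <- min(max_components, n)
  best <- NULL
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, restarts)
  for (r in seq_len(restarts)) {
    set.seed(seeds[r])
    fit <- tryCatch(
      dpgmm_once(X, K, alpha, iterations, tol),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$score > best$score)) best <- fit
  }
  if (is.null(best)) abort("Mixture fit failed in every restart.")
  best
}

dpgmm_once <- function(X, K, alpha, iterations, tol) {
  n <- nrow(X); d <- ncol(X)
  # priors on standardized features
  m0 <- 0; beta0 <- 1; a0 <- 1; b0 <- 1
  km <- suppressWarnings(kmeans(X, centers = min(K, nrow(unique(X))),
                                iter.max = 30, nstart = 1))
  R <- matrix(1e-10, n, K)
  R[cbind(seq_len(n), km$cluster)] <- 1
  R <- R / rowSums(R)
  score_prev <- -Inf
  score <- -Inf
  for (it in seq_len(iterations)) {
    Nk <- colSums(R) + 1e-12
    # stick-breaking posteriors
    g1 <- 1 + Nk
    g2 <- alpha + rev(cumsum(rev(Nk))) - Nk
    elogv <- digamma(g1) - digamma(g1 + g2)
    elog1mv <- digamma(g2) - digamma(g1 + g2)
    elogpi <- elogv + c(0, cumsum(elog1mv)[-K])
    # Gaussian-Gamma posteriors (diagonal)
    xbar <- t(R) %*% X / Nk                       # K x d
    S <- t(R) %*% (X * X) / Nk - xbar^2           # K x d (biased, >= 0)
    S[S < 0] <- 0
    betak <- beta0 + Nk
    mk <- (beta0 * m0 + Nk * xbar) / betak
    ak <- a0 + Nk / 2
    bk <- b0 + 0.5 * (Nk * S + beta0 * Nk * (xbar - m0)^2 / betak)
    elambda <- ak / bk                            # K x d
    eloglambda <- digamma(ak) - log(bk)
    # responsibilities
    quad <- outer(rep(1, n), rowSums(elambda * mk^2) + d / betak) -
      2 * X %*% t(elambda * mk) + (X * X) %*% t(elambda)
    logrho <- outer(rep(1, n), elogpi + 0.5 * rowSums(eloglambda) -
                      0.5 * d * log(2 * pi)) - 0.5 * quad
    mx <- apply(logrho, 1, max)
    lse <- mx + log(rowSums(exp(logrho - mx)))
    R <- exp(logrho - lse)
    score <- sum(lse)
    if (is.finite(score) && abs(score - score_prev) < tol * abs(score)) break
    score_prev <- score
  }
  labels <- max.col(R, ties.method = "first")
  list(labels = labels, R = R, score = score, centers_std = mk,
       weights = colSums(R) / n)
}
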