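# Independent oracles and fixture builders shared across test files.
# Everything here is written against the model definitions directly (dense
# linear algebra, brute-force loops), not against the package's code paths.

# Restricted log-likelihood of y ~ N(1*mu, sum sigma2_k K_k + sigma2_e I),
# computed by dense solve/determinant (independent of reml_pieces).
oracle_loglik <- function(y, Klist, sigma2, sigma2_e) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (k in seq_along(Klist)) V <- V + sigma2[k] * unclass(Klist[[k]])
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XVX <- drop(t(X) %*% Vi %*% X)
  P <- Vi - Vi %*% X %*% t(X) %*% Vi / XVX
  as.numeric(-0.5 * ((n - 1) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       log(XVX) + drop(t(y) %*% P %*% y)))
}

# Brute-force grid maximization of the single-kernel restricted likelihood
# over (sigma2_g, sigma2_e) in (0, 3*var(y)]^2. Uses the eigendecomposition
# of K for a closed-form per-point evaluation (an independent derivation of
# the same likelihood). Optionally refines once around the coarse argmax.
oracle_grid_fit <- function(y, K, len = 200L, refine = FALSE) {
  n <- length(y)
  e <- eigen(unclass(K), symmetric = TRUE)
  ys <- drop(crossprod(e$vectors, y))
  xs <- drop(crossprod(e$vectors, rep(1, n)))
  ll_at <- function(sg, se) {
    v <- sg * e$values + se
    xvx <- sum(xs^2 / v)
    mu <- sum(xs * ys / v) / xvx
    ypy <- sum(ys^2 / v) - xvx * mu^2
    -0.5 * ((n - 1) * log(2 * pi) + sum(log(v)) + log(xvx) + ypy)
  }
  search <- function(glo, ghi, elo, ehi) {
    gg <- seq(glo, ghi, length.out = len)
    ee <- seq(elo, ehi, length.out = len)
    lls <- outer(gg, ee, Vectorize(ll_at))
    b <- arrayInd(which.max(lls), dim(lls))
    list(sg = gg[b[1]], se = ee[b[2]], loglik = max(lls),
         step = c(gg[2] - gg[1], ee[2] - ee[1]))
  }
  hi <- 3 * var(y)
  coarse <- search(hi / len, hi, hi / len, hi)
  out <- coarse
  if (refine) {
    fine <- search(max(coarse$sg - coarse$step[1], 0), coarse$sg + coarse$step[1],
                   max(coarse$se - coarse$step[2], 1e-8), coarse$se + coarse$step[2])
    if (fine$loglik >= coarse$loglik) out <- fine
  }
  out$coarse_loglik <- coarse$loglik
  out$ratio <- out$sg / (out$sg + out$se)
  out
}

# Henderson mixed-model-equation predictions with test records unobserved:
# solve for (mu, u over all lines) from the training records only. The
# kernel is PSD but typically singular, so u is parameterized on the range
# of K (u = U a with a ~ N(0, D sigma2_k), K = U D U'), which keeps the MME
# exact without inverting K.
oracle_mme_predict <- function(y_train, Kfull, train, test, sigma2_k,
                               sigma2_e) {
  K <- unclass(Kfull)
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > 1e-12 * max(e$values)
  U <- e$vectors[, keep, drop = FALSE]
  d <- e$values[keep]
  ntr <- length(train)
  X <- matrix(1, ntr, 1)
  W <- U[train, , drop = FALSE]         # incidence of a on training records
  lhs <- rbind(
    cbind(crossprod(X) / sigma2_e, crossprod(X, W) / sigma2_e),
    cbind(crossprod(W, X) / sigma2_e,
          crossprod(W) / sigma2_e + diag(1 / (d * sigma2_k))))
  rhs <- rbind(crossprod(X, y_train), crossprod(W, y_train)) / sigma2_e
  sol <- solve(lhs, rhs)
  mu <- sol[1]
  a <- sol[-1]
  u <- drop(U %*% a)
  drop(mu + u[test])
}

# draw y from the generative multi-kernel model given kernels and components
draw_from_model <- function(Klist, sigma2, sigma2_e, seed) {
  n <- nrow(Klist[[1]])
  set.seed(seed)
  y <- rnorm(n, 0, sqrt(sigma2_e))
  for (k in seq_along(Klist)) {
    ch <- chol(unclass(Klist[[k]]) + diag(1e-8, n))
    y <- y + sqrt(sigma2[k]) * drop(t(ch) %*% rnorm(n))
  }
  y
}

# small complete genotype fixture with mixed dosages
toy_genotypes <- function(n = 12L, m = 30L, seed = 42L) {
  set.seed(seed)
  d <- matrix(sample(c(0, 1, 2), n * m, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4)), n, m)
  rownames(d) <- sprintf("L%03d", seq_len(n))
  colnames(d) <- sprintf("M%05d", seq_len(m))
  genotype_matrix(d)
}
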