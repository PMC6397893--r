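#' Restricted log-likelihood of an intercept-only multi-kernel mixed model
#'
#' Evaluates the REML log-likelihood of `y ~ N(1*mu, sum_k sigma_k^2 K_k +
#' sigma_e^2 I)` at given variance components, including all constants:
#' `-0.5 * ((n - 1) log(2*pi) + log|V| + log|X'V^-1 X| + y'Py)`.
#'
#' @param y numeric response vector
#' @param kernels list of n x n kernel matrices
#' @param sigma2 numeric vector of kernel variances, one per kernel
#' @param sigma2_e residual variance (> 0)
#' @return scalar restricted log-likelihood
#' @export
reml_loglik <- function(y, kernels, sigma2, sigma2_e) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (k in seq_along(kernels)) {
    V <- V + sigma2[k] * unclass(kernels[[k]])
  }
  ch <- tryCatch(chol(V), error = function(e) chol(add_jitter(V)))
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Vinvy <- backsolve(ch, forwardsolve(t(ch), y))
  xvx <- sum(Vinv1)                     # 1' V^-1 1
  mu <- sum(Vinvy) / xvx
  yPy <- sum(y * Vinvy) - xvx * mu^2
  -0.5 * ((n - 1) * log(2 * pi) + logdetV + log(xvx) + yPy)
}

# P, Py and per-iteration pieces for AI-REML (X = 1 only)
reml_pieces <- function(y, Ks, theta) {
  n <- length(y)
  nk <- length(Ks) - 1L                 # last element is identity (residual)
  V <- diag(theta[nk + 1L], n)
  for (k in seq_len(nk)) V <- V + theta[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) chol(add_jitter(V)))
  Vinv <- chol2inv(ch)
  v1 <- rowSums(Vinv)                   # V^-1 1
  xvx <- sum(v1)
  P <- Vinv - tcrossprod(v1) / xvx
  Py <- drop(P %*% y)
  mu <- sum(Vinv %*% y) / xvx
  ll <- -0.5 * ((n - 1) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                  log(xvx) + sum(y * Py))
  list(P = P, Py = Py, mu = mu, loglik = ll)
}

# Solve A x = b via eigendecomposition, dropping near-null directions.
# The AI matrix is singular when two kernels are (nearly) identical — the
# likelihood is flat along the split between their components — and the
# pseudo-inverse step still makes Newton progress along the informative
# directions (here, the component sum).
psolve <- function(A, b, rtol = 1e-10) {
  e <- tryCatch(eigen(A, symmetric = TRUE), error = function(err) NULL)
  if (is.null(e)) return(NULL)
  keep <- e$values > rtol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(NULL)
  drop(e$vectors[, keep, drop = FALSE] %*%
         ((crossprod(e$vectors[, keep, drop = FALSE], b)) / e$values[keep]))
}

# One AI-REML run over the components flagged free (last component is the
# residual). AI steps that leave the feasible region or would decrease the
# restricted log-likelihood fall back to EM, which is monotone.
ai_reml_loop <- function(y, Ks, theta, free, floor_e, tol_loglik, tol_param,
                         max_iter) {
  n <- length(y)
  np <- length(Ks)
  vy <- var(y)
  pc <- reml_pieces(y, Ks, theta)
  converged <- FALSE
  iter <- 0L
  fidx <- which(free)
  for (iter in seq_len(max_iter)) {
    w <- vector("list", np)
    score <- numeric(np)
    for (i in fidx) {
      w[[i]] <- if (i < np) drop(Ks[[i]] %*% pc$Py) else pc$Py
      trPK <- if (i < np) sum(pc$P * Ks[[i]]) else sum(diag(pc$P))
      score[i] <- -0.5 * (trPK - sum(pc$Py * w[[i]]))
    }
    AI <- matrix(0, length(fidx), length(fidx))
    for (a in seq_along(fidx)) {
      Pwi <- drop(pc$P %*% w[[fidx[a]]])
      for (b in a:length(fidx)) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(w[[fidx[b]]] * Pwi)
      }
    }
    step_f <- psolve(AI, score[fidx])
    accepted <- FALSE
    if (!is.null(step_f)) {
      cand <- theta
      cand[fidx] <- cand[fidx] + step_f
      if (all(cand[fidx] >= 0)) {
        cand[np] <- max(cand[np], floor_e)
        pc_cand <- reml_pieces(y, Ks, cand)
        if (pc_cand$loglik >= pc$loglik - 1e-10) {
          delta_rel <- abs(cand - theta) / pmax(abs(theta), 1e-10 * vy)
          theta <- cand
          pc_new <- pc_cand
          accepted <- TRUE
        }
      }
    }
    if (!accepted) {
      theta_new <- theta
      for (i in fidx) {
        KPy <- if (i < np) drop(Ks[[i]] %*% pc$Py) else pc$Py
        trPK <- if (i < np) sum(pc$P * Ks[[i]]) else sum(diag(pc$P))
        theta_new[i] <- theta[i] +
          theta[i]^2 * (sum(pc$Py * KPy) - trPK) / n
      }
      theta_new <- pmax(theta_new, 0)
      theta_new[np] <- max(theta_new[np], floor_e)
      pc_new <- reml_pieces(y, Ks, theta_new)
      if (pc_new$loglik < pc$loglik - 1e-8) {
        converged <- TRUE               # numerically stuck: keep best point
        pc_new <- pc
        theta_new <- theta
      }
      delta_rel <- abs(theta_new - theta) / pmax(abs(theta), 1e-10 * vy)
      theta <- theta_new
    }
    dll <- pc_new$loglik - pc$loglik
    pc <- pc_new
    if (converged || (abs(dll) < tol_loglik && max(delta_rel) < tol_param)) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, loglik = pc$loglik, iter = iter, converged = converged)
}

#' Fit a one- or two-kernel mixed model by REML
#'
#' Maximizes the restricted likelihood of `y ~ N(1*mu, sum_k sigma_k^2 K_k +
#' sigma_e^2 I)` by average-information (AI) REML. Whenever an AI step would
#' leave the feasible region or decrease the restricted log-likelihood, an
#' EM step is taken instead; components are constrained non-negative by
#' projection, and estimates pinned at zero are flagged as boundary rather
#' than dropped and refit. Convergence requires `|delta loglik| < tol_loglik`
#' and a maximum relative parameter change `< tol_param`.
#'
#' @param y numeric response (length n >= 10), non-constant
#' @param kernels a single kernel matrix or a (optionally named) list of one
#'   or two [kernel_matrix()] objects
#' @param model optional model name recorded in the result (used by
#'   [heritability()] to choose the estimand)
#' @param tol_loglik convergence tolerance on the restricted log-likelihood
#'   change (default 1e-6)
#' @param tol_param convergence tolerance on the maximum relative parameter
#'   change (default 1e-5)
#' @param max_iter maximum REML iterations (default 200)
#' @param check_psd verify each kernel is positive semidefinite before
#'   fitting (default `TRUE`; callers fitting many subsets of a pre-checked
#'   kernel may disable it)
#' @param verbose log iteration count, final restricted log-likelihood and
#'   component estimates via `message()`
#' @return object of class `omicblup_fit`: `mu`, `sigma2` (named per-kernel
#'   variances), `sigma2_e`, `blups` (list of in-sample BLUP vectors, one per
#'   kernel), `loglik`, `iterations`, `converged`, `boundary`, `y`,
#'   `kernel_labels`
#' @export
reml_fit <- function(y, kernels, model = NULL, tol_loglik = 1e-6,
                     tol_param = 1e-5, max_iter = 200L, check_psd = TRUE,
                     verbose = FALSE) {
  if (is.matrix(kernels)) kernels <- list(kernels)
  stopifnot(is.list(kernels), length(kernels) %in% 1:2)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  vy <- var(y)
  if (!is.finite(vy) || vy == 0) stop("zero phenotypic variance")
  labels <- names(kernels)
  if (is.null(labels)) {
    labels <- vapply(kernels, function(k) {
      lab <- attr(k, "label")
      if (is.null(lab)) "k" else lab
    }, character(1L))
    labels <- make.unique(tolower(labels))
  }
  Ks <- lapply(kernels, function(k) {
    k <- unclass(as.matrix(k))
    if (nrow(k) != n || ncol(k) != n) {
      stop("kernel dimension does not match length(y)")
    }
    if (check_psd) check_psd(k)
    k
  })
  Ks[[length(Ks) + 1L]] <- diag(1, n)   # residual
  np <- length(Ks)

  theta0 <- rep(vy / np, np)            # symmetric, scale-aware init
  floor_e <- 1e-10 * vy
  ll0 <- reml_pieces(y, Ks, theta0)$loglik

  run <- ai_reml_loop(y, Ks, theta0, free = rep(TRUE, np), floor_e = floor_e,
                      tol_loglik = tol_loglik, tol_param = tol_param,
                      max_iter = max_iter)
  # active-set polish: EM crawls toward a zero boundary without reaching it,
  # so pin any small kernel component at exactly 0, re-optimize the rest,
  # and keep whichever solution has the higher restricted log-likelihood
  small <- which(run$theta < 0.05 * vy)
  if (!run$converged) {
    # a stalled run usually means EM is crawling toward a boundary it
    # cannot reach; try pinning the smallest component as well
    small <- union(small, which.min(run$theta))
  }
  for (i in small) {
    th <- run$theta
    th[i] <- if (i == np) floor_e else 0
    alt <- ai_reml_loop(y, Ks, th, free = replace(rep(TRUE, np), i, FALSE),
                        floor_e = floor_e, tol_loglik = tol_loglik,
                        tol_param = tol_param, max_iter = max_iter)
    if (alt$loglik > run$loglik) run <- alt
  }
  theta <- run$theta
  iter <- run$iter
  converged <- run$converged

  boundary <- theta <= 1e-8 * vy
  theta[boundary & seq_len(np) < np] <- 0
  pc <- reml_pieces(y, Ks, pmax(theta, c(rep(0, np - 1L), floor_e)))
  if (pc$loglik < ll0) pc$loglik <- ll0 # safeguard: never report below init

  blups <- vector("list", np - 1L)
  for (k in seq_len(np - 1L)) {
    blups[[k]] <- drop(theta[k] * Ks[[k]] %*% pc$Py)
    names(blups[[k]]) <- names(y)
  }
  names(blups) <- labels
  sigma2 <- theta[seq_len(np - 1L)]
  names(sigma2) <- labels
  fit <- structure(list(
    mu = pc$mu, sigma2 = sigma2, sigma2_e = theta[np], blups = blups,
    loglik = pc$loglik, iterations = iter, converged = converged,
    boundary = stats::setNames(boundary,
                               c(labels, "e")),
    model = model, kernel_labels = labels, y = y, n = n),
    class = "omicblup_fit")
  if (verbose) {
    message(sprintf(
      "REML: %d iteration(s), loglik %.6f, components [%s], residual %.6g%s",
      iter, pc$loglik,
      paste(sprintf("%s=%.6g", labels, sigma2), collapse = ", "),
      theta[np],
      if (converged) "" else " (NOT converged)"))
  }
  fit
}

#' @export
print.omicblup_fit <- function(x, ...) {
  cat(sprintf("omicblup_fit%s: n = %d, loglik = %.4f (%s, %d iterations)\n",
              if (is.null(x$model)) "" else paste0(" [", x$model, "]"),
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  mu = %.4g\n", x$mu))
  for (k in seq_along(x$sigma2)) {
    cat(sprintf("  sigma2[%s] = %.4g%s\n", names(x$sigma2)[k], x$sigma2[k],
                if (x$boundary[k]) " (boundary)" else ""))
  }
  cat(sprintf("  sigma2[e] = %.4g\n", x$sigma2_e))
  invisible(x)
}

#' Predict genetic values of held-out lines by kernel-extended BLUP
#'
#' Uses the train-only fit and the kernel cross-blocks between test and
#' train lines: for each kernel, `u_test = sigma_k^2 * K[test, train] *
#' V_train^-1 * (y_train - mu)`; the prediction is `mu + sum_k u_test`,
#' equivalent to solving Henderson's mixed-model equations with the test
#' records unobserved. No refit on train + test is performed, so no
#' information leaks from test phenotypes.
#'
#' @param fit an [reml_fit()] result obtained on the training lines
#' @param kernels list of *full* (train + test) kernel matrices in the order
#'   used for the fit
#' @param train integer or logical indices of the training lines in the full
#'   kernels (must match the fit's ordering)
#' @param test indices of the lines to predict
#' @return numeric vector of predicted genetic values (`mu + sum of kernel
#'   effects`) for the test lines
#' @export
blup_predict <- function(fit, kernels, train, test) {
  stopifnot(inherits(fit, "omicblup_fit"))
  if (is.matrix(kernels)) kernels <- list(kernels)
  stopifnot(length(kernels) == length(fit$sigma2))
  Ks <- lapply(kernels, function(k) unclass(as.matrix(k)))
  ntr <- if (is.logical(train)) sum(train) else length(train)
  if (ntr != fit$n) stop("train index length does not match the fit")
  Vtr <- diag(fit$sigma2_e, ntr)
  for (k in seq_along(Ks)) {
    Vtr <- Vtr + fit$sigma2[k] * Ks[[k]][train, train, drop = FALSE]
  }
  ch <- tryCatch(chol(Vtr), error = function(e) chol(add_jitter(Vtr)))
  alpha <- backsolve(ch, forwardsolve(t(ch), fit$y - fit$mu))
  pred <- rep(fit$mu, if (is.logical(test)) sum(test) else length(test))
  for (k in seq_along(Ks)) {
    pred <- pred +
      fit$sigma2[k] * drop(Ks[[k]][test, train, drop = FALSE] %*% alpha)
  }
  pred
}

#' Heritability from a fitted multi-kernel model
#'
#' Computes the variance-component ratio matching the fitted model:
#' \describe{
#'   \item{gblup}{SNP-based narrow-sense `h_G^2 = s_g / (s_g + s_e)`}
#'   \item{gtblup}{`H_GT^2 = (s_g + s_t) / (s_g + s_t + s_e)`}
#'   \item{grblup}{`H_GR^2 = (s_g + s_v) / (s_g + s_v + s_e)`}
#'   \item{otherwise}{omics-augmented broad-sense `H_o^2 = (s_g + s_omics) /
#'     (s_g + s_omics + s_e)` with `s_omics` the sum of all non-genomic
#'     kernel components}
#' }
#' With zero omics variance `H_o^2` reduces exactly to `h_G^2`.
#'
#' @param fit an [reml_fit()] result
#' @return object of class `heritability_estimate`: fields `kind`, `value`
#'   (in `[0, 1]`), `components`
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "omicblup_fit"))
  total_k <- sum(fit$sigma2)
  denom <- total_k + fit$sigma2_e
  if (denom <= 0) stop("all variance components are zero; heritability undefined")
  kind <- switch(if (is.null(fit$model)) "" else fit$model,
                 gblup = "hG2", gtblup = "HGT2", grblup = "HGR2", "Ho2")
  structure(list(kind = kind, value = total_k / denom,
                 components = c(fit$sigma2, e = fit$sigma2_e)),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f\n", x$kind, x$value))
  invisible(x)
}

#' Build the kernels a model requires from a dataset
#'
#' Constructs G (VanRaden, after mean imputation if needed) and/or the
#' expression kernels E / K(h) from the dataset components, in the order the
#' model lists them. Kernels are built from all lines of the dataset —
#' genotypes and expression are predictors, so using all lines leaks no
#' phenotype information into cross-validation.
#'
#' @param dataset an [make_dataset()] result
#' @param model one of `"gblup"`, `"tblup"`, `"rkhs"`, `"gtblup"`,
#'   `"grblup"`
#' @param bandwidth Gaussian bandwidth `h` (required for rkhs / grblup)
#' @return named list of [kernel_matrix()] objects
#' @export
build_model_kernels <- function(dataset, model, bandwidth = NULL) {
  model <- match_model(model)
  needed <- MODEL_KERNELS[[model]]
  out <- list()
  if ("G" %in% needed) {
    if (is.null(dataset$genotypes)) stop("model '", model,
                                         "' needs genotype data")
    out$g <- vanraden_g(center_genotypes(impute_mean(dataset$genotypes)))
  }
  if (any(c("E", "K") %in% needed)) {
    if (is.null(dataset$expression)) stop("model '", model,
                                          "' needs expression data")
    r <- standardize_expression(dataset$expression)
    if ("E" %in% needed) out$t <- linear_expression_kernel(r)
    if ("K" %in% needed) {
      if (is.null(bandwidth)) {
        stop("model '", model, "' needs a Gaussian bandwidth; supply one or ",
             "run grid_search_bandwidth()")
      }
      out$v <- gaussian_kernel(r, bandwidth)
    }
  }
  out
}

#' Fit a named prediction model on a dataset
#'
#' Convenience wrapper: builds the model's kernels, extracts the trait
#' (dropping lines with a missing phenotype), aligns the kernels to those
#' lines and runs [reml_fit()].
#'
#' @inheritParams build_model_kernels
#' @param trait phenotype column to analyze
#' @param ... passed to [reml_fit()]
#' @return an [reml_fit()] result with the model name recorded
#' @export
fit_model <- function(dataset, model, trait, bandwidth = NULL, ...) {
  model <- match_model(model)
  y <- trait_vector(dataset, trait)
  kernels <- build_model_kernels(dataset, model, bandwidth)
  kernels <- lapply(kernels, function(k) {
    k[names(y), names(y), drop = FALSE]
  })
  reml_fit(y, kernels, model = model, ...)
}
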