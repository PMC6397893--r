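#' Replicated k-fold partitions of a line panel
#'
#' For each replicate, lines are shuffled under a seed derived from the
#' master seed (see [derive_seeds()]) and split into k folds whose sizes
#' differ by at most one. The same master seed always yields the same plans,
#' so several models can be compared on identical partitions.
#'
#' @param ids character vector of line IDs (or an integer n)
#' @param k number of folds (>= 2)
#' @param reps number of replicates (>= 1)
#' @param seed master seed
#' @return list of `reps` fold plans; each is a list with `replicate`,
#'   `seed`, and `fold` (named integer vector mapping line -> fold)
#' @export
make_folds <- function(ids, k = 5L, reps = 20L, seed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) {
    ids <- sprintf("L%03d", seq_len(ids))
  }
  n <- length(ids)
  stopifnot(k >= 2L, reps >= 1L)
  if (n < k) stop("need at least k lines (n = ", n, ", k = ", k, ")")
  rep_seeds <- derive_seeds(seed, reps)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  lapply(seq_len(reps), function(r) {
    perm <- with_seed(rep_seeds[r], sample.int(n))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(k), times = sizes)
    names(fold) <- ids
    list(replicate = r, seed = rep_seeds[r], fold = fold)
  })
}

#' Predictive ability: correlation of predictions with observations
#'
#' Pearson's correlation between predicted genetic values and observed
#' phenotypes of held-out lines. Returns `NA` when either vector is constant
#' (the correlation is undefined); [run_cv()] excludes such folds from the
#' summary with a logged count.
#'
#' @param predicted,observed numeric vectors of equal length >= 3
#' @return correlation in `[-1, 1]`, or `NA` if undefined
#' @export
predictive_ability <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed lengths differ")
  }
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (sd(predicted) == 0 || sd(observed) == 0) return(NA_real_)
  cor(predicted, observed)
}

#' Replicated cross-validated predictive ability of a model
#'
#' Runs `reps` replicates of k-fold cross-validation. Kernels are built once
#' from all lines' predictors (genotype and expression are predictors, not
#' responses, so this leaks no phenotype information); within each fold the
#' model is fitted by REML on the training block only and held-out lines are
#' predicted through the kernel cross-blocks ([blup_predict()]). One
#' predictive ability is computed per (replicate, fold), giving `reps * k`
#' values; the summary is their mean and standard deviation. Folds where the
#' fit does not converge or the correlation is undefined are excluded from
#' the summary and counted.
#'
#' @inheritParams fit_model
#' @param k folds per replicate (default 5)
#' @param reps replicates (default 20)
#' @param seed master seed driving all fold assignments
#' @param kernels optional pre-built kernel list (as from
#'   [build_model_kernels()]) to reuse across calls
#' @param reml_opts list of options passed to [reml_fit()]
#' @return object of class `cv_result`: `table` (data.frame replicate, fold,
#'   ability, converged), `mean`, `sd`, `n_excluded`, `model`, `bandwidth`
#' @export
run_cv <- function(dataset, model, trait, k = 5L, reps = 20L, seed = 1L,
                   bandwidth = NULL, kernels = NULL, reml_opts = list()) {
  model <- match_model(model)
  y <- trait_vector(dataset, trait)
  n <- length(y)
  if (is.null(kernels)) {
    kernels <- build_model_kernels(dataset, model, bandwidth)
  }
  kernels <- lapply(kernels, function(kk) {
    kk <- unclass(as.matrix(kk))[names(y), names(y), drop = FALSE]
    check_psd(kk)
    kk
  })
  plans <- make_folds(names(y), k = k, reps = reps, seed = seed)
  rows <- vector("list", reps * k)
  i <- 0L
  for (plan in plans) {
    for (f in seq_len(k)) {
      i <- i + 1L
      test <- which(plan$fold == f)
      train <- which(plan$fold != f)
      fit <- tryCatch(
        do.call(reml_fit,
                c(list(y = y[train],
                       kernels = lapply(kernels, function(kk)
                         kk[train, train, drop = FALSE]),
                       model = model, check_psd = FALSE),
                  reml_opts)),
        error = function(e) NULL)
      ability <- NA_real_
      conv <- FALSE
      if (!is.null(fit) && fit$converged) {
        conv <- TRUE
        pred <- blup_predict(fit, kernels, train, test)
        ability <- predictive_ability(pred, y[test])
      }
      rows[[i]] <- data.frame(replicate = plan$replicate, fold = f,
                              ability = ability, converged = conv)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$ability)
  if (sum(!ok) > 0L) {
    message(sprintf("run_cv(%s): %d of %d folds excluded from summary",
                    model, sum(!ok), nrow(tab)))
  }
  structure(list(table = tab,
                 mean = mean(tab$ability[ok]),
                 sd = sd(tab$ability[ok]),
                 n_excluded = sum(!ok),
                 model = model, trait = trait, k = k, reps = reps,
                 seed = seed, bandwidth = bandwidth),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s%s]: %d x %d-fold, mean ability %.4f (sd %.4f)%s\n",
              x$model,
              if (is.null(x$bandwidth)) "" else sprintf(", h = %.4g",
                                                        x$bandwidth),
              x$reps, x$k, x$mean, x$sd,
              if (x$n_excluded > 0L) sprintf(", %d fold(s) excluded",
                                             x$n_excluded) else ""))
  invisible(x)
}

#' Grid search for the Gaussian kernel bandwidth
#'
#' Runs [run_cv()] once per candidate bandwidth on *identical* fold plans
#' (same master seed) and selects the bandwidth maximizing the mean
#' predictive ability; ties are broken toward the smaller bandwidth. The
#' selected bandwidth's `cv_result` is returned alongside the full grid
#' summary. The search nests inside the same fold plans later used for model
#' comparison, which is mildly optimistic for the Gaussian-kernel models;
#' see the methods vignette.
#'
#' @inheritParams run_cv
#' @param grid vector of candidate bandwidths (default:
#'   [default_bandwidth_grid()] of the standardized expression)
#' @return list: `bandwidth` (selected h), `cv` (its [run_cv()] result),
#'   `grid` (data.frame h, mean_ability, sd_ability)
#' @export
grid_search_bandwidth <- function(dataset, model = "rkhs", trait,
                                  grid = NULL, k = 5L, reps = 20L,
                                  seed = 1L, reml_opts = list()) {
  model <- match_model(model)
  if (!"K" %in% MODEL_KERNELS[[model]]) {
    stop("model '", model, "' has no Gaussian kernel to tune")
  }
  r <- standardize_expression(dataset$expression)
  if (is.null(grid)) grid <- default_bandwidth_grid(r)
  grid <- sort(unique(as.numeric(grid)))
  if (!length(grid) || any(!is.finite(grid)) || any(grid <= 0)) {
    stop("bandwidth grid must be non-empty, finite and strictly positive")
  }
  results <- vector("list", length(grid))
  base_kernels <- build_model_kernels(dataset, model,
                                      bandwidth = grid[1L])
  for (i in seq_along(grid)) {
    kernels <- base_kernels
    kernels$v <- gaussian_kernel(r, grid[i])
    results[[i]] <- tryCatch(
      run_cv(dataset, model, trait, k = k, reps = reps, seed = seed,
             bandwidth = grid[i], kernels = kernels,
             reml_opts = reml_opts),
      error = function(e) NULL)
  }
  means <- vapply(results, function(r) {
    if (is.null(r) || !is.finite(r$mean)) -Inf else r$mean
  }, numeric(1L))
  ok <- is.finite(means)
  if (!any(ok)) stop("cross-validation failed for every grid value")
  best <- which(means == max(means))[1L]   # grid sorted: ties -> smaller h
  list(bandwidth = grid[best], cv = results[[best]],
       grid = data.frame(h = grid,
                         mean_ability = ifelse(ok, means, NA_real_),
                         sd_ability = vapply(results, function(r)
                           if (is.null(r)) NA_real_ else r$sd, numeric(1L))))
}

#' Tukey HSD comparison of model predictive abilities
#'
#' Treats the per-(replicate, fold) predictive abilities of each model as
#' groups of a one-way layout and performs all pairwise comparisons with
#' studentized-range (Tukey-Kramer) adjustment. The models share fold plans,
#' so the observations are positively correlated across groups; the plain
#' one-way treatment ignores that pairing and is therefore conservative for
#' between-model contrasts.
#'
#' @param abilities named list of numeric vectors (one per model), or a
#'   named list of `cv_result` objects
#' @param conf.level confidence level for the adjusted intervals
#' @return data.frame of class `model_comparison` with one row per pair:
#'   `pair`, `diff` (first minus second), `lwr`, `upr`, `p_adj`
#' @export
tukey_hsd <- function(abilities, conf.level = 0.95) {
  if (all(vapply(abilities, inherits, logical(1L), "cv_result"))) {
    abilities <- lapply(abilities, function(r)
      r$table$ability[!is.na(r$table$ability)])
  }
  stopifnot(is.list(abilities), !is.null(names(abilities)))
  m <- length(abilities)
  if (m < 2L) stop("need at least 2 models to compare")
  ns <- lengths(abilities)
  means <- vapply(abilities, mean, numeric(1L))
  df <- sum(ns) - m
  mse <- sum(vapply(abilities, function(x) sum((x - mean(x))^2),
                    numeric(1L))) / df
  pairs <- utils::combn(names(abilities), 2L)
  qcrit <- qtukey(conf.level, m, df)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- means[a] - means[b]
    se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
    data.frame(pair = paste(a, b, sep = "-"),
               diff = unname(d),
               lwr = unname(d - qcrit * se),
               upr = unname(d + qcrit * se),
               p_adj = ptukey(abs(d) / se, m, df, lower.tail = FALSE))
  }))
  class(out) <- c("model_comparison", class(out))
  out
}
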