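test_that("fold plans are balanced partitions, deterministic in the master seed", {
  ids <- sprintf("L%03d", 1:185)
  plans <- make_folds(ids, k = 5, reps = 20, seed = 7)
  expect_length(plans, 20L)
  for (plan in plans) {
    expect_setequal(names(plan$fold), ids)              # covers all lines
    expect_true(all(as.integer(table(plan$fold)) == 37L))            # 185 / 5 exactly
  }
  # fold sizes differ by at most one when n is not divisible by k
  p7 <- make_folds(7, k = 5, reps = 3, seed = 1)
  for (plan in p7) {
    expect_equal(sort(as.integer(table(plan$fold))), c(1L, 1L, 1L, 2L, 2L))
  }
  # same master seed -> identical plans; different seed -> different
  expect_identical(make_folds(ids, 5, 20, seed = 7), plans)
  expect_false(identical(make_folds(ids, 5, 20, seed = 8), plans))
  expect_error(make_folds(3, k = 5, reps = 1, seed = 1), "at least k")
})

test_that("predictive ability is Pearson correlation with NA for constants", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(predictive_ability(x, x), 1.0)
  expect_equal(predictive_ability(-x, x), -1.0)
  expect_true(is.na(predictive_ability(rep(1, 5), x)))
  expect_error(predictive_ability(1:4, 1:5), "lengths differ")
  expect_error(predictive_ability(1:2, 2:1), "at least 3")
  # invariance to positive affine transforms of predictions
  y <- rnorm(20)
  p <- y + rnorm(20)
  expect_equal(predictive_ability(2.3 * p + 7, y), predictive_ability(p, y),
               tolerance = 1e-12)
})

test_that("run_cv produces reps*k abilities, reproducibly, with disjoint folds", {
  sim <- simulate_dataset(n_lines = 80, n_markers = 200, n_genes = 50,
                          seed = 91)
  cv1 <- run_cv(sim$dataset, "gblup", "trait", k = 4, reps = 3, seed = 5)
  expect_equal(nrow(cv1$table), 12L)
  expect_equal(cv1$table$replicate, rep(1:3, each = 4))
  ok <- !is.na(cv1$table$ability)
  expect_equal(cv1$mean, mean(cv1$table$ability[ok]))
  # bit-identical rerun under the same master seed
  cv2 <- run_cv(sim$dataset, "gblup", "trait", k = 4, reps = 3, seed = 5)
  expect_identical(cv1$table, cv2$table)
})

test_that("strong simulated signal yields high cross-validated ability", {
  sim <- simulate_dataset(n_lines = 400, n_markers = 400, n_genes = 40,
                          additive = 0.8, mediated = 0, residual = 0.2,
                          seed = 101)
  cv <- run_cv(sim$dataset, "gblup", "trait", k = 5, reps = 2, seed = 11)
  expect_gt(cv$mean, 0.5)
  expect_lt(cv$mean, 0.95)
})

test_that("null phenotypes give cross-validated ability near zero", {
  sim <- simulate_dataset(n_lines = 120, n_markers = 200, n_genes = 40,
                          additive = 0, mediated = 0, residual = 1,
                          seed = 111)
  cv <- suppressMessages(run_cv(sim$dataset, "gblup", "trait", k = 5,
                                reps = 6, seed = 13))
  ok <- !is.na(cv$table$ability)
  # under pure noise many folds hit the zero-variance boundary and are
  # excluded; the remaining abilities must sit in the null band
  expect_gte(sum(ok), 1L)
  se <- sd(cv$table$ability[ok]) / sqrt(sum(ok))
  expect_lt(abs(cv$mean), 2 * se + 0.1)
})

test_that("bandwidth grid search shares fold plans and prefers the generative h", {
  sim <- simulate_dataset(n_lines = 90, n_markers = 150, n_genes = 30,
                          seed = 121)
  r <- standardize_expression(sim$dataset$expression)
  h_star <- mean_sq_distance(r)
  # phenotype regenerated through the Gaussian kernel at h_star each time;
  # grid points are spaced x20 so they are distinguishable above CV noise
  K <- gaussian_kernel(r, h_star)
  d2 <- sim$dataset
  hits <- 0L
  for (s in 1:5) {
    y <- draw_from_model(list(K), 1, 0.25, seed = 2000 + s)
    d2$phenotypes$trait <- unname(y)
    gs <- suppressMessages(grid_search_bandwidth(
      d2, "rkhs", "trait", grid = c(h_star / 20, h_star, 20 * h_star),
      k = 5, reps = 3, seed = 300 + s))
    if (isTRUE(all.equal(gs$bandwidth, h_star))) hits <- hits + 1L
    expect_equal(nrow(gs$cv$table), 15L)
  }
  expect_gte(hits, 3L)                                  # majority of 5 seeds
  # a single-value grid returns that value
  gs1 <- grid_search_bandwidth(d2, "rkhs", "trait", grid = h_star,
                               k = 5, reps = 1, seed = 3)
  expect_equal(gs1$bandwidth, h_star)
  expect_error(grid_search_bandwidth(d2, "gblup", "trait"), "no Gaussian")
  expect_error(grid_search_bandwidth(d2, "rkhs", "trait", grid = -1),
               "positive")
})

test_that("tukey_hsd matches the reference implementation and behaves at the null", {
  set.seed(33)
  groups <- list(a = rnorm(40, 0.2, 0.05), b = rnorm(40, 0.25, 0.05),
                 c = rnorm(40, 0.2, 0.05))
  mine <- tukey_hsd(groups)
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = data.frame(
    y = unlist(groups),
    g = factor(rep(names(groups), lengths(groups))))))$g
  # reference rows are b-a, c-a, c-b with opposite sign convention
  expect_equal(mine$diff, -unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(sort(c(mine$lwr, mine$upr)),
               sort(unname(c(-ref[, "upr"], -ref[, "lwr"]))),
               tolerance = 1e-10)

  # identical tables: zero difference, p ~ 1
  same <- tukey_hsd(list(m1 = groups$a, m2 = groups$a))
  expect_equal(same$diff, 0)
  expect_gt(same$p_adj, 0.999)

  # strongly separated groups: tiny adjusted p
  big <- tukey_hsd(list(lo = rnorm(100, 0.2, 0.01),
                        hi = rnorm(100, 0.3, 0.01)))
  expect_lt(big$p_adj, 1e-3)

  expect_error(tukey_hsd(list(only = rnorm(10))), "at least 2")
})

test_that("tukey_hsd keeps type-I error near nominal under the null", {
  set.seed(55)
  rejections <- 0L
  for (i in 1:100) {
    fam <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    if (any(tukey_hsd(fam)$p_adj < 0.05)) rejections <- rejections + 1L
  }
  expect_lte(rejections, 10L)
})

test_that("tukey_hsd difference antisymmetry holds across orderings", {
  set.seed(66)
  g <- list(x = rnorm(20), y = rnorm(20, 0.3))
  ab <- tukey_hsd(g)
  ba <- tukey_hsd(rev(g))
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  expect_equal(ab$p_adj, ba$p_adj, tolerance = 1e-12)
})
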