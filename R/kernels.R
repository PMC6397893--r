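#' Construct a labeled kernel matrix
#'
#' Wraps an n x n similarity matrix with line IDs, a label (`"G"`, `"E"`,
#' `"K"` or `"custom"`) and construction metadata. Symmetry is enforced at
#' construction; positive semidefiniteness can be asserted with
#' [check_psd()].
#'
#' @param values symmetric numeric matrix with line IDs as dimnames
#' @param label kernel label
#' @param metadata named list (e.g. bandwidth `h`, VanRaden denominator)
#' @return matrix of class `kernel_matrix` with attributes `label`,
#'   `metadata`
#' @export
kernel_matrix <- function(values, label = "custom", metadata = list()) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-10) {
    stop("kernel matrix is not symmetric (tolerance 1e-10)")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- sprintf("L%03d",
                                                    seq_len(nrow(values)))
  }
  values <- (values + t(values)) / 2
  structure(values, label = label, metadata = metadata,
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix [%s]: %d x %d lines\n",
              attr(x, "label"), nrow(x), ncol(x)))
  invisible(x)
}

#' Assert that a kernel is positive semidefinite
#'
#' Checks that the smallest eigenvalue is at least `-tol` times the largest.
#'
#' @param K symmetric matrix
#' @param tol relative tolerance (default 1e-8)
#' @return `K`, invisibly; error if the check fails
#' @export
check_psd <- function(K, tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  hi <- max(abs(ev))
  if (hi > 0 && lo < -tol * hi) {
    stop(sprintf("kernel is not positive semidefinite (min eigenvalue %.3e, max %.3e)",
                 lo, hi))
  }
  invisible(K)
}

#' Center marker dosages by twice the allele frequency
#'
#' Column j of the centered matrix `Z` is `dosage_j - 2 * p_j`, where `p_j`
#' is the counted-allele frequency, giving entries `-2p`, `1 - 2p`, `2 - 2p`
#' for dosages 0, 1, 2. Heterozygous dosage 1 is supported even though fully
#' inbred panels carry only the homozygote entries.
#'
#' @param g a [genotype_matrix()] without missing values (run [impute_mean()]
#'   first)
#' @return object of class `centered_genotypes` with fields `Z` and `p`
#' @export
center_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosages)) {
    stop("genotypes contain missing values; run impute_mean() first")
  }
  Z <- sweep(g$dosages, 2L, 2 * g$freqs)
  structure(list(Z = Z, p = g$freqs), class = "centered_genotypes")
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))` from centered dosages. G is
#' invariant to swapping allele labels at any marker (dosage `d -> 2 - d`,
#' `p -> 1 - p` flips the sign of that Z column), so minor- versus
#' alternate-allele orientation does not matter.
#'
#' @param z a [center_genotypes()] result
#' @return [kernel_matrix()] with label `"G"`; the denominator is stored in
#'   the metadata
#' @export
vanraden_g <- function(z) {
  stopifnot(inherits(z, "centered_genotypes"))
  denom <- 2 * sum(z$p * (1 - z$p))
  if (denom <= 0) {
    stop("zero denominator: all markers are monomorphic")
  }
  G <- tcrossprod(z$Z) / denom
  kernel_matrix(G, label = "G", metadata = list(denominator = denom))
}

#' Linear expression kernel
#'
#' `E = R R'` from column-standardized expression. No further scaling is
#' applied by default (any overall scale is absorbed by the transcriptomic
#' variance component); set `normalize = TRUE` to rescale to mean diagonal 1
#' for numerical comparability with G.
#'
#' @param r a [standardize_expression()] result (n x m matrix)
#' @param normalize rescale so that `mean(diag(E)) == 1` (default `FALSE`)
#' @return [kernel_matrix()] with label `"E"`
#' @export
linear_expression_kernel <- function(r, normalize = FALSE) {
  r <- as.matrix(r)
  E <- tcrossprod(r)
  meta <- list(n_genes = ncol(r), normalized = normalize)
  if (normalize) E <- E / mean(diag(E))
  kernel_matrix(E, label = "E", metadata = meta)
}

#' Gaussian expression kernel
#'
#' `K_ij = exp(-||r_i - r_j||^2 / h)` on the rows (line profiles) of the
#' standardized expression matrix, with bandwidth `h > 0`. The diagonal is
#' exactly 1 and entries decrease monotonically with distance; large `h`
#' drives all entries to 1.
#'
#' @param r standardized expression matrix (lines x genes)
#' @param h positive bandwidth; larger values give slower similarity decay
#' @return [kernel_matrix()] with label `"K"`; `h` is stored in the metadata
#' @export
gaussian_kernel <- function(r, h) {
  stopifnot(is.numeric(h), length(h) == 1L)
  if (!is.finite(h) || h <= 0) stop("bandwidth h must be a positive number")
  r <- as.matrix(r)
  sq <- rowSums(r^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(r)
  d2[d2 < 0] <- 0                       # numerical negatives
  K <- exp(-d2 / h)
  diag(K) <- 1
  kernel_matrix(K, label = "K", metadata = list(bandwidth = h))
}

#' Mean pairwise squared distance between expression profiles
#'
#' The data-adaptive scale used to anchor the default bandwidth grid: the
#' mean of `||r_i - r_j||^2` over all unordered line pairs.
#'
#' @param r standardized expression matrix
#' @return positive scalar
#' @export
mean_sq_distance <- function(r) {
  r <- as.matrix(r)
  sq <- rowSums(r^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(r)
  mean(d2[upper.tri(d2)])
}

#' Default logarithmic bandwidth grid
#'
#' 13 log-spaced values from `0.1 * d` to `100 * d`, where `d` is the mean
#' pairwise squared distance of the expression profiles. The grid adapts to
#' the dimensionality of the data: squared distances grow linearly with the
#' number of standardized genes, and useful bandwidths track that scale.
#'
#' @param r standardized expression matrix
#' @param length.out number of grid points (default 13)
#' @return numeric vector of bandwidths
#' @export
default_bandwidth_grid <- function(r, length.out = 13L) {
  d <- mean_sq_distance(r)
  if (!is.finite(d) || d <= 0) stop("degenerate expression distances")
  exp(seq(log(0.1 * d), log(100 * d), length.out = length.out))
}

# add ridge eps*I when a factorization needs it; logged by callers
add_jitter <- function(V, eps = 1e-8) {
  V + diag(eps * mean(diag(V)), nrow(V))
}
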