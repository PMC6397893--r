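#' Filter markers by missing rate and minor allele frequency
#'
#' A marker is kept when its call rate is at least `1 - max_missing` *and*
#' its minor allele frequency `min(p, 1 - p)` is at least `min_maf`
#' (boundaries inclusive: exclusion applies to rates strictly below / MAF
#' strictly below the thresholds). Allele frequencies are recomputed on the
#' retained data.
#'
#' @param g a [genotype_matrix()]
#' @param max_missing maximum tolerated per-marker missing fraction
#'   (default 0.05, i.e. call rate of at least 95 percent)
#' @param min_maf minimum minor allele frequency (default 0.01)
#' @return filtered [genotype_matrix()]; attribute `"report"` holds counts of
#'   markers removed per criterion
#' @export
filter_markers <- function(g, max_missing = 0.05, min_maf = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"),
            max_missing >= 0, max_missing < 1,
            min_maf >= 0, min_maf <= 0.5)
  miss <- colMeans(is.na(g$dosages))
  maf <- pmin(g$freqs, 1 - g$freqs)
  keep_call <- miss <= max_missing
  keep_maf <- !is.na(maf) & maf >= min_maf
  keep <- keep_call & keep_maf
  if (!any(keep)) stop("no markers pass filters")
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE], validate = FALSE)
  attr(out, "report") <- list(
    markers_removed_callrate = sum(!keep_call),
    markers_removed_maf = sum(keep_call & !keep_maf),
    markers_retained = sum(keep))
  out
}

#' Filter lines by genotype call rate
#'
#' A line is kept when its fraction of missing calls is at most
#' `max_missing`. Marker frequencies are recomputed on the retained lines.
#'
#' @inheritParams filter_markers
#' @return filtered [genotype_matrix()]; attribute `"report"` holds the
#'   number of lines removed
#' @export
filter_lines <- function(g, max_missing = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"), max_missing >= 0, max_missing < 1)
  miss <- rowMeans(is.na(g$dosages))
  keep <- miss <= max_missing
  if (!any(keep)) stop("no lines pass filters")
  out <- genotype_matrix(g$dosages[keep, , drop = FALSE], validate = FALSE)
  attr(out, "report") <- list(lines_removed = sum(!keep),
                              lines_retained = sum(keep))
  out
}

#' Mean-impute missing genotype calls
#'
#' Each missing dosage is replaced by the marker's mean dosage `2 * p`
#' computed over non-missing calls, so the per-marker mean dosage is
#' preserved exactly. Post-imputation dosages may be non-integer; downstream
#' centering handles real-valued dosages.
#'
#' @param g a [genotype_matrix()]
#' @return [genotype_matrix()] without missing values
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (!anyNA(d)) return(g)
  all_missing <- colSums(!is.na(d)) == 0L
  if (any(all_missing)) {
    stop("marker(s) with zero non-missing calls: ",
         paste(colnames(d)[all_missing][seq_len(min(3L, sum(all_missing)))],
               collapse = ", "))
  }
  fill <- 2 * g$freqs
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- fill[idx[, 2L]]
  genotype_matrix(d, validate = FALSE)
}

#' Column-standardize gene expression levels
#'
#' Each gene column is centered by its mean across lines and divided by its
#' sample standard deviation (n - 1 denominator):
#' `r_ij = (x_ij - mean_j) / sd_j`. Genes with zero variance cannot be
#' standardized and are dropped with a warning.
#'
#' @param x an [expression_matrix()] (or numeric matrix), >= 2 lines
#' @return matrix `R` of class `standardized_expression`; attributes
#'   `"center"`, `"scale"` hold the per-gene mean and sd used and
#'   `"dropped"` the IDs of constant genes removed
#' @export
standardize_expression <- function(x) {
  m <- unclass(as.matrix(x))
  if (nrow(m) < 2L) stop("standardization needs >= 2 lines (sd undefined)")
  if (anyNA(m)) stop("expression matrix must not contain missing values")
  mu <- colMeans(m)
  s <- apply(m, 2L, sd)
  constant <- s == 0
  if (all(constant)) stop("all genes are constant; nothing to standardize")
  if (any(constant)) {
    warning(sprintf("dropping %d constant gene(s): %s", sum(constant),
                    paste(utils::head(colnames(m)[constant], 3L),
                          collapse = ", ")))
  }
  keep <- !constant
  r <- sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep]), 2L, s[keep], "/")
  structure(r, center = mu[keep], scale = s[keep],
            dropped = colnames(m)[constant],
            class = c("standardized_expression", "matrix", "array"))
}
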