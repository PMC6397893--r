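#' Simulate genotypes of fully inbred lines
#'
#' Emulates a panel of fully homozygous lines (such as those produced by
#' ~20 generations of full-sib inbreeding): each marker draws a counted-allele
#' frequency `q ~ Uniform[maf_range]` and each line carries dosage 2 with
#' probability `q`, else 0 — no heterozygotes, and markers are independent
#' (no linkage disequilibrium by default; see the methods vignette).
#'
#' @param n_lines number of lines (>= 2)
#' @param n_markers number of markers (>= 1)
#' @param maf_range bounds of the uniform allele-frequency distribution;
#'   the default lower bound 0.05 keeps simulated panels comfortably inside
#'   the standard post-filter regime (MAF >= 0.01)
#' @param seed RNG seed
#' @return a [genotype_matrix()] with dosages in `{0, 2}`
#' @export
simulate_genotypes <- function(n_lines = 200L, n_markers = 1000L,
                               maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(n_lines >= 2L, n_markers >= 1L, length(maf_range) == 2L)
  if (maf_range[1L] < 0 || maf_range[2L] > 1 ||
      maf_range[1L] > maf_range[2L]) {
    stop("invalid maf_range")
  }
  with_seed(seed, {
    q <- runif(n_markers, maf_range[1L], maf_range[2L])
    d <- matrix(2 * rbinom(n_lines * n_markers, 1L,
                           rep(q, each = n_lines)),
                nrow = n_lines, ncol = n_markers,
                dimnames = list(sprintf("L%03d", seq_len(n_lines)),
                                sprintf("M%05d", seq_len(n_markers))))
    g <- genotype_matrix(d, validate = FALSE)
    attr(g, "true_freqs") <- q
    g
  })
}

#' Simulate expression levels partly driven by genotype
#'
#' Each gene is a linear combination of a few causal markers (cis-like
#' additive effects on centered dosages), optionally plus
#' additive-by-additive epistatic terms (products of centered dosages of
#' marker pairs), plus Gaussian noise. The epistatic encoding is invisible
#' to the additive genomic kernel but expressible through expression
#' columns, which is exactly the signal the transcriptome kernels are meant
#' to capture.
#'
#' @param geno a complete [genotype_matrix()]
#' @param n_genes number of genes
#' @param n_causal causal markers per gene (additive; may be 0)
#' @param cis_scale sd of the additive marker-on-gene effects
#' @param n_epistatic epistatic marker pairs per gene (may be 0)
#' @param epistatic_scale sd of the pair-effect sizes
#' @param noise_sd sd of the independent expression noise
#' @param seed RNG seed
#' @return list: `expression` ([expression_matrix()]), `truth` (per-gene
#'   causal markers, pairs and effects)
#' @export
simulate_expression <- function(geno, n_genes = 200L, n_causal = 2L,
                                cis_scale = 1, n_epistatic = 1L,
                                epistatic_scale = 1, noise_sd = 1,
                                seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$dosages)) stop("genotypes must be complete")
  nm <- ncol(geno$dosages)
  if (n_causal > nm) stop("n_causal exceeds the number of markers")
  if (n_epistatic > 0L && nm < 2L) stop("epistasis needs >= 2 markers")
  Z <- center_genotypes(geno)$Z
  n <- nrow(Z)
  with_seed(seed, {
    expr <- matrix(0, n, n_genes,
                   dimnames = list(rownames(Z),
                                   sprintf("G%05d", seq_len(n_genes))))
    truth <- vector("list", n_genes)
    for (j in seq_len(n_genes)) {
      col <- rnorm(n, 0, noise_sd)
      cis <- integer(0); a <- numeric(0)
      if (n_causal > 0L) {
        cis <- sample.int(nm, n_causal)
        a <- rnorm(n_causal, 0, cis_scale)
        col <- col + drop(Z[, cis, drop = FALSE] %*% a)
      }
      pairs <- matrix(integer(0), ncol = 2L); b <- numeric(0)
      if (n_epistatic > 0L) {
        pairs <- t(replicate(n_epistatic, sample.int(nm, 2L)))
        b <- rnorm(n_epistatic, 0, epistatic_scale)
        for (e in seq_len(n_epistatic)) {
          col <- col + b[e] * Z[, pairs[e, 1L]] * Z[, pairs[e, 2L]]
        }
      }
      expr[, j] <- col
      truth[[j]] <- list(cis_markers = cis, cis_effects = a,
                         epistatic_pairs = pairs, epistatic_effects = b)
    }
    list(expression = expression_matrix(expr), truth = truth)
  })
}

#' Simulate a phenotype with controlled variance shares
#'
#' Builds `y = mu + additive + mediated + residual`: the additive term is a
#' polygenic combination of centered dosages, the mediated term a linear
#' combination of standardized expression columns, the residual independent
#' Gaussian noise. Each term is rescaled post hoc to an empirical standard
#' deviation of `sqrt(share)`, so the realized share of each term in the sum
#' of term variances matches its target exactly (at the cost of slightly
#' distorting the effect-size distribution; see the methods vignette).
#'
#' @param geno complete [genotype_matrix()]
#' @param expr [expression_matrix()] on the same lines
#' @param additive target additive (marker-driven) variance share
#' @param mediated target expression-mediated variance share
#' @param residual target residual share (default `1 - additive - mediated`)
#' @param mean intercept of the trait
#' @param seed RNG seed
#' @return list: `y` (named numeric vector), `truth` (scaled effect vectors,
#'   the three terms, and `realized_shares`)
#' @export
simulate_phenotype <- function(geno, expr, additive = 0.4, mediated = 0.3,
                               residual = NULL, mean = 0, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(residual)) residual <- 1 - additive - mediated
  shares <- c(additive = additive, mediated = mediated, residual = residual)
  if (any(shares < 0)) stop("variance shares must be non-negative")
  if (sum(shares) > 1 + 1e-12) stop("variance shares sum to more than 1")
  if (sum(shares) == 0) stop("at least one variance share must be positive")
  Z <- center_genotypes(geno)$Z
  n <- nrow(Z)
  if (!identical(rownames(Z), rownames(expr))) {
    stop("genotype and expression line IDs differ")
  }
  scale_to <- function(v, share) {
    if (share == 0) return(list(term = numeric(n) * 0, factor = 0))
    s <- sd(v)
    if (s == 0) stop("degenerate term with zero variance; cannot scale")
    list(term = v / s * sqrt(share), factor = sqrt(share) / s)
  }
  with_seed(seed, {
    a_raw <- rnorm(ncol(Z))
    add <- scale_to(drop(Z %*% a_raw), additive)
    R <- standardize_expression(expr)
    b_raw <- rnorm(ncol(R))
    med <- scale_to(drop(unclass(R) %*% b_raw), mediated)
    res <- scale_to(rnorm(n), residual)
    y <- mean + add$term + med$term + res$term
    names(y) <- rownames(Z)
    vars <- c(additive = var(add$term), mediated = var(med$term),
              residual = var(res$term))
    list(y = y,
         truth = list(marker_effects = a_raw * add$factor,
                      gene_effects = b_raw * med$factor,
                      terms = list(additive = add$term,
                                   mediated = med$term,
                                   residual = res$term),
                      target_shares = shares,
                      realized_shares = vars / sum(vars),
                      var_y = var(y)))
  })
}

#' Simulate a complete aligned dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_expression()] and [simulate_phenotype()] under seeds derived
#' from one master seed, returning an [make_dataset()] object with one trait
#' named `"trait"` plus the simulation truth.
#'
#' @param n_lines,n_markers,maf_range passed to [simulate_genotypes()]
#' @param n_genes,n_causal,cis_scale,n_epistatic,epistatic_scale,noise_sd
#'   passed to [simulate_expression()]
#' @param additive,mediated,residual passed to [simulate_phenotype()]
#' @param seed master seed
#' @return list: `dataset` (an `omic_dataset`), `truth`
#' @export
simulate_dataset <- function(n_lines = 200L, n_markers = 1000L,
                             maf_range = c(0.05, 0.5), n_genes = 200L,
                             n_causal = 2L, cis_scale = 1,
                             n_epistatic = 1L, epistatic_scale = 1,
                             noise_sd = 1, additive = 0.4, mediated = 0.3,
                             residual = NULL, seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  geno <- simulate_genotypes(n_lines, n_markers, maf_range, seed = seeds[1L])
  ex <- simulate_expression(geno, n_genes = n_genes, n_causal = n_causal,
                            cis_scale = cis_scale,
                            n_epistatic = n_epistatic,
                            epistatic_scale = epistatic_scale,
                            noise_sd = noise_sd, seed = seeds[2L])
  ph <- simulate_phenotype(geno, ex$expression, additive = additive,
                           mediated = mediated, residual = residual,
                           seed = seeds[3L])
  phen <- data.frame(trait = unname(ph$y), row.names = names(ph$y))
  list(dataset = make_dataset(genotypes = geno, expression = ex$expression,
                              phenotypes = phen),
       truth = list(expression = ex$truth, phenotype = ph$truth))
}
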