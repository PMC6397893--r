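#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds line-by-marker allele dosages (counts of the
#' counted allele, usually the minor allele) with `NA` marking missing calls,
#' together with the per-marker counted-allele frequency computed over
#' non-missing calls.
#'
#' @param dosages numeric matrix, lines in rows, markers in columns; entries
#'   in `[0, 2]` (integer `{0, 1, 2}` before imputation) or `NA`
#' @param validate check that entries lie in `[0, 2]`
#' @return an object of class `genotype_matrix` with fields `dosages` and
#'   `freqs`
#' @export
genotype_matrix <- function(dosages, validate = TRUE) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("L%03d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("M%05d", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(rownames(dosages))) {
    stop("duplicate line ID: ",
         rownames(dosages)[duplicated(rownames(dosages))][1L])
  }
  if (validate) {
    bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(dosages))
      stop(sprintf("dosage outside [0, 2] at line '%s', marker '%s'",
                   rownames(dosages)[rc[1L]], colnames(dosages)[rc[2L]]))
    }
  }
  structure(list(dosages = dosages, freqs = marker_freqs(dosages)),
            class = "genotype_matrix")
}

# counted-allele frequency per marker over non-missing calls
marker_freqs <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %d missing calls\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Line identifiers of an object
#' @param x a `genotype_matrix`, expression matrix, kernel matrix or dataset
#' @return character vector of line IDs
#' @export
line_ids <- function(x) UseMethod("line_ids")

#' @export
line_ids.genotype_matrix <- function(x) rownames(x$dosages)

#' @export
line_ids.default <- function(x) rownames(x)

#' Read genotypes from TSV or VCF
#'
#' TSV: tab-separated, header row of marker IDs, first column line IDs, cells
#' in `{0, 1, 2, NA}` counting copies of the counted allele. VCF: a minimal
#' biallelic dialect with a GT field; the dosage counts the *minor* allele at
#' each site (sites where the alternate allele is the major one are flipped).
#' The genomic relationship matrix is invariant to which allele is counted,
#' because swapping allele labels at a marker only flips the sign of its
#' centered column.
#'
#' @param path file path
#' @param format `"tsv"`, `"vcf"`, or `"auto"` (by file extension)
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = "NA")
  if (ncol(tab) < 2L) stop("genotype TSV needs line IDs plus >= 1 marker")
  ids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)))
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  nonnum <- which(!is.na(raw) & is.na(m))
  bad <- sort(unique(c(bad, nonnum)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("genotype parse error at row %d, column '%s': value '%s' not in {0,1,2,NA}",
                 rc[1L], colnames(m)[rc[2L]], raw[bad[1L]]))
  }
  rownames(m) <- ids
  genotype_matrix(m)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))    # single-record VCF
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    i <- which(multi)[1L]
    stop(sprintf("multi-allelic VCF record at %s:%s (ALT '%s'); only biallelic sites are supported",
                 fix[i, "CHROM"], fix[i, "POS"], alt[i]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  # count ALT alleles per call; "." anywhere in the call -> missing
  count_alt <- function(cell) {
    if (is.na(cell) || grepl("\\.", cell)) return(NA_real_)
    sum(as.numeric(strsplit(cell, "[/|]")[[1L]]))
  }
  dos <- apply(gt, c(1L, 2L), count_alt)
  bad <- which(!is.na(dos) & !(dos %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(dos))
    stop(sprintf("GT dosage outside {0,1,2} at site '%s', sample '%s'",
                 rownames(dos)[rc[1L]], colnames(dos)[rc[2L]]))
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  rownames(dos) <- ids
  dos <- t(dos)                      # lines x markers
  # flip sites where ALT is the major allele so dosage counts the minor allele
  p_alt <- marker_freqs(dos)
  flip <- !is.na(p_alt) & p_alt > 0.5
  dos[, flip] <- 2 - dos[, flip]
  genotype_matrix(dos)
}

#' Read an expression matrix from TSV
#'
#' Tab-separated, header row of gene IDs, first column line IDs, numeric
#' cells, no missing values.
#'
#' @param path file path
#' @return numeric matrix (lines x genes) of class `expression_matrix`
#' @export
read_expression <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("no features: expression TSV needs >= 1 gene column")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate line ID: ", ids[duplicated(ids)][1L])
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  m <- raw
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("expression parse error at line '%s', gene '%s': value '%s' is not numeric",
                 ids[rc[1L]], colnames(m)[rc[2L]], raw[bad[1L]]))
  }
  rownames(m) <- ids
  expression_matrix(m)
}

#' Construct an expression matrix
#' @param m numeric matrix, lines in rows, genes in columns, no missing values
#' @return `m` with class `expression_matrix`
#' @export
expression_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) == 0L) stop("no features")
  if (anyNA(m)) stop("expression matrix must not contain missing values")
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%03d", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) {
    stop("duplicate line ID: ", rownames(m)[duplicated(rownames(m))][1L])
  }
  if (is.null(colnames(m))) colnames(m) <- sprintf("G%05d", seq_len(ncol(m)))
  class(m) <- c("expression_matrix", class(m))
  m
}

#' Read a line-by-trait phenotype table from TSV
#'
#' Header row of trait names, first column line IDs; `NA` marks a missing
#' phenotype (those lines are excluded per analyzed trait, not globally).
#'
#' @param path file path
#' @return data.frame with line IDs as row names
#' @export
read_phenotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = "NA")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate line ID: ", ids[duplicated(ids)][1L])
  out <- tab[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Write a matrix (kernel, dosage or expression) as labeled TSV
#'
#' Values are written with 17 significant digits so a round-trip reproduces
#' them to double precision.
#'
#' @param m matrix with row and column names
#' @param path output path
#' @param id_header name of the first (row ID) column
#' @export
write_matrix_tsv <- function(m, path, id_header = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m))
  chr[is.na(m)] <- "NA"
  header <- paste(c(id_header, colnames(m)), collapse = "\t")
  body <- paste(rownames(m), apply(chr, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = "NA")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Write / read a kernel matrix as TSV
#'
#' The file carries line IDs in both the header row and the first column. On
#' read, symmetry is enforced (max |K_ij - K_ji| <= 1e-8) and, when
#' `line_ids` is supplied, the matrix is re-aligned to that ordering; an ID
#' set mismatch is an error.
#'
#' @param K kernel matrix (see [kernel_matrix()])
#' @param path file path
#' @return `read_kernel` returns a [kernel_matrix()]
#' @export
write_kernel <- function(K, path) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  write_matrix_tsv(unclass(K), path)
}

#' @rdname write_kernel
#' @param line_ids optional character vector the kernel must be aligned to
#' @param label kernel label to attach (`"G"`, `"E"`, `"K"` or other)
#' @export
read_kernel <- function(path, line_ids = NULL, label = "custom") {
  m <- read_matrix_tsv(path)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("kernel file must be square with identical row and column IDs")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop("kernel read from '", path, "' is not symmetric (tolerance 1e-8)")
  }
  if (!is.null(line_ids)) {
    if (!setequal(rownames(m), line_ids)) {
      missing_ids <- setdiff(line_ids, rownames(m))
      extra_ids <- setdiff(rownames(m), line_ids)
      stop("kernel IDs do not match dataset IDs (",
           length(missing_ids), " missing, ", length(extra_ids), " extra)")
    }
    m <- m[line_ids, line_ids, drop = FALSE]
  }
  m <- (m + t(m)) / 2
  kernel_matrix(m, label = label)
}

#' Assemble an aligned dataset of genotypes, expression and phenotypes
#'
#' Components are aligned on the intersection of their line IDs (sorted, so
#' the result is a pure function of the ID sets). Lines present in one
#' component but absent from another are dropped with a message reporting the
#' count. Per-trait missing phenotypes are retained here and excluded at
#' analysis time.
#'
#' @param genotypes optional [genotype_matrix()]
#' @param expression optional [expression_matrix()]
#' @param phenotypes optional data.frame of traits with line-ID row names
#' @return object of class `omic_dataset` with fields `line_ids`,
#'   `genotypes`, `expression`, `phenotypes`
#' @export
make_dataset <- function(genotypes = NULL, expression = NULL,
                         phenotypes = NULL) {
  id_sets <- list()
  if (!is.null(genotypes)) id_sets$genotypes <- line_ids(genotypes)
  if (!is.null(expression)) id_sets$expression <- rownames(expression)
  if (!is.null(phenotypes)) id_sets$phenotypes <- rownames(phenotypes)
  if (!length(id_sets)) stop("at least one component is required")
  common <- sort(Reduce(intersect, id_sets))
  if (!length(common)) stop("no lines shared across components")
  for (nm in names(id_sets)) {
    dropped <- length(setdiff(id_sets[[nm]], common))
    if (dropped > 0L) {
      message(sprintf("dropping %d line(s) from %s not shared by all components",
                      dropped, nm))
    }
  }
  if (!is.null(genotypes)) {
    genotypes$dosages <- genotypes$dosages[common, , drop = FALSE]
    genotypes$freqs <- marker_freqs(genotypes$dosages)
  }
  if (!is.null(expression)) {
    expression <- expression[common, , drop = FALSE]
    expression <- expression_matrix(as.matrix(expression))
  }
  if (!is.null(phenotypes)) {
    phenotypes <- phenotypes[common, , drop = FALSE]
  }
  structure(list(line_ids = common, genotypes = genotypes,
                 expression = expression, phenotypes = phenotypes),
            class = "omic_dataset")
}

#' @export
print.omic_dataset <- function(x, ...) {
  cat(sprintf("omic_dataset: %d lines\n", length(x$line_ids)))
  if (!is.null(x$genotypes))
    cat(sprintf("  genotypes:  %d markers\n", ncol(x$genotypes$dosages)))
  if (!is.null(x$expression))
    cat(sprintf("  expression: %d genes\n", ncol(x$expression)))
  if (!is.null(x$phenotypes))
    cat(sprintf("  phenotypes: %s\n",
                paste(colnames(x$phenotypes), collapse = ", ")))
  invisible(x)
}

#' @export
line_ids.omic_dataset <- function(x) x$line_ids

# phenotype vector for one trait with per-trait NA lines removed
trait_vector <- function(dataset, trait) {
  if (is.null(dataset$phenotypes)) stop("dataset has no phenotypes")
  if (!trait %in% colnames(dataset$phenotypes)) {
    stop("unknown trait '", trait, "'; available: ",
         paste(colnames(dataset$phenotypes), collapse = ", "))
  }
  y <- dataset$phenotypes[[trait]]
  names(y) <- rownames(dataset$phenotypes)
  y[!is.na(y)]
}
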