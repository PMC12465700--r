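# Readers/writers for genotype, expression, phenotype and kernel files.
# All downstream modules consume only the in-memory classes built here.

# ---- genotype container ------------------------------------------------

#' Construct a genotype matrix object
#'
#' Container for additive SNP dosages (counts of the stored allele, 0/1/2)
#' with per-SNP metadata.  `freq` is the stored-allele frequency; when not
#' supplied it is computed from the dosages as `colMeans(dosages)/2`.  Note
#' this is the coding-allele frequency, not necessarily the *minor* allele
#' frequency.
#'
#' @param dosages n x p numeric matrix of dosages in \{0, 1, 2\}.
#' @param individual_ids,snp_ids row / column identifiers.
#' @param chrom,pos_bp optional per-SNP chromosome label and 1-based
#'   physical position.
#' @param freq optional per-SNP stored-allele frequency in `[0, 1]`.
#' @param report list of load diagnostics (imputed count etc.).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, individual_ids = rownames(dosages),
                        snp_ids = colnames(dosages),
                        chrom = NULL, pos_bp = NULL, freq = NULL,
                        report = list()) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(snp_ids))
    snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  stop_if_not_ids(individual_ids, "individual")
  stop_if_not_ids(snp_ids, "SNP")
  if (anyNA(dosages)) stop("dosages contain missing values after load")
  bad <- which(!(dosages %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(dosages)) + 1
    j <- ((bad[1] - 1) %/% nrow(dosages)) + 1
    stop(sprintf("dosage outside {0,1,2} at individual '%s', SNP '%s': %s",
                 individual_ids[i], snp_ids[j], dosages[bad[1]]))
  }
  if (is.null(freq)) freq <- colMeans(dosages) / 2
  stopifnot(length(freq) == ncol(dosages), all(freq >= 0 & freq <= 1))
  dimnames(dosages) <- list(individual_ids, snp_ids)
  structure(list(individual_ids = individual_ids, snp_ids = snp_ids,
                 dosages = dosages,
                 chrom = chrom %||% rep(NA_character_, ncol(dosages)),
                 pos_bp = pos_bp %||% rep(NA_integer_, ncol(dosages)),
                 freq = unname(freq), report = report),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (length(x$report))
    cat("  load report:",
        paste(names(x$report), unlist(x$report), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Read a genotype dosage file
#'
#' Supports the PLINK `.raw` additive export (header
#' `FID IID PAT MAT SEX PHENOTYPE` then one column per SNP) and a plain TSV
#' with an id column followed by SNP columns.  Missing dosages are imputed
#' to the rounded per-SNP mean and counted in the load report; monomorphic
#' SNPs are counted but kept.
#'
#' @param path file path.
#' @param fmt `"plink_raw"` or `"tsv"`.
#' @param map optional data.frame with columns `snp_id`, `chrom`, `pos_bp`
#'   (1-based) supplying SNP coordinates.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, fmt = c("plink_raw", "tsv"), map = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "plink_raw") {
    dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", "-9"),
                            data.table = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(dt) < 6 || !identical(names(dt)[1:6], need))
      stop("malformed plink_raw header: expected columns ",
           paste(need, collapse = " "))
    if (ncol(dt) == 6) stop("no SNP columns")
    ids <- as.character(dt$IID)
    X <- as.matrix(dt[, -(1:6), drop = FALSE])
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            na.strings = c("NA", ""), data.table = FALSE)
    if (ncol(dt) < 2) stop("no SNP columns")
    ids <- as.character(dt[[1]])
    X <- as.matrix(dt[, -1, drop = FALSE])
  }
  storage.mode(X) <- "double"
  bad <- which(!is.na(X) & !(X %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(X)) + 1
    j <- ((bad[1] - 1) %/% nrow(X)) + 1
    stop(sprintf("dosage outside {0,1,2,NA} at row '%s', column '%s': %s",
                 ids[i], colnames(X)[j], X[bad[1]]))
  }
  n_imputed <- sum(is.na(X))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(X)) > 0)) {
      mj <- mean(X[, j], na.rm = TRUE)
      if (is.nan(mj)) mj <- 0  # all-missing column
      X[is.na(X[, j]), j] <- round(mj)
    }
  }
  freq <- colMeans(X) / 2
  chrom <- pos <- NULL
  if (!is.null(map)) {
    idx <- match(colnames(X), map$snp_id)
    chrom <- as.character(map$chrom[idx])
    pos <- as.integer(map$pos_bp[idx])
  }
  geno_matrix(X, individual_ids = ids, snp_ids = colnames(X),
              chrom = chrom, pos_bp = pos, freq = freq,
              report = list(n_imputed = n_imputed,
                            n_monomorphic = sum(freq == 0 | freq == 1)))
}

#' Write a genotype matrix as TSV (id column + one column per SNP)
#' @param geno a [geno_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(id = geno$individual_ids, geno$dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- expression container ----------------------------------------------

#' Construct a gene-expression matrix object
#'
#' @param values n x m numeric matrix, individuals in rows, genes in columns.
#' @param individual_ids,gene_ids identifiers.
#' @param state one of `"tpm"`, `"log2p1"`, `"standardized"`; records which
#'   transformations have been applied.  Allowed transitions are
#'   tpm -> log2p1 -> standardized.
#' @param gene_chrom,gene_start,gene_end optional per-gene coordinates
#'   (1-based, inclusive).
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, individual_ids = rownames(values),
                        gene_ids = colnames(values),
                        state = c("tpm", "log2p1", "standardized"),
                        gene_chrom = NULL, gene_start = NULL,
                        gene_end = NULL) {
  state <- match.arg(state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  stop_if_not_ids(individual_ids, "individual")
  stop_if_not_ids(gene_ids, "gene")
  if (state == "tpm" && any(values < 0))
    stop("negative TPM value encountered")
  if (state == "standardized" &&
      any(abs(colMeans(values)) > 1e-8))
    stop("standardized expression columns must have mean 0")
  dimnames(values) <- list(individual_ids, gene_ids)
  structure(list(individual_ids = individual_ids, gene_ids = gene_ids,
                 values = values, state = state,
                 gene_chrom = gene_chrom, gene_start = gene_start,
                 gene_end = gene_end),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d individuals x %d genes (state: %s)\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Read a gene-expression TSV (id column + one column per gene)
#'
#' @param path file path.
#' @param transform_log2p1 if `TRUE`, the file holds raw TPM and
#'   `log2(x + 1)` is applied after load; the returned object then has
#'   `state = "log2p1"`.
#' @param state scale the file is already on when no transform is
#'   requested: `"tpm"` (non-negative, the default) or `"log2p1"`
#'   (log-scale values, e.g. files written by [write_expression()]).
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, transform_log2p1 = FALSE,
                            state = c("tpm", "log2p1")) {
  state <- match.arg(state)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          data.table = FALSE)
  ids <- as.character(dt[[1]])
  X <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing expression values not supported")
  if (transform_log2p1) {
    if (state != "tpm") stop("log2(TPM+1) transform needs raw TPM input")
    if (any(X < 0)) stop("negative TPM value encountered")
    X <- log2(X + 1)
    state <- "log2p1"
  } else if (state == "tpm" && any(X < 0)) {
    stop("negative TPM value encountered")
  }
  expr_matrix(X, individual_ids = ids, state = state)
}

#' Write an expression matrix as TSV
#' @param expr an [expr_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(id = expr$individual_ids,
                   format(expr$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- phenotype table ---------------------------------------------------

#' Construct a phenotype / DRP table
#'
#' @param individual_ids identifiers.
#' @param y response (simulated phenotype or de-regressed proof).
#' @param rel optional EBV reliability per individual, in `[0, 1)`.
#' @param birth_year optional integer birth year (forward validation).
#' @return a data.frame of class `pheno_table`.
#' @export
pheno_table <- function(individual_ids, y, rel = NULL, birth_year = NULL) {
  stop_if_not_ids(individual_ids, "individual")
  stopifnot(length(y) == length(individual_ids))
  if (!is.null(rel)) {
    if (any(rel < 0 | rel >= 1)) stop("rel outside [0,1)")
  }
  df <- data.frame(id = as.character(individual_ids), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  if (!is.null(rel)) df$rel <- as.numeric(rel)
  if (!is.null(birth_year)) df$birth_year <- as.integer(birth_year)
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Read a phenotype TSV with columns `id`, `y` and optionally `rel`,
#' `birth_year`
#' @param path file path.
#' @return a [pheno_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "y") %in% names(dt)))
    stop("phenotype file must have columns 'id' and 'y'")
  pheno_table(dt$id, dt$y,
              rel = if ("rel" %in% names(dt)) dt$rel else NULL,
              birth_year = if ("birth_year" %in% names(dt))
                dt$birth_year else NULL)
}

#' Write a phenotype table as TSV
#' @param pheno a [pheno_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- kernel TSV round-trip ---------------------------------------------

#' Write a kernel matrix as a square id-labelled TSV
#'
#' Values are written with 17 significant digits so that
#' `read_kernel(write_kernel(K))` reproduces `K` to 1e-12.
#'
#' @param K a [kernel_matrix()].
#' @param path output path.
#' @export
write_kernel <- function(K, path) {
  V <- as.matrix(K)
  df <- data.frame(id = K$individual_ids,
                   format(V, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  names(df) <- c("id", K$individual_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square id-labelled kernel TSV
#'
#' @param path file path.
#' @param kind kernel kind label to attach (stored metadata only).
#' @return a [kernel_matrix()].
#' @export
read_kernel <- function(path, kind = "linear") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(dt[[1]])
  V <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(V) <- "double"
  if (nrow(V) != ncol(V))
    stop("non-square kernel file: ", nrow(V), " rows, ", ncol(V), " columns")
  if (!identical(colnames(V), ids))
    stop("kernel row/column ids disagree")
  if (max(abs(V - t(V))) > 1e-6)
    stop("kernel file asymmetric beyond 1e-6")
  kernel_matrix((V + t(V)) / 2, individual_ids = ids, kind = kind)
}
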