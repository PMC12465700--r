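# Fixtures built in code: tiny genotype/expression/phenotype objects and
# files used across the suite.

make_geno <- function(dosages, ids = NULL, snps = NULL, ...) {
  geno_matrix(dosages,
              individual_ids = ids %||% paste0("i", seq_len(nrow(dosages))),
              snp_ids = snps %||% paste0("s", seq_len(ncol(dosages))), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# plink .raw fixture: 2 individuals, 2 SNPs, one missing dosage
plink_raw_fixture <- function(path) {
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_C",
    "f1 i1 0 0 1 -9 NA 2",
    "f2 i2 0 0 2 -9 0 2",
    "f3 i3 0 0 1 -9 2 0"),
    path)
  path
}
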