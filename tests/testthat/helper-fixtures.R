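# Fixtures are generated in code at test time; nothing is stored on disk.

# Minimal VCF with the genotype call shapes the reader must handle:
# het / phased hom-alt / fully missing / half-call / multi-allelic.
write_test_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "12345", ".", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1|1", "./.", sep = "\t"),
    paste("1", "20000", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/.", "1/1", sep = "\t"),
    paste("2", "30000", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/0", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}

write_test_raw <- function(path = tempfile(fileext = ".raw"),
                           header = "FID IID PAT MAT SEX PHENOTYPE rs1_A") {
  writeLines(c(header,
               "f1 i1 0 0 1 -9 0",
               "f2 i2 0 0 2 1.5 2"), path)
  path
}

# Columns orthonormal and orthogonal to the intercept, so Pearson
# correlation with any vector is proportional to the plain inner
# product and greedy selection must reduce to marginal ranking.
orthonormal_design <- function(n, m, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (m + 1)), n))))
  Q[, -1, drop = FALSE][, seq_len(m), drop = FALSE]
}

random_dosage_instance <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(sample(0:2, n * m, replace = TRUE,
                prob = c(0.5, 0.35, 0.15)), n, m)
}
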