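# Small builders shared across the suite.

# Genotype matrix from a bare dosage matrix; markers laid out on one
# chromosome 1e5 bp apart unless a map is supplied.
tiny_geno <- function(dosage, map = NULL, chrom = "1") {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  }
  if (is.null(map)) {
    map <- tibble::tibble(
      marker = sprintf("m%02d", seq_len(ncol(dosage))),
      chrom = chrom, pos = seq(1e6, by = 1e5, length.out = ncol(dosage)),
      allele_minor = "A", allele_major = "G")
  }
  geno_matrix(dosage, map)
}

# A hand-built multiplex pedigree: one family, two parents, `n_sibs`
# affected siblings with the given onsets.
tiny_family <- function(fid, aaos, sex_sibs = NULL) {
  n <- length(aaos)
  if (is.null(sex_sibs)) sex_sibs <- rep(1L, n)
  pedigree_table(
    fid = fid,
    iid = c(paste0(fid, "_P1"), paste0(fid, "_P2"),
            paste0(fid, "_S", seq_len(n))),
    father = c("0", "0", rep(paste0(fid, "_P1"), n)),
    mother = c("0", "0", rep(paste0(fid, "_P2"), n)),
    sex = c(1L, 2L, sex_sibs),
    affected = c(FALSE, FALSE, rep(TRUE, n)),
    aao = c(NA, NA, aaos),
    age = c(60, 60, aaos + 10),
    role = c("parent", "parent", rep("co_sib", n)))
}
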