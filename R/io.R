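#' Read a PED/MAP file pair
#'
#' White-space PED dialect: `FID IID PAT MAT SEX PHENO` followed by one
#' allele pair per marker; `0 0` denotes a missing genotype.  The minor
#' allele at each marker is the less frequent allele over all loaded samples
#' (ties broken by allele lexical order) and the returned dosages count that
#' allele; downstream code never re-orients.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A list with `geno` (a [geno_matrix()]) and `ped` (pedigree tibble;
#'   `aao`, `age`, `role` are NA — they travel in the phenotype TSV, not in
#'   PED).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               col.names = c("chrom", "marker", "cm", "pos"),
                               colClasses = c("character", "character",
                                              "character", "integer"))
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nrow(map_raw)
  lens <- lengths(toks)
  if (any(lens != want)) {
    stop("ragged PED row at line ", which(lens != want)[1],
         ": expected ", want, " fields, found ", lens[lens != want][1])
  }
  n <- length(toks)
  L <- nrow(map_raw)
  meta <- t(vapply(toks, function(x) x[1:6], character(6)))
  al <- t(vapply(toks, function(x) x[-(1:6)], character(2L * L)))
  a1 <- al[, seq(1L, 2L * L, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * L, by = 2L), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  dosage <- matrix(NA_real_, n, L)
  minor <- major <- character(L)
  for (j in seq_len(L)) {
    obs <- c(a1[, j], a2[, j])
    tab <- sort(table(obs[!is.na(obs)]), decreasing = FALSE)
    alleles <- names(tab)
    if (length(alleles) > 2L) {
      stop("non-biallelic marker ", map_raw$marker[j], " (",
           length(alleles), " alleles)")
    }
    if (length(alleles) == 0L) alleles <- c("?", "?")
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    # less frequent first; exact tie -> lexical order
    if (tab[[1]] == tab[[length(tab)]]) alleles <- sort(alleles)
    minor[j] <- alleles[1]
    major[j] <- alleles[2]
    dosage[, j] <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
  }
  rownames(dosage) <- meta[, 2]
  map <- tibble::tibble(marker = map_raw$marker, chrom = map_raw$chrom,
                        pos = map_raw$pos, allele_minor = minor,
                        allele_major = major)
  sexv <- suppressWarnings(as.integer(meta[, 5]))
  sexv[!sexv %in% 1:2] <- NA_integer_
  phen <- suppressWarnings(as.integer(meta[, 6]))
  aff <- ifelse(phen %in% c(1L, 2L), phen == 2L, NA)
  ped <- pedigree_table(fid = meta[, 1], iid = meta[, 2],
                        father = meta[, 3], mother = meta[, 4],
                        sex = sexv, affected = aff)
  list(geno = geno_matrix(dosage, map), ped = ped)
}

#' Write a PED/MAP file pair
#'
#' Inverse of [read_ped_map()].  The PED phenotype column carries affection
#' (1 = unaffected, 2 = affected, 0 = missing); quantitative phenotypes are
#' written separately with [write_phenotypes()].
#'
#' @param g A [geno_matrix()].
#' @param ped Pedigree tibble covering the samples of `g`.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the PED path.
#' @export
write_ped_map <- function(g, ped, ped_path, map_path) {
  map <- g$map
  utils::write.table(
    data.frame(map$chrom, map$marker, 0,
               format(map$pos, scientific = FALSE, trim = TRUE)),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  ped <- ped[match(sample_ids(g), ped$iid), ]
  d <- g$dosage
  n <- nrow(d)
  L <- ncol(d)
  allele1 <- allele2 <- matrix("0", n, L)
  for (j in seq_len(L)) {
    mi <- map$allele_minor[j]; ma <- map$allele_major[j]
    allele1[, j] <- c(ma, mi, mi)[d[, j] + 1L]
    allele2[, j] <- c(ma, ma, mi)[d[, j] + 1L]
    allele1[is.na(d[, j]), j] <- "0"
    allele2[is.na(d[, j]), j] <- "0"
  }
  inter <- matrix("", n, 2L * L)
  inter[, seq(1L, 2L * L, 2L)] <- allele1
  inter[, seq(2L, 2L * L, 2L)] <- allele2
  phen <- ifelse(is.na(ped$affected), 0L, ifelse(ped$affected, 2L, 1L))
  meta <- cbind(ped$fid, ped$iid, ped$father, ped$mother,
                ifelse(is.na(ped$sex), 0L, ped$sex), phen)
  writeLines(apply(cbind(meta, inter), 1, paste, collapse = " "), ped_path)
  invisible(ped_path)
}

#' Read genotypes from a minimal VCF
#'
#' Supports VCF 4.x with a GT field, biallelic records only; multi-allelic
#' records are skipped with a warning.  `./.` becomes a missing dosage.  The
#' counted (minor) allele is recomputed from the loaded samples — it is the
#' less frequent of REF/ALT, not assumed to be ALT.
#'
#' @param vcf_path Path to an uncompressed VCF.
#' @return A [geno_matrix()].
#' @export
read_vcf_gt <- function(vcf_path) {
  lines <- readLines(vcf_path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("no #CHROM header line in ", vcf_path)
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  recs <- strsplit(body, "\t")
  multi <- vapply(recs, function(r) grepl(",", r[5], fixed = TRUE), logical(1))
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    recs <- recs[!multi]
  }
  L <- length(recs)
  n <- length(samples)
  alt_count <- matrix(NA_real_, n, L, dimnames = list(samples, NULL))
  chrom <- pos <- id <- ref <- alt <- character(L)
  for (j in seq_len(L)) {
    r <- recs[[j]]
    chrom[j] <- r[1]; pos[j] <- r[2]; id[j] <- r[3]
    ref[j] <- r[4]; alt[j] <- r[5]
    gt_idx <- match("GT", strsplit(r[9], ":", fixed = TRUE)[[1]])
    gt <- vapply(strsplit(r[-(1:9)], ":", fixed = TRUE),
                 function(f) f[gt_idx], character(1))
    al <- strsplit(gt, "[/|]")
    alt_count[, j] <- vapply(al, function(a) {
      if (any(a == ".")) NA_real_ else sum(a == "1")
    }, numeric(1))
  }
  # orient to the observed minor allele, ties -> lexical order on the allele
  afreq <- colMeans(alt_count, na.rm = TRUE) / 2
  dosage <- alt_count
  minor <- alt; major <- ref
  flip <- afreq > 0.5 | (afreq == 0.5 & pmin(ref, alt) == ref)
  flip[is.na(flip)] <- FALSE
  dosage[, flip] <- 2 - dosage[, flip]
  minor[flip] <- ref[flip]
  major[flip] <- alt[flip]
  noid <- id == "." | !nzchar(id)
  id[noid] <- paste0(chrom[noid], ":", pos[noid])
  geno_matrix(dosage,
              tibble::tibble(marker = id, chrom = chrom,
                             pos = as.integer(pos),
                             allele_minor = minor, allele_major = major))
}

#' Write an association result table as TSV
#'
#' One row per marker, stable column order, p-values in scientific notation
#' with four significant digits.
#'
#' @param results Tibble of association results.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  pcols <- grep("^p($|_)", names(out), value = TRUE)
  for (pc in pcols) {
    out[[pc]] <- ifelse(is.na(results[[pc]]), NA,
                        formatC(results[[pc]], format = "e", digits = 3))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back an association result TSV
#'
#' @param path Path written by [write_results_tsv()].
#' @return A tibble with numeric p-value columns restored.
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read the phenotype side table
#'
#' Quantitative phenotypes (AAO, age) and pipeline labels travel in a TSV
#' next to the PED, never inside it.
#'
#' @param ped Pedigree tibble.
#' @param path TSV path.
#' @return Invisibly `path`; `read_phenotypes()` returns the tibble.
#' @export
write_phenotypes <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    fid = "c", iid = "c", father = "c", mother = "c",
                    sex = "i", affected = "l", aao = "d", age = "d",
                    role = "c", aao_group = "c"))
}
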