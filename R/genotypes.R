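#' Construct a genotype matrix
#'
#' The central genotype container: a samples-by-markers matrix of minor-allele
#' dosages in `{0, 1, 2, NA}` together with a marker map.  Minor/major
#' orientation is fixed when the object is built (from pooled allele
#' frequencies) and is never flipped downstream, so every effect estimate and
#' MAF in the pipeline refers to the same allele.
#'
#' @param dosage Numeric matrix, samples in rows, markers in columns; values
#'   in `{0, 1, 2, NA}`.  Row names are sample ids, column names marker ids.
#' @param map Tibble with one row per marker: `marker`, `chrom`, `pos`
#'   (1-based bp), `allele_minor`, `allele_major`.  Order must match the
#'   columns of `dosage`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  stopifnot(is.numeric(dosage))
  map <- tibble::as_tibble(map)
  req <- c("marker", "chrom", "pos", "allele_minor", "allele_major")
  if (!all(req %in% names(map))) {
    stop("marker map must have columns: ", paste(req, collapse = ", "))
  }
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " markers but map has ", nrow(map))
  }
  if (is.null(rownames(dosage))) {
    stop("dosage must carry sample ids as row names")
  }
  colnames(dosage) <- map$marker
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad)) stop("dosages must lie in {0, 1, 2, NA}")
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " markers\n", sep = "")
  cat("  missing: ",
      format(round(100 * mean(is.na(x$dosage)), 2), nsmall = 2), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Sample ids of a genotype matrix
#' @param g A `geno_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(g) rownames(g$dosage)

#' Marker ids of a genotype matrix
#' @param g A `geno_matrix`.
#' @return Character vector of marker ids.
#' @export
marker_ids <- function(g) g$map$marker

#' Subset a genotype matrix
#'
#' @param g A `geno_matrix`.
#' @param samples,markers Character ids (or logical/integer index) to keep;
#'   `NULL` keeps all.  Sample/marker order follows the selection.
#' @return A `geno_matrix`.
#' @export
geno_subset <- function(g, samples = NULL, markers = NULL) {
  d <- g$dosage
  map <- g$map
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker)
    d <- d[, markers, drop = FALSE]
    map <- map[markers, ]
  }
  geno_matrix(d, map)
}

#' Per-marker minor allele frequency
#'
#' @param g A `geno_matrix`.
#' @param samples Optional sample ids over which to compute the frequency.
#' @return Named numeric vector of MAFs (allele-count scale, complete
#'   genotypes only).
#' @export
marker_maf <- function(g, samples = NULL) {
  d <- g$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Bind two genotype matrices over the same marker map
#'
#' @param a,b `geno_matrix` objects sharing an identical marker map.
#' @return A `geno_matrix` with the samples of `a` followed by those of `b`.
#' @export
geno_rbind <- function(a, b) {
  if (!identical(a$map$marker, b$map$marker)) {
    stop("marker maps differ; cannot bind")
  }
  geno_matrix(rbind(a$dosage, b$dosage), a$map)
}

#' Assemble a pedigree table
#'
#' One row per individual.  `role` distinguishes probands, co-affected
#' siblings, parents and unrelated controls; `aao_group` carries the
#' family-level onset stratum assigned by [rank_and_select_extremes()].
#'
#' @param fid,iid Family and individual ids (character).
#' @param father,mother Parent iids, `"0"` for founders.
#' @param sex 1 = male, 2 = female, NA unknown.
#' @param affected Logical (NA unknown).
#' @param aao,age Years, NA when missing.
#' @param role One of `"proband"`, `"co_sib"`, `"parent"`, `"control"`.
#' @param aao_group One of `"earliest"`, `"earlier"`, `"later"`, `"latest"`,
#'   `"none"`.
#' @return A tibble with the columns above.
#' @export
pedigree_table <- function(fid, iid, father = "0", mother = "0",
                           sex = NA_integer_, affected = NA,
                           aao = NA_real_, age = NA_real_,
                           role = NA_character_, aao_group = "none") {
  out <- tibble::tibble(
    fid = as.character(fid), iid = as.character(iid),
    father = as.character(father), mother = as.character(mother),
    sex = as.integer(sex), affected = as.logical(affected),
    aao = as.numeric(aao), age = as.numeric(age),
    role = as.character(role), aao_group = as.character(aao_group)
  )
  bad <- !is.na(out$aao) & !is.na(out$age) & out$aao > out$age
  if (any(bad)) {
    stop("age at onset exceeds current age for: ",
         paste(out$iid[bad], collapse = ", "))
  }
  out
}

#' Check Mendelian consistency of a family cohort
#'
#' For every offspring-father-mother trio with all three genotypes
#' non-missing at a marker, verifies that the offspring dosage is attainable
#' from the parental pair (e.g. parents 0 and 0 cannot produce dosage 1).
#'
#' @param g A `geno_matrix`.
#' @param ped Pedigree tibble with `iid`, `father`, `mother`.
#' @return Count of inconsistent (trio, marker) pairs.
#' @export
count_mendel_errors <- function(g, ped) {
  d <- g$dosage
  kids <- ped[ped$father != "0" & ped$mother != "0", ]
  kids <- kids[kids$iid %in% rownames(d) &
                 kids$father %in% rownames(d) &
                 kids$mother %in% rownames(d), ]
  if (!nrow(kids)) return(0L)
  n_bad <- 0L
  for (i in seq_len(nrow(kids))) {
    gc <- d[kids$iid[i], ]
    gf <- d[kids$father[i], ]
    gm <- d[kids$mother[i], ]
    ok <- !is.na(gc) & !is.na(gf) & !is.na(gm)
    # transmissible minor-allele count from a parent: floor(g/2) .. ceiling(g/2)
    lo <- floor(gf / 2) + floor(gm / 2)
    hi <- ceiling(gf / 2) + ceiling(gm / 2)
    n_bad <- n_bad + sum(ok & (gc < lo | gc > hi))
  }
  n_bad
}
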