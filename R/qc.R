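#' Per-sample genotyping call rate
#'
#' @param g A [geno_matrix()].
#' @return Tibble with `iid` and `call_rate` (fraction of non-missing
#'   genotypes, in `[0, 1]`).
#' @export
sample_call_rate <- function(g) {
  stopifnot(ncol(g$dosage) >= 1)
  tibble::tibble(iid = sample_ids(g),
                 call_rate = unname(rowMeans(!is.na(g$dosage))))
}

#' Per-marker genotyping call rate
#'
#' @param g A [geno_matrix()].
#' @return Tibble with `marker` and `call_rate`.
#' @export
marker_call_rate <- function(g) {
  tibble::tibble(marker = marker_ids(g),
                 call_rate = unname(colMeans(!is.na(g$dosage))))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums, over all heterozygote counts of the correct parity, the
#' probabilities no larger than that of the observed heterozygote count.
#' Intended to be computed on founders or one member per family.
#'
#' @param nAA,nAa,naa Genotype counts (AA = major homozygote, Aa =
#'   heterozygote, aa = minor homozygote).
#' @return The exact p-value; `NA` when all counts are zero.
#' @export
hwe_exact <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) return(NA_real_)
  n_minor <- 2 * naa + nAa
  # heterozygote counts sharing the parity of n_minor and feasible
  het <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log P(nAa = h | allele counts) up to a shared constant
  logp <- function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lfactorial(n) - lfactorial(h) - lfactorial(hom_minor) -
      lfactorial(hom_major) + h * log(2)
  }
  lp <- vapply(het, logp, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAa, het)]
  min(1, sum(pr[pr <= p_obs + 1e-12 * p_obs]))
}

#' Marker-level quality filters
#'
#' Applies, in order, marker call rate, minor-allele frequency and exact
#' Hardy-Weinberg filters with strictly-greater retention rules: a marker is
#' kept only if call rate > `call_thresh`, MAF > `maf_thresh` and HWE
#' p > `hwe_thresh`.  A marker failing several rules is reported under the
#' first.  HWE uses genotype counts over `hwe_samples` when given (one member
#' per family avoids relatedness distortion).
#'
#' @param g A [geno_matrix()].
#' @param call_thresh,maf_thresh,hwe_thresh Retention thresholds.
#' @param hwe_samples Optional sample ids on which HWE is computed.
#' @return A list with `keep` (marker ids retained) and `removed` (tibble:
#'   `marker`, `reason` in `low_call` / `low_maf` / `hwe_fail`, `value`).
#' @export
marker_filters <- function(g, call_thresh = 0.98, maf_thresh = 0.05,
                           hwe_thresh = 0.001, hwe_samples = NULL) {
  stopifnot(call_thresh > 0, call_thresh < 1, maf_thresh > 0,
            maf_thresh < 1, hwe_thresh > 0, hwe_thresh < 1)
  cr <- colMeans(!is.na(g$dosage))
  maf <- marker_maf(g)
  dh <- if (is.null(hwe_samples)) g$dosage else
    g$dosage[hwe_samples, , drop = FALSE]
  reason <- rep(NA_character_, ncol(g$dosage))
  value <- rep(NA_real_, ncol(g$dosage))
  reason[cr <= call_thresh] <- "low_call"
  value[cr <= call_thresh] <- cr[cr <= call_thresh]
  idx <- is.na(reason) & maf <= maf_thresh
  reason[idx] <- "low_maf"; value[idx] <- maf[idx]
  for (j in which(is.na(reason))) {
    x <- dh[, j]
    p <- hwe_exact(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
    if (!is.na(p) && p <= hwe_thresh) {
      reason[j] <- "hwe_fail"; value[j] <- p
    }
  }
  mk <- marker_ids(g)
  bad <- !is.na(reason)
  list(keep = mk[!bad],
       removed = tibble::tibble(marker = mk[bad], reason = reason[bad],
                                value = unname(value[bad])))
}

#' Pairwise identity-by-state distance
#'
#' `d(i, j) = 1 - shared / (2 * M)` where, over the `M` markers non-missing
#' in both samples, a pair of identical dosages shares 2 alleles, dosages one
#' apart share 1 and opposite homozygotes share 0.  Equivalent to half the
#' mean absolute dosage difference (the allele-sharing Hamming distance on
#' biallelic markers).
#'
#' @param g A [geno_matrix()].
#' @return Symmetric matrix of distances with zero diagonal; `NA` (with a
#'   warning) for pairs with no jointly typed marker.
#' @export
ibs_distance <- function(g) {
  d <- g$dosage
  stopifnot(nrow(d) >= 2)
  obs <- !is.na(d)
  dd <- d
  dd[!obs] <- 0
  # sum |di - dj| over shared markers = di^2 + dj^2 - 2 di dj reworked via
  # indicator matrices per dosage level (avoids an n^2 * L loop)
  lev <- lapply(0:2, function(v) (dd == v & obs) * 1)
  m_ij <- obs %*% t(obs)
  absdiff <- matrix(0, nrow(d), nrow(d))
  for (a in 0:2) for (b in 0:2) {
    if (abs(a - b) == 0) next
    absdiff <- absdiff + abs(a - b) * (lev[[a + 1]] %*% t(lev[[b + 1]]))
  }
  dist <- absdiff / (2 * m_ij)
  if (any(m_ij == 0)) {
    warning("sample pair(s) with no jointly typed marker: distance NA")
    dist[m_ij == 0] <- NA_real_
  }
  diag(dist) <- 0
  dimnames(dist) <- list(rownames(d), rownames(d))
  dist
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix and takes the top-`k`
#' eigenpairs; coordinates are eigenvectors scaled by the root eigenvalue,
#' ordered by decreasing eigenvalue, each with zero mean.  The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal.
#' @param k Number of components (default 4).
#' @return A list of class `mds_components`: `coords` (tibble `iid`,
#'   `mds1`..`mdsk`) and `eigenvalues`.
#' @export
classical_mds <- function(d, k = 4) {
  d <- as.matrix(d)
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(diag(d) == 0), all(d >= 0, na.rm = TRUE))
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1),
                         eig = TRUE)
  pts <- fit$points
  npos <- sum(fit$eig > 1e-8 * max(abs(fit$eig)))
  if (npos < k) {
    warning("only ", npos, " positive eigenvalue(s); returning ",
            ncol(pts), " component(s)")
  }
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  coords <- tibble::as_tibble(pts, .name_repair = ~ paste0("mds",
                                                           seq_along(.x)))
  coords <- dplyr::bind_cols(tibble::tibble(iid = rownames(d)), coords)
  structure(list(coords = coords,
                 eigenvalues = fit$eig[seq_len(ncol(pts))]),
            class = "mds_components")
}

#' @export
print.mds_components <- function(x, ...) {
  cat("<mds_components> ", nrow(x$coords), " samples, ",
      ncol(x$coords) - 1, " components; eigenvalues: ",
      paste(signif(x$eigenvalues, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Flag ancestry outliers on MDS components
#'
#' A sample is flagged when, on any component, its coordinate lies more than
#' `z_thresh` leave-one-out standard deviations from the leave-one-out mean.
#' Degenerate components (SD 0 without the sample) never flag.
#'
#' @param mds An `mds_components` object.
#' @param z_thresh Flagging threshold in SD units.
#' @return Character vector of flagged sample ids.
#' @export
ancestry_outliers <- function(mds, z_thresh = 5) {
  co <- mds$coords
  stopifnot(nrow(co) >= 10)
  x <- as.matrix(co[, -1, drop = FALSE])
  n <- nrow(x)
  flagged <- logical(n)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    s <- sum(v); ss <- sum(v^2)
    loo_mean <- (s - v) / (n - 1)
    loo_var <- pmax((ss - v^2) / (n - 1) - loo_mean^2, 0) * (n - 1) / (n - 2)
    loo_sd <- sqrt(loo_var)
    ok <- loo_sd > 0
    flagged[ok] <- flagged[ok] |
      (abs(v[ok] - loo_mean[ok]) > z_thresh * loo_sd[ok])
  }
  co$iid[flagged]
}

#' KING-robust kinship coefficient for one pair
#'
#' `phi = (N_AaAa - 2 * N_AAaa) / (N_Aa(i) + N_Aa(j))` over jointly typed
#' markers: `N_AaAa` markers heterozygous in both, `N_AAaa` opposite
#' homozygotes, `N_Aa(.)` per-sample heterozygote counts.  Duplicate samples
#' and monozygotic twins give ~0.5, parent-offspring ~0.25; the conventional
#' duplicate threshold is 0.354 (half-way in log2 scale).
#'
#' @param g A [geno_matrix()].
#' @param i,j Sample ids.
#' @return Kinship estimate, or `NA` (with warning) when the denominator is
#'   zero.
#' @export
kinship_robust <- function(g, i, j) {
  gi <- g$dosage[i, ]
  gj <- g$dosage[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n_het_i <- sum(gi == 1)
  n_het_j <- sum(gj == 1)
  if (n_het_i + n_het_j == 0) {
    warning("pair (", i, ", ", j, "): no heterozygous marker, kinship NA")
    return(NA_real_)
  }
  n_hethet <- sum(gi == 1 & gj == 1)
  n_opp <- sum(abs(gi - gj) == 2)
  (n_hethet - 2 * n_opp) / (n_het_i + n_het_j)
}

#' All pairwise KING-robust kinship estimates
#'
#' @param g A [geno_matrix()].
#' @param threshold Report only pairs at or above this estimate (default
#'   reports all).
#' @return Tibble `iid1`, `iid2`, `kinship`.
#' @export
kinship_pairs <- function(g, threshold = -Inf) {
  d <- g$dosage
  obs <- !is.na(d)
  het <- (d == 1 & obs) * 1
  hom0 <- (d == 0 & obs) * 1
  hom2 <- (d == 2 & obs) * 1
  n_hethet <- het %*% t(het)
  n_opp <- hom0 %*% t(hom2) + hom2 %*% t(hom0)
  het_i <- het %*% t(obs)   # het in i over markers typed in both
  denom <- het_i + t(het_i)
  phi <- (n_hethet - 2 * n_opp) / denom
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  out <- tibble::tibble(iid1 = rownames(d)[idx[, 1]],
                        iid2 = rownames(d)[idx[, 2]],
                        kinship = phi[idx])
  out[!is.na(out$kinship) & out$kinship >= threshold, ]
}

#' Genomic inflation factor
#'
#' `lambda = median(chi^2_1 statistics) / 0.4549364`, the null median of a
#' 1-df chi-square.  P-values are converted through the inverse chi-square
#' CDF.  Values near 1 indicate no residual confounding inflation.
#'
#' @param p P-values (or pass `chi2`).
#' @param chi2 1-df chi-square statistics (alternative to `p`).
#' @return The inflation factor.
#' @export
genomic_inflation <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p) || !length(p)) stop("supply p-values or chi-square statistics")
    chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  chi2 <- chi2[!is.na(chi2)]
  if (!length(chi2)) stop("no usable statistics")
  if (length(chi2) < 100) {
    warning("fewer than 100 tests; inflation estimate is unstable")
  }
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Sample-level quality control in the standard order
#'
#' Applies the three sample checks in a fixed order — call rate, then
#' pairwise kinship, then ancestry — so a sample failing several is reported
#' under the first.  Kinship-flagged pairs drop the member with the lower
#' call rate.  Ancestry outliers are found by leave-one-out z-scoring of
#' classical MDS components of the IBS distance matrix, computed on the
#' samples surviving the first two checks.
#'
#' @param g A [geno_matrix()] restricted to the samples under QC (e.g.
#'   probands).
#' @param call_thresh Minimum call rate (strict >).
#' @param kinship_thresh Duplicate/relatedness flag level.
#' @param z_thresh Ancestry outlier threshold (SD units).
#' @param k Number of MDS components examined.
#' @return A list of class `qc_report`: `keep` (ids), `removed` (tibble
#'   `iid`, `reason`, `value`), `mds` (components over the retained + tested
#'   samples), `thresholds`.
#' @export
sample_qc <- function(g, call_thresh = 0.98, kinship_thresh = 0.354,
                      z_thresh = 5, k = 4) {
  cr <- sample_call_rate(g)
  removed <- tibble::tibble(iid = character(0), reason = character(0),
                            value = numeric(0))
  low <- cr[cr$call_rate <= call_thresh, ]
  if (nrow(low)) {
    removed <- dplyr::bind_rows(removed,
      tibble::tibble(iid = low$iid, reason = "low_call",
                     value = low$call_rate))
  }
  keep <- setdiff(sample_ids(g), removed$iid)

  g2 <- geno_subset(g, samples = keep)
  kin <- kinship_pairs(g2, threshold = kinship_thresh)
  if (nrow(kin)) {
    crk <- stats::setNames(cr$call_rate, cr$iid)
    for (r in seq_len(nrow(kin))) {
      pair <- c(kin$iid1[r], kin$iid2[r])
      if (any(pair %in% removed$iid)) next
      drop <- pair[which.min(crk[pair])]
      removed <- dplyr::bind_rows(removed,
        tibble::tibble(iid = drop, reason = "high_kinship",
                       value = kin$kinship[r]))
    }
    keep <- setdiff(keep, removed$iid)
  }

  g3 <- geno_subset(g, samples = keep)
  mds <- classical_mds(ibs_distance(g3), k = k)
  out_ids <- ancestry_outliers(mds, z_thresh = z_thresh)
  if (length(out_ids)) {
    removed <- dplyr::bind_rows(removed,
      tibble::tibble(iid = out_ids, reason = "ancestry_outlier",
                     value = NA_real_))
    keep <- setdiff(keep, out_ids)
  }
  structure(list(keep = keep, removed = removed, mds = mds,
                 thresholds = c(call = call_thresh,
                                kinship = kinship_thresh, z = z_thresh)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> retained ", length(x$keep), " sample(s); removed ",
      nrow(x$removed), ":\n", sep = "")
  if (nrow(x$removed)) {
    tab <- table(x$removed$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}
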