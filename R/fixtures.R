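#' Synthetic candidate-bookkeeping fixture
#'
#' Builds the standard fixture for candidate accounting: an extreme-contrast
#' scan sample in which exactly `n_suggestive` markers carry a strong
#' between-tail frequency contrast (so their association p-values fall below
#' the suggestive threshold), three of which lie within 300 bp on one
#' chromosome in near-perfect linkage disequilibrium, plus null background
#' markers.  A replication-round genotype set over the same markers is
#' included in which exactly one collapsed-set survivor (the first retained
#' non-clique marker in map order) is planted with a low call rate, so the
#' downstream accounting runs `n_suggestive` -> after LD collapse -> after
#' the replication call-rate filter.
#'
#' @param n_suggestive Number of suggestive markers (default 17).
#' @param n_background Null markers added around them.
#' @param n_per_group Samples per onset tail in the scan set.
#' @param n_repl Samples in the replication set.
#' @param seed Integer seed.
#' @return List: `geno_scan`, `groups` (named labels), `geno_repl`,
#'   `clique_markers`, `lowcall_marker`.
#' @export
make_candidate_fixture <- function(n_suggestive = 17, n_background = 30,
                                   n_per_group = 95, n_repl = 181,
                                   seed = 1L) {
  stopifnot(n_suggestive >= 3)
  set.seed(seed)
  n <- 2 * n_per_group
  ids <- sprintf("S%03d", seq_len(n))
  groups <- stats::setNames(rep(c("earliest", "latest"), each = n_per_group),
                            ids)

  # clique of 3 markers within 300 bp on one chromosome, r^2 ~ 1
  base <- c(stats::rbinom(n_per_group, 2, 0.50),
            stats::rbinom(n_per_group, 2, 0.10))
  clique <- matrix(base, n, 3)
  for (j in 2:3) {
    flip <- which(stats::runif(n) < 0.01)
    clique[flip, j] <- vapply(clique[flip, j], function(x) {
      sample(setdiff(0:2, x), 1)
    }, numeric(1))
  }
  n_iso <- n_suggestive - 3
  iso <- rbind(
    matrix(stats::rbinom(n_per_group * n_iso, 2, 0.50), n_per_group, n_iso),
    matrix(stats::rbinom(n_per_group * n_iso, 2, 0.10), n_per_group, n_iso))
  bg <- matrix(stats::rbinom(n * n_background, 2, 0.3), n, n_background)

  dosage <- cbind(clique, iso, bg)
  rownames(dosage) <- ids
  L <- ncol(dosage)
  clique_markers <- c("cand_c1", "cand_c2", "cand_c3")
  markers <- c(clique_markers,
               sprintf("cand_%02d", seq_len(n_iso)),
               sprintf("null_%02d", seq_len(n_background)))
  chrom <- c(rep("6", 3),
             as.character(rep_len(c(1:5, 7:22), n_iso)),
             as.character(rep_len(1:22, n_background)))
  pos <- integer(L)
  pos[1:3] <- c(161816611L, 161816724L, 161816881L)   # spacing < 300 bp
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & pos == 0)
    pos[idx] <- seq(5e6, by = 1e6, length.out = length(idx))
  }
  map <- tibble::tibble(marker = markers, chrom = chrom, pos = pos,
                        allele_minor = "A", allele_major = "G")
  geno_scan <- geno_matrix(dosage, map)

  # replication round: same markers, independent sample, one survivor
  # planted at ~90% call rate
  maf_repl <- colMeans(dosage) / 2
  d_repl <- matrix(stats::rbinom(n_repl * L, 2, rep(maf_repl, each = n_repl)),
                   n_repl, L)
  rownames(d_repl) <- sprintf("R%03d", seq_len(n_repl))
  lowcall_marker <- "cand_01"
  j <- match(lowcall_marker, markers)
  d_repl[stats::runif(n_repl) < 0.10, j] <- NA_real_
  # ensure the rate actually falls below the 0.98 retention bound
  if (mean(!is.na(d_repl[, j])) > 0.98) {
    d_repl[seq_len(ceiling(0.05 * n_repl)), j] <- NA_real_
  }
  list(geno_scan = geno_scan, groups = groups,
       geno_repl = geno_matrix(d_repl, map),
       clique_markers = clique_markers, lowcall_marker = lowcall_marker)
}

#' Standard 190-proband QC defect fixture
#'
#' Convenience composition used throughout the tests: a cohort of
#' `2 * n_extreme` multiplex families is simulated, ranked, and its probands
#' carry the standard planted defects (2 low-call samples, 1 near-duplicate,
#' 2 ancestry outliers from an fst = 0.1 subpopulation).
#'
#' @param n_extreme Families per tail (95 gives the standard 190 probands).
#' @param markers Marker count.
#' @param seed Integer seed.
#' @return List: `cohort` (defect-planted), `ped` (with extremes labelled),
#'   `manifest`, `probands` (ids entering sample QC).
#' @export
make_proband_qc_fixture <- function(n_extreme = 95, markers = 20000,
                                    seed = 1L) {
  cfg <- sim_config(n_families = 2 * n_extreme, markers = markers,
                    seed = seed)
  cohort <- simulate_cohort(cfg)
  ped <- rank_and_select_extremes(cohort, n_extreme = n_extreme)
  cohort$ped <- ped
  fx <- make_qc_fixture(cohort, n_lowcall = 2, n_duplicate = 1,
                        n_outlier = 2, seed = seed + 1L)
  list(cohort = fx$cohort, ped = ped, manifest = fx$manifest,
       probands = ped$iid[ped$role == "proband"])
}
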