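# Independent enumeration oracle for the exact HWE test: direct conditional
# probabilities from factorials, no shared code with hwe_exact().
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nm <- 2 * naa + nAa
  hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  pr <- vapply(hets, function(h) {
    exp(lchoose(n, h) + lchoose(n - h, (nm - h) / 2) + h * log(2) -
          lchoose(2 * n, nm))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == nAa] * (1 + 1e-12)])
}

test_that("sample and marker call rates count missing genotypes", {
  d <- rbind(c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0),
             c(0, NA, 2, 0, 1, 2, 0, 1, 2, 0))
  g <- tiny_geno(d)
  cr <- sample_call_rate(g)
  expect_identical(cr$call_rate, c(1, 0.9))
  expect_identical(marker_call_rate(g)$call_rate[2], 0.5)
})

test_that("exact HWE p-values equal the enumeration oracle", {
  cases <- list(c(25, 50, 25), c(0, 100, 0), c(100, 0, 0), c(3, 1, 4),
                c(57, 14, 50), c(0, 0, 7), c(12, 1, 1), c(68, 59, 13))
  set.seed(1)
  for (i in 1:40) {
    n <- sample(1:200, 1)
    k <- rmultinom(1, n, c(0.4, 0.4, 0.2))
    cases[[length(cases) + 1]] <- as.vector(k)
  }
  for (cs in cases) {
    expect_equal(hwe_exact(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12,
                 info = paste(cs, collapse = ","))
  }
  expect_identical(hwe_exact(100, 0, 0), 1)
  expect_lt(hwe_exact(0, 100, 0), 1e-3)
  expect_true(is.na(hwe_exact(0, 0, 0)))
})

test_that("marker filters apply strict thresholds in a fixed order", {
  set.seed(42)
  n <- 100
  good <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  lowcall <- c(rbinom(n / 2, 2, 0.3), rep(NA, n / 2))        # call rate 0.5
  # MAF exactly at the 0.05 bound -> removed under strict ">"
  atmaf <- c(rep(1, round(0.1 * n)), rep(0, n - round(0.1 * n)))
  hwe_bad <- rep(1, n)                                       # all-het
  g <- tiny_geno(cbind(good[, 1], lowcall, atmaf, hwe_bad, good[, 2],
                       good[, 3]))
  out <- marker_filters(g)
  expect_setequal(out$removed$marker, c("m02", "m03", "m04"))
  expect_identical(
    out$removed$reason[match(c("m02", "m03", "m04"), out$removed$marker)],
    c("low_call", "low_maf", "hwe_fail"))
  expect_setequal(out$keep, c("m01", "m05", "m06"))
})

test_that("IBS distance matches a brute-force per-pair loop", {
  g <- tiny_geno(rbind(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1),
                       c(2, 1, 0, 2, NA)))
  d <- ibs_distance(g)
  expect_identical(unname(d[1, 2]), 0)
  # samples 1 and 3: dosage diff (2,0,2,2,-) over 4 shared -> 6/8
  expect_identical(unname(d[1, 3]), 0.75)
  set.seed(7)
  dd <- matrix(sample(c(0:2, NA), 15, replace = TRUE), 3, 5)
  dd[1, 1] <- 0; dd[2, 1] <- 2      # guarantee overlap
  g2 <- tiny_geno(dd)
  d2 <- ibs_distance(g2)
  for (i in 1:2) for (j in (i + 1):3) {
    ok <- !is.na(dd[i, ]) & !is.na(dd[j, ])
    shared <- sum(2 - abs(dd[i, ok] - dd[j, ok]))
    expect_equal(unname(d2[i, j]), 1 - shared / (2 * sum(ok)))
  }
  # opposite homozygotes everywhere -> distance 1
  g3 <- tiny_geno(rbind(rep(0, 4), rep(2, 4)))
  expect_identical(unname(ibs_distance(g3)[1, 2]), 1)
})

test_that("classical MDS reproduces Euclidean configurations", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  D <- as.matrix(dist(X))
  mds <- classical_mds(D, k = 4)
  co <- as.matrix(mds$coords[, -1])
  expect_equal(as.matrix(dist(co)), unname(D), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(mds$eigenvalues) <= 1e-8))
  expect_true(all(abs(colMeans(co)) < 1e-8))
  # permutation equivariance
  p <- sample(10)
  mds_p <- classical_mds(D[p, p], k = 4)
  expect_equal(as.matrix(mds_p$coords[order(p), -1]), co,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("MDS component 1 separates two clusters", {
  D <- matrix(1, 12, 12)
  D[1:6, 1:6] <- 0
  D[7:12, 7:12] <- 0
  diag(D) <- 0
  rownames(D) <- colnames(D) <- sprintf("s%02d", 1:12)
  mds <- suppressWarnings(classical_mds(D, k = 2))
  c1 <- mds$coords$mds1
  expect_true(all(c1[1:6] * c1[7:12][1] < 0) ||
                all(sign(c1[1:6]) != sign(c1[7:12])))
})

test_that("MDS separates simulated subpopulations on component 1", {
  co <- simulate_cohort(sim_config(n_families = 60, markers = 4000,
                                   fst = 0.05, prop_pop2 = 0.5, seed = 17))
  founders <- co$ped$iid[co$ped$role == "parent"]
  g <- geno_subset(co$geno, samples = founders[seq(1, length(founders),
                                                   by = 2)])
  mds <- classical_mds(ibs_distance(g))
  pop <- co$family_pop[co$ped$fid[match(mds$coords$iid, co$ped$iid)]]
  r <- abs(cor(mds$coords$mds1, pop))
  expect_gt(r, 0.9)
})

test_that("leave-one-out ancestry flagging hits planted outliers only", {
  set.seed(5)
  n <- 50
  coords <- tibble::tibble(iid = sprintf("s%02d", 1:n),
                           mds1 = rnorm(n, 0, 0.01),
                           mds2 = rnorm(n, 0, 0.01))
  coords$mds1[c(3, 9)] <- 0.4   # far outliers
  mds <- structure(list(coords = coords, eigenvalues = c(1, 0.5)),
                   class = "mds_components")
  expect_setequal(ancestry_outliers(mds), c("s03", "s09"))
  # degenerate: identical coordinates never flag
  coords2 <- tibble::tibble(iid = sprintf("s%02d", 1:12), mds1 = 1,
                            mds2 = 1)
  mds2 <- structure(list(coords = coords2, eigenvalues = c(1, 1)),
                    class = "mds_components")
  expect_length(ancestry_outliers(mds2), 0)
})

test_that("homogeneous cohorts rarely flag anyone at z = 5", {
  flags <- vapply(1:6, function(s) {
    co <- simulate_cohort(sim_config(n_families = 30, markers = 1500,
                                     seed = 100 + s))
    founders <- co$ped$iid[co$ped$role == "parent"]
    g <- geno_subset(co$geno, samples = founders)
    length(ancestry_outliers(classical_mds(ibs_distance(g))))
  }, numeric(1))
  expect_gte(mean(flags == 0), 5 / 6)
})

test_that("KING-robust kinship recovers duplicate and parent-offspring", {
  # self-comparison: phi = n_het / (2 n_het) = 0.5
  set.seed(8)
  d <- rbind(a = rbinom(500, 2, 0.3), b = rbinom(500, 2, 0.3))
  d["b", ] <- d["a", ]
  g <- tiny_geno(d)
  expect_identical(kinship_robust(g, "a", "b"), 0.5)
  # parent-offspring over 5000 markers
  co <- simulate_cohort(sim_config(n_families = 1, markers = 5000,
                                   seed = 19))
  ids <- co$ped$iid
  phi <- kinship_robust(co$geno, ids[1], ids[3])
  expect_lt(abs(phi - 0.25), 0.03)
  # planted duplicate with 1% discordance stays above the 0.354 bound
  d2 <- d
  flip <- sample(500, 5)
  d2["b", flip] <- (d2["b", flip] + 1) %% 3
  expect_gt(kinship_robust(tiny_geno(d2), "a", "b"), 0.354)
  # undefined without heterozygous markers
  g0 <- tiny_geno(rbind(a = c(0, 0, 2), b = c(0, 2, 2)))
  expect_warning(phi0 <- kinship_robust(g0, "a", "b"), "heterozygous")
  expect_true(is.na(phi0))
})

test_that("kinship_pairs agrees with the per-pair estimator", {
  set.seed(12)
  d <- matrix(rbinom(5 * 300, 2, 0.25), 5, 300)
  d[sample(length(d), 50)] <- NA
  g <- tiny_geno(d)
  pairs <- kinship_pairs(g)
  for (r in seq_len(nrow(pairs))) {
    expect_equal(pairs$kinship[r],
                 kinship_robust(g, pairs$iid1[r], pairs$iid2[r]))
  }
})

test_that("genomic inflation factor behaves as a median ratio", {
  expect_equal(genomic_inflation(chi2 = rep(0.4549364, 200)), 1,
               tolerance = 1e-6)
  chi <- rchisq(1000, 1)
  expect_equal(genomic_inflation(chi2 = 2 * chi),
               2 * genomic_inflation(chi2 = chi))
  set.seed(2)
  p <- runif(1e4)
  expect_lt(abs(genomic_inflation(p = p) - 1), 0.03)
  expect_error(genomic_inflation(), "supply")
})

test_that("sample QC removes exactly the planted manifest, in order", {
  px <- make_proband_qc_fixture(n_extreme = 30, markers = 6000, seed = 2)
  g <- geno_subset(px$cohort$geno, samples = px$probands)
  qc <- sample_qc(g)
  expect_setequal(qc$removed$iid, px$manifest$iid)
  expect_identical(length(qc$keep), 55L)
  reason_of <- setNames(qc$removed$reason, qc$removed$iid)
  man <- setNames(
    c(low_call = "low_call", duplicate = "high_kinship",
      ancestry_outlier = "ancestry_outlier")[px$manifest$defect],
    px$manifest$iid)
  expect_identical(reason_of[names(man)], man)
})
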