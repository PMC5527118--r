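test_that("replication applies the Bonferroni rule over 14 tests", {
  set.seed(15)
  d <- matrix(rbinom(80 * 3, 2, 0.3), 80, 3)
  g <- tiny_geno(d)
  grp <- setNames(rep(c("earliest", "latest"), 40), sample_ids(g))
  out <- sibling_replication(g, grp, m_tests = 14)
  expect_equal(attr(out, "bonferroni"), 0.05 / 14)
  expect_equal(signif(attr(out, "bonferroni"), 2), 0.0036)
  # a marker with p = 0.01 does not survive 0.05/14
  expect_false(isTRUE(out$significant[which(out$p > 0.0036)[1]]))
  expect_true(all(out$significant == (out$p < 0.05 / 14), na.rm = TRUE))
})

test_that("replication recovers the learning-set direction for a planted modifier", {
  hits <- 0
  for (s in 1:5) {
    co <- simulate_cohort(sim_config(
      n_families = 150, markers = 30, n_modifier_snps = 1,
      modifier_effects_years = -4, maf_range = c(0.3, 0.3), seed = 40 + s))
    ped <- rank_and_select_extremes(co, n_extreme = 40)
    pm <- co$true_modifiers$marker
    prob <- ped[ped$role == "proband" &
                  ped$aao_group %in% c("earliest", "latest"), ]
    sib <- ped[ped$role == "co_sib" &
                 ped$aao_group %in% c("earliest", "latest"), ]
    gp <- geno_subset(co$geno, samples = prob$iid, markers = pm)
    gs <- geno_subset(co$geno, samples = sib$iid, markers = pm)
    b_learn <- sibling_replication(
      gp, setNames(prob$aao_group, prob$iid), m_tests = 1)$beta
    b_rep <- sibling_replication(
      gs, setNames(sib$aao_group, sib$iid), m_tests = 1)$beta
    if (sign(b_learn) == sign(b_rep)) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("two-level ordinal trend reduces to binary logistic regression", {
  set.seed(16)
  d <- matrix(rbinom(120 * 4, 2, 0.3), 120, 4)
  g <- tiny_geno(d)
  grp <- setNames(rep(c("earliest", "latest"), each = 60), sample_ids(g))
  tr <- ordinal_trend(g, grp)
  y <- as.numeric(grp[sample_ids(g)] == "earliest")
  for (j in seq_len(4)) {
    fit <- logistic_fit(y, cbind(dosage = d[, j]))
    expect_equal(tr$beta[j], fit$beta[fit$term == "dosage"],
                 tolerance = 1e-5)
  }
})

test_that("the proportional-odds fit maximises its own likelihood", {
  set.seed(17)
  n <- 200
  x <- rbinom(n, 2, 0.3)
  lat <- 0.5 * x + rlogis(n)
  y4 <- cut(lat, c(-Inf, -1, 0.5, 2, Inf), labels = FALSE)
  grp <- setNames(c("latest", "later", "earlier", "earliest")[y4],
                  sprintf("s%03d", 1:n))
  g <- geno_matrix(matrix(x, n, 1, dimnames = list(names(grp), "m1")),
                   tibble::tibble(marker = "m1", chrom = "1", pos = 100L,
                                  allele_minor = "A", allele_major = "G"))
  tr <- ordinal_trend(g, grp)
  # log-likelihood oracle for the cumulative-logit model
  lev <- c("latest", "later", "earlier", "earliest")
  yi <- match(grp, lev)
  loglik <- function(beta, zeta) {
    zb <- c(-Inf, zeta, Inf)
    upper <- plogis(zb[yi + 1] - beta * x)
    lower <- plogis(zb[yi] - beta * x)
    sum(log(pmax(upper - lower, 1e-300)))
  }
  # recover the fitted cutpoints by refitting with the same routine
  fit <- MASS::polr(factor(grp, levels = lev, ordered = TRUE) ~ x,
                    Hess = TRUE)
  ll_hat <- loglik(coef(fit)[["x"]], fit$zeta)
  set.seed(18)
  worse <- replicate(1000, {
    b <- coef(fit)[["x"]] + rnorm(1, 0, 0.5)
    z <- sort(fit$zeta + rnorm(3, 0, 0.5))
    loglik(b, z)
  })
  expect_true(all(worse <= ll_hat + 1e-6))
  expect_equal(tr$beta[1], coef(fit)[["x"]], tolerance = 1e-6)
})

test_that("null ordinal trend p-values are uniform", {
  set.seed(19)
  ps <- replicate(60, {
    n <- 120
    x <- rbinom(n, 2, 0.3)
    grp <- setNames(sample(rep(c("latest", "later", "earlier", "earliest"),
                               each = n / 4)), sprintf("s%03d", 1:n))
    g <- geno_matrix(matrix(x, n, 1,
                            dimnames = list(names(grp), "m1")),
                     tibble::tibble(marker = "m1", chrom = "1", pos = 100L,
                                    allele_minor = "A", allele_major = "G"))
    ordinal_trend(g, grp)$p_trend
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("GRS weights are frozen log odds ratios", {
  res <- tibble::tibble(marker = c("m01", "m02"),
                        beta = c(log(2), log(0.5)))
  g <- tiny_geno(rbind(a = c(1, 2), b = c(0, 0)))
  prof <- grs_learn(res, g)
  expect_equal(exp(unname(prof$weights)), c(2, 0.5), tolerance = 1e-12)
  sc <- grs_score(prof, g)
  expect_equal(sc$grs[sc$iid == "a"], log(2) * 1 + log(0.5) * 2)
  expect_equal(sc$grs[sc$iid == "b"], 0)      # all-major-homozygote
  # all OR = 1 -> every score 0
  prof0 <- grs_learn(dplyr::mutate(res, beta = 0), g)
  expect_true(all(grs_score(prof0, g)$grs == 0))
})

test_that("missing genotypes are imputed at the learning mean dosage", {
  res <- tibble::tibble(marker = c("m01", "m02"), beta = c(0.4, -0.3))
  g_learn <- tiny_geno(rbind(a = c(0, 2), b = c(1, 1), c = c(2, 0),
                             d = c(1, 1)))
  prof <- grs_learn(res, g_learn)
  g_new <- tiny_geno(rbind(x = c(NA_real_, NA_real_)))
  sc <- grs_score(prof, g_new)
  maf <- colMeans(g_learn$dosage) / 2
  expect_equal(sc$grs, sum(c(0.4, -0.3) * 2 * maf))
})

test_that("GRS scoring is a dot product and linear over marker partitions", {
  set.seed(20)
  w <- rnorm(5)
  res <- tibble::tibble(marker = sprintf("m%02d", 1:5), beta = w)
  d <- matrix(rbinom(3 * 5, 2, 0.4), 3, 5)
  g <- tiny_geno(d)
  prof <- grs_learn(res, g)
  sc <- grs_score(prof, g)
  expect_equal(sc$grs, as.vector(d %*% w), tolerance = 1e-12)
  # linearity over a disjoint marker partition
  g_a <- geno_subset(g, markers = sprintf("m%02d", 1:2))
  g_b <- geno_subset(g, markers = sprintf("m%02d", 3:5))
  expect_equal(grs_score(prof, g_a)$grs + grs_score(prof, g_b)$grs,
               sc$grs, tolerance = 1e-12)
  expect_error(grs_score(prof, tiny_geno(matrix(0, 1, 1,
    dimnames = list("z", "other")),
    map = tibble::tibble(marker = "other", chrom = "1", pos = 1L,
                         allele_minor = "A", allele_major = "G"))),
    "overlap")
})

test_that("tidy and glance expose the GRS profile", {
  res <- tibble::tibble(marker = c("m01", "m02"), beta = c(0.4, -0.3))
  g <- tiny_geno(rbind(a = c(0, 2), b = c(1, 1)))
  prof <- grs_learn(res, g)
  td <- tidy(prof)
  expect_identical(td$marker, c("m01", "m02"))
  expect_equal(td$or_, exp(c(0.4, -0.3)))
  expect_identical(glance(prof)$n_markers, 2L)
})

test_that("Mann-Whitney matches exact enumeration and symmetry", {
  # identical multisets: U at its centre, p = 1
  out <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$u, 4.5)
  expect_equal(out$p, 1)
  # exact branch vs wilcox.test's exact distribution (no ties)
  a <- c(1.2, 3.4, 0.7, 5.1)
  b <- c(2.2, 4.4, 6.1, 0.1)
  ours <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_identical(ours$method, "exact")
  expect_equal(ours$p, ref$p.value)
  # large shift: U pinned at an extreme, p very small
  big <- mann_whitney(rnorm(20) + 100, rnorm(20))
  expect_identical(big$u, 400)
  expect_lt(big$p, 0.001)
  expect_equal(mann_whitney(rep(1, 5), rep(1, 7))$p, 1)
})

test_that("Mann-Whitney normal branch tracks the tie-corrected reference", {
  set.seed(21)
  a <- sample(1:5, 30, replace = TRUE)
  b <- sample(2:6, 25, replace = TRUE)
  ours <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("GRS group trend equals closed-form least squares", {
  set.seed(22)
  n <- 80
  grp <- setNames(rep(c("latest", "later", "earlier", "earliest"),
                      each = n / 4), sprintf("s%03d", 1:n))
  scores <- tibble::tibble(iid = names(grp), grs = rnorm(n))
  out <- grs_group_trend(scores, grp)
  r <- match(grp, c("latest", "later", "earlier", "earliest"))
  sxx <- sum((r - mean(r))^2)
  slope <- sum((r - mean(r)) * (scores$grs - mean(scores$grs))) / sxx
  resid <- scores$grs - mean(scores$grs) - slope * (r - mean(r))
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  expect_equal(out$slope, slope, tolerance = 1e-10)
  expect_equal(out$t, slope / se, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(-abs(slope / se), n - 2), tolerance = 1e-10)
  # perfect gradient -> slope 1, tiny p; flat scores -> slope 0, p 1
  sc2 <- tibble::tibble(iid = names(grp), grs = r)
  out2 <- suppressWarnings(grs_group_trend(sc2, grp))
  expect_equal(out2$slope, 1, tolerance = 1e-12)
  sc3 <- tibble::tibble(iid = names(grp), grs = 2)
  out3 <- suppressWarnings(grs_group_trend(sc3, grp))
  expect_equal(out3$slope, 0)
  expect_equal(out3$p, 1)
})

test_that("group descriptives use Fisher's exact and Welch tests", {
  ped <- dplyr::bind_rows(
    dplyr::mutate(tiny_family("FA", c(15, 16), sex_sibs = c(1L, 1L)),
                  aao_group = "earliest"),
    dplyr::mutate(tiny_family("FB", c(30, 31), sex_sibs = c(2L, 1L)),
                  aao_group = "latest"))
  sibs <- ped[ped$affected %in% TRUE, ]
  out <- group_descriptives(sibs)
  expect_identical(out$test, c("fisher_exact", "welch_t", "welch_t"))
  # Fisher oracle on the 2x2 (3,1; 1,3) layout
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher.test(tab)$p.value, 0.4857142857, tolerance = 1e-9)
  g1 <- c(15, 16); g2 <- c(30, 31)
  expect_equal(out$p[out$variable == "aao"],
               t.test(g1, g2)$p.value, tolerance = 1e-12)
})
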