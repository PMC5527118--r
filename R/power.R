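#' Analytic power of the two-group extreme-onset design
#'
#' Power of the 1-df additive trend (Cochran-Armitage) test comparing
#' genotype distributions between an early-onset and a late-onset patient
#' group.  Genotype frequencies follow Hardy-Weinberg at the given MAF; the
#' baseline penetrance-scale value `f0` is solved from
#' `prev = f0 * (P(g0) + grr_het * P(g1) + grr_hom * P(g2))`, where `prev`
#' is the prevalence of early onset among patients; group-specific genotype
#' distributions then follow by Bayes.  The trend statistic uses additive
#' scores (0, 1, 2); its null variance is evaluated at the pooled mixture
#' and its alternative distribution is normal with the group-specific
#' variances, giving
#' `power = P(|T| > z_{alpha/2})` in closed form.
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @param grr_het,grr_hom Genotype relative risks (het / hom vs non-carrier),
#'   both >= 1.
#' @param prev_early Prevalence of early onset among patients, in (0, 1).
#' @param n_per_group Patients per group.
#' @param alpha Two-sided significance level.
#' @return Power in [0, 1].
#' @export
power_two_group <- function(maf, grr_het, grr_hom, prev_early,
                            n_per_group, alpha = 0.05) {
  stopifnot(maf > 0, maf <= 0.5, grr_het >= 1, grr_hom >= 1,
            prev_early > 0, prev_early < 1, n_per_group > 0,
            alpha > 0, alpha < 1)
  pg <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  grr <- c(1, grr_het, grr_hom)
  f0 <- prev_early / sum(grr * pg)
  f <- f0 * grr
  if (any(f > 1)) stop("parameter error: implied penetrance exceeds 1")
  p_early <- f * pg / prev_early          # P(g | early)
  p_late <- (1 - f) * pg / (1 - prev_early)

  x <- 0:2
  mu_e <- sum(x * p_early)
  mu_l <- sum(x * p_late)
  v_e <- sum(x^2 * p_early) - mu_e^2
  v_l <- sum(x^2 * p_late) - mu_l^2
  pool <- (p_early + p_late) / 2
  v0 <- sum(x^2 * pool) - sum(x * pool)^2

  n <- n_per_group
  se0 <- sqrt(v0 * 2 / n)                  # null SE of the mean difference
  se1 <- sqrt((v_e + v_l) / n)             # SE under the alternative
  delta <- mu_e - mu_l
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((delta - zc * se0) / se1) +
    stats::pnorm((-delta - zc * se0) / se1)
}

#' Monte-Carlo power of the two-group design
#'
#' Simulation companion to [power_two_group()]: draws genotype counts from
#' the early/late multinomials and applies the additive trend test at level
#' `alpha`.
#'
#' @inheritParams power_two_group
#' @param n_rep Replicates.
#' @param seed Integer seed.
#' @return Estimated power.
#' @export
power_two_group_mc <- function(maf, grr_het, grr_hom, prev_early,
                               n_per_group, alpha = 0.05, n_rep = 1e4,
                               seed = 1L) {
  set.seed(seed)
  pg <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  grr <- c(1, grr_het, grr_hom)
  f0 <- prev_early / sum(grr * pg)
  f <- f0 * grr
  p_early <- f * pg / prev_early
  p_late <- (1 - f) * pg / (1 - prev_early)
  n <- n_per_group
  ce <- stats::rmultinom(n_rep, n, p_early)
  cl <- stats::rmultinom(n_rep, n, p_late)
  x <- 0:2
  mean_e <- colSums(ce * x) / n
  mean_l <- colSums(cl * x) / n
  pool <- (ce + cl) / (2 * n)
  v0 <- colSums(pool * x^2) - colSums(pool * x)^2
  tstat <- (mean_e - mean_l) / sqrt(v0 * 2 / n)
  crit <- stats::qnorm(1 - alpha / 2)
  mean(abs(tstat) > crit, na.rm = TRUE)
}
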