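#' Sibling replication of candidate markers
#'
#' Unadjusted per-marker logistic regression of family tail membership in
#' the co-affected siblings, with a Bonferroni verdict at `0.05 / m_tests`.
#'
#' @param g_sibs [geno_matrix()] over the co-affected siblings.
#' @param groups Named labels (`earliest` / `latest`) per sibling, from the
#'   family's stratum.
#' @param m_tests Number of candidate tests entering the Bonferroni
#'   correction.
#' @param sex Optional named sex vector (1/2); when given, fits adjust for
#'   it.
#' @return Tibble `marker`, `beta`, `or_`, `se`, `p`, `maf_earliest`,
#'   `maf_latest`, `n_used`, `significant`; the threshold is in
#'   `attr(, "bonferroni")`.
#' @export
sibling_replication <- function(g_sibs, groups, m_tests, sex = NULL) {
  stopifnot(m_tests >= 1)
  grp <- normalise_groups(groups, sample_ids(g_sibs))
  y <- as.numeric(grp == "earliest")
  thr <- 0.05 / m_tests
  d <- g_sibs$dosage
  sx <- if (!is.null(sex)) as.numeric(sex[sample_ids(g_sibs)])
  res <- purrr::map(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    ok <- !is.na(x) & (is.null(sx) | !is.na(sx %||% 0))
    out <- tibble::tibble(beta = NA_real_, se = NA_real_, p = NA_real_,
                          maf_earliest = mean(x[ok & y == 1]) / 2,
                          maf_latest = mean(x[ok & y == 0]) / 2,
                          n_used = sum(ok))
    if (stats::var(x[ok]) == 0) return(out)
    X <- cbind(dosage = x[ok], if (!is.null(sx)) cbind(sex = sx[ok]))
    fit <- logistic_fit(y[ok], X)
    row <- fit[fit$term == "dosage", ]
    out$beta <- row$beta; out$se <- row$se; out$p <- row$p
    out
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(tibble::tibble(marker = marker_ids(g_sibs)), res)
  out$or_ <- exp(out$beta)
  out$significant <- !is.na(out$p) & out$p < thr
  out <- out[, c("marker", "beta", "or_", "se", "p", "maf_earliest",
                 "maf_latest", "n_used", "significant")]
  attr(out, "bonferroni") <- thr
  out
}

#' Ordinal (proportional-odds) trend across onset groups
#'
#' Cumulative-logit proportional-odds regression of the ordered family
#' stratum on marker dosage, one marker at a time.  The outcome is ordered
#' with `earliest` highest, so an odds ratio above 1 means the minor allele
#' is associated with earlier onset — the same sign convention as the
#' two-group scan.
#'
#' @param g A [geno_matrix()] over the probands of all four groups.
#' @param groups Named labels per sample from
#'   `latest < later < earlier < earliest`.
#' @param sex Optional named sex vector; adjusts when given.
#' @return Tibble `marker`, `beta`, `or_trend`, `se`, `p_trend`, plus one
#'   MAF column per represented group.
#' @export
ordinal_trend <- function(g, groups, sex = NULL) {
  grp <- normalise_groups(groups, sample_ids(g))
  levs <- c("latest", "later", "earlier", "earliest")
  present <- levs[levs %in% unique(grp)]
  if (length(present) < 2) stop("need >= 2 onset groups represented")
  yord <- factor(grp, levels = present, ordered = TRUE)
  sx <- if (!is.null(sex)) as.numeric(sex[sample_ids(g)])
  d <- g$dosage
  res <- purrr::map(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    ok <- !is.na(x)
    mafs <- vapply(present, function(l) mean(x[ok & grp == l]) / 2,
                   numeric(1))
    out <- tibble::tibble(beta = NA_real_, se = NA_real_, p_trend = NA_real_)
    out[paste0("maf_", present)] <- as.list(mafs)
    if (stats::var(x[ok]) == 0) return(out)
    if (length(unique(as.integer(yord[ok]))) == 2) {
      # two represented levels: the cumulative-logit model is binary
      # logistic regression on the upper level
      y2 <- as.numeric(yord[ok] == max(yord[ok]))
      X <- cbind(dosage = x[ok], if (!is.null(sx)) cbind(sex = sx[ok]))
      fit <- try(logistic_fit(y2, X), silent = TRUE)
      if (inherits(fit, "try-error")) return(out)
      row <- fit[fit$term == "dosage", ]
      if (!row$converged) return(out)
      out$beta <- row$beta; out$se <- row$se; out$p_trend <- row$p
      return(out)
    }
    dat <- data.frame(y = droplevels(yord[ok]), dosage = x[ok])
    form <- y ~ dosage
    if (!is.null(sx)) { dat$sex <- sx[ok]; form <- y ~ dosage + sex }
    fit <- try(suppressWarnings(
      MASS::polr(form, data = dat, Hess = TRUE, method = "logistic")),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(out)
    beta <- fit$coefficients[["dosage"]]
    if (abs(beta) > 15) return(out)   # separation guard
    se <- sqrt(diag(stats::vcov(fit)))[["dosage"]]
    out$beta <- beta; out$se <- se
    out$p_trend <- 2 * stats::pnorm(-abs(beta / se))
    out
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(tibble::tibble(marker = marker_ids(g)), res)
  out$or_trend <- exp(out$beta)
  dplyr::relocate(out, "marker", "beta", "or_trend", "se", "p_trend")
}

#' Learn genetic-risk-score weights
#'
#' Freezes per-marker weights `w_j = log(OR_j)` (natural log) from a
#' learning-set association table, together with the learning-set MAFs used
#' to impute missing dosages at scoring time.  Weights are never refit when
#' the profile is applied to new samples.
#'
#' @param results Association tibble with `marker` and `beta` (log OR).
#' @param g_learn [geno_matrix()] of the learning samples (for MAFs).
#' @param markers Markers to include (default: all in `results`).
#' @return An object of class `grs_profile`.
#' @export
grs_learn <- function(results, g_learn, markers = results$marker) {
  rows <- results[match(markers, results$marker), ]
  drop <- is.na(rows$beta)
  if (any(drop)) {
    warning("marker(s) without a finite log OR excluded: ",
            paste(rows$marker[drop], collapse = ", "))
    rows <- rows[!drop, ]
  }
  stopifnot(nrow(rows) > 0)
  maf <- marker_maf(geno_subset(g_learn, markers = rows$marker))
  structure(list(weights = stats::setNames(rows$beta, rows$marker),
                 learning_maf = maf),
            class = "grs_profile")
}

#' @export
print.grs_profile <- function(x, ...) {
  cat("<grs_profile> ", length(x$weights), " markers; |w| range ",
      paste(signif(range(abs(x$weights)), 3), collapse = " - "), "\n",
      sep = "")
  invisible(x)
}

#' Score samples with a frozen GRS profile
#'
#' `score_i = sum_j w_j * g_ij` with genotypes coded 0/1/2 minor-allele
#' dosage; a missing dosage is imputed by its learning-set mean `2 * MAF_j`
#' so scores stay comparable across missingness patterns.
#'
#' @param profile A `grs_profile`.
#' @param g A [geno_matrix()].
#' @return Tibble `iid`, `grs`.
#' @export
grs_score <- function(profile, g) {
  common <- intersect(names(profile$weights), marker_ids(g))
  if (!length(common)) stop("no marker overlap between profile and genotypes")
  d <- g$dosage[, common, drop = FALSE]
  imp <- 2 * profile$learning_maf[common]
  for (j in seq_along(common)) d[is.na(d[, j]), j] <- imp[j]
  w <- profile$weights[common]
  tibble::tibble(iid = rownames(d), grs = as.vector(d %*% w))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two score vectors with midranks for ties.  With
#' `n_a + n_b <= 12` the null distribution of U is enumerated exactly over
#' all group assignments; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param a,b Numeric vectors.
#' @return Tibble `u`, `z`, `p`, `method`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b)
  all_v <- c(a, b)
  r <- rank(all_v)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (stats::var(all_v) == 0) {
    return(tibble::tibble(u = u, z = 0, p = 1, method = "degenerate"))
  }
  if (na + nb <= 12) {
    sets <- utils::combn(na + nb, na)
    us <- apply(sets, 2, function(s) sum(r[s]) - na * (na + 1) / 2)
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    z <- (u - mu) / stats::sd(us)
    return(tibble::tibble(u = u, z = z, p = p, method = "exact"))
  }
  n <- na + nb
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- na * nb / 12 * (n + 1 - tie_term)
  mu <- na * nb / 2
  cc <- sign(u - mu) * 0.5
  z <- (u - mu - cc) / sqrt(v)
  tibble::tibble(u = u, z = z, p = 2 * stats::pnorm(-abs(z)),
                 method = "normal")
}

#' Linear trend of the GRS across ordered onset groups
#'
#' Ordinary least squares of the score on the group rank (latest = 1 ...
#' earliest = 4), so a positive slope means higher risk score with earlier
#' onset.
#'
#' @param scores Tibble `iid`, `grs` (from [grs_score()]).
#' @param groups Named group labels per sample.
#' @return Tibble `slope`, `se`, `t`, `p`, `n`, plus per-group means and
#'   standard errors in `attr(, "group_summary")`.
#' @export
grs_group_trend <- function(scores, groups) {
  grp <- normalise_groups(groups, scores$iid)
  levs <- c("latest", "later", "earlier", "earliest")
  rank <- match(grp, levs)
  ok <- !is.na(rank) & !is.na(scores$grs)
  if (length(unique(rank[ok])) < 2) stop("need >= 2 onset groups")
  fit <- stats::lm(scores$grs[ok] ~ rank[ok])
  sm <- summary(fit)$coefficients
  gs <- tibble::tibble(group = grp[ok], grs = scores$grs[ok]) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$grs),
                     se = stats::sd(.data$grs) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(slope = sm[2, 1], se = sm[2, 2], t = sm[2, 3],
                        p = sm[2, 4], n = sum(ok))
  if (isTRUE(all.equal(out$se, 0)) || is.nan(out$t)) {
    out$t <- 0; out$p <- 1
  }
  attr(out, "group_summary") <- gs
  out
}

#' Group descriptives in the style of a baseline-characteristics table
#'
#' Compares two groups: dichotomous variables by two-sided Fisher's exact
#' test, continuous variables by Welch's two-sided t-test.
#'
#' @param ped Pedigree tibble restricted to the compared individuals.
#' @param group_col Column naming the two groups (default `aao_group`).
#' @return Tibble `variable`, per-group summaries, `p`, `test`.
#' @export
group_descriptives <- function(ped, group_col = "aao_group") {
  grp <- ped[[group_col]]
  levs <- unique(grp)
  stopifnot(length(levs) == 2)
  g1 <- ped[grp == levs[1], ]; g2 <- ped[grp == levs[2], ]
  row_cont <- function(var) {
    x1 <- g1[[var]][!is.na(g1[[var]])]
    x2 <- g2[[var]][!is.na(g2[[var]])]
    p <- if (length(x1) > 1 && length(x2) > 1 &&
             (stats::sd(x1) > 0 || stats::sd(x2) > 0)) {
      stats::t.test(x1, x2)$p.value
    } else if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else NA_real_
    tibble::tibble(
      variable = var,
      summary_1 = sprintf("%.1f(%.1f)", mean(x1), stats::sd(x1)),
      summary_2 = sprintf("%.1f(%.1f)", mean(x2), stats::sd(x2)),
      p = p, test = "welch_t")
  }
  male1 <- sum(g1$sex == 1, na.rm = TRUE); tot1 <- sum(!is.na(g1$sex))
  male2 <- sum(g2$sex == 1, na.rm = TRUE); tot2 <- sum(!is.na(g2$sex))
  tab <- matrix(c(male1, tot1 - male1, male2, tot2 - male2), 2)
  p_sex <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
    stats::fisher.test(tab)$p.value
  dplyr::bind_rows(
    tibble::tibble(
      variable = "male",
      summary_1 = sprintf("%d(%.0f%%)", male1, 100 * male1 / max(tot1, 1)),
      summary_2 = sprintf("%d(%.0f%%)", male2, 100 * male2 / max(tot2, 1)),
      p = p_sex, test = "fisher_exact"),
    row_cont("age"),
    if (any(!is.na(ped$aao))) row_cont("aao")) |>
    stats::setNames(c("variable", paste0("summary_", levs), "p", "test"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
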