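#' Logistic regression fit with separation guarding
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm.fit()]) returning per-column Wald statistics.  Fits that fail
#' to converge or drift into complete/quasi-separation (any |beta| > 15 on
#' the log-odds scale) are flagged and their p-values set missing.
#'
#' @param y Binary outcome (0/1 or logical).
#' @param X Numeric matrix of predictors (no intercept column; one is
#'   added).
#' @return Tibble `term`, `beta`, `se`, `z`, `p`, `converged`.
#' @export
logistic_fit <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(unique(y[!is.na(y)])) == 2)
  const <- apply(X, 2, function(v) stats::var(v, na.rm = TRUE) == 0)
  if (any(const)) stop("constant predictor column: ",
                       paste(colnames(X)[const], collapse = ", "))
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   control = list(epsilon = 1e-14, maxit = 60)))
  beta <- fit$coefficients
  ok <- fit$converged && all(abs(beta) <= 15, na.rm = TRUE)
  # observed-information covariance from the final IRLS weights
  w <- fit$weights
  XtWX <- crossprod(Xd * sqrt(w))
  se <- rep(NA_real_, length(beta))
  cov <- try(solve(XtWX), silent = TRUE)
  if (!inherits(cov, "try-error")) se <- sqrt(diag(cov))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (!ok) p[] <- NA_real_
  tibble::tibble(term = names(beta), beta = unname(beta), se = unname(se),
                 z = unname(z), p = unname(p), converged = ok)
}

#' Extreme-group genome scan
#'
#' Per-marker additive-dosage logistic regression of tail membership
#' (1 = earliest-onset group) with ancestry adjustment: every MDS component
#' whose between-group two-sample t-test has p < 0.05 enters as a covariate
#' (when none does, the scan runs unadjusted and says so).  Missing dosages
#' drop the sample marker-wise.
#'
#' @param g A [geno_matrix()] over the scanned samples.
#' @param groups Named character vector (or tibble `iid`, `aao_group`)
#'   assigning each sample to `earliest` or `latest`.
#' @param mds Optional `mds_components` over (at least) the scanned samples.
#' @return A tibble of class `aao_scan`: `marker`, `chrom`, `pos`, `beta`
#'   (log odds ratio per minor allele, earliest vs latest), `or_`, `se`,
#'   `p_wald`, `p_empirical` (NA until [empirical_p()] fills it),
#'   `maf_earliest`, `maf_latest`, `n_used`; the adjusted components are in
#'   `attr(, "adjusted_components")`.
#' @export
gwas_scan <- function(g, groups, mds = NULL) {
  grp <- normalise_groups(groups, sample_ids(g))
  stopifnot(all(grp %in% c("earliest", "latest")))
  y <- as.numeric(grp == "earliest")

  covars <- NULL
  used_comp <- character(0)
  if (!is.null(mds)) {
    co <- mds$coords[match(sample_ids(g), mds$coords$iid), ]
    comp_cols <- setdiff(names(co), "iid")
    for (cc in comp_cols) {
      pt <- stats::t.test(co[[cc]][y == 1], co[[cc]][y == 0])$p.value
      if (pt < 0.05) used_comp <- c(used_comp, cc)
    }
    if (length(used_comp)) {
      covars <- as.matrix(co[, used_comp, drop = FALSE])
    } else {
      message("no MDS component separates the groups (t-test p >= 0.05); ",
              "scan runs unadjusted")
    }
  }

  d <- g$dosage
  res <- purrr::map(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    ok <- !is.na(x)
    out <- tibble::tibble(
      beta = NA_real_, se = NA_real_, p_wald = NA_real_,
      maf_earliest = mean(x[ok & y == 1]) / 2,
      maf_latest = mean(x[ok & y == 0]) / 2,
      n_used = sum(ok))
    if (stats::var(x[ok]) == 0 || length(unique(y[ok])) < 2) return(out)
    X <- cbind(dosage = x[ok],
               if (!is.null(covars)) covars[ok, , drop = FALSE])
    fit <- logistic_fit(y[ok], X)
    row <- fit[fit$term == "dosage", ]
    out$beta <- row$beta; out$se <- row$se; out$p_wald <- row$p
    out
  }) |> purrr::list_rbind()

  out <- dplyr::bind_cols(g$map[, c("marker", "chrom", "pos")], res)
  out$or_ <- exp(out$beta)
  out$p_empirical <- NA_real_
  out <- out[, c("marker", "chrom", "pos", "beta", "or_", "se", "p_wald",
                 "p_empirical", "maf_earliest", "maf_latest", "n_used")]
  attr(out, "adjusted_components") <- used_comp
  class(out) <- c("aao_scan", class(out))
  out
}

normalise_groups <- function(groups, ids) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$aao_group, groups$iid)
  }
  if (is.null(names(groups))) stop("groups must be named by sample id")
  g <- groups[ids]
  if (anyNA(g)) stop("group label missing for ",
                     paste(utils::head(ids[is.na(g)]), collapse = ", "))
  unname(g)
}

#' Permutation empirical p-value for one marker
#'
#' Permutes the group labels, refits the same logistic model and compares
#' Wald |z| of the dosage term with the observed value.  The estimate is
#' `(1 + #{perm >= obs}) / (1 + B)`; permutation stops early once 10
#' exceedances accrue (the estimate is then already stable in relative
#' terms).  With `n <= 8` samples and `B_max` at least the number of
#' distinct label assignments, all of them are enumerated instead and the
#' result is exact (without the +1 correction).
#'
#' @param g A [geno_matrix()].
#' @param groups As in [gwas_scan()].
#' @param mds Optional `mds_components` (the same adjustment rule applies).
#' @param marker Marker id.
#' @param B_max Maximum number of permutations.
#' @param seed Integer seed.
#' @return A list: `p` (the estimate; NA when the observed fit does not
#'   converge), `B` (permutations used), `exhaustive`.
#' @export
empirical_p <- function(g, groups, mds = NULL, marker, B_max = 1e4,
                        seed = 1L) {
  stopifnot(B_max >= 100)
  grp <- normalise_groups(groups, sample_ids(g))
  y <- as.numeric(grp == "earliest")
  x <- g$dosage[, marker]
  ok <- !is.na(x)
  covars <- scan_covars(g, y, mds)
  zstat <- function(yy) {
    X <- cbind(dosage = x[ok], if (!is.null(covars)) covars[ok, , drop = FALSE])
    fit <- try(logistic_fit(yy[ok], X), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    row <- fit[fit$term == "dosage", ]
    if (!row$converged) return(NA_real_)
    abs(row$z)
  }
  z_obs <- zstat(y)
  if (is.na(z_obs)) return(list(p = NA_real_, B = 0L, exhaustive = FALSE))

  n <- length(y)
  n1 <- sum(y == 1)
  n_assign <- choose(n, n1)
  if (n <= 8 && n_assign <= B_max) {
    sets <- utils::combn(n, n1)
    zs <- apply(sets, 2, function(s) {
      yy <- numeric(n); yy[s] <- 1
      zstat(yy)
    })
    p <- mean(zs >= z_obs - 1e-12, na.rm = TRUE)
    return(list(p = p, B = ncol(sets), exhaustive = TRUE))
  }

  set.seed(seed)
  exceed <- 0L
  b <- 0L
  while (b < B_max) {
    b <- b + 1L
    zb <- zstat(sample(y))
    if (!is.na(zb) && zb >= z_obs - 1e-12) exceed <- exceed + 1L
    if (exceed >= 10L) break
  }
  list(p = (1 + exceed) / (1 + b), B = b, exhaustive = FALSE)
}

scan_covars <- function(g, y, mds) {
  if (is.null(mds)) return(NULL)
  co <- mds$coords[match(sample_ids(g), mds$coords$iid), ]
  comp_cols <- setdiff(names(co), "iid")
  used <- comp_cols[vapply(comp_cols, function(cc) {
    stats::t.test(co[[cc]][y == 1], co[[cc]][y == 0])$p.value < 0.05
  }, logical(1))]
  if (!length(used)) return(NULL)
  as.matrix(co[, used, drop = FALSE])
}

#' Select suggestive and genome-wide candidates
#'
#' Markers with Wald p strictly below the suggestive threshold are retained,
#' those below the genome-wide threshold flagged separately, and the set is
#' sorted by (chromosome, position).
#'
#' @param results An `aao_scan` tibble.
#' @param suggestive,genomewide Strict thresholds.
#' @return Tibble of class `candidate_set`: scan columns plus `genomewide`
#'   (logical) and `status` (`"retained"`).
#' @export
select_candidates <- function(results, suggestive = 1e-4,
                              genomewide = 7.2e-8) {
  stopifnot(nrow(results) > 0)
  hit <- !is.na(results$p_wald) & results$p_wald < suggestive
  out <- results[hit, ]
  out$genomewide <- out$p_wald < genomewide
  out$status <- "retained"
  out$collapsed_into <- NA_character_
  out <- dplyr::arrange(out, suppressWarnings(as.numeric(.data$chrom)),
                        .data$chrom, .data$pos)
  class(out) <- c("candidate_set", setdiff(class(out), "candidate_set"))
  out
}

#' Collapse candidates in high linkage disequilibrium
#'
#' Greedy collapse by ascending association p-value: each candidate is
#' absorbed into an already-retained marker when their dosage correlation
#' squared exceeds `r2_thresh` and they lie within `window_bp` on the same
#' chromosome; the retained marker of each clique is therefore its
#' smallest-p member.  The result is independent of the input row order.
#'
#' @param candidates A `candidate_set`.
#' @param g A [geno_matrix()] holding the candidate dosages.
#' @param r2_thresh Squared-correlation threshold (strict >).
#' @param window_bp Maximum separation in bp (inclusive).
#' @return The `candidate_set` with `status` updated to `ld_collapsed` and
#'   `collapsed_into` filled for absorbed markers.
#' @export
ld_collapse <- function(candidates, g, r2_thresh = 0.8,
                        window_bp = 5e5) {
  cand <- dplyr::arrange(candidates, .data$p_wald, .data$marker)
  d <- g$dosage[, cand$marker, drop = FALSE]
  kept <- integer(0)
  sink <- rep(NA_character_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    absorbed <- FALSE
    for (k in kept) {
      if (cand$chrom[i] != cand$chrom[k]) next
      if (abs(cand$pos[i] - cand$pos[k]) > window_bp) next
      xi <- d[, i]; xk <- d[, k]
      ok <- !is.na(xi) & !is.na(xk)
      if (!sum(ok)) {
        warning("candidates ", cand$marker[i], " and ", cand$marker[k],
                " share no typed sample; treated as unlinked")
        next
      }
      r2 <- suppressWarnings(stats::cor(xi[ok], xk[ok]))^2
      if (!is.na(r2) && r2 > r2_thresh) {
        absorbed <- TRUE
        sink[i] <- cand$marker[k]
        break
      }
    }
    if (!absorbed) kept <- c(kept, i)
  }
  cand$status <- ifelse(is.na(sink), "retained", "ld_collapsed")
  cand$collapsed_into <- sink
  out <- dplyr::arrange(cand, suppressWarnings(as.numeric(.data$chrom)),
                        .data$chrom, .data$pos)
  class(out) <- c("candidate_set", setdiff(class(out), "candidate_set"))
  out
}

#' Exclude candidates failing a replication-round call-rate filter
#'
#' Candidates re-genotyped on a second platform can fail that round's marker
#' call-rate check; they are dropped from confirmation with status
#' `lowcall_excluded`.
#'
#' @param candidates A `candidate_set` (after collapse).
#' @param g_replication [geno_matrix()] from the replication round.
#' @param call_thresh Strict retention threshold.
#' @return The updated `candidate_set`.
#' @export
replication_callrate_filter <- function(candidates, g_replication,
                                        call_thresh = 0.98) {
  cr <- marker_call_rate(g_replication)
  rate <- cr$call_rate[match(candidates$marker, cr$marker)]
  fail <- candidates$status == "retained" &
    (!is.na(rate) & rate <= call_thresh)
  candidates$status[fail] <- "lowcall_excluded"
  candidates
}
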