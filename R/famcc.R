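# Offspring dosage distribution given a parental dosage pair: convolution
# of two independent transmissions (het parent transmits the minor allele
# with probability 1/2; homozygotes are deterministic).
offspring_dist <- function(g_f, g_m) {
  tx <- function(g) switch(as.character(g),
                           "0" = c(1, 0), "1" = c(0.5, 0.5), "2" = c(0, 1))
  pf <- tx(g_f); pm <- tx(g_m)
  d <- numeric(3)
  for (a in 0:1) for (b in 0:1) d[a + b + 1] <- d[a + b + 1] + pf[a + 1] * pm[b + 1]
  d
}

#' Family-based association test, additive model
#'
#' FBAT-style statistic for one marker with affection as the outcome: for
#' every affected, genotyped offspring with both parents genotyped, the
#' observed minor-allele dosage `X` is compared with its Mendelian
#' expectation conditional on the parental pair.  `S = sum X`,
#' `E[S]` and `Var[S]` accumulate over offspring (independent given
#' parents), and `z = (S - E[S]) / sqrt(Var[S])` is referred to the standard
#' normal, two-sided.  Families without a heterozygous parent contribute
#' nothing and are uninformative.  Families with a missing parental genotype
#' are excluded (a deliberate simplification relative to sufficient-statistic
#' conditioning; their count is reported).
#'
#' @param g A [geno_matrix()] over parents and offspring.
#' @param ped Pedigree tibble (`iid`, `father`, `mother`, `affected`).
#' @param marker Marker id.
#' @return Tibble `marker`, `s`, `e_s`, `var_s`, `z`, `p`,
#'   `n_informative_families`, `n_families_excluded`.
#' @export
fbat_additive <- function(g, ped, marker) {
  d <- g$dosage[, marker]
  kids <- ped[ped$affected %in% TRUE & ped$father != "0" & ped$mother != "0", ]
  have <- function(id) id %in% names(d) & !is.na(d[id])
  usable <- have(kids$iid) & have(kids$father) & have(kids$mother)
  n_excluded <- length(unique(kids$fid[!usable]))
  kids <- kids[usable, ]
  s <- e_s <- var_s <- 0
  informative <- character(0)
  for (i in seq_len(nrow(kids))) {
    dist <- offspring_dist(d[[kids$father[i]]], d[[kids$mother[i]]])
    e <- sum(0:2 * dist)
    v <- sum((0:2)^2 * dist) - e^2
    s <- s + d[[kids$iid[i]]]
    e_s <- e_s + e
    var_s <- var_s + v
    if (v > 0) informative <- union(informative, kids$fid[i])
  }
  if (var_s <= 0) {
    return(tibble::tibble(marker = marker, s = s, e_s = e_s, var_s = var_s,
                          z = NA_real_, p = NA_real_,
                          n_informative_families = 0L,
                          n_families_excluded = n_excluded))
  }
  z <- (s - e_s) / sqrt(var_s)
  tibble::tibble(marker = marker, s = s, e_s = e_s, var_s = var_s, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 n_informative_families = length(informative),
                 n_families_excluded = n_excluded)
}

#' FBAT scan over a marker panel
#'
#' @param g A [geno_matrix()].
#' @param ped Pedigree tibble.
#' @param markers Marker ids (default all).
#' @return Row-bound [fbat_additive()] results.
#' @export
fbat_scan <- function(g, ped, markers = marker_ids(g)) {
  purrr::map(markers, function(m) fbat_additive(g, ped, m)) |>
    purrr::list_rbind()
}

#' Frequency-match controls to cases
#'
#' Computes the case distribution over sex-by-age-bin strata and selects
#' `ratio` controls per case, allocating per-stratum quotas by
#' largest-remainder rounding of `ratio * case count` (so quotas sum exactly
#' to `ratio * n_cases`) and sampling controls without replacement within
#' each stratum.
#'
#' @param cases Pedigree tibble of cases (`iid`, `sex`, `age`).
#' @param pool Pedigree tibble of candidate controls.
#' @param ratio Controls per case.
#' @param age_bin_years Width of the age bins.
#' @param seed Integer seed for within-stratum sampling.
#' @return A list of class `matched_set`: `controls` (tibble `iid`, `sex`,
#'   `age_bin`), `strata` (per-stratum cases, quota, pool size), `ratio`.
#' @export
match_controls <- function(cases, pool, ratio = 5, age_bin_years = 5,
                           seed = 1L) {
  stopifnot(ratio > 0, age_bin_years > 0)
  bin <- function(age) floor(age / age_bin_years)
  cs <- tibble::tibble(sex = cases$sex, age_bin = bin(cases$age)) |>
    dplyr::count(.data$sex, .data$age_bin, name = "n_cases")
  po <- tibble::tibble(iid = pool$iid, sex = pool$sex,
                       age_bin = bin(pool$age))
  strata <- cs |>
    dplyr::left_join(dplyr::count(po, .data$sex, .data$age_bin,
                                  name = "n_pool"),
                     by = c("sex", "age_bin")) |>
    dplyr::mutate(n_pool = dplyr::coalesce(.data$n_pool, 0L))

  target <- as.integer(round(ratio * nrow(cases)))
  raw <- ratio * strata$n_cases
  quota <- as.integer(floor(raw))
  short <- target - sum(quota)
  if (short > 0) {
    extra <- order(raw - quota, -strata$n_cases, decreasing = TRUE)[seq_len(short)]
    quota[extra] <- quota[extra] + 1L
  }
  strata$quota <- quota
  deficient <- strata[strata$quota > strata$n_pool, ]
  if (nrow(deficient)) {
    stop("matching error: deficient stratum(s) ",
         paste(sprintf("sex=%d age_bin=%d (need %d, have %d)",
                       deficient$sex, deficient$age_bin, deficient$quota,
                       deficient$n_pool), collapse = "; "))
  }
  set.seed(seed)
  picks <- purrr::pmap(strata, function(sex, age_bin, n_cases, n_pool,
                                        quota) {
    ids <- po$iid[po$sex == sex & po$age_bin == age_bin]
    ids[sample.int(length(ids), quota)]
  })
  chosen <- po[po$iid %in% unlist(picks), ]
  structure(list(controls = chosen, strata = strata, ratio = ratio),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("<matched_set> ", nrow(x$controls), " controls over ",
      nrow(x$strata), " strata at ratio ", x$ratio, "\n", sep = "")
  invisible(x)
}

#' Case-control association with age and sex adjustment
#'
#' Per-marker additive logistic regression of case status on dosage with age
#' and sex covariates, over the matched case + control sample.
#'
#' @param g_cases,g_controls [geno_matrix()] objects over the same marker
#'   map.
#' @param covars Tibble `iid`, `age`, `sex` covering all samples.
#' @return Tibble `marker`, `beta`, `or_`, `se`, `p`, `n_used`.
#' @export
case_control_assoc <- function(g_cases, g_controls, covars) {
  g <- geno_rbind(g_cases, g_controls)
  y <- c(rep(1, nrow(g_cases$dosage)), rep(0, nrow(g_controls$dosage)))
  cv <- covars[match(sample_ids(g), covars$iid), ]
  if (anyNA(cv$age) || anyNA(cv$sex)) {
    stop("age/sex covariates missing for some samples")
  }
  d <- g$dosage
  purrr::map(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    ok <- !is.na(x)
    out <- tibble::tibble(marker = marker_ids(g)[j], beta = NA_real_,
                          or_ = NA_real_, se = NA_real_, p = NA_real_,
                          n_used = sum(ok))
    if (stats::var(x[ok]) == 0) return(out)
    X <- cbind(dosage = x[ok], age = cv$age[ok], sex = cv$sex[ok])
    keep <- apply(X, 2, function(v) stats::var(v) > 0)
    fit <- logistic_fit(y[ok], X[, keep, drop = FALSE])
    row <- fit[fit$term == "dosage", ]
    out$beta <- row$beta; out$or_ <- exp(row$beta)
    out$se <- row$se; out$p <- row$p
    out
  }) |> purrr::list_rbind()
}
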