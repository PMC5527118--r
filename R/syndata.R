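#' Simulation configuration for a multiplex-family cohort
#'
#' Collects every generative parameter of the synthetic cohort.  Defaults
#' describe a multiplex-family ascertainment: families with two or more
#' siblings affected by the disease, a mean age at onset of 23.7 years with a
#' total SD near 9.2 decomposed into a family random effect (SD 4) and
#' individual noise (SD 7), and per-minor-allele modifier shifts in years.
#'
#' @param n_families Number of families.
#' @param sibs_per_family Affected siblings per family (ascertainment
#'   requires at least 2).
#' @param markers Number of biallelic autosomal markers.
#' @param maf_range Interval in (0, 0.5] from which ancestral minor-allele
#'   frequencies are drawn uniformly.
#' @param n_modifier_snps Number of markers given a non-zero onset effect.
#' @param modifier_effects_years Per-minor-allele shift in onset (years) for
#'   each modifier marker; recycled to `n_modifier_snps`.
#' @param aao_mean_years Baseline mean age at onset.
#' @param family_sd_years SD of the shared family random effect.
#' @param residual_sd_years SD of the individual residual.
#' @param fst Balding-Nichols divergence for an optional second
#'   subpopulation; 0 disables structure.
#' @param prop_pop2 Fraction of families drawn from subpopulation 2 (used
#'   only when `fst > 0`).
#' @param missing_rate Per-genotype missingness, applied uniformly at random.
#' @param susceptibility_snp Index of a marker whose minor allele raises
#'   disease risk (0 = none); used to give family-based association a
#'   non-null test bed.
#' @param susceptibility_grr Per-allele genotype relative risk of the
#'   susceptibility marker.
#' @param seed Integer seed; identical (config, seed) gives byte-identical
#'   cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 100,
                       sibs_per_family = 2,
                       markers = 200,
                       maf_range = c(0.05, 0.5),
                       n_modifier_snps = 0,
                       modifier_effects_years = numeric(0),
                       aao_mean_years = 23.7,
                       family_sd_years = 4,
                       residual_sd_years = 7,
                       fst = 0,
                       prop_pop2 = 0.5,
                       missing_rate = 0,
                       susceptibility_snp = 0,
                       susceptibility_grr = 1,
                       seed = 1L) {
  cfg <- list(n_families = n_families, sibs_per_family = sibs_per_family,
              markers = markers, maf_range = maf_range,
              n_modifier_snps = n_modifier_snps,
              modifier_effects_years = rep_len(
                if (n_modifier_snps > 0) modifier_effects_years else numeric(0),
                n_modifier_snps),
              aao_mean_years = aao_mean_years,
              family_sd_years = family_sd_years,
              residual_sd_years = residual_sd_years,
              fst = fst, prop_pop2 = prop_pop2,
              missing_rate = missing_rate,
              susceptibility_snp = as.integer(susceptibility_snp),
              susceptibility_grr = susceptibility_grr,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid simulation config: field '", field, "' ", why,
                  call. = FALSE)
  }
  chk(cfg$n_families >= 1, "n_families", "must be >= 1")
  chk(cfg$sibs_per_family >= 2, "sibs_per_family",
      "must be >= 2 (multiplex ascertainment)")
  chk(cfg$markers >= 1, "markers", "must be >= 1")
  chk(length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
        cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2],
      "maf_range", "must be an interval within (0, 0.5]")
  chk(cfg$n_modifier_snps <= cfg$markers, "n_modifier_snps",
      "cannot exceed the marker count")
  chk(cfg$family_sd_years >= 0, "family_sd_years", "must be >= 0")
  chk(cfg$residual_sd_years >= 0, "residual_sd_years", "must be >= 0")
  chk(cfg$fst >= 0 && cfg$fst < 1, "fst", "must lie in [0, 1)")
  chk(cfg$prop_pop2 >= 0 && cfg$prop_pop2 <= 1, "prop_pop2",
      "must lie in [0, 1]")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  chk(cfg$susceptibility_snp >= 0 &&
        cfg$susceptibility_snp <= cfg$markers, "susceptibility_snp",
      "must index a marker or be 0")
  chk(cfg$susceptibility_grr >= 1, "susceptibility_grr", "must be >= 1")
  invisible(cfg)
}

# Balding-Nichols subpopulation frequency draw around ancestral p.
bn_freq <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

# One transmitted minor-allele count from a parent of given dosage.
transmit <- function(par_dosage) {
  n <- length(par_dosage)
  out <- integer(n)
  out[par_dosage == 2] <- 1L
  het <- par_dosage == 1
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

#' Simulate a seeded multiplex-family cohort
#'
#' Founders draw alleles per marker from the (sub)population frequency;
#' offspring genotypes arise by gene dropping, so Mendelian consistency holds
#' by construction.  Each affected sibling's age at onset is
#' `mu + sum_j beta_j * g_ij + f_fam + eps`, with a Normal family effect and
#' Normal residual, floored at 7 years; current age adds an illness duration
#' drawn Uniform(5, 20) years.  When a susceptibility marker is configured,
#' transmissions at that marker to (ascertained-affected) siblings are
#' reweighted by the per-allele relative risk.
#'
#' @param config A [sim_config()].
#' @return A list of class `family_cohort` with elements `geno`
#'   ([geno_matrix()] over parents and siblings), `ped` (pedigree tibble),
#'   `true_modifiers` (tibble: marker, effect_years), `founder_maf`
#'   (ancestral frequencies), `family_pop` (subpopulation per family) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$markers
  nf <- cfg$n_families
  ns <- cfg$sibs_per_family

  maf <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
  map <- default_marker_map(L)

  mod_idx <- if (cfg$n_modifier_snps > 0) {
    sort(sample.int(L, cfg$n_modifier_snps))
  } else integer(0)
  beta <- numeric(L)
  beta[mod_idx] <- cfg$modifier_effects_years

  fam_pop <- if (cfg$fst > 0) {
    1L + stats::rbinom(nf, 1L, cfg$prop_pop2)
  } else rep(1L, nf)
  freq <- rbind(pop1 = bn_freq(maf, cfg$fst), pop2 = bn_freq(maf, cfg$fst))
  if (cfg$fst <= 0) freq[2, ] <- freq[1, ]

  fids <- sprintf("F%04d", seq_len(nf))
  n_per_fam <- 2L + ns
  n_tot <- nf * n_per_fam
  dosage <- matrix(NA_real_, n_tot, L)
  iids <- character(n_tot)
  ped_rows <- vector("list", nf)

  srr <- cfg$susceptibility_grr
  s_idx <- cfg$susceptibility_snp

  row <- 0L
  for (f in seq_len(nf)) {
    p <- freq[fam_pop[f], ]
    g_f <- stats::rbinom(L, 2L, p)
    g_m <- stats::rbinom(L, 2L, p)
    sib_g <- matrix(0L, ns, L)
    for (s in seq_len(ns)) {
      g_c <- transmit(g_f) + transmit(g_m)
      if (s_idx > 0 && srr > 1) {
        # ascertained-affected child: accept transmission at the risk locus
        # with probability proportional to grr^dosage (rejection sampling)
        repeat {
          if (stats::runif(1) <= srr^g_c[s_idx] / srr^2) break
          g_c[s_idx] <- transmit(g_f[s_idx]) + transmit(g_m[s_idx])
        }
      }
      sib_g[s, ] <- g_c
    }
    f_fam <- stats::rnorm(1, 0, cfg$family_sd_years)
    eps <- stats::rnorm(ns, 0, cfg$residual_sd_years)
    aao <- cfg$aao_mean_years + as.vector(sib_g %*% beta) + f_fam + eps
    aao <- pmax(aao, 7)
    dur <- stats::runif(ns, 5, 20)
    sib_sex <- 1L + stats::rbinom(ns, 1L, 0.5)
    par_sex <- c(1L, 2L)
    par_age <- round(max(aao + dur) + stats::runif(2, 22, 32), 1)

    ids <- c(paste0(fids[f], "_P1"), paste0(fids[f], "_P2"),
             paste0(fids[f], "_S", seq_len(ns)))
    iids[row + seq_len(n_per_fam)] <- ids
    dosage[row + 1L, ] <- g_f
    dosage[row + 2L, ] <- g_m
    dosage[row + 2L + seq_len(ns), ] <- sib_g
    ped_rows[[f]] <- pedigree_table(
      fid = fids[f], iid = ids,
      father = c("0", "0", rep(ids[1], ns)),
      mother = c("0", "0", rep(ids[2], ns)),
      sex = c(par_sex, sib_sex),
      affected = c(FALSE, FALSE, rep(TRUE, ns)),
      aao = c(NA, NA, round(aao, 1)),
      age = c(par_age, round(aao + dur, 1)),
      role = c("parent", "parent", rep("co_sib", ns)),
      aao_group = "none")
    row <- row + n_per_fam
  }
  rownames(dosage) <- iids
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(dosage)) < cfg$missing_rate
    dosage[miss] <- NA_real_
  }
  structure(list(
    geno = geno_matrix(dosage, map),
    ped = dplyr::bind_rows(ped_rows),
    true_modifiers = tibble::tibble(marker = map$marker[mod_idx],
                                    effect_years = beta[mod_idx]),
    founder_maf = stats::setNames(maf, map$marker),
    family_pop = stats::setNames(fam_pop, fids),
    config = cfg), class = "family_cohort")
}

# Evenly spread markers over 22 autosomes with increasing positions.
default_marker_map <- function(L) {
  chrom <- as.character(rep_len(1:22, L))
  pos <- integer(L)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- seq(1e6, by = 1e5, length.out = k)
  }
  tibble::tibble(marker = sprintf("snp%05d", seq_len(L)), chrom = chrom,
                 pos = pos, allele_minor = "A", allele_major = "G")
}

#' @export
print.family_cohort <- function(x, ...) {
  cat("<family_cohort> ", x$config$n_families, " families, ",
      nrow(x$geno$dosage), " individuals, ", ncol(x$geno$dosage),
      " markers, ", nrow(x$true_modifiers), " modifier SNP(s)\n", sep = "")
  invisible(x)
}

#' Rank families by mean sibling onset and label extremes
#'
#' Families are ranked by the mean age at onset of their affected siblings
#' (ties broken by family id, lexically, so the labelling is deterministic
#' and invariant to input order).  The `n_extreme` families at each tail
#' become `earliest` / `latest`; the next `n_middle` inward on each side
#' become `earlier` / `later`; the rest keep `aao_group = "none"`.  Within
#' each labelled family one affected sibling is promoted to proband — the
#' minimum-onset sibling on the early side, the maximum-onset sibling on the
#' late side (ties by individual id) — and the remaining affected siblings
#' stay co-affected.
#'
#' @param cohort A `family_cohort` (or its pedigree tibble).
#' @param n_extreme Families per tail.
#' @param n_middle Families per intermediate group.
#' @return The pedigree tibble with `aao_group` and `role` filled in.
#' @export
rank_and_select_extremes <- function(cohort, n_extreme, n_middle = 0) {
  ped <- if (inherits(cohort, "family_cohort")) cohort$ped else cohort
  sibs <- ped[ped$affected %in% TRUE & !is.na(ped$aao), ]
  fam <- sibs |>
    dplyr::group_by(.data$fid) |>
    dplyr::summarise(mean_aao = mean(.data$aao), n_aff = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$mean_aao, .data$fid)
  if (any(fam$n_aff < 2)) {
    stop("every family must carry >= 2 affected siblings with onset ages")
  }
  nf <- nrow(fam)
  if (2 * (n_extreme + n_middle) > nf) {
    stop("cannot select 2*(", n_extreme, "+", n_middle, ") families from ",
         nf)
  }
  grp <- rep("none", nf)
  grp[seq_len(n_extreme)] <- "earliest"
  if (n_middle > 0) grp[n_extreme + seq_len(n_middle)] <- "earlier"
  grp[nf + 1 - seq_len(n_extreme)] <- "latest"
  if (n_middle > 0) grp[nf - n_extreme + 1 - seq_len(n_middle)] <- "later"
  fam$aao_group <- grp

  ped$aao_group <- fam$aao_group[match(ped$fid, fam$fid)]
  ped$aao_group[is.na(ped$aao_group)] <- "none"

  early <- c("earliest", "earlier")
  is_sib <- ped$affected %in% TRUE & !is.na(ped$aao) &
    ped$role %in% c("co_sib", "proband")
  ped$role[is_sib] <- "co_sib"
  for (f in fam$fid[fam$aao_group != "none"]) {
    rows <- which(ped$fid == f & is_sib)
    side_early <- fam$aao_group[fam$fid == f] %in% early
    a <- ped$aao[rows]
    pick <- if (side_early) {
      rows[order(a, ped$iid[rows])][1]
    } else {
      rows[order(-a, ped$iid[rows])][1]
    }
    ped$role[pick] <- "proband"
  }
  ped
}

#' Plant quality-control defects into a cohort
#'
#' Produces the standard QC test fixture: selected probands are given a low
#' genotyping call rate (10% of genotypes dropped, i.e. call rate ~0.90),
#' replaced by a near-duplicate of another proband (1% random discordance —
#' half miscalls, half no-calls, so the copy's call rate sits just below its
#' source's and kinship-based removal resolves the pair deterministically),
#' or redrawn from a diverged subpopulation (Balding-Nichols, `fst` 0.1) so
#' they appear as ancestry outliers.  Defect assignments never overlap.
#'
#' @param base A `family_cohort` whose pedigree already labels probands.
#' @param n_lowcall,n_duplicate,n_outlier Number of probands per defect.
#' @param seed Integer seed for the defect draws.
#' @param outlier_fst Divergence of the outlier subpopulation.
#' @return A list with `cohort` (modified copy of `base`) and `manifest`
#'   (tibble: `iid`, `defect`, and for duplicates `source_iid`).
#' @export
make_qc_fixture <- function(base, n_lowcall = 2, n_duplicate = 1,
                            n_outlier = 2, seed = 1L, outlier_fst = 0.1) {
  stopifnot(inherits(base, "family_cohort"))
  set.seed(seed)
  probands <- base$ped$iid[base$ped$role == "proband"]
  n_def <- n_lowcall + n_duplicate + n_outlier
  if (length(probands) < n_def + n_duplicate) {
    stop("fixture error: ", length(probands),
         " probands cannot host ", n_def, " defects")
  }
  chosen <- sample(probands, n_def)
  low_ids <- utils::head(chosen, n_lowcall)
  dup_ids <- chosen[n_lowcall + seq_len(n_duplicate)]
  out_ids <- utils::tail(chosen, n_outlier)

  d <- base$geno$dosage
  L <- ncol(d)
  for (id in low_ids) {
    drop <- sample.int(L, ceiling(0.10 * L))
    d[id, drop] <- NA_real_
  }
  src_pool <- setdiff(probands, chosen)
  manifest <- tibble::tibble(iid = character(0), defect = character(0),
                             source_iid = character(0))
  for (id in dup_ids) {
    src <- src_pool[sample.int(length(src_pool), 1)]
    g <- d[src, ]
    flip <- which(stats::runif(L) < 0.01)
    miss <- flip[seq_along(flip) %% 2 == 0]
    flip <- setdiff(flip, miss)
    g[flip] <- vapply(g[flip], function(x) {
      sample(setdiff(0:2, x), 1)
    }, numeric(1))
    g[miss] <- NA_real_
    d[id, ] <- g
    manifest <- dplyr::bind_rows(manifest,
      tibble::tibble(iid = id, defect = "duplicate", source_iid = src))
  }
  if (n_outlier > 0) {
    p_out <- bn_freq(base$founder_maf, outlier_fst)
    for (id in out_ids) d[id, ] <- stats::rbinom(L, 2L, p_out)
  }
  manifest <- dplyr::bind_rows(
    tibble::tibble(iid = low_ids, defect = "low_call",
                   source_iid = NA_character_),
    manifest,
    tibble::tibble(iid = out_ids, defect = "ancestry_outlier",
                   source_iid = NA_character_))
  out <- base
  out$geno <- geno_matrix(d, base$geno$map)
  list(cohort = out, manifest = manifest)
}

#' Simulate an unrelated control pool
#'
#' Founder-like genotypes at the cohort's marker map, drawn from the supplied
#' per-marker frequencies, with age and sex for frequency matching.  Controls
#' carry their own one-person family ids, disjoint from the cohort's.
#'
#' @param map Marker map tibble (as in a [geno_matrix()]).
#' @param maf Per-marker minor-allele frequencies for the control population.
#' @param n Number of controls.
#' @param age_range Uniform age range (years).
#' @param seed Integer seed.
#' @return A list with `ped` and `geno`.
#' @export
simulate_control_pool <- function(map, maf, n, age_range = c(18, 60),
                                  seed = 1L) {
  stopifnot(n > 0, length(maf) == nrow(map))
  set.seed(seed)
  L <- nrow(map)
  dosage <- matrix(stats::rbinom(n * L, 2L, rep(maf, each = n)), n, L)
  ids <- sprintf("C%05d", seq_len(n))
  rownames(dosage) <- ids
  ped <- pedigree_table(
    fid = paste0("CF", seq_len(n)), iid = ids,
    sex = 1L + stats::rbinom(n, 1L, 0.5),
    affected = FALSE,
    age = round(stats::runif(n, age_range[1], age_range[2]), 1),
    role = "control")
  list(ped = ped, geno = geno_matrix(dosage, map))
}
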