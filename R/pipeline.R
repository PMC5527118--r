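#' Pipeline configuration
#'
#' Bundles the simulation (or input) settings with every stage threshold at
#' its conventional default: sample/marker call rate 0.98, MAF 0.05, HWE
#' 0.001, kinship 0.354, ancestry z 5, suggestive threshold 1e-4,
#' genome-wide 7.2e-8, LD r-squared 0.8 within 500 kb, control:case ratio 5
#' in 5-year age bins.  All stage seeds derive from the single root seed in
#' a fixed order so any stage can be re-run in isolation.
#'
#' @param sim A [sim_config()] describing the cohort (or `NULL` when `ped` /
#'   `map` paths are supplied).
#' @param ped_path,map_path,phenotype_path Optional input files used instead
#'   of simulation.
#' @param n_extreme,n_middle Families per tail / per intermediate group.
#' @param call_thresh,maf_thresh,hwe_thresh,kinship_thresh,z_thresh Marker
#'   and sample QC thresholds.
#' @param suggestive,genomewide Candidate-selection thresholds.
#' @param r2_thresh,window_bp LD-collapse settings.
#' @param perm_B Permutations per candidate for empirical p-values (0
#'   disables).
#' @param ratio,age_bin_years Control matching settings.
#' @param control_pool_n Size of the simulated control pool.
#' @param seed Root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, ped_path = NULL, map_path = NULL,
                            phenotype_path = NULL,
                            n_extreme = 25, n_middle = 15,
                            call_thresh = 0.98, maf_thresh = 0.05,
                            hwe_thresh = 0.001, kinship_thresh = 0.354,
                            z_thresh = 5, suggestive = 1e-4,
                            genomewide = 7.2e-8, r2_thresh = 0.8,
                            window_bp = 5e5, perm_B = 1000,
                            ratio = 5, age_bin_years = 5,
                            control_pool_n = 2000, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 11L, qc = 23L, scan = 37L, perm = 41L,
               controls = 53L, match = 67L)
  (cfg$seed + offsets[[stage]] * 1000L) %% .Machine$integer.max
}

#' Run the full modifier-locus pipeline
#'
#' Simulate (or load) a multiplex-family cohort, label the onset extremes,
#' QC the probands, scan earliest-vs-latest with MDS adjustment, select and
#' LD-collapse suggestive candidates, replicate in co-affected siblings,
#' test the four-group ordinal trend, build and test the GRS, and run the
#' susceptibility-side FBAT and matched case-control analyses.  Every stage
#' writes a TSV artifact plus a run log; re-running with the same config
#' reproduces the tables byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of in-memory stage results; artifacts are in
#'   `out_dir`.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.tsv")
  log_rows <- list()
  note <- function(stage, ...) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, detail = paste0(...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, "ERROR: ", conditionMessage(e))
      readr::write_tsv(dplyr::bind_rows(log_rows), log_path)
      stop("pipeline aborted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  # -- cohort ---------------------------------------------------------------
  cohort <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- as.integer(stage_seed(config, "simulate"))
      simulate_cohort(sim)
    } else {
      io <- read_ped_map(config$ped_path, config$map_path)
      ped <- read_phenotypes(config$phenotype_path)
      structure(list(geno = io$geno, ped = ped,
                     true_modifiers = tibble::tibble(),
                     founder_maf = marker_maf(io$geno),
                     config = NULL), class = "family_cohort")
    }
  })
  note("input", nrow(cohort$ped), " individuals, ",
       ncol(cohort$geno$dosage), " markers")

  ped <- run_stage("select", rank_and_select_extremes(
    cohort, n_extreme = config$n_extreme, n_middle = config$n_middle))
  write_phenotypes(ped, file.path(out_dir, "phenotypes.tsv"))

  extreme <- ped[ped$role == "proband" &
                   ped$aao_group %in% c("earliest", "latest"), ]
  g_prob <- geno_subset(cohort$geno, samples = extreme$iid)

  # -- marker + sample QC ---------------------------------------------------
  mk <- run_stage("marker_qc", marker_filters(
    g_prob, call_thresh = config$call_thresh,
    maf_thresh = config$maf_thresh, hwe_thresh = config$hwe_thresh))
  g_prob <- geno_subset(g_prob, markers = mk$keep)
  note("marker_qc", length(mk$keep), " markers kept, ",
       nrow(mk$removed), " removed")

  qc <- run_stage("sample_qc", sample_qc(
    g_prob, call_thresh = config$call_thresh,
    kinship_thresh = config$kinship_thresh, z_thresh = config$z_thresh))
  readr::write_tsv(qc$removed, file.path(out_dir, "qc_report.tsv"))
  readr::write_tsv(qc$mds$coords, file.path(out_dir, "mds.tsv"))
  note("sample_qc", nrow(extreme), " in, ", length(qc$keep), " kept, ",
       nrow(qc$removed), " removed")
  g_scan <- geno_subset(g_prob, samples = qc$keep)
  groups <- stats::setNames(extreme$aao_group, extreme$iid)[qc$keep]

  # -- scan -----------------------------------------------------------------
  mds_keep <- classical_mds(ibs_distance(g_scan))
  scan <- run_stage("scan", gwas_scan(g_scan, groups, mds_keep))
  lambda <- genomic_inflation(chi2 = (scan$beta / scan$se)^2)
  write_results_tsv(scan, file.path(out_dir, "gwas_results.tsv"))
  note("scan", nrow(scan), " markers scanned; lambda = ",
       format(round(lambda, 4), nsmall = 4))

  cand <- run_stage("candidates", select_candidates(
    scan, suggestive = config$suggestive, genomewide = config$genomewide))
  if (config$perm_B > 0 && nrow(cand)) {
    for (m in cand$marker) {
      ep <- empirical_p(g_scan, groups, mds_keep, m,
                        B_max = config$perm_B,
                        seed = stage_seed(config, "perm"))
      cand$p_empirical[cand$marker == m] <- ep$p
    }
  }
  cand <- run_stage("ld_collapse", ld_collapse(
    cand, g_scan, r2_thresh = config$r2_thresh,
    window_bp = config$window_bp))
  write_results_tsv(cand, file.path(out_dir, "candidates.tsv"))
  note("candidates", sum(cand$status == "retained"), " retained, ",
       sum(cand$status == "ld_collapsed"), " collapsed")
  final <- cand$marker[cand$status == "retained"]

  results <- list(cohort = cohort, ped = ped, qc = qc, scan = scan,
                  lambda = lambda, candidates = cand)
  if (!length(final)) {
    note("confirm", "no candidates; downstream stages skipped")
    readr::write_tsv(dplyr::bind_rows(log_rows), log_path)
    yaml::write_yaml(serialise_config(config),
                     file.path(out_dir, "config_resolved.yaml"))
    return(invisible(results))
  }

  # -- sibling replication --------------------------------------------------
  sibs <- ped[ped$role == "co_sib" &
                ped$aao_group %in% c("earliest", "latest") &
                ped$fid %in% extreme$fid[extreme$iid %in% qc$keep], ]
  g_sibs <- geno_subset(cohort$geno, samples = sibs$iid, markers = final)
  repl <- run_stage("replication", sibling_replication(
    g_sibs, stats::setNames(sibs$aao_group, sibs$iid),
    m_tests = length(final)))
  write_results_tsv(repl, file.path(out_dir, "replication.tsv"))
  note("replication", sum(repl$significant), " of ", nrow(repl),
       " significant at Bonferroni ",
       format(attr(repl, "bonferroni"), digits = 2))

  # -- four-group trend -----------------------------------------------------
  four <- ped[ped$role == "proband" & ped$aao_group != "none", ]
  four <- four[!(four$aao_group %in% c("earliest", "latest")) |
                 four$iid %in% qc$keep, ]
  g_four <- geno_subset(cohort$geno, samples = four$iid, markers = final)
  trend <- run_stage("trend", ordinal_trend(
    g_four, stats::setNames(four$aao_group, four$iid)))
  write_results_tsv(trend, file.path(out_dir, "trend.tsv"))

  # -- GRS ------------------------------------------------------------------
  profile <- run_stage("grs", grs_learn(scan, g_scan, markers = final))
  sc_prob <- grs_score(profile, g_scan)
  sc_sibs <- grs_score(profile, g_sibs)
  sc_four <- grs_score(profile, g_four)
  scores <- dplyr::bind_rows(
    dplyr::mutate(sc_prob, set = "proband"),
    dplyr::mutate(sc_sibs, set = "co_sib"),
    dplyr::mutate(sc_four[!(sc_four$iid %in% sc_prob$iid), ],
                  set = "four_group"))
  readr::write_tsv(scores, file.path(out_dir, "grs_scores.tsv"))
  grp_of <- stats::setNames(ped$aao_group, ped$iid)
  mw_prob <- mann_whitney(sc_prob$grs[grp_of[sc_prob$iid] == "earliest"],
                          sc_prob$grs[grp_of[sc_prob$iid] == "latest"])
  mw_sibs <- mann_whitney(sc_sibs$grs[grp_of[sc_sibs$iid] == "earliest"],
                          sc_sibs$grs[grp_of[sc_sibs$iid] == "latest"])
  tr_grs <- grs_group_trend(sc_four, stats::setNames(four$aao_group,
                                                     four$iid))
  grs_tests <- dplyr::bind_rows(
    dplyr::mutate(mw_prob, test = "mann_whitney_probands"),
    dplyr::mutate(mw_sibs, test = "mann_whitney_sibs"),
    tibble::tibble(u = NA, z = tr_grs$t, p = tr_grs$p,
                   method = "ols_trend", test = "grs_group_trend"))
  readr::write_tsv(grs_tests, file.path(out_dir, "grs_tests.tsv"))
  note("grs", "proband contrast p = ", format(mw_prob$p, digits = 3),
       "; sib contrast p = ", format(mw_sibs$p, digits = 3),
       "; four-group trend p = ", format(tr_grs$p, digits = 3))

  # -- susceptibility side --------------------------------------------------
  fam_ids <- unique(extreme$fid[extreme$iid %in% qc$keep])
  fam_ped <- ped[ped$fid %in% fam_ids, ]
  g_fam <- geno_subset(cohort$geno,
                       samples = intersect(fam_ped$iid,
                                           sample_ids(cohort$geno)),
                       markers = final)
  fbat <- run_stage("fbat", fbat_scan(g_fam, fam_ped))
  write_results_tsv(fbat, file.path(out_dir, "fbat.tsv"))

  cases <- ped[ped$iid %in% qc$keep, ]
  pool <- run_stage("controls", simulate_control_pool(
    cohort$geno$map, cohort$founder_maf, n = config$control_pool_n,
    seed = stage_seed(config, "controls")))
  ms <- run_stage("match", match_controls(
    cases, pool$ped, ratio = config$ratio,
    age_bin_years = config$age_bin_years,
    seed = stage_seed(config, "match")))
  g_cases <- geno_subset(cohort$geno, samples = cases$iid, markers = final)
  g_ctrl <- geno_subset(pool$geno, samples = ms$controls$iid,
                        markers = final)
  covars <- dplyr::bind_rows(cases[, c("iid", "age", "sex")],
                             pool$ped[pool$ped$iid %in% ms$controls$iid,
                                      c("iid", "age", "sex")])
  cc <- run_stage("casecontrol", case_control_assoc(g_cases, g_ctrl, covars))
  write_results_tsv(cc, file.path(out_dir, "casecontrol.tsv"))
  note("casecontrol", nrow(ms$controls), " matched controls; ",
       sum(cc$p < 0.05, na.rm = TRUE), " markers at p < 0.05")

  readr::write_tsv(dplyr::bind_rows(log_rows), log_path)
  yaml::write_yaml(serialise_config(config),
                   file.path(out_dir, "config_resolved.yaml"))
  invisible(c(results, list(replication = repl, trend = trend,
                            grs_profile = profile, grs_scores = scores,
                            grs_tests = grs_tests, fbat = fbat,
                            matched = ms, casecontrol = cc)))
}

serialise_config <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  out
}

#' Summarise a completed run directory
#'
#' Assembles a human-readable markdown summary from the persisted stage
#' artifacts: sample attrition, the candidate table, GRS contrasts and the
#' susceptibility-side tests.  Missing artifacts are flagged rather than
#' fatal.
#'
#' @param run_dir Directory produced by [run_full()].
#' @return Character vector of markdown lines (invisibly written to
#'   `report.md` in `run_dir`).
#' @export
report <- function(run_dir) {
  lines <- c("# Modifier-locus pipeline run", "")
  grab <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE) else NULL
  }
  log <- grab("run_log.tsv")
  if (!is.null(log)) {
    lines <- c(lines, "## Stage log", "",
               paste0("- **", log$stage, "**: ", log$detail), "")
  } else lines <- c(lines, "*(run log missing)*", "")
  cand <- grab("candidates.tsv")
  if (!is.null(cand)) {
    lines <- c(lines, "## Candidates", "",
               paste0("- ", cand$marker, " (chr", cand$chrom, ":",
                      cand$pos, "): p = ", cand$p_wald, ", status = ",
                      cand$status))
  } else lines <- c(lines, "*(no candidate table)*")
  gt <- grab("grs_tests.tsv")
  if (!is.null(gt)) {
    lines <- c(lines, "", "## GRS tests", "",
               paste0("- ", gt$test, ": p = ", format(gt$p, digits = 3)))
  }
  lines <- c(lines, "")
  writeLines(lines, file.path(run_dir, "report.md"))
  invisible(lines)
}
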