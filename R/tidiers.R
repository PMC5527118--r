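#' Tidy a GRS profile
#'
#' @param x A `grs_profile`.
#' @param ... Unused.
#' @return Tibble `marker`, `weight`, `or_`, `learning_maf`.
#' @export
tidy.grs_profile <- function(x, ...) {
  tibble::tibble(marker = names(x$weights), weight = unname(x$weights),
                 or_ = exp(unname(x$weights)),
                 learning_maf = unname(x$learning_maf[names(x$weights)]))
}

#' One-line summary of a GRS profile
#'
#' @param x A `grs_profile`.
#' @param ... Unused.
#' @return Tibble `n_markers`, `mean_abs_weight`.
#' @export
glance.grs_profile <- function(x, ...) {
  tibble::tibble(n_markers = length(x$weights),
                 mean_abs_weight = mean(abs(x$weights)))
}

#' Tidy a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return The removed-samples tibble (`iid`, `reason`, `value`).
#' @export
tidy.qc_report <- function(x, ...) x$removed

#' One-line summary of a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return Tibble with retained/removed counts by reason.
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_retained = length(x$keep),
    n_low_call = sum(x$removed$reason == "low_call"),
    n_high_kinship = sum(x$removed$reason == "high_kinship"),
    n_ancestry_outlier = sum(x$removed$reason == "ancestry_outlier"))
}

#' Tidy a matched control set
#'
#' @param x A `matched_set`.
#' @param ... Unused.
#' @return The per-stratum allocation tibble.
#' @export
tidy.matched_set <- function(x, ...) x$strata

#' One-line summary of a matched set
#'
#' @param x A `matched_set`.
#' @param ... Unused.
#' @return Tibble `n_controls`, `n_strata`, `ratio`.
#' @export
glance.matched_set <- function(x, ...) {
  tibble::tibble(n_controls = nrow(x$controls), n_strata = nrow(x$strata),
                 ratio = x$ratio)
}
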