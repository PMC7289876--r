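#' Effective dose by the conventional DLP method
#'
#' Dose length product times the region-specific (whole-body) conversion
#' factor, `k_body = 0.015` mSv/(mGy cm).
#'
#' @param dlp Dose length product in mGy cm (>= 0).
#' @param k_body Conversion factor in mSv/(mGy cm).
#' @return Effective dose in mSv (full precision; report at 1 decimal).
#' @export
ed_dlp <- function(dlp, k_body = 0.015) {
  if (any(!is.finite(dlp)) || any(dlp < 0)) stop("dlp must be non-negative")
  if (any(k_body <= 0)) stop("k_body must be positive")
  dlp * k_body
}

#' Individual DLP-to-effective-dose conversion factor
#'
#' The per-patient counterpart of the population k-factor: the Monte Carlo
#' effective dose divided by the scanner-reported DLP.
#'
#' @param ed_mc Effective dose in mSv.
#' @param dlp Dose length product in mGy cm (> 0).
#' @return k in mSv/(mGy cm) (full precision; report at 3 decimals).
#' @export
k_mc <- function(ed_mc, dlp) {
  if (any(!is.finite(dlp)) || any(dlp <= 0)) {
    stop("dlp must be positive (k undefined at dlp = 0)")
  }
  if (any(ed_mc < 0)) stop("ed_mc must be non-negative")
  ed_mc / dlp
}

#' Relative deviation of an alternative dose estimate from a reference
#'
#' @param alternative Alternative estimate (mSv).
#' @param reference Reference estimate (mSv, > 0).
#' @return Percent deviation `100 * (alternative - reference) / reference`.
#' @export
relative_deviation <- function(alternative, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference must be positive")
  }
  100 * (alternative - reference) / reference
}

#' Count conversion factors within a band around the population value
#'
#' @param k_values Per-patient conversion factors.
#' @param center Band center (default the population k_body 0.015).
#' @param band Half-width as a fraction of `center` (default 10%).
#' @return Number of values in the closed interval `center * (1 +/- band)`.
#' @export
k_within_band <- function(k_values, center = 0.015, band = 0.10) {
  if (!length(k_values)) stop("k_values must be non-empty")
  lo <- center * (1 - band)
  hi <- center * (1 + band)
  sum(k_values >= lo & k_values <= hi)
}

#' Per-patient dose report for a cohort table
#'
#' Derives the conventional effective dose, individual conversion factor and
#' method deviations for every patient of a cohort table (as returned by
#' [load_cohort_table()] or produced by the synthetic pipeline). `ed_nci` is
#' an optionally ingested reference column; when absent, only the
#' NCI-dependent outputs are left out.
#'
#' @param cohort Data.frame with columns `dlp`, `ed_mc` and optionally
#'   `ed_nci` (plus any identifying columns, which are carried through).
#' @param k_body Population conversion factor.
#' @return A `dose_report` data.frame with `ed_dlp`, `k_mc`,
#'   `dev_mc_vs_dlp` and (when available) `dev_nci_vs_dlp`, at full
#'   precision.
#' @export
dose_report <- function(cohort, k_body = 0.015) {
  stopifnot(is.data.frame(cohort), all(c("dlp", "ed_mc") %in% names(cohort)))
  out <- cohort
  out$ed_dlp <- ed_dlp(cohort$dlp, k_body)
  out$k_mc <- k_mc(cohort$ed_mc, cohort$dlp)
  out$dev_mc_vs_dlp <- relative_deviation(cohort$ed_mc, out$ed_dlp)
  if ("ed_nci" %in% names(cohort)) {
    out$dev_nci_vs_dlp <- relative_deviation(cohort$ed_nci, out$ed_dlp)
  }
  class(out) <- c("dose_report", "data.frame")
  out
}

#' Round a dose report to the reporting precision
#'
#' mSv and percent columns at 1 decimal, conversion factors at 3 decimals
#' (half-up rounding, as in printed dose tables).
#'
#' @param report A `dose_report`.
#' @return A data.frame with rounded derived columns.
#' @export
format_dose_report <- function(report) {
  out <- as.data.frame(report)
  for (col in intersect(c("ed_dlp", "ed_mc", "ed_nci", "dev_mc_vs_dlp",
                          "dev_nci_vs_dlp"), names(out))) {
    out[[col]] <- round_half_up(out[[col]], 1)
  }
  if ("k_mc" %in% names(out)) out$k_mc <- round_half_up(out$k_mc, 3)
  out
}
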