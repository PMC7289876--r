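#' Summary statistics for a cohort variable
#'
#' Sample mean, standard deviation (n-1 denominator), minimum, maximum and
#' range, optionally split by a grouping column.
#'
#' @param cohort Data.frame (e.g. a `dose_report`).
#' @param variable Column name to summarize.
#' @param by Optional grouping column (e.g. `"sex"`).
#' @return A data.frame with columns `variable`, (group,) `n`, `mean`, `sd`,
#'   `min`, `max`, `range`.
#' @export
summarize_cohort <- function(cohort, variable, by = NULL) {
  if (!variable %in% names(cohort)) stop("unknown variable: ", variable)
  one <- function(x, label = NULL) {
    x <- x[is.finite(x)]
    if (length(x) < 2) stop("need at least 2 records to summarize")
    out <- data.frame(
      variable = variable, n = length(x), mean = mean(x), sd = stats::sd(x),
      min = min(x), max = max(x), range = max(x) - min(x),
      stringsAsFactors = FALSE
    )
    if (!is.null(label)) out <- cbind(group = label, out)
    out
  }
  if (is.null(by)) {
    one(cohort[[variable]])
  } else {
    if (!by %in% names(cohort)) stop("unknown grouping column: ", by)
    groups <- split(cohort[[variable]], cohort[[by]])
    do.call(rbind, Map(one, groups, names(groups)))
  }
}

#' Bland-Altman agreement analysis
#'
#' Mean and standard deviation of the paired differences `a - b` and the
#' 95% limits of agreement (mean +/- 1.96 SD).
#'
#' @param a,b Paired measurements (equal length >= 2), e.g. two
#'   effective-dose estimates in mSv.
#' @return An `agreement_result` list: `mean_difference`, `sd_difference`,
#'   `limits_of_agreement` (lower, upper), `pairs_n`, `mean_values`,
#'   `differences`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired series must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_difference = m, sd_difference = s,
         limits_of_agreement = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
         pairs_n = length(d), mean_values = (a + b) / 2, differences = d),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$pairs_n, ")\n", sep = "")
  cat("  mean difference: ", signif(x$mean_difference, 4), "\n", sep = "")
  cat("  limits of agreement: [", signif(x$limits_of_agreement[1], 4), ", ",
      signif(x$limits_of_agreement[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Tie-corrected Spearman rank correlation
#'
#' Average ranks are assigned to ties (the standard tie correction). A
#' two-sided p-value from the t approximation is attached as an attribute;
#' it is informational output, not a gatekeeper.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The rank correlation coefficient with attribute `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant input")
  }
  rs <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  )
  structure(rs, p_value = p)
}

#' Matched-pair patient comparison
#'
#' Percent change from patient 1 to patient 2 for each shared dose and risk
#' metric, mirroring a pairwise comparison of two patients who match on all
#' but one characteristic.
#'
#' @param p1,p2 Single-row data.frames (or named lists) holding the metrics.
#' @param metrics Metric columns to compare.
#' @return Named vector of percent differences `100 * (p2 - p1) / p1`.
#' @export
matched_pair_compare <- function(p1, p2,
                                 metrics = c("dlp", "ed_dlp", "ed_nci",
                                             "ed_mc", "lar", "err")) {
  metrics <- intersect(metrics, intersect(names(p1), names(p2)))
  if (!length(metrics)) stop("no shared metrics to compare")
  out <- vapply(metrics, function(m) {
    v1 <- as.numeric(p1[[m]])
    v2 <- as.numeric(p2[[m]])
    if (!is.finite(v1) || v1 == 0) {
      stop("zero or missing denominator for metric: ", m)
    }
    100 * (v2 - v1) / v1
  }, numeric(1))
  names(out) <- metrics
  out
}
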