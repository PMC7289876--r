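#' Mean absorbed dose over an organ
#'
#' Arithmetic mean of the absorbed-dose grid over the voxels carrying the
#' organ's label. An absent organ is an explicit error (not zero), so that
#' missing organs — aplasia, resection, or a deliberately omitted class —
#' remain distinguishable from an unirradiated organ.
#'
#' @param map A `dose_map` with `absorbed_dose` populated (see
#'   [scale_to_absorbed()]).
#' @param labels Integer label grid congruent with the dose grid.
#' @param organ Organ name from [organ_vocabulary()].
#' @return Mean absorbed organ dose in mGy.
#' @export
organ_mean_dose <- function(map, labels, organ) {
  stopifnot(inherits(map, "dose_map"))
  if (is.null(map$absorbed_dose)) {
    stop("dose map has no absorbed dose; call scale_to_absorbed() first")
  }
  if (!identical(dim(map$absorbed_dose), dim(labels))) {
    stop("label grid not congruent with dose grid")
  }
  vocab <- organ_vocabulary()
  if (!organ %in% vocab$organ) stop("unknown organ: ", organ)
  mask <- labels == vocab$label[vocab$organ == organ]
  if (!any(mask)) stop("organ missing from label map: ", organ)
  mean(map$absorbed_dose[mask])
}

#' Equivalent dose from absorbed dose
#'
#' Multiplies by the radiation weighting factor, which is 1 for photons, so
#' the value is numerically unchanged (mGy -> mSv).
#'
#' @param absorbed Absorbed dose in mGy (>= 0).
#' @param w_r Radiation weighting factor (1 for photons).
#' @return Equivalent dose in mSv.
#' @export
equivalent_dose <- function(absorbed, w_r = 1) {
  if (any(!is.finite(absorbed)) || any(absorbed < 0)) {
    stop("absorbed dose must be non-negative")
  }
  absorbed * w_r
}

#' Effective organ dose
#'
#' Equivalent organ dose times the organ's ICRP 103 tissue weighting factor.
#'
#' @param equivalent Equivalent organ dose in mSv.
#' @param organ Organ name.
#' @param tables Weighting tables from [icrp_weights()].
#' @return Effective organ dose contribution in mSv.
#' @export
effective_organ_dose <- function(equivalent, organ, tables = icrp_weights("female")) {
  if (!organ %in% names(tables$w_t)) stop("organ not in weighting table: ", organ)
  if (any(equivalent < 0)) stop("equivalent dose must be non-negative")
  equivalent * tables$w_t[[organ]]
}

#' Aggregate a dose map into an organ dose table
#'
#' Computes, for every organ of the sex-appropriate vocabulary present in the
#' label map: mean absorbed dose (mGy), equivalent dose (x W_R, mSv),
#' effective organ dose (x W_T, mSv) and the relative contribution to the
#' whole-body effective dose. The whole-body effective dose `ed_mc` is the
#' sum of the effective organ doses over the organs present; absent organs
#' are reported in the `missing` attribute, not imputed.
#'
#' @param map A scaled `dose_map`.
#' @param labels Label grid congruent with the dose grid.
#' @param sex `"female"` or `"male"` (selects the weighting table).
#' @return An `organ_dose_table`: data.frame (organ, absorbed_dose,
#'   equivalent_dose, w_t, effective_dose, contribution) with attributes
#'   `ed_mc` and `missing`.
#' @export
organ_dose_table <- function(map, labels, sex = c("female", "male")) {
  sex <- match.arg(sex)
  weights <- icrp_weights(sex)
  organs <- names(weights$w_t)
  vocab <- organ_vocabulary()
  present <- vapply(organs, function(o) {
    any(labels == vocab$label[vocab$organ == o])
  }, logical(1))
  if (!any(present)) stop("no vocabulary organ present in label map")
  rows <- lapply(organs[present], function(o) {
    absorbed <- organ_mean_dose(map, labels, o)
    equiv <- equivalent_dose(absorbed, weights$w_r)
    eff <- effective_organ_dose(equiv, o, weights)
    data.frame(organ = o, absorbed_dose = absorbed, equivalent_dose = equiv,
               w_t = weights$w_t[[o]], effective_dose = eff,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ed_mc <- sum(tab$effective_dose)
  tab$contribution <- if (ed_mc > 0) tab$effective_dose / ed_mc else NA_real_
  structure(tab, ed_mc = ed_mc, missing = organs[!present],
            sex = sex, class = c("organ_dose_table", "data.frame"))
}

#' Whole-body effective dose from an organ dose table
#'
#' The sum of the effective organ doses over the organs present. Missing
#' organs contribute nothing (their absence is reported by the table, not
#' imputed).
#'
#' @param table An `organ_dose_table`.
#' @return Whole-body effective dose in mSv.
#' @export
total_effective_dose <- function(table) {
  stopifnot(inherits(table, "organ_dose_table"))
  if (nrow(table) == 0) stop("empty organ dose table")
  sum(table$effective_dose)
}

#' Relative organ contributions to the whole-body effective dose
#'
#' @param table An `organ_dose_table`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
organ_contribution <- function(table) {
  stopifnot(inherits(table, "organ_dose_table"))
  ed <- total_effective_dose(table)
  if (ed <= 0) stop("whole-body effective dose is zero; contributions undefined")
  stats::setNames(table$effective_dose / ed, table$organ)
}

#' Write an organ dose table as CSV (reported precision) or JSON (full)
#'
#' Doses are reported at 1 decimal and contributions at 3 decimals in the CSV
#' variant; the JSON variant keeps full precision.
#'
#' @param table An `organ_dose_table`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_organ_dose_table <- function(table, path) {
  stopifnot(inherits(table, "organ_dose_table"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(organs = as.data.frame(table), ed_mc = attr(table, "ed_mc"),
           missing = attr(table, "missing"), sex = attr(table, "sex")),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    out <- as.data.frame(table)
    for (col in c("absorbed_dose", "equivalent_dose", "effective_dose")) {
      out[[col]] <- round_half_up(out[[col]], 1)
    }
    out$contribution <- round_half_up(out$contribution, 3)
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
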