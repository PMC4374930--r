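#' Filter out measurements dominated by mixing with tropospheric N2O
#'
#' Low-concentration soil and surface-water samples mostly reflect mixing
#' with tropospheric N2O rather than the source signature. Only soil,
#' freshwater and marine records are eligible for retention, and a record
#' is kept iff at least one criterion holds:
#'
#' * (i) it is a report of emitted N2O (`is_emitted` is `TRUE`), regardless
#'   of flux strength;
#' * (ii) soil-profile gas with `concentration_ppb > 650` (strict);
#' * (iii) freshwater, or marine from the top 100 m of the water column
#'   (`depth_m <= 100`, or depth absent for surface samples), with dissolved
#'   `saturation_pct > 200` (strict).
#'
#' A record eligible for a criterion but missing the field the criterion
#' needs is excluded and counted under "insufficient metadata" — it is never
#' retained by default. The per-category retention report is attached as the
#' `"retention"` attribute and returned by [retention_report()].
#'
#' @param dataset an [n2o_dataset()].
#' @return the filtered [n2o_dataset()], with a `retention` attribute: a
#'   data frame of per-category `total`, `kept`, and
#'   `insufficient_metadata` counts.
#' @export
filter_source_subset <- function(dataset) {
  stopifnot(inherits(dataset, "n2o_dataset"))
  eligible_cats <- c("soil", "freshwater", "marine")
  cat <- dataset$category
  eligible <- cat %in% eligible_cats

  emitted <- !is.na(dataset$is_emitted) & dataset$is_emitted

  conc_ok <- !is.na(dataset$concentration_ppb) & dataset$concentration_ppb > 650
  soil_keep <- cat == "soil" & conc_ok

  sat_ok <- !is.na(dataset$saturation_pct) & dataset$saturation_pct > 200
  surface <- is.na(dataset$depth_m) | dataset$depth_m <= 100
  fw_keep <- cat == "freshwater" & sat_ok
  marine_keep <- cat == "marine" & sat_ok & surface

  keep <- eligible & (emitted | soil_keep | fw_keep | marine_keep)

  # "insufficient metadata": eligible, not kept, and the category's own
  # criterion could not even be evaluated because its field is absent
  # (and the record is not flagged emitted).
  missing_meta <- eligible & !keep & is.na(dataset$is_emitted) &
    ((cat == "soil" & is.na(dataset$concentration_ppb)) |
     (cat %in% c("freshwater", "marine") & is.na(dataset$saturation_pct)))

  rep_df <- do.call(rbind, lapply(eligible_cats, function(cc) {
    idx <- cat == cc
    data.frame(category = cc, total = sum(idx), kept = sum(keep & idx),
               insufficient_metadata = sum(missing_meta & idx))
  }))

  out <- dataset[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(dataset, "provenance")
  class(out) <- class(dataset)
  attr(out, "retention") <- rep_df
  out
}

#' @rdname filter_source_subset
#' @export
retention_report <- function(dataset) attr(dataset, "retention")

#' Pool soil and freshwater into the continental source
#'
#' The continental N2O source is operationally defined as soil plus
#' freshwater. Records in those two categories are relabelled
#' `"continental"`; all other records pass through unchanged. Pooling is
#' idempotent.
#'
#' @param dataset an [n2o_dataset()] (normally already filtered).
#' @return an [n2o_dataset()] with soil/freshwater relabelled.
#' @export
pool_continental <- function(dataset) {
  stopifnot(inherits(dataset, "n2o_dataset"))
  dataset$category[dataset$category %in% c("soil", "freshwater")] <- "continental"
  dataset
}

#' Flux-weighted average of isotope values
#'
#' @param values per-mil isotope values.
#' @param weights non-negative flux weights, not all zero, same length.
#' @return `sum(values * weights) / sum(weights)`.
#' @export
flux_weighted_average <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length")
  }
  if (any(weights < 0)) stop("negative flux weight")
  if (all(weights == 0)) stop("all flux weights are zero")
  sum(values * weights) / sum(weights)
}
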