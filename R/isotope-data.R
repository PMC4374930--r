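# Canonical column set of an N2O isotope dataset. Deltas are per-mil
# (d15N vs air-N2, d18O vs VSMOW); concentration is ppb v/v; saturation is
# percent of atmospheric equilibrium; depth is metres.
N2O_COLUMNS <- c(
  "d15N_bulk", "d18O", "d15N_alpha", "d15N_beta", "site_preference",
  "category", "site", "reference",
  "concentration_ppb", "saturation_pct", "depth_m",
  "flux", "is_emitted", "filter_note"
)

N2O_NUMERIC_COLUMNS <- c(
  "d15N_bulk", "d18O", "d15N_alpha", "d15N_beta", "site_preference",
  "concentration_ppb", "saturation_pct", "depth_m", "flux"
)

#' Source and reservoir categories of N2O isotope measurements
#'
#' The eight categories used to classify compiled N2O isotope records, plus
#' the derived `"continental"` label produced by [pool_continental()].
#'
#' @param derived if `TRUE`, include the pooled `"continental"` label.
#' @return character vector of category labels.
#' @export
n2o_categories <- function(derived = FALSE) {
  base <- c("Antarctic", "freshwater", "groundwater", "marine",
            "soil", "stratosphere", "troposphere", "urban_wastewater")
  if (derived) c(base, "continental") else base
}

# Lenient-mode remapping of common category spellings to canonical labels.
CATEGORY_ALIASES <- c(
  "ocean"            = "marine",
  "oceanic"          = "marine",
  "sea"              = "marine",
  "seawater"         = "marine",
  "river"            = "freshwater",
  "lake"             = "freshwater",
  "stream"           = "freshwater",
  "soils"            = "soil",
  "terrestrial"      = "soil",
  "ground_water"     = "groundwater",
  "ground water"     = "groundwater",
  "wastewater"       = "urban_wastewater",
  "urban wastewater" = "urban_wastewater",
  "antarctic"        = "Antarctic",
  "tropospheric"     = "troposphere",
  "stratospheric"    = "stratosphere"
)

# Column-name aliases (case/Unicode variants seen in compiled tables) mapped
# to the canonical schema.
COLUMN_ALIASES <- list(
  d15N_bulk         = c("d15N_bulk", "d15N", "d15n", "δ15N", "δ15N_bulk",
                        "d15Nbulk", "d15N.N2O", "d15N-N2O", "delta15N"),
  d18O              = c("d18O", "d18o", "δ18O", "d18O.N2O", "d18O-N2O", "delta18O"),
  d15N_alpha        = c("d15N_alpha", "d15Na", "d15N.alpha", "δ15Nα", "alpha"),
  d15N_beta         = c("d15N_beta", "d15Nb", "d15N.beta", "δ15Nβ", "beta"),
  site_preference   = c("site_preference", "SP", "sp", "sitepref", "site.preference"),
  category          = c("category", "Category", "source_category", "group"),
  site              = c("site", "Site", "site_description", "description"),
  reference         = c("reference", "Reference", "ref", "citation"),
  concentration_ppb = c("concentration_ppb", "concentration", "conc_ppb",
                        "N2O_ppb", "ppb"),
  saturation_pct    = c("saturation_pct", "saturation", "sat_pct", "percent_saturation"),
  depth_m           = c("depth_m", "depth", "Depth"),
  flux              = c("flux", "Flux", "flux_weight", "weight"),
  is_emitted        = c("is_emitted", "emitted", "flux_chamber"),
  filter_note       = c("filter_note", "filter", "criteria", "filter_criteria")
)

#' Construct an N2O isotope dataset
#'
#' Builds the canonical data frame of isotope records used throughout the
#' package. Any subset of the canonical columns may be supplied; missing
#' optional columns are filled with `NA` (never 0). Records are validated:
#' categories must be among [n2o_categories()], site preference and bulk
#' d15N must be consistent with the isotopomer deltas when all are present
#' (within 0.05 per-mil), and concentration/saturation/depth must be
#' non-negative.
#'
#' @param df data frame with a `category` column and at least one delta
#'   column (`d15N_bulk`, `d18O`, `d15N_alpha`, `d15N_beta`, or
#'   `site_preference`).
#' @param provenance optional list recording where the records came from
#'   (source path, rows read/rejected, rejection reasons).
#' @return an object of class `n2o_dataset` (a data frame with the
#'   canonical columns and a `provenance` attribute).
#' @export
n2o_dataset <- function(df, provenance = NULL) {
  stopifnot(is.data.frame(df))
  if (!"category" %in% names(df)) {
    stop("missing mandatory column: category")
  }
  deltas <- c("d15N_bulk", "d18O", "d15N_alpha", "d15N_beta", "site_preference")
  if (!any(deltas %in% names(df))) {
    stop("missing mandatory columns: at least one of ",
         paste(deltas, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (col in N2O_COLUMNS) {
    if (col %in% names(df)) {
      out[[col]] <- df[[col]]
    } else if (col %in% N2O_NUMERIC_COLUMNS) {
      out[[col]] <- rep(NA_real_, nrow(df))
    } else if (col == "is_emitted") {
      out[[col]] <- rep(NA, nrow(df))
    } else {
      out[[col]] <- rep(NA_character_, nrow(df))
    }
  }
  out$category <- as.character(out$category)
  out$is_emitted <- as.logical(out$is_emitted)
  for (col in N2O_NUMERIC_COLUMNS) out[[col]] <- as.numeric(out[[col]])
  validate_n2o_records(out)
  if (is.null(provenance)) {
    provenance <- list(source = NA_character_, rows_read = nrow(out),
                       rows_rejected = 0L, reasons = character(0))
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("n2o_dataset", "data.frame")
  out
}

validate_n2o_records <- function(df) {
  bad_cat <- setdiff(unique(df$category), n2o_categories(derived = TRUE))
  if (length(bad_cat)) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "))
  }
  for (col in c("concentration_ppb", "saturation_pct", "depth_m")) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative values in ", col)
  }
  both <- !is.na(df$d15N_alpha) & !is.na(df$d15N_beta)
  if (any(both)) {
    sp_calc <- df$d15N_alpha[both] - df$d15N_beta[both]
    bulk_calc <- (df$d15N_alpha[both] + df$d15N_beta[both]) / 2
    sp_obs <- df$site_preference[both]
    bulk_obs <- df$d15N_bulk[both]
    bad_sp <- !is.na(sp_obs) & abs(sp_obs - sp_calc) > 0.05
    bad_bulk <- !is.na(bulk_obs) & abs(bulk_obs - bulk_calc) > 0.05
    if (any(bad_sp)) {
      stop("site_preference inconsistent with d15N_alpha - d15N_beta in ",
           sum(bad_sp), " record(s) (> 0.05 per-mil)")
    }
    if (any(bad_bulk)) {
      stop("d15N_bulk inconsistent with (d15N_alpha + d15N_beta)/2 in ",
           sum(bad_bulk), " record(s) (> 0.05 per-mil)")
    }
  }
  invisible(df)
}

#' @export
print.n2o_dataset <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("N2O isotope dataset: ", nrow(x), " records\n", sep = "")
  tab <- table(x$category)
  cat("  categories: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(prov) && isTRUE(prov$rows_rejected > 0)) {
    cat("  rejected at parse: ", prov$rows_rejected, " row(s)\n", sep = "")
  }
  invisible(x)
}

#' Read a compiled N2O isotope table from CSV
#'
#' Reads a comma-delimited, UTF-8, header-first table of isotope records.
#' Column names are resolved against a documented alias map, so e.g.
#' `d15N`, `delta15N` and `d15N-N2O` all map to `d15N_bulk`. Malformed
#' numeric cells and (in strict mode) unknown categories reject the row,
#' never the file: the returned dataset's `provenance` attribute lists each
#' rejected row with its reason.
#'
#' @param path CSV file path.
#' @param strict if `TRUE` (default), rows with unrecognised category labels
#'   are rejected; if `FALSE`, labels are first passed through the category
#'   alias table (e.g. "ocean" -> "marine") and only then rejected.
#' @param sep field separator, comma by default.
#' @return an [n2o_dataset()] with provenance (rows read, rows rejected,
#'   reasons).
#' @export
read_n2o_dataset <- function(path, strict = TRUE, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  nm <- names(raw)
  canon <- rep(NA_character_, length(nm))
  for (target in names(COLUMN_ALIASES)) {
    hit <- match(tolower(nm), tolower(COLUMN_ALIASES[[target]]))
    canon[!is.na(hit) & is.na(canon)] <- target
  }
  keep <- !is.na(canon)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]
  if (!"category" %in% names(raw)) {
    stop("missing mandatory column: category (no alias matched)")
  }
  deltas <- c("d15N_bulk", "d18O", "d15N_alpha", "d15N_beta", "site_preference")
  if (!any(deltas %in% names(raw))) {
    stop("missing mandatory columns: at least one delta column among ",
         paste(deltas, collapse = ", "))
  }

  n <- nrow(raw)
  reject <- character(n)  # "" = keep

  cat_in <- trimws(raw$category)
  if (!strict) {
    hit <- CATEGORY_ALIASES[tolower(cat_in)]
    cat_in[!is.na(hit)] <- unname(hit[!is.na(hit)])
  }
  bad <- !(cat_in %in% n2o_categories(derived = TRUE))
  reject[bad] <- paste0("unknown category: ", cat_in[bad])
  raw$category <- cat_in

  parsed <- raw
  for (col in intersect(N2O_NUMERIC_COLUMNS, names(raw))) {
    txt <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(txt))
    malformed <- !is.na(txt) & txt != "" & txt != "NA" & is.na(num)
    reject[malformed & reject == ""] <-
      paste0("malformed numeric in ", col, ": '", txt[malformed & reject == ""], "'")
    parsed[[col]] <- num
  }
  if ("is_emitted" %in% names(raw)) {
    txt <- toupper(trimws(raw$is_emitted))
    lg <- rep(NA, n)
    lg[txt %in% c("TRUE", "T", "1", "YES")] <- TRUE
    lg[txt %in% c("FALSE", "F", "0", "NO")] <- FALSE
    parsed$is_emitted <- lg
  }
  for (col in c("concentration_ppb", "saturation_pct", "depth_m")) {
    if (col %in% names(parsed)) {
      neg <- !is.na(parsed[[col]]) & parsed[[col]] < 0
      reject[neg & reject == ""] <- paste0("negative ", col)
    }
  }

  kept <- parsed[reject == "", , drop = FALSE]
  reasons <- reject[reject != ""]
  names(reasons) <- which(reject != "")
  prov <- list(source = path, rows_read = n,
               rows_rejected = length(reasons), reasons = reasons)
  n2o_dataset(kept, provenance = prov)
}

#' Write an N2O isotope dataset to CSV
#'
#' Inverse of [read_n2o_dataset()]: `read_n2o_dataset(write_n2o_dataset(d))`
#' reproduces the record collection (text fields bit-for-bit, numerics to
#' full double precision).
#'
#' @param dataset an [n2o_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_n2o_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "n2o_dataset"))
  df <- as.data.frame(dataset)
  for (col in N2O_NUMERIC_COLUMNS) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert d18O between the atmospheric-O2 and VSMOW reference frames
#'
#' Delta values measured against atmospheric O2 are re-expressed against
#' Vienna Standard Mean Ocean Water with the exact scale-shift identity
#' `value + offset + value * offset / 1000`. The default offset of 23.88
#' per-mil is the modern d18O of atmospheric O2 vs VSMOW.
#'
#' @param value per-mil delta vs atmospheric O2; must exceed -1000.
#' @param ref_offset per-mil of atmospheric O2 vs VSMOW (default 23.88).
#' @return per-mil delta vs VSMOW.
#' @export
convert_d18O_reference <- function(value, ref_offset = 23.88) {
  if (any(value <= -1000)) stop("delta value must exceed -1000 per-mil")
  value + ref_offset + value * ref_offset / 1000
}

#' Site preference and bulk d15N of the N2O isotopomers
#'
#' In the linear NNO molecule the central (alpha) and terminal (beta)
#' nitrogen can differ in 15N enrichment. The site preference is
#' `alpha - beta`; the bulk d15N is their mean.
#'
#' @param alpha d15N of the central nitrogen, per-mil.
#' @param beta d15N of the terminal nitrogen, per-mil.
#' @return per-mil site preference (resp. bulk d15N).
#' @export
site_preference <- function(alpha, beta) {
  stopifnot(all(is.finite(alpha)), all(is.finite(beta)))
  alpha - beta
}

#' @rdname site_preference
#' @export
bulk_from_isotopomers <- function(alpha, beta) {
  stopifnot(all(is.finite(alpha)), all(is.finite(beta)))
  (alpha + beta) / 2
}
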