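# Detection-limit censoring and global-mean delta-Crt normalization.
#
# A cell is detectable iff its QC flag passed, the value is present, and
# Crt < detection limit (a value *equal* to the limit is undetectable). A
# miRNA is retained in a fluid iff it is detectable in at least
# ceil(min_fraction * n) of that fluid's samples, pooled across days and
# groups; the per-fluid removal sets mirror the panel-level exclusions a
# low-expression miRNA earns.

#' Apply detectability rules to a Crt table
#'
#' @param crt A [as_crt_tbl()] table.
#' @param limit Detection limit in cycles; values at or above it are
#'   undetectable. Default 35.
#' @param min_fraction Minimum fraction of a fluid's samples in which a
#'   miRNA must be detectable to be retained. Default 2/3.
#'
#' @return A `detection_mask`: list with `detectable` (tibble
#'   `sample_id`, `mirna_id`, `detectable`), `removed` (tibble `fluid`,
#'   `mirna_id`), `n_samples` (tibble `fluid`, `n`), and the parameters.
#' @export
apply_detection_rules <- function(crt, limit = 35, min_fraction = 2 / 3) {
  stopifnot(inherits(crt, "crt_tbl"), nrow(crt) > 0)
  x <- tibble::as_tibble(crt)
  x$detectable <- x$qc_pass & !is.na(x$crt) & x$crt < limit

  n_samples <- x |>
    dplyr::distinct(.data$sample_id, .data$fluid) |>
    dplyr::count(.data$fluid, name = "n")
  if (any(!.dcv_fluids %in% n_samples$fluid)) {
    warning("No samples for fluid(s): ",
            paste(setdiff(.dcv_fluids, n_samples$fluid), collapse = ", "))
  }

  removed <- x |>
    dplyr::group_by(.data$fluid, .data$mirna_id) |>
    dplyr::summarise(n_detected = sum(.data$detectable), .groups = "drop") |>
    dplyr::left_join(n_samples, by = "fluid") |>
    dplyr::filter(.data$n_detected < ceiling(min_fraction * .data$n)) |>
    dplyr::select("fluid", "mirna_id")

  structure(
    list(
      detectable = x[, c("sample_id", "mirna_id", "detectable")],
      removed = removed,
      n_samples = n_samples,
      limit = limit,
      min_fraction = min_fraction
    ),
    class = "detection_mask"
  )
}

#' @export
print.detection_mask <- function(x, ...) {
  cat("Detection mask (limit ", x$limit, " cycles, min fraction ",
      format(x$min_fraction, digits = 3), ")\n", sep = "")
  for (fl in x$n_samples$fluid) {
    rem <- x$removed$mirna_id[x$removed$fluid == fl]
    cat("  ", fl, ": ", x$n_samples$n[x$n_samples$fluid == fl],
        " samples, ", length(rem), " miRNA(s) removed",
        if (length(rem) > 0) paste0(" (", paste(rem, collapse = ", "), ")"),
        "\n", sep = "")
  }
  invisible(x)
}

new_norm_tbl <- function(x, variant) {
  structure(tibble::as_tibble(x), variant = variant,
            class = c("norm_tbl", class(tibble::tibble())))
}

#' Global-mean delta-Crt normalization
#'
#' Normalizes each sample against its own panel-wide location: the custom
#' panel has no designated endogenous normalizer, so the per-sample mean of
#' all expressed targets plays that role. The location is computed over the
#' sample's detectable values of retained (non-removed) miRNAs, and
#' `delta_crt = crt - location` wherever detectable (missing otherwise).
#' Lower Crt means higher abundance, so plots conventionally show
#' `-delta_crt`.
#'
#' @param crt A [as_crt_tbl()] table.
#' @param mask A [apply_detection_rules()] mask computed from `crt`.
#' @param variant `"geometric"` (location = geometric mean of the detectable
#'   Crt values; the default, following the stated formula
#'   `dCrt = Crt_target - Crt_geomean`) or `"arithmetic"` (location =
#'   arithmetic mean, the classical global-mean on the cycle scale; exactly
#'   shift-invariant and zero-sum per sample). The two differ by well under
#'   0.1 cycle for typical Crt spreads.
#'
#' @return A `norm_tbl`: long tibble with the sample metadata plus
#'   `mirna_id`, `delta_crt`, and `location`; removed miRNAs are dropped
#'   from each fluid, and samples with fewer than 2 detectable values are
#'   excluded with a warning.
#' @export
normalize_global_mean <- function(crt, mask,
                                  variant = c("geometric", "arithmetic")) {
  stopifnot(inherits(crt, "crt_tbl"), inherits(mask, "detection_mask"))
  variant <- match.arg(variant)

  x <- dplyr::left_join(tibble::as_tibble(crt), mask$detectable,
                        by = c("sample_id", "mirna_id"))
  x <- dplyr::anti_join(x, mask$removed, by = c("fluid", "mirna_id"))

  loc_fun <- if (variant == "geometric") {
    function(v) exp(mean(log(v)))
  } else {
    mean
  }
  locs <- x |>
    dplyr::filter(.data$detectable) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(location = loc_fun(.data$crt),
                     n_detectable = dplyr::n(), .groups = "drop")

  unusable <- dplyr::union(
    setdiff(unique(x$sample_id), locs$sample_id),
    locs$sample_id[locs$n_detectable < 2]
  )
  if (length(unusable) > 0) {
    warning("Excluding sample(s) with < 2 detectable miRNAs: ",
            paste(unusable, collapse = ", "))
    x <- dplyr::filter(x, !.data$sample_id %in% unusable)
    locs <- dplyr::filter(locs, !.data$sample_id %in% unusable)
  }

  out <- x |>
    dplyr::left_join(locs[, c("sample_id", "location")], by = "sample_id") |>
    dplyr::mutate(
      delta_crt = dplyr::if_else(.data$detectable,
                                 .data$crt - .data$location, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(.crt_meta_cols), "mirna_id",
                  "delta_crt", "location")
  new_norm_tbl(out, variant)
}

#' @export
print.norm_tbl <- function(x, ...) {
  cat("Normalized delta-Crt table (", attr(x, "variant"),
      " global mean), ", dplyr::n_distinct(x$sample_id), " samples x ",
      dplyr::n_distinct(x$mirna_id), " miRNAs\n", sep = "")
  NextMethod()
}
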