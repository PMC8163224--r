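# Data model: a Crt table is a long tibble with one row per (sample, miRNA)
# cell. Samples are patient biofluid draws (subject x fluid x post-bleed day)
# or healthy-control draws (subject x fluid, day NA). `crt` is the raw
# relative-threshold cycle; NA is the explicit MISSING state. Detection-limit
# censoring is *not* applied on input: a stored value >= 35 is kept as drawn
# and only becomes "undetectable" in the QC stage.

.dcv_groups <- c("DCV_POS", "DCV_NEG", "HC")
.dcv_fluids <- c("CSF", "PLASMA")
.dcv_days <- c("PBD3", "PBD7")

.crt_meta_cols <- c("sample_id", "subject_id", "group", "fluid", "day", "cohort")
.crt_long_cols <- c(.crt_meta_cols, "mirna_id", "crt", "qc_pass")

new_crt_tbl <- function(x) {
  structure(x, class = c("crt_tbl", class(tibble::tibble())))
}

#' Construct and validate a Crt table
#'
#' @param x A data frame with columns `sample_id`, `subject_id`, `group`
#'   (`DCV_POS`/`DCV_NEG`/`HC`), `fluid` (`CSF`/`PLASMA`), `day`
#'   (`PBD3`/`PBD7`, `NA` for healthy controls), `cohort` (`A`/`B`/`C` or
#'   `NA`), `mirna_id`, `crt` (cycles, `NA` = missing), `qc_pass` (logical).
#'
#' @return The validated table with class `crt_tbl`.
#' @export
as_crt_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(.crt_long_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("Crt table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- dplyr::select(x, dplyr::all_of(.crt_long_cols))
  x$crt <- as.double(x$crt)
  x$qc_pass <- as.logical(x$qc_pass)
  validate_crt_tbl(new_crt_tbl(x))
}

validate_crt_tbl <- function(x) {
  bad_enum <- function(col, levels, allow_na = FALSE) {
    v <- x[[col]]
    bad <- !(v %in% levels) & !(allow_na & is.na(v))
    if (any(bad)) {
      stop(sprintf(
        "Invalid %s value(s) %s at row(s) %s",
        col,
        paste(unique(v[bad]), collapse = ", "),
        paste(utils::head(which(bad), 5), collapse = ", ")
      ), call. = FALSE)
    }
  }
  bad_enum("group", .dcv_groups)
  bad_enum("fluid", .dcv_fluids)
  bad_enum("day", .dcv_days, allow_na = TRUE)
  bad_enum("cohort", c("A", "B", "C"), allow_na = TRUE)

  hc_day <- x$group == "HC" & !is.na(x$day)
  if (any(hc_day)) {
    stop("Healthy-control samples must have day = NA (rows ",
         paste(utils::head(which(hc_day), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  dup <- duplicated(x[, c("sample_id", "mirna_id")])
  if (any(dup)) {
    keys <- unique(paste0("(", x$sample_id[dup], ", ", x$mirna_id[dup], ")"))
    stop("Duplicate (sample, miRNA) record(s): ",
         paste(utils::head(keys, 5), collapse = "; "), call. = FALSE)
  }
  nonpos <- !is.na(x$crt) & (!is.finite(x$crt) | x$crt <= 0)
  if (any(nonpos)) {
    stop("Crt values must be finite and > 0 or missing (rows ",
         paste(utils::head(which(nonpos), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  # one metadata tuple per sample_id
  meta <- dplyr::distinct(as.data.frame(x)[, .crt_meta_cols])
  if (anyDuplicated(meta$sample_id)) {
    stop("sample_id maps to more than one metadata tuple: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Sample metadata of a Crt or normalized table
#'
#' @param x A `crt_tbl` or `norm_tbl`.
#' @return One row per sample with the six metadata columns.
#' @export
sample_meta <- function(x) {
  dplyr::distinct(tibble::as_tibble(x)[, .crt_meta_cols])
}

#' Read a Crt table from CSV
#'
#' Reads either the long dialect (one row per sample x miRNA cell) or the
#' wide dialect (one row per sample; metadata columns first, then one column
#' per miRNA). Blank cells and the sentinel `"NA"` denote missing values;
#' a Crt at or above the detection limit is read as-is, never as missing.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @param permissive In wide format, keep miRNA columns that are not part of
#'   the packaged panel instead of rejecting them.
#'
#' @return A validated [as_crt_tbl()] table.
#' @export
read_crt_table <- function(path, format = c("long", "wide"),
                           permissive = FALSE) {
  format <- match.arg(format)
  if (format == "long") {
    x <- readr::read_csv(
      path,
      col_types = readr::cols(
        sample_id = readr::col_character(),
        subject_id = readr::col_character(),
        group = readr::col_character(),
        fluid = readr::col_character(),
        day = readr::col_character(),
        cohort = readr::col_character(),
        mirna_id = readr::col_character(),
        crt = readr::col_character(),
        qc_pass = readr::col_logical()
      ),
      na = character(),
      progress = FALSE
    )
    x$day[x$day %in% c("", "NA")] <- NA_character_
    x$cohort[x$cohort %in% c("", "NA")] <- NA_character_
    x$crt <- parse_crt_column(x$crt)
    as_crt_tbl(x)
  } else {
    x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
    missing_meta <- setdiff(.crt_meta_cols, names(x))
    if (length(missing_meta) > 0) {
      stop("Wide Crt table lacks metadata column(s): ",
           paste(missing_meta, collapse = ", "), call. = FALSE)
    }
    mirna_cols <- setdiff(names(x), .crt_meta_cols)
    qc_cols <- grep("^qc_pass\\.", mirna_cols, value = TRUE)
    mirna_cols <- setdiff(mirna_cols, qc_cols)
    unknown <- setdiff(mirna_cols, dcv_panel()$mirna_id)
    if (length(unknown) > 0 && !permissive) {
      stop("Unknown miRNA column(s): ", paste(unknown, collapse = ", "),
           " (set permissive = TRUE to keep them)", call. = FALSE)
    }
    long <- tidyr::pivot_longer(
      x[, c(.crt_meta_cols, mirna_cols)],
      cols = dplyr::all_of(mirna_cols),
      names_to = "mirna_id", values_to = "crt"
    )
    long$day[long$day %in% c("", "NA")] <- NA_character_
    long$cohort[long$cohort %in% c("", "NA")] <- NA_character_
    long$crt <- parse_crt_column(long$crt)
    if (length(qc_cols) > 0) {
      qc <- tidyr::pivot_longer(
        x[, c("sample_id", qc_cols)],
        cols = dplyr::all_of(qc_cols),
        names_to = "mirna_id", values_to = "qc_pass"
      )
      qc$mirna_id <- sub("^qc_pass\\.", "", qc$mirna_id)
      qc$qc_pass <- as.logical(qc$qc_pass)
      long <- dplyr::left_join(long, qc, by = c("sample_id", "mirna_id"))
      long$qc_pass[is.na(long$qc_pass)] <- TRUE
    } else {
      long$qc_pass <- TRUE
    }
    as_crt_tbl(long)
  }
}

parse_crt_column <- function(v) {
  v <- trimws(v)
  out <- rep(NA_real_, length(v))
  present <- !(v %in% c("", "NA"))
  parsed <- suppressWarnings(as.numeric(v[present]))
  if (anyNA(parsed)) {
    bad <- which(present)[is.na(parsed)]
    stop("Unparseable Crt value(s) ", paste(unique(v[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  out[present] <- parsed
  out
}

#' Write a tabular artifact to CSV
#'
#' CSV writers for the package's tabular artifact types. Numeric values are
#' written in full precision so `read(write(x))` reproduces `x`; missing
#' values are written as empty cells.
#'
#' @param x The artifact (a `crt_tbl`, `norm_tbl`, `dcv_prediction`, or any
#'   data frame).
#' @param path Output CSV path.
#' @param ... Passed to methods; `format` for `crt_tbl` (`"long"` or
#'   `"wide"`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, ...) {
  UseMethod("write_table")
}

#' @export
write_table.default <- function(x, path, ...) {
  readr::write_csv(tibble::as_tibble(x), path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.crt_tbl <- function(x, path, format = c("long", "wide"), ...) {
  format <- match.arg(format)
  if (format == "long") {
    readr::write_csv(tibble::as_tibble(x), path, na = "", progress = FALSE)
  } else {
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(x)[, c(.crt_meta_cols, "mirna_id", "crt")],
      names_from = "mirna_id", values_from = "crt"
    )
    qc <- tidyr::pivot_wider(
      tibble::as_tibble(x)[, c("sample_id", "mirna_id", "qc_pass")],
      names_from = "mirna_id", values_from = "qc_pass",
      names_prefix = "qc_pass."
    )
    readr::write_csv(dplyr::left_join(wide, qc, by = "sample_id"),
                     path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' @export
write_table.norm_tbl <- function(x, path, ...) {
  out <- tibble::as_tibble(x)
  out$variant <- attr(x, "variant")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
write_table.dcv_prediction <- function(x, path, ...) {
  readr::write_csv(tibble::as_tibble(x), path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a normalized table written by [write_table()]
#'
#' @param path CSV path.
#' @return A `norm_tbl` (long tibble of per-cell delta-Crt values with the
#'   per-sample location term and the normalization variant as an attribute).
#' @export
read_norm_table <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      subject_id = readr::col_character(),
      group = readr::col_character(),
      fluid = readr::col_character(),
      day = readr::col_character(),
      cohort = readr::col_character(),
      mirna_id = readr::col_character(),
      delta_crt = readr::col_double(),
      location = readr::col_double(),
      variant = readr::col_character()
    ),
    progress = FALSE
  )
  variant <- unique(x$variant)
  stopifnot(length(variant) == 1)
  x$variant <- NULL
  new_norm_tbl(x, variant)
}
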