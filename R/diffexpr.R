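# Per-miRNA two-group screening on the delta-Crt scale.
#
# The six standard comparisons (per fluid) are:
#   I   DCV+ vs DCV-  at PBD3
#   II  DCV+ vs DCV-  at PBD7
#   III DCV+ PBD3 vs HC
#   IV  DCV- PBD3 vs HC
#   V   DCV+ PBD7 vs HC
#   VI  DCV- PBD7 vs HC

.dcv_comparisons <- tibble::tibble(
  comparison = c("I", "II", "III", "IV", "V", "VI"),
  group1 = c("DCV_POS", "DCV_POS", "DCV_POS", "DCV_NEG", "DCV_POS", "DCV_NEG"),
  day1 = c("PBD3", "PBD7", "PBD3", "PBD3", "PBD7", "PBD7"),
  group2 = c("DCV_NEG", "DCV_NEG", "HC", "HC", "HC", "HC"),
  day2 = c("PBD3", "PBD7", NA, NA, NA, NA)
)

#' Pooled-variance two-sample t-test
#'
#' Student's two-tailed t-test with pooled variance, as used for the
#' per-miRNA differential-expression screen. Missing values are dropped
#' per vector; with fewer than 2 finite values in either group the result
#' is undetermined (all-NA) rather than an error.
#'
#' @param x,y Numeric vectors of delta-Crt values.
#' @param welch Use the Welch (unequal-variance) form instead.
#' @return A one-row tibble `n1`, `n2`, `mean_diff` (mean(x) - mean(y)),
#'   `t_stat`, `p_value`.
#' @export
t_test_two_group <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2 ||
      (stats::sd(x) == 0 && stats::sd(y) == 0)) {
    return(tibble::tibble(n1 = length(x), n2 = length(y),
                          mean_diff = if (length(x) > 0 && length(y) > 0)
                            mean(x) - mean(y) else NA_real_,
                          t_stat = NA_real_, p_value = NA_real_))
  }
  fit <- stats::t.test(x, y, var.equal = !welch)
  tibble::tibble(
    n1 = length(x), n2 = length(y),
    mean_diff = mean(x) - mean(y),
    t_stat = unname(fit$statistic),
    p_value = fit$p.value
  )
}

#' Significance star codes
#'
#' Maps p-values to the conventional star legend: `****` p < 0.0001,
#' `***` 0.0001 <= p < 0.001, `**` 0.001 <= p < 0.01, `*` 0.01 <= p < 0.05,
#' `ns` p >= 0.05. Intervals are closed on the smaller-p side so the map is
#' total and non-overlapping. `NA` maps to `"UD"` (undetermined).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of star codes.
#' @export
p_to_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "UD",
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Differential-expression screen over the six standard comparisons
#'
#' Runs the pooled t-test for every retained miRNA, fluid, and comparison
#' (DCV+ vs DCV- at each day; each patient group and day vs healthy
#' controls). miRNAs in a fluid's removal set, and comparisons where either
#' group has fewer than 2 observations, are reported as `UD`.
#'
#' @param nm A [normalize_global_mean()] table.
#' @param mask The [apply_detection_rules()] mask (for the removal sets).
#' @param welch Use Welch's t-test instead of the pooled form.
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (an extension; the canonical screen applies none).
#'   If supplied, adds a `p_adjusted` column (adjusted within fluid x
#'   comparison); stars remain keyed to the raw p-values.
#' @return Tibble `mirna_id`, `fluid`, `comparison` (I..VI), `n1`, `n2`,
#'   `mean_diff`, `t_stat`, `p_value`, `stars`.
#' @export
differential_expression <- function(nm, mask, welch = FALSE, adjust = NULL) {
  stopifnot(inherits(nm, "norm_tbl"))
  x <- tibble::as_tibble(nm)

  grid <- tidyr::expand_grid(
    mirna_id = unique(x$mirna_id),
    fluid = intersect(.dcv_fluids, unique(x$fluid)),
    .dcv_comparisons
  )

  pick <- function(fl, m, grp, dy) {
    rows <- x$fluid == fl & x$mirna_id == m & x$group == grp &
      (if (is.na(dy)) is.na(x$day) else !is.na(x$day) & x$day == dy)
    x$delta_crt[rows]
  }

  res <- purrr::pmap_dfr(
    grid,
    function(mirna_id, fluid, comparison, group1, day1, group2, day2) {
      stats <- t_test_two_group(pick(fluid, mirna_id, group1, day1),
                                pick(fluid, mirna_id, group2, day2),
                                welch = welch)
      dplyr::bind_cols(
        tibble::tibble(mirna_id = mirna_id, fluid = fluid,
                       comparison = comparison),
        stats
      )
    }
  )

  # removal propagates as UD in every comparison of that fluid
  removed_key <- paste(mask$removed$fluid, mask$removed$mirna_id)
  res$removed <- paste(res$fluid, res$mirna_id) %in% removed_key
  res$p_value[res$removed] <- NA_real_
  res$t_stat[res$removed] <- NA_real_
  res$mean_diff[res$removed] <- NA_real_
  res$stars <- p_to_stars(res$p_value)
  res$removed <- NULL

  if (!is.null(adjust)) {
    res <- res |>
      dplyr::group_by(.data$fluid, .data$comparison) |>
      dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value,
                                                 method = adjust)) |>
      dplyr::ungroup()
  }
  res
}

#' Count significant miRNAs in a comparison
#'
#' @param de A [differential_expression()] result.
#' @param fluid,comparison The cell to count.
#' @param alpha Significance level (default 0.05).
#' @return Number of miRNAs with `p_value < alpha`.
#' @export
count_significant <- function(de, fluid, comparison = "I", alpha = 0.05) {
  sum(de$p_value[de$fluid == fluid & de$comparison == comparison] < alpha,
      na.rm = TRUE)
}

#' Group-mean expression summary (heatmap values)
#'
#' Mean of `-delta_crt` (higher = more abundant) per (group, fluid, day,
#' miRNA) cell, for heatmap-style overviews. Missing values are excluded;
#' an empty cell yields `NA`.
#'
#' @param nm A [normalize_global_mean()] table.
#' @return Tibble `group`, `fluid`, `day`, `mirna_id`, `mean_neg_delta`, `n`.
#' @export
group_mean_summary <- function(nm) {
  stopifnot(inherits(nm, "norm_tbl"))
  tibble::as_tibble(nm) |>
    dplyr::group_by(.data$group, .data$fluid, .data$day, .data$mirna_id) |>
    dplyr::summarise(
      mean_neg_delta = ifelse(all(is.na(.data$delta_crt)), NA_real_,
                              mean(-.data$delta_crt, na.rm = TRUE)),
      n = sum(!is.na(.data$delta_crt)),
      .groups = "drop"
    )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test summing hypergeometric probabilities no larger than
#' that of the observed table; used for cohort demographic comparisons.
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, c, b, d), 2)` i.e.
#'   rows are outcome, columns are group.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(length(counts) == 4, all(counts >= 0),
            all(counts == round(counts)))
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("Zero margin in 2x2 table; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}
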