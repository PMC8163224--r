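# Empirical ROC analysis. The AUC is the tie-corrected pairwise-comparison
# (Mann-Whitney) statistic; the curve enumerates thresholds at every
# distinct observed score, and its trapezoidal area equals the pairwise
# statistic identically.

#' Empirical AUC by pairwise comparison
#'
#' `auc = (#\{pos > neg\} + 0.5 * #\{ties\}) / (n_pos * n_neg)`, with
#' orientation already applied (higher score = DCV+).
#'
#' @param pos,neg Finite score vectors for the positive and negative group.
#' @return The AUC in \[0, 1\].
#' @export
auc_empirical <- function(pos, neg) {
  stopifnot(length(pos) >= 1, length(neg) >= 1,
            all(is.finite(pos)), all(is.finite(neg)))
  r <- rank(c(pos, neg), ties.method = "average")
  rp <- sum(r[seq_along(pos)])
  (rp - length(pos) * (length(pos) + 1) / 2) / (length(pos) * length(neg))
}

#' Choose the score orientation for a miRNA
#'
#' A discriminator votes DCV+ on the side of its own group mean, so the
#' orientation is `HIGHER_IS_DCV` iff the DCV+ mean delta-Crt is at least
#' the DCV- mean (ties break to `HIGHER_IS_DCV`).
#'
#' @param pos,neg Delta-Crt vectors for DCV+ and DCV- (missing dropped).
#' @return `"HIGHER_IS_DCV"` or `"LOWER_IS_DCV"`.
#' @export
orient_scores <- function(pos, neg) {
  pos <- pos[is.finite(pos)]
  neg <- neg[is.finite(neg)]
  stopifnot(length(pos) > 0, length(neg) > 0)
  if (mean(pos) >= mean(neg)) "HIGHER_IS_DCV" else "LOWER_IS_DCV"
}

#' Empirical ROC curve for one miRNA
#'
#' Thresholds are enumerated at every distinct observed score; points run
#' from (0, 0) to (1, 1) and are monotone in both coordinates. The reported
#' `auc` is the trapezoidal area, which equals [auc_empirical()] exactly.
#'
#' @param pos,neg Oriented score vectors (higher = DCV+).
#' @param mirna_id,fluid,day Optional labels carried into the result.
#' @param orientation Optional orientation label carried into the result.
#' @return A `dcv_roc` object: list with `points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`, and the labels.
#' @export
roc_curve <- function(pos, neg, mirna_id = NA_character_,
                      fluid = NA_character_, day = NA_character_,
                      orientation = "HIGHER_IS_DCV") {
  stopifnot(length(pos) >= 1, length(neg) >= 1,
            all(is.finite(pos)), all(is.finite(neg)))
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  pts <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(pos >= t), 0),
    fpr = vapply(c(Inf, thr), function(t) mean(neg >= t), 0)
  )
  auc_trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                     utils::tail(pts$tpr, -1)) / 2)
  structure(
    list(points = pts[, c("threshold", "fpr", "tpr")],
         auc = auc_trap, n_pos = length(pos), n_neg = length(neg),
         mirna_id = mirna_id, fluid = fluid, day = day,
         orientation = orientation),
    class = "dcv_roc"
  )
}

#' @export
print.dcv_roc <- function(x, ...) {
  cat("Empirical ROC",
      if (!is.na(x$mirna_id)) paste0(" for ", x$mirna_id), ": AUC = ",
      format(x$auc, digits = 4), " (", x$n_pos, " pos vs ", x$n_neg,
      " neg, ", x$orientation, ")\n", sep = "")
  invisible(x)
}

#' miRNAs with complete data across the given samples
#'
#' The model-building candidate pool: miRNAs of a fluid/day stratum with no
#' missing delta-Crt in any of the given samples (and not in the fluid's
#' removal set, which drops them from the normalized table already).
#'
#' @param nm A [normalize_global_mean()] table.
#' @param fluid,day Stratum selectors.
#' @param sample_ids Optional restriction to specific samples (defaults to
#'   all samples of the stratum present in `nm`).
#' @return Character vector of miRNA ids.
#' @export
complete_candidates <- function(nm, fluid = "CSF", day = "PBD3",
                                sample_ids = NULL) {
  x <- dplyr::filter(tibble::as_tibble(nm), .data$fluid == !!fluid,
                     !is.na(.data$day), .data$day == !!day)
  if (!is.null(sample_ids)) {
    x <- dplyr::filter(x, .data$sample_id %in% sample_ids)
  }
  x |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(complete = !anyNA(.data$delta_crt), .groups = "drop") |>
    dplyr::filter(.data$complete) |>
    dplyr::pull("mirna_id")
}

#' ROC screen over a stratum
#'
#' Orients and computes the empirical AUC of each candidate miRNA for
#' DCV+ vs DCV- in one fluid/day stratum.
#'
#' @param nm A [normalize_global_mean()] table.
#' @param fluid,day Stratum selectors.
#' @param candidates miRNA ids to screen; defaults to
#'   [complete_candidates()].
#' @return Tibble `mirna_id`, `fluid`, `day`, `orientation`, `auc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_screen <- function(nm, fluid = "CSF", day = "PBD3", candidates = NULL) {
  if (is.null(candidates)) candidates <- complete_candidates(nm, fluid, day)
  x <- dplyr::filter(tibble::as_tibble(nm), .data$fluid == !!fluid,
                     !is.na(.data$day), .data$day == !!day,
                     .data$mirna_id %in% candidates)
  purrr::map_dfr(candidates, function(m) {
    pos <- x$delta_crt[x$mirna_id == m & x$group == "DCV_POS"]
    neg <- x$delta_crt[x$mirna_id == m & x$group == "DCV_NEG"]
    pos <- pos[is.finite(pos)]
    neg <- neg[is.finite(neg)]
    ori <- orient_scores(pos, neg)
    s <- if (ori == "HIGHER_IS_DCV") 1 else -1
    tibble::tibble(
      mirna_id = m, fluid = fluid, day = day, orientation = ori,
      auc = auc_empirical(s * pos, s * neg),
      n_pos = length(pos), n_neg = length(neg)
    )
  })
}

#' Find perfect discriminators
#'
#' Returns the candidate miRNAs whose oriented empirical AUC is exactly 1,
#' i.e. whose DCV+ and DCV- delta-Crt ranges are disjoint in the given
#' stratum.
#'
#' @inheritParams roc_screen
#' @return Character vector of miRNA ids.
#' @export
find_perfect_separators <- function(nm, fluid = "CSF", day = "PBD3",
                                    candidates = NULL) {
  screen <- roc_screen(nm, fluid = fluid, day = day, candidates = candidates)
  screen$mirna_id[screen$auc == 1]
}
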