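# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold predictor
#'
#' @param x A `threshold_predictor`.
#' @param ... Unused.
#' @return One-row tibble `mirna_id`, `cutoff`, `orientation`.
#' @export
tidy.threshold_predictor <- function(x, ...) {
  tibble::tibble(mirna_id = x$mirna_id, cutoff = x$cutoff,
                 orientation = x$orientation)
}

#' Tidy a CART decision tree
#'
#' @param x A `dcv_tree`.
#' @param ... Unused.
#' @return One row per node: `node_id`, `depth`, `type`, `variable`,
#'   `threshold`, `class`, `n_pos`, `n_neg`.
#' @export
tidy.dcv_tree <- function(x, ...) {
  rows <- list()
  visit <- function(node, id, depth) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      node_id = id, depth = depth, type = node$type,
      variable = if (node$type == "split") node$var else NA_character_,
      threshold = if (node$type == "split") node$threshold else NA_real_,
      class = if (node$type == "leaf") node$class else NA_character_,
      n_pos = unname(node$counts["DCV_POS"]),
      n_neg = unname(node$counts["DCV_NEG"])
    )
    if (node$type == "split") {
      visit(node$left, paste0(id, "L"), depth + 1)
      visit(node$right, paste0(id, "R"), depth + 1)
    }
  }
  visit(x$root, "0", 0)
  dplyr::bind_rows(rows)
}

#' @rdname tidy.dcv_tree
#' @export
glance.dcv_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(
    n_nodes = nrow(nodes),
    n_leaves = sum(nodes$type == "leaf"),
    depth = max(nodes$depth),
    n_variables_used = dplyr::n_distinct(nodes$variable, na.rm = TRUE),
    n_candidates = length(x$variables)
  )
}

#' Tidy a consensus panel
#'
#' @param x A `consensus_panel`.
#' @param ... Unused.
#' @return One row per predictor: `predictor`, `type`, `cutoff`,
#'   `orientation`.
#' @export
tidy.consensus_panel <- function(x, ...) {
  purrr::imap_dfr(x$predictors, function(p, nm) {
    if (inherits(p, "threshold_predictor")) {
      tibble::tibble(predictor = nm, type = "threshold",
                     cutoff = p$cutoff, orientation = p$orientation)
    } else {
      tibble::tibble(predictor = nm, type = "cart_tree",
                     cutoff = NA_real_, orientation = NA_character_)
    }
  })
}

#' @rdname tidy.consensus_panel
#' @export
glance.consensus_panel <- function(x, ...) {
  tibble::tibble(
    n_predictors = length(x$predictors),
    n_separators = length(x$separators),
    k = x$k, fluid = x$fluid, day = x$day,
    n_candidates = length(x$candidates)
  )
}

#' Tidy an ROC result
#'
#' @param x A `dcv_roc`.
#' @param ... Unused.
#' @return The ROC points tibble (`threshold`, `fpr`, `tpr`).
#' @export
tidy.dcv_roc <- function(x, ...) {
  x$points
}

#' @rdname tidy.dcv_roc
#' @export
glance.dcv_roc <- function(x, ...) {
  tibble::tibble(mirna_id = x$mirna_id, fluid = x$fluid, day = x$day,
                 orientation = x$orientation, auc = x$auc,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a prediction table
#'
#' @param x A `dcv_prediction`.
#' @param ... Unused.
#' @return The per-subject rows as a plain tibble.
#' @export
tidy.dcv_prediction <- function(x, ...) {
  out <- x
  attr(out, "summary") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.dcv_prediction
#' @export
glance.dcv_prediction <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(n = s$n, n_correct = s$n_correct,
                 accuracy_percent = s$accuracy_percent)
}
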