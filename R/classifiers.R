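# DCV risk predictors: single-miRNA cutoff votes for the perfect
# discriminators, a Gini-impurity CART decision tree over the remaining
# complete-data miRNAs, and the >= k-of-8 consensus call.

#' Fit a single-miRNA threshold predictor
#'
#' Only defined for perfect discriminators: the cutoff is placed at the
#' midpoint of the empty interval between the two training groups, so the
#' predictor classifies every training subject correctly. The vote uses a
#' strict inequality: a value exactly at the cutoff votes DCV-.
#'
#' @param pos,neg Training delta-Crt values for DCV+ and DCV-.
#' @param mirna_id Label carried on the predictor.
#' @param orientation `"HIGHER_IS_DCV"` or `"LOWER_IS_DCV"`; inferred from
#'   the group means when `NULL`.
#' @param cutoff Optional override (e.g. an externally published cutoff);
#'   when supplied it is used verbatim instead of the midpoint.
#' @return A `threshold_predictor`: list with `mirna_id`, `cutoff`,
#'   `orientation`.
#' @export
fit_threshold <- function(pos, neg, mirna_id = NA_character_,
                          orientation = NULL, cutoff = NULL) {
  pos <- pos[is.finite(pos)]
  neg <- neg[is.finite(neg)]
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  if (is.null(orientation)) orientation <- orient_scores(pos, neg)
  disjoint <- if (orientation == "HIGHER_IS_DCV") {
    min(pos) > max(neg)
  } else {
    max(pos) < min(neg)
  }
  if (!disjoint && is.null(cutoff)) {
    stop("Group ranges overlap for ", mirna_id,
         "; a threshold predictor requires a perfect discriminator ",
         "(use find_perfect_separators first)", call. = FALSE)
  }
  if (is.null(cutoff)) {
    cutoff <- if (orientation == "HIGHER_IS_DCV") {
      (max(neg) + min(pos)) / 2
    } else {
      (min(neg) + max(pos)) / 2
    }
  }
  structure(list(mirna_id = mirna_id, cutoff = cutoff,
                 orientation = orientation),
            class = "threshold_predictor")
}

#' @export
print.threshold_predictor <- function(x, ...) {
  cat("Threshold predictor ", x$mirna_id, ": DCV+ iff delta-Crt ",
      if (x$orientation == "HIGHER_IS_DCV") "> " else "< ",
      format(x$cutoff, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict a DCV vote from one subject profile
#'
#' @param object A `threshold_predictor`, `dcv_tree`, or `consensus_panel`.
#' @param profile Named numeric vector of the subject's delta-Crt values
#'   (names are miRNA ids).
#' @param ... Unused.
#' @return For single predictors, `"DCV_POS"`, `"DCV_NEG"`, or `"ABSTAIN"`
#'   (a required value is missing). For a consensus panel, see
#'   [consensus_call()].
#' @export
predict.threshold_predictor <- function(object, profile, ...) {
  v <- profile[[object$mirna_id]]
  if (is.null(v) || is.na(v)) return("ABSTAIN")
  hit <- if (object$orientation == "HIGHER_IS_DCV") {
    v > object$cutoff
  } else {
    v < object$cutoff
  }
  if (hit) "DCV_POS" else "DCV_NEG"
}

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

#' Fit a CART decision tree
#'
#' Greedy binary recursive partitioning with Gini impurity, written for
#' small biomarker training sets: every (variable, threshold) pair is
#' evaluated with thresholds at midpoints between consecutive sorted
#' distinct values; the split minimizing the weighted child impurity is
#' chosen, with deterministic tie-breaks (lowest impurity, then earliest
#' variable in column order, then smallest threshold). Recursion stops at a
#' pure node or when a stopping parameter binds. The defaults
#' (`min_split = 2`, `min_leaf = 1`, `max_depth = 5`,
#' `min_impurity_decrease = 0`) allow a perfect fit on a cohort-sized
#' training set.
#'
#' Routing: a value strictly below a node's threshold goes left, otherwise
#' right. Prediction abstains if a required value is missing (no surrogate
#' splits).
#'
#' @param X Data frame or matrix of delta-Crt values, subjects in rows,
#'   candidate miRNAs in columns; no missing values.
#' @param y Binary class labels (`DCV_POS`/`DCV_NEG`).
#' @param min_split Minimum node size eligible for splitting.
#' @param min_leaf Minimum child size.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_impurity_decrease Minimum weighted impurity decrease a split
#'   must strictly exceed.
#' @return A `dcv_tree` object.
#' @export
fit_cart <- function(X, y, min_split = 2, min_leaf = 1, max_depth = 5,
                     min_impurity_decrease = 0) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), !anyNA(X))
  classes <- c("DCV_POS", "DCV_NEG")
  stopifnot(all(y %in% classes))

  leaf <- function(yy) {
    counts <- c(DCV_POS = sum(yy == "DCV_POS"),
                DCV_NEG = sum(yy == "DCV_NEG"))
    cls <- if (counts["DCV_POS"] > counts["DCV_NEG"]) "DCV_POS" else "DCV_NEG"
    list(type = "leaf", class = cls, counts = counts)
  }

  best_split <- function(XX, yy) {
    n <- length(yy)
    best <- NULL
    for (j in seq_along(XX)) {
      v <- XX[[j]]
      u <- sort(unique(v))
      if (length(u) < 2) next
      thresholds <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
      for (thr in thresholds) {
        left <- v < thr
        nl <- sum(left)
        if (nl < min_leaf || n - nl < min_leaf) next
        imp <- (nl * gini_impurity(table(factor(yy[left], classes))) +
                  (n - nl) * gini_impurity(table(factor(yy[!left], classes)))) / n
        if (is.null(best) || imp < best$impurity - 1e-12) {
          best <- list(var = names(XX)[j], j = j, threshold = thr,
                       impurity = imp, left = left)
        }
      }
    }
    best
  }

  grow <- function(XX, yy, depth) {
    node_leaf <- leaf(yy)
    if (length(unique(yy)) == 1 || length(yy) < min_split ||
        depth >= max_depth) {
      return(node_leaf)
    }
    sp <- best_split(XX, yy)
    parent_imp <- gini_impurity(table(factor(yy, classes)))
    if (is.null(sp) || parent_imp - sp$impurity <= min_impurity_decrease) {
      return(node_leaf)
    }
    list(
      type = "split", var = sp$var, threshold = sp$threshold,
      counts = node_leaf$counts,
      left = grow(XX[sp$left, , drop = FALSE], yy[sp$left], depth + 1),
      right = grow(XX[!sp$left, , drop = FALSE], yy[!sp$left], depth + 1)
    )
  }

  if (ncol(X) == 0 || nrow(X) == 0) {
    stop("fit_cart requires at least one subject and one variable")
  }
  root <- grow(X, y, 0)
  structure(
    list(root = root, variables = names(X),
         params = list(min_split = min_split, min_leaf = min_leaf,
                       max_depth = max_depth,
                       min_impurity_decrease = min_impurity_decrease)),
    class = "dcv_tree"
  )
}

tree_vars_used <- function(node) {
  if (node$type == "leaf") return(character())
  c(node$var, tree_vars_used(node$left), tree_vars_used(node$right))
}

#' @rdname predict.threshold_predictor
#' @export
predict.dcv_tree <- function(object, profile, ...) {
  node <- object$root
  while (node$type == "split") {
    v <- profile[[node$var]]
    if (is.null(v) || is.na(v)) return("ABSTAIN")
    node <- if (v < node$threshold) node$left else node$right
  }
  node$class
}

#' @export
print.dcv_tree <- function(x, ...) {
  cat("CART decision tree (", length(unique(tree_vars_used(x$root))),
      " variable(s) used of ", length(x$variables), " candidates)\n",
      sep = "")
  show <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, label, "-> ", node$class, " (",
          node$counts["DCV_POS"], "+/", node$counts["DCV_NEG"], "-)\n",
          sep = "")
    } else {
      cat(pad, label, node$var, " < ",
          format(node$threshold, digits = 4), "?\n", sep = "")
      show(node$left, indent + 1, "yes: ")
      show(node$right, indent + 1, "no:  ")
    }
  }
  show(x$root, 0, "")
  invisible(x)
}

#' Consensus call from eight predictor votes
#'
#' The panel calls DCV+ when at least `k` of the 8 votes are DCV+, DCV-
#' when at least `k` are DCV-, and is indeterminate otherwise (abstentions
#' count towards neither side).
#'
#' @param votes Character vector of votes
#'   (`DCV_POS`/`DCV_NEG`/`ABSTAIN`).
#' @param k Vote threshold; default 5.
#' @return List with `call` (`DCV_POS`, `DCV_NEG`, or `INDETERMINATE`),
#'   `n_pos`, `n_neg`.
#' @export
consensus_call <- function(votes, k = 5) {
  n_pos <- sum(votes == "DCV_POS")
  n_neg <- sum(votes == "DCV_NEG")
  call <- if (n_pos >= k) {
    "DCV_POS"
  } else if (n_neg >= k) {
    "DCV_NEG"
  } else {
    "INDETERMINATE"
  }
  list(call = call, n_pos = n_pos, n_neg = n_neg)
}

#' Fit the consensus DCV risk panel
#'
#' From a normalized training stratum (CSF at PBD3 by default), restricts
#' to the complete-data candidate miRNAs, identifies the perfect
#' discriminators (oriented AUC = 1), fits one midpoint threshold predictor
#' per discriminator, fits one CART tree on the remaining candidates, and
#' assembles the >= `k`-of-n consensus classifier.
#'
#' @param nm A [normalize_global_mean()] table containing DCV+ and DCV-
#'   training samples.
#' @param fluid,day Training stratum.
#' @param candidates Candidate miRNA pool; defaults to
#'   [complete_candidates()] on the training samples. When test-cohort
#'   completeness is known, pass the intersection explicitly.
#' @param k Consensus vote threshold.
#' @param cutoffs Optional named numeric vector of cutoff overrides, keyed
#'   by miRNA id (e.g. externally published cutoffs).
#' @param cart_params List of [fit_cart()] stopping parameters.
#' @return A `consensus_panel`: list with `predictors` (threshold
#'   predictors then the tree), `separators`, `tree`, `k`, `fluid`, `day`,
#'   `candidates`.
#' @export
fit_consensus_panel <- function(nm, fluid = "CSF", day = "PBD3",
                                candidates = NULL, k = 5, cutoffs = NULL,
                                cart_params = list()) {
  if (is.null(candidates)) candidates <- complete_candidates(nm, fluid, day)
  x <- dplyr::filter(tibble::as_tibble(nm), .data$fluid == !!fluid,
                     !is.na(.data$day), .data$day == !!day,
                     .data$group %in% c("DCV_POS", "DCV_NEG"),
                     .data$mirna_id %in% candidates)
  seps <- find_perfect_separators(nm, fluid, day, candidates)

  thresholds <- purrr::map(seps, function(m) {
    pos <- x$delta_crt[x$mirna_id == m & x$group == "DCV_POS"]
    neg <- x$delta_crt[x$mirna_id == m & x$group == "DCV_NEG"]
    fit_threshold(pos, neg, mirna_id = m,
                  cutoff = if (!is.null(cutoffs)) cutoffs[[m]] else NULL)
  })
  names(thresholds) <- seps

  tree_candidates <- setdiff(candidates, seps)
  wide <- x |>
    dplyr::filter(.data$mirna_id %in% tree_candidates) |>
    tidyr::pivot_wider(id_cols = c("sample_id", "group"),
                       names_from = "mirna_id", values_from = "delta_crt")
  X <- as.data.frame(wide[, tree_candidates, drop = FALSE])
  tree <- do.call(fit_cart, c(list(X = X, y = wide$group), cart_params))

  structure(
    list(predictors = c(thresholds, list(tree = tree)),
         separators = seps, tree = tree, k = k,
         fluid = fluid, day = day, candidates = candidates),
    class = "consensus_panel"
  )
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat("Consensus DCV risk panel (", length(x$predictors),
      " predictors, call at >= ", x$k, " votes; trained on ", x$fluid,
      "/", x$day, ")\n", sep = "")
  for (p in x$predictors) {
    if (inherits(p, "threshold_predictor")) print(p)
  }
  cat("plus 1 decision tree on ",
      length(setdiff(x$candidates, x$separators)), " candidate miRNAs\n",
      sep = "")
  invisible(x)
}

#' @rdname predict.threshold_predictor
#' @export
predict.consensus_panel <- function(object, profile, ...) {
  votes <- vapply(object$predictors, function(p) predict(p, profile), "")
  c(consensus_call(votes, object$k), list(votes = votes))
}

#' Per-subject delta-Crt profiles of a stratum
#'
#' @param nm A [normalize_global_mean()] table.
#' @param fluid,day Stratum selectors.
#' @return Named list of named delta-Crt vectors, one per subject.
#' @export
subject_profiles <- function(nm, fluid = "CSF", day = "PBD3") {
  x <- dplyr::filter(tibble::as_tibble(nm), .data$fluid == !!fluid,
                     !is.na(.data$day), .data$day == !!day)
  split(x, x$subject_id) |>
    purrr::map(function(d) stats::setNames(d$delta_crt, d$mirna_id))
}

#' Serialize a consensus panel to JSON
#'
#' @param panel A [fit_consensus_panel()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
panel_to_json <- function(panel, path) {
  ser_node <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf", class = node$class,
           counts = as.list(node$counts))
    } else {
      list(type = "split", var = node$var, threshold = node$threshold,
           counts = as.list(node$counts),
           left = ser_node(node$left), right = ser_node(node$right))
    }
  }
  obj <- list(
    k = panel$k, fluid = panel$fluid, day = panel$day,
    candidates = panel$candidates, separators = panel$separators,
    thresholds = purrr::map(
      panel$predictors[panel$separators],
      function(p) list(mirna_id = p$mirna_id, cutoff = p$cutoff,
                       orientation = p$orientation)
    ),
    tree = list(variables = panel$tree$variables,
                params = panel$tree$params,
                root = ser_node(panel$tree$root))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a consensus panel from JSON
#'
#' @param path JSON path written by [panel_to_json()].
#' @return A `consensus_panel`.
#' @export
panel_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_node <- function(node) {
    counts <- c(DCV_POS = node$counts$DCV_POS, DCV_NEG = node$counts$DCV_NEG)
    if (node$type == "leaf") {
      list(type = "leaf", class = node$class, counts = counts)
    } else {
      list(type = "split", var = node$var, threshold = node$threshold,
           counts = counts, left = de_node(node$left),
           right = de_node(node$right))
    }
  }
  thresholds <- purrr::map(obj$thresholds, function(p) {
    structure(list(mirna_id = p$mirna_id, cutoff = p$cutoff,
                   orientation = p$orientation),
              class = "threshold_predictor")
  })
  names(thresholds) <- vapply(thresholds, `[[`, "", "mirna_id")
  tree <- structure(
    list(root = de_node(obj$tree$root),
         variables = unlist(obj$tree$variables),
         params = obj$tree$params),
    class = "dcv_tree"
  )
  structure(
    list(predictors = c(thresholds, list(tree = tree)),
         separators = unlist(obj$separators), tree = tree, k = obj$k,
         fluid = obj$fluid, day = obj$day,
         candidates = unlist(obj$candidates)),
    class = "consensus_panel"
  )
}
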