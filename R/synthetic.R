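# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: a 47-miRNA panel measured in CSF and plasma at
# post-bleed days 3 and 7 for DCV+/DCV- aSAH patients and fluid-only samples
# for healthy controls; normally distributed Crt per (miRNA, group, fluid,
# day); a planted set of perfect DCV+/DCV- separators at (CSF, PBD3) with
# disjoint group ranges enforced by construction; per-fluid low-expression
# sets centred near the detection limit so they fail the two-thirds
# detectability rule; and completely-at-random missingness.

# The seven miRNAs reported as perfect discriminators at (CSF, PBD3).
.default_separators <- c(
  "hsa-let-7b-5p", "hsa-miR-15b-5p", "hsa-miR-17-5p", "hsa-miR-19b-3p",
  "hsa-miR-20a-5p", "hsa-miR-24-3p", "hsa-miR-29a-3p"
)

# Low-expression (sub-detection) sets per fluid.
.default_low_expression <- list(
  CSF = c("hsa-miR-107", "hsa-miR-144-3p", "hsa-miR-153-3p",
          "hsa-miR-15a-5p", "hsa-miR-29b-3p", "hsa-miR-874-3p"),
  PLASMA = c("hsa-miR-124-3p", "hsa-miR-144-3p", "hsa-miR-1298-5p",
             "hsa-miR-153-3p", "hsa-miR-874-3p", "hsa-miR-9-5p")
)

# CSF miRNAs left null by default so that 37 of the 40 retained CSF miRNAs
# carry a planted PBD3 effect; these mirror the clearly non-significant
# panel members of the differential-expression screen.
.default_csf_null <- c("hsa-miR-1298-5p", "hsa-miR-155-5p",
                       "hsa-miR-181c-5p")
.n_plasma_planted <- 29

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the training-cohort structure of the study design: 8
#' DCV+ and 10 DCV- aSAH patients sampled in CSF and plasma at post-bleed
#' days 3 and 7, 8 healthy controls sampled once per fluid, a detection
#' limit of 35 cycles, 7 planted perfect separators at (CSF, PBD3), 6
#' sub-detection miRNAs per fluid, and planted DCV+ vs DCV- mean shifts of
#' 2.5 within-group SD in 37 retained CSF and 29 retained plasma miRNAs at
#' PBD3 (signs split near-evenly so the panel-wide mean is essentially
#' unshifted and the global-mean location stays stable).
#'
#' @param seed Integer RNG seed; the whole cohort is deterministic given it.
#' @param n_dcv_pos,n_dcv_neg,n_hc Group sizes.
#' @param baseline_crt_mean,baseline_crt_sd Mean and within-group SD of raw
#'   Crt (cycles) for an unshifted miRNA.
#' @param effect_sizes Tibble `mirna_id`, `fluid`, `day`, `shift`: the DCV+
#'   minus DCV- mean Crt shift in cycles (negative = higher abundance in
#'   DCV+). Defaults to [default_effect_sizes()].
#' @param perfect_separators miRNA ids whose DCV+/DCV- ranges at (CSF, PBD3)
#'   are made disjoint by construction.
#' @param gap Minimum guaranteed raw-Crt gap (cycles) between the separator
#'   groups; default 4 within-group SD.
#' @param low_expression Named list (`CSF`, `PLASMA`) of miRNA ids drawn
#'   near the detection limit.
#' @param censored_fraction Target probability that a low-expression value
#'   falls at or above the detection limit. Must exceed 1/3.
#' @param detection_limit Cycles; fixed at 35 in the assay design.
#' @param missing_rate Completely-at-random missingness probability
#'   (separator cells at CSF/PBD3 are exempt so the planted separators always
#'   satisfy the complete-data candidate rule).
#' @param hc_scale Position of the healthy-control mean between DCV- (0) and
#'   DCV+ (1); default 0.5.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_dcv_pos = 8L, n_dcv_neg = 10L, n_hc = 8L,
                             baseline_crt_mean = 28, baseline_crt_sd = 1.0,
                             effect_sizes = NULL,
                             perfect_separators = .default_separators,
                             gap = 4 * baseline_crt_sd,
                             low_expression = .default_low_expression,
                             censored_fraction = 0.8,
                             detection_limit = 35,
                             missing_rate = 0.03,
                             hc_scale = 0.5) {
  if (is.null(effect_sizes)) {
    effect_sizes <- default_effect_sizes(sd = baseline_crt_sd,
                                         baseline = baseline_crt_mean)
  }
  stopifnot(
    gap > 0,
    missing_rate >= 0, missing_rate < 1,
    censored_fraction > 1 / 3, censored_fraction < 1,
    all(perfect_separators %in% panel_mirnas()),
    all(unlist(low_expression) %in% panel_mirnas())
  )
  structure(
    list(
      seed = as.integer(seed),
      n_dcv_pos = as.integer(n_dcv_pos),
      n_dcv_neg = as.integer(n_dcv_neg),
      n_hc = as.integer(n_hc),
      baseline_crt_mean = baseline_crt_mean,
      baseline_crt_sd = baseline_crt_sd,
      effect_sizes = effect_sizes,
      perfect_separators = perfect_separators,
      gap = gap,
      low_expression = low_expression,
      censored_fraction = censored_fraction,
      detection_limit = detection_limit,
      missing_rate = missing_rate,
      hc_scale = hc_scale
    ),
    class = "synthetic_config"
  )
}

#' Default planted effect sizes
#'
#' Plants DCV+ vs DCV- mean shifts of `effect_sd` standard deviations at
#' PBD3 in 37 of the 40 retained CSF miRNAs and 29 of the 40 retained
#' plasma miRNAs, and no shift at PBD7. The seven separator miRNAs always
#' shift downwards (towards higher abundance in DCV+); the remaining
#' planted shifts split near-evenly in sign so that the per-sample global
#' mean is nearly unchanged between groups.
#'
#' @param sd Within-group SD the shifts are scaled by.
#' @param effect_sd Shift magnitude of an ordinary planted miRNA, in SD
#'   units; default 2.5.
#' @param separator_effect_sd Shift magnitude of the seven separator
#'   miRNAs; default 8, large enough that draws are already separated by
#'   the guaranteed gap and the disjointness enforcement rarely has to
#'   move values (so its shifts cannot leak into other miRNAs through the
#'   global-mean location).
#' @param baseline Baseline Crt the shifts apply around; used to balance
#'   the planted shifts on the log scale of the geometric global mean.
#' @return Tibble `mirna_id`, `fluid`, `day`, `shift`.
#' @export
default_effect_sizes <- function(sd = 1.0, effect_sd = 2.5,
                                 separator_effect_sd = 8, baseline = 28) {
  mirnas <- panel_mirnas()

  plant <- function(fluid, planted, separators) {
    # separators shift strongly towards higher abundance (lower Crt) in
    # DCV+; the free signs are chosen so the sample's geometric-mean
    # location barely moves between groups (the geometric mean averages
    # log Crt, so balancing happens on that scale, not the cycle scale)
    free <- setdiff(planted, separators)
    dlog <- function(s) log((baseline + s) / baseline)
    tot <- length(separators) * dlog(-separator_effect_sd * sd) +
      (0:length(free)) * dlog(effect_sd * sd) +
      (length(free):0) * dlog(-effect_sd * sd)
    n_pos <- which.min(abs(tot)) - 1L
    shift <- stats::setNames(rep(-effect_sd * sd, length(planted)), planted)
    shift[separators] <- -separator_effect_sd * sd
    shift[utils::head(free, n_pos)] <- effect_sd * sd
    tibble::tibble(
      mirna_id = planted, fluid = fluid, day = "PBD3",
      shift = unname(shift[planted])
    )
  }

  csf_retained <- setdiff(mirnas, .default_low_expression$CSF)
  csf_planted <- setdiff(csf_retained, .default_csf_null)

  plasma_retained <- setdiff(mirnas, .default_low_expression$PLASMA)
  plasma_planted <- utils::head(plasma_retained, .n_plasma_planted)

  dplyr::bind_rows(
    plant("CSF", csf_planted, .default_separators),
    plant("PLASMA", plasma_planted, character())
  )
}

#' Generate a synthetic cohort
#'
#' Draws a full Crt table for the configured cohort: patients contribute
#' CSF and plasma samples at PBD3 and PBD7, healthy controls one sample per
#' fluid. Values are normal per (miRNA, group, fluid, day); planted
#' separators at (CSF, PBD3) are post-shifted so the DCV+ and DCV- ranges
#' are disjoint by at least `gap`, and every non-separator analyzable miRNA
#' at (CSF, PBD3) is nudged to overlap if a draw is accidentally disjoint,
#' so the perfect-separator set equals the planted set by construction.
#' Values at or above the detection limit are stored as drawn (censoring is
#' a downstream rule). Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param cohort Cohort label stamped on patient samples (`"A"` by default;
#'   healthy controls carry `NA`).
#' @param subject_prefix Prefix for generated subject ids.
#' @return A [as_crt_tbl()] table.
#' @export
generate_cohort <- function(config = synthetic_config(), cohort = "A",
                            subject_prefix = "S") {
  stopifnot(inherits(config, "synthetic_config"))
  sd <- config$baseline_crt_sd
  if (config$gap > 0 && sd <= 0) {
    stop("Separator gap requires a positive within-group SD")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  mirnas <- panel_mirnas()
  subjects <- tibble::tibble(
    subject_id = sprintf("%s%02d", subject_prefix,
                         seq_len(config$n_dcv_pos + config$n_dcv_neg)),
    group = rep(c("DCV_POS", "DCV_NEG"),
                c(config$n_dcv_pos, config$n_dcv_neg))
  )
  hc <- tibble::tibble(
    subject_id = sprintf("HC%02d", seq_len(config$n_hc)),
    group = "HC"
  )

  grid_pat <- tidyr::expand_grid(subjects, fluid = .dcv_fluids,
                                 day = .dcv_days)
  grid_pat$cohort <- cohort
  grid_hc <- tidyr::expand_grid(hc, fluid = .dcv_fluids)
  grid_hc$day <- NA_character_
  grid_hc$cohort <- NA_character_
  samples <- dplyr::bind_rows(grid_pat, grid_hc)
  samples$sample_id <- paste(samples$subject_id, samples$fluid,
                             dplyr::coalesce(samples$day, "HC"), sep = "_")

  cells <- tidyr::expand_grid(samples, mirna_id = mirnas)

  # per-cell mean: baseline, plus planted shift for DCV+ (HC sits at
  # hc_scale between DCV- and DCV+ using the PBD3 shift), with
  # low-expression miRNAs recentred near the detection limit.
  eff <- config$effect_sizes
  cells <- dplyr::left_join(
    cells, dplyr::rename(eff, shift_day = "shift"),
    by = c("mirna_id", "fluid", "day")
  )
  eff3 <- dplyr::filter(eff, .data$day == "PBD3")
  cells <- dplyr::left_join(
    cells,
    dplyr::select(dplyr::rename(eff3, shift_pbd3 = "shift"),
                  "mirna_id", "fluid", "shift_pbd3"),
    by = c("mirna_id", "fluid")
  )
  cells$shift_day <- dplyr::coalesce(cells$shift_day, 0)
  cells$shift_pbd3 <- dplyr::coalesce(cells$shift_pbd3, 0)

  cells$mu <- config$baseline_crt_mean +
    ifelse(cells$group == "DCV_POS", cells$shift_day,
           ifelse(cells$group == "HC",
                  config$hc_scale * cells$shift_pbd3, 0))

  low_mu <- config$detection_limit +
    stats::qnorm(config$censored_fraction) * sd
  for (fl in names(config$low_expression)) {
    idx <- cells$fluid == fl &
      cells$mirna_id %in% config$low_expression[[fl]]
    cells$mu[idx] <- low_mu
  }

  cells$crt <- stats::rnorm(nrow(cells), cells$mu, sd)

  # enforce the planted separator gap at (CSF, PBD3) on the raw scale
  at_cp3 <- cells$fluid == "CSF" & !is.na(cells$day) & cells$day == "PBD3"
  for (m in config$perfect_separators) {
    idx <- at_cp3 & cells$mirna_id == m
    pos <- which(idx & cells$group == "DCV_POS")
    neg <- which(idx & cells$group == "DCV_NEG")
    if (length(pos) == 0 || length(neg) == 0) next
    pv <- cells$crt[pos]
    nv <- cells$crt[neg]
    dir <- sign(eff3$shift[match(m, eff3$mirna_id)])
    if (is.na(dir) || dir == 0) dir <- -1
    if (dir < 0) { # DCV+ below DCV-
      deficit <- max(pv) - (min(nv) - config$gap)
      if (deficit > 0) cells$crt[pos] <- pv - deficit
    } else {
      deficit <- (max(nv) + config$gap) - min(pv)
      if (deficit > 0) cells$crt[pos] <- pv + deficit
    }
  }

  # completely-at-random missingness, exempting separator cells at CSF/PBD3
  exempt <- at_cp3 & cells$mirna_id %in% config$perfect_separators
  miss <- stats::runif(nrow(cells)) < config$missing_rate & !exempt
  cells$crt[miss] <- NA_real_

  cells$qc_pass <- TRUE
  out <- as_crt_tbl(cells[, .crt_long_cols])

  # Anti-separation pass: downstream discrimination is judged on the
  # delta-Crt scale, so a non-separator whose groups come out accidentally
  # disjoint there is nudged back into overlap (one DCV+ raw value moved
  # so its delta-Crt sits 1.25 SD inside the DCV- delta range). Nudges
  # shift the sample's own location slightly, so the pass re-runs the
  # actual normalizer until the separator set equals the planted set.
  for (iter in 1:8) {
    mask <- suppressWarnings(
      apply_detection_rules(out, limit = config$detection_limit)
    )
    nm <- suppressWarnings(normalize_global_mean(out, mask))
    x <- dplyr::filter(tibble::as_tibble(nm), .data$fluid == "CSF",
                       !is.na(.data$day), .data$day == "PBD3")
    locs <- stats::setNames(x$location, x$sample_id)
    fixed <- 0L
    for (m in setdiff(unique(x$mirna_id), config$perfect_separators)) {
      xm <- x[x$mirna_id == m & !is.na(x$delta_crt), ]
      dp <- xm$delta_crt[xm$group == "DCV_POS"]
      dn <- xm$delta_crt[xm$group == "DCV_NEG"]
      if (length(dp) == 0 || length(dn) == 0) next
      target <- NULL
      if (max(dp) < min(dn)) {
        sid <- xm$sample_id[xm$group == "DCV_POS"][which.max(dp)]
        target <- min(dn) + 1.25 * sd
      } else if (min(dp) > max(dn)) {
        sid <- xm$sample_id[xm$group == "DCV_POS"][which.min(dp)]
        target <- max(dn) - 1.25 * sd
      }
      if (!is.null(target)) {
        i <- which(out$sample_id == sid & out$mirna_id == m)
        out$crt[i] <- target + locs[[sid]]
        fixed <- fixed + 1L
      }
    }
    if (fixed == 0L) break
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
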