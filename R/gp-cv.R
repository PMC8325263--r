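# Cross-validated prediction accuracy and the marker-subset / QTL-augmented
# experiments built on the GCA/SCA GBLUP model.

#' Cross-validated prediction accuracy
#'
#' Repeated k-fold cross-validation of the GCA/SCA GBLUP model: per run,
#' hybrids are shuffled into `n_folds` near-equal folds (run `r` uses a
#' reproducible sub-seed of `seed`); for each fold the variance components
#' are re-estimated on the training hybrids, the validation hybrids are
#' predicted, and the Pearson correlation between observed and predicted
#' values in the validation set is recorded as the prediction accuracy.
#'
#' @param data A [ttc_gp_data()] object.
#' @param trait Trait to cross-validate (default first).
#' @param kinships Optional precomputed [build_kinships()] object.
#' @param n_folds Folds per run (default 5, i.e. 80/20 splits).
#' @param n_runs Number of runs (default 100).
#' @param seed Master seed; fold assignments derive from it.
#' @param response `"blues"` or `"plots"` (see [fit_gca_sca()]).
#' @param fixed Optional fixed-covariate matrix (rows named by hybrid id).
#' @param warm_start Reuse the full-data variance components as starting
#'   values in each fold (default `TRUE`; speeds convergence).
#' @return Object of class `ttc_cv`: tibble `run`, `fold`, `n_val`,
#'   `accuracy`, with mean/SD summary available via [glance.ttc_cv()].
#' @export
cross_validate <- function(data, trait = NULL, kinships = NULL, n_folds = 5,
                           n_runs = 100, seed = 1,
                           response = c("blues", "plots"), fixed = NULL,
                           warm_start = TRUE) {
  response <- match.arg(response)
  stop_if_not(n_folds >= 2, "`n_folds` must be >= 2")
  stop_if_not(n_runs >= 1, "`n_runs` must be >= 1")
  kin <- kinships %||% gp_kinships(data)
  trait <- trait %||% data$blues$trait[1]
  obs_tbl <- dplyr::filter(data$blues, .data$trait == !!trait)
  hybrids <- obs_tbl$hybrid_id
  yobs <- setNames(obs_tbl$value, obs_tbl$hybrid_id)
  init <- NULL
  if (warm_start) {
    full <- fit_gca_sca(data, trait = trait, kinships = kin,
                        response = response, fixed = fixed)
    init <- unname(full$sigma2)
  }
  res <- list()
  dropped <- 0L
  for (r in seq_len(n_runs)) {
    ord <- with_seed(substream_seed(seed, r), sample(hybrids))
    fold_id <- rep(seq_len(n_folds), length.out = length(ord))
    for (f in seq_len(n_folds)) {
      val <- ord[fold_id == f]
      train <- setdiff(hybrids, val)
      fit <- fit_gca_sca(data, trait = trait, kinships = kin,
                         response = response, train = train, fixed = fixed,
                         init = init, check_psd = FALSE)
      pred <- predict(fit, hybrids = val)
      o <- yobs[pred$hybrid_id]
      if (sd(o) < 1e-12 || sd(pred$predicted) < 1e-12) {
        dropped <- dropped + 1L
        acc <- NA_real_
      } else {
        acc <- cor(o, pred$predicted)
      }
      res[[length(res) + 1L]] <- tibble::tibble(run = r, fold = f,
                                                n_val = length(val),
                                                accuracy = acc)
    }
  }
  if (dropped > 0) {
    rlang::warn(paste(dropped, "fold(s) with zero-variance predictions excluded"))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "trait") <- trait
  attr(out, "n_folds") <- n_folds
  attr(out, "n_runs") <- n_runs
  class(out) <- unique(c("ttc_cv", class(out)))
  out
}

#' Prediction accuracy as a function of the marker set
#'
#' Re-runs cross-validation on marker subsets, either random subsets of
#' fixed sizes (with repeats) or groups defined by a maximum marker
#' missing-rate threshold (markers whose missing rate exceeds the threshold
#' are excluded; the rest are mean-imputed as usual).
#'
#' @param data A [ttc_gp_data()] object.
#' @param trait Trait to evaluate.
#' @param sizes Integer vector of random subset sizes (mode 1).
#' @param repeats Random repeats per size (default 5).
#' @param max_missing Numeric vector of missing-rate thresholds (mode 2).
#' @param n_runs,n_folds,seed,response Cross-validation settings (fewer
#'   runs than the headline analysis are typical here: the curve is the
#'   target, not the absolute accuracy).
#' @return Tibble: `group`, `rep`, `n_markers`, `accuracy`, `accuracy_sd`.
#' @export
marker_subset_experiment <- function(data, trait = NULL, sizes = NULL,
                                     repeats = 5, max_missing = NULL,
                                     n_runs = 10, n_folds = 5, seed = 1,
                                     response = "blues") {
  stop_if_not(xor(is.null(sizes), is.null(max_missing)),
              "give exactly one of `sizes` or `max_missing`")
  markers <- colnames(data$lines)
  res <- list()
  if (!is.null(sizes)) {
    stop_if_not(all(sizes >= 1), "subset sizes must be >= 1")
    for (si in seq_along(sizes)) {
      for (rp in seq_len(repeats)) {
        sub <- with_seed(substream_seed(seed, si * 1000 + rp), {
          sample(markers, min(sizes[si], length(markers)))
        })
        cv <- cross_validate(data, trait = trait,
                             kinships = gp_kinships(data, markers = sub),
                             n_folds = n_folds, n_runs = n_runs,
                             seed = substream_seed(seed, si * 1000 + rp),
                             response = response)
        res[[length(res) + 1L]] <- tibble::tibble(
          group = sizes[si], rep = rp, n_markers = length(sub),
          accuracy = mean(cv$accuracy, na.rm = TRUE),
          accuracy_sd = sd(cv$accuracy, na.rm = TRUE))
      }
    }
  } else {
    miss <- colMeans(is.na(data$lines))
    for (mi in seq_along(max_missing)) {
      sub <- markers[miss <= max_missing[mi]]
      if (length(sub) < 1) next
      cv <- cross_validate(data, trait = trait,
                           kinships = gp_kinships(data, markers = sub),
                           n_folds = n_folds, n_runs = n_runs,
                           seed = substream_seed(seed, mi), response = response)
      res[[length(res) + 1L]] <- tibble::tibble(
        group = max_missing[mi], rep = 1L, n_markers = length(sub),
        accuracy = mean(cv$accuracy, na.rm = TRUE),
        accuracy_sd = sd(cv$accuracy, na.rm = TRUE))
    }
  }
  dplyr::bind_rows(res)
}

# markers lying inside any QTL flanking interval (inclusive), plus the
# flanking markers themselves
qtl_interval_markers <- function(map, qtl_hits) {
  stop_if_not(all(c("chrom", "flank_left", "flank_right") %in% names(qtl_hits)) ||
                all(c("chrom", "interval") %in% names(qtl_hits)),
              "qtl hits need chrom plus flank_left/flank_right or interval")
  if (!"flank_left" %in% names(qtl_hits)) {
    parts <- strsplit(qtl_hits$interval, "-", fixed = TRUE)
    qtl_hits$flank_left <- vapply(parts, `[`, "", 1)
    qtl_hits$flank_right <- vapply(parts, `[`, "", 2)
  }
  out <- character(0)
  for (k in seq_len(nrow(qtl_hits))) {
    mm <- map[map$chrom == qtl_hits$chrom[k], ]
    li <- match(qtl_hits$flank_left[k], mm$marker)
    ri <- match(qtl_hits$flank_right[k], mm$marker)
    stop_if_not(!is.na(li) && !is.na(ri), "flanking marker not on the map")
    out <- c(out, mm$marker[seq(min(li, ri), max(li, ri))])
  }
  unique(out)
}

#' QTL-augmented genomic prediction experiment
#'
#' Compares cross-validated accuracy of a baseline model using only markers
#' outside all QTL-defining intervals against an augmented model that adds
#' the QTL flanking markers, either inside the relationship matrices
#' (`mode = "kinship"`) or as fixed covariates (`mode = "fixed"`). Both
#' models use identical fold splits so the per-fold accuracy differences
#' are paired; a resampling standard error of the mean difference is
#' reported.
#'
#' @param data A [ttc_gp_data()] object.
#' @param map The marker map (used to resolve flanking intervals).
#' @param qtl_hits Tibble of QTL hits with `chrom` and flanking markers
#'   (columns `flank_left`/`flank_right` or `interval` `"mL-mR"`). Zero
#'   rows give identical baseline and augmented models.
#' @param trait Trait to evaluate.
#' @param mode `"kinship"` or `"fixed"`.
#' @param n_runs,n_folds,seed,response Cross-validation settings.
#' @return List of class `ttc_qtl_augmented`: `results` (tibble `model`,
#'   `run`, `fold`, `accuracy`), `summary` (per-model mean/SD plus the
#'   paired mean difference and its SE), `markers` (baseline and augmenting
#'   marker sets).
#' @export
qtl_augmented_experiment <- function(data, map, qtl_hits,
                                     trait = NULL,
                                     mode = c("kinship", "fixed"),
                                     n_runs = 10, n_folds = 5, seed = 1,
                                     response = "blues") {
  mode <- match.arg(mode)
  markers <- colnames(data$lines)
  if (nrow(qtl_hits) > 0) {
    inside <- qtl_interval_markers(map, qtl_hits)
    flanks <- unique(c(qtl_hits$flank_left, qtl_hits$flank_right,
                       unlist(strsplit(qtl_hits$interval %||% character(0),
                                       "-", fixed = TRUE))))
    flanks <- intersect(flanks, markers)
  } else {
    inside <- character(0)
    flanks <- character(0)
  }
  baseline_markers <- setdiff(markers, inside)
  stop_if_not(length(baseline_markers) >= 1,
              "all markers lie inside QTL intervals")
  kin_base <- gp_kinships(data, markers = baseline_markers)
  cv_base <- cross_validate(data, trait = trait, kinships = kin_base,
                            n_folds = n_folds, n_runs = n_runs, seed = seed,
                            response = response)
  if (length(flanks) == 0) {
    cv_aug <- cv_base
  } else if (mode == "kinship") {
    kin_aug <- gp_kinships(data, markers = c(baseline_markers, flanks))
    cv_aug <- cross_validate(data, trait = trait, kinships = kin_aug,
                             n_folds = n_folds, n_runs = n_runs, seed = seed,
                             response = response)
  } else {
    lm_enc <- encode_and_impute(data$lines[, flanks, drop = FALSE],
                                allow_het = FALSE)$M
    tm_enc <- encode_and_impute(data$testers[, flanks, drop = FALSE])$M
    hm <- data$hybrid_map
    Xq <- (lm_enc[hm$maternal, , drop = FALSE] +
             tm_enc[hm$paternal, , drop = FALSE]) / 2
    # drop constant covariates (monomorphic in the hybrids)
    Xq <- Xq[, apply(Xq, 2, sd) > 1e-12, drop = FALSE]
    rownames(Xq) <- hm$hybrid_id
    cv_aug <- cross_validate(data, trait = trait, kinships = kin_base,
                             n_folds = n_folds, n_runs = n_runs, seed = seed,
                             response = response,
                             fixed = if (ncol(Xq) > 0) Xq else NULL)
  }
  results <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(cv_base), model = "baseline"),
    dplyr::mutate(tibble::as_tibble(cv_aug), model = "augmented")
  )
  diffs <- cv_aug$accuracy - cv_base$accuracy
  summary <- tibble::tibble(
    baseline_mean = mean(cv_base$accuracy, na.rm = TRUE),
    augmented_mean = mean(cv_aug$accuracy, na.rm = TRUE),
    diff_mean = mean(diffs, na.rm = TRUE),
    diff_se = sd(diffs, na.rm = TRUE) / sqrt(sum(is.finite(diffs)))
  )
  structure(list(results = results, summary = summary,
                 markers = list(baseline = baseline_markers,
                                augmenting = flanks)),
            class = "ttc_qtl_augmented")
}
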