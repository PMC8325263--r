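# Configuration-driven orchestration: simulate -> transform -> scan -> predict.
# All randomness flows from one master seed through named sub-streams so any
# stage can be reproduced in isolation.

#' Default analysis configuration
#'
#' Returns the nested configuration list consumed by
#' [run_ttc_pipeline()]. Either the `simulation` block is used to generate
#' a dataset, or `input` paths to `map.csv` / `genotypes.csv` /
#' `phenotypes.csv` are given (exactly one of the two is active;
#' supplying `input` disables simulation). Any subset of settings can be
#' overridden via `utils::modifyList()` semantics, or by a YAML file with
#' the same structure.
#'
#' @param ... Named overrides merged into the defaults (nested lists merge
#'   recursively).
#' @return A configuration list of class `ttc_config`.
#' @export
ttc_config <- function(...) {
  base <- list(
    input = NULL,
    simulation = list(
      n_chrom = 10, markers_per_chrom = 163, chrom_length_cM = 694,
      n_ril = 122, n_blocks = 3, plants_per_family = 8,
      intermating_rounds = 4, missing_rate = 0,
      traits = c("LL", "LW", "LA", "SDW"), h2_target = 0.25
    ),
    stages = c("transform", "scan1d", "scan2d", "predict"),
    scan1d = list(walk_step = 1, n_perm = 1000, alpha = 0.05,
                  p_enter = 0.001, window_cM = 10),
    scan2d = list(walk_step = 5, n_perm = 200, alpha = 0.05,
                  p_enter = 1e-04, min_sep_cM = 20),
    prediction = list(n_folds = 5, n_runs = 100, response = "blues"),
    seed = 1
  )
  over <- list(...)
  cfg <- utils::modifyList(base, over)
  structure(cfg, class = c("ttc_config", "list"))
}

read_ttc_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(ttc_config, as.list(cfg))
}

#' Run the full triple-testcross analysis pipeline
#'
#' Executes the configured stages in order: data acquisition (simulation or
#' file input), phenotype aggregation and transformation (BLUEs, mid-parent
#' heterosis, Z1/Z2/Z3), one-dimensional heterotic QTL scans,
#' two-dimensional epistasis scans (H3 and Z3), and GCA/SCA genomic
#' prediction. Per-stage CSV outputs are written to `outdir` when given;
#' the returned report bundle is fully re-derivable from config + seed.
#'
#' @param config A [ttc_config()] list or path to a YAML file.
#' @param seed Optional master seed overriding `config$seed`.
#' @param outdir Optional output directory for CSV/JSON artefacts.
#' @return A `ttc_report` list: `provenance`, `blues`, `mph`, `anova`,
#'   `transforms`, `qtl_hits`, `scan_profiles`, `epistasis_hits`,
#'   `varcomps`, `cv_summary`.
#' @export
run_ttc_pipeline <- function(config = ttc_config(), seed = NULL,
                             outdir = NULL) {
  if (is.character(config)) config <- read_ttc_config(config)
  stop_if_not(inherits(config, "ttc_config") || is.list(config),
              "`config` must be a ttc_config or a YAML path")
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, name) {
    if (!is.null(outdir)) readr::write_csv(tbl, file.path(outdir, name))
    tbl
  }
  stage <- function(name) name %in% config$stages
  report <- list(provenance = list(
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("ttcqtl"))
  ))

  # --- data -----------------------------------------------------------
  if (!is.null(config$input)) {
    map <- read_genetic_map(config$input$map)
    geno <- read_genotypes(config$input$genotypes)
    pheno <- read_phenotypes(config$input$phenotypes)
    sim <- NULL
  } else {
    sc <- config$simulation
    map <- build_map(sc$n_chrom, sc$markers_per_chrom, sc$chrom_length_cM)
    arch <- lapply(sc$traits, function(tr) {
      if (tr %in% c("LL", "LW", "LA", "SDW")) sim_architecture(tr)
      else sim_architecture("polygenic", map = map,
                            seed = substream_seed(seed, 99))
    })
    names(arch) <- sc$traits
    design <- trial_design(n_ril = sc$n_ril, n_blocks = sc$n_blocks,
                           plants_per_family = sc$plants_per_family,
                           intermating_rounds = sc$intermating_rounds,
                           missing_rate = sc$missing_rate)
    sim <- sim_ttc(arch, map = map, design = design,
                   seed = substream_seed(seed, 1),
                   h2_target = sc$h2_target)
    geno <- sim$ril_geno
    pheno <- sim$phenotypes
    if (!is.null(outdir)) write_sim_dataset(sim, outdir)
  }

  # --- transform ------------------------------------------------------
  blues <- trans <- NULL
  if (stage("transform") || stage("scan1d") || stage("scan2d") || stage("predict")) {
    blues <- emit(compute_blues(pheno), "blues.csv")
    report$blues <- blues
    if (all(c("P1", "P2", "F1") %in% blues$population)) {
      report$mph <- emit(mph_from_blues(blues), "mph.csv")
    }
    report$anova <- population_anova(blues)
    trans <- emit(ttc_transforms(ttc_triplets(blues)), "transforms.csv")
    report$transforms <- trans
  }

  # --- scan1d ---------------------------------------------------------
  if (stage("scan1d")) {
    s1 <- config$scan1d
    hits <- scan_heterotic_qtls(trans, geno, map, walk_step = s1$walk_step,
                                n_perm = s1$n_perm, alpha = s1$alpha,
                                seed = substream_seed(seed, 2),
                                p_enter = s1$p_enter,
                                window_cM = s1$window_cM,
                                keep_profiles = TRUE)
    report$qtl_hits <- emit(tibble::as_tibble(hits), "qtl_hits.csv")
    report$scan_profiles <- emit(attr(hits, "profiles"), "scan_profile.csv")
  }

  # --- scan2d ---------------------------------------------------------
  if (stage("scan2d")) {
    s2 <- config$scan2d
    cache2 <- pair_cache(geno, map, s2$walk_step, s2$min_sep_cM)
    epi <- list()
    for (tr in unique(trans$trait)) {
      tt <- dplyr::filter(trans, .data$trait == tr)
      for (ds in c("H3", "Z3")) {
        y <- setNames(tt[[ds]], tt$id)
        ps <- pair_scan(y, geno, map, walk_step = s2$walk_step,
                        min_sep_cM = s2$min_sep_cM, p_enter = s2$p_enter,
                        dataset = ds, cache = cache2)
        th <- pair_permutation_threshold(
          y, geno, map, n_perm = s2$n_perm, alpha = s2$alpha,
          seed = substream_seed(seed, 3), walk_step = s2$walk_step,
          p_enter = s2$p_enter, cache = cache2)
        h <- call_epistasis(ps, th)
        if (nrow(h) > 0) {
          epi[[length(epi) + 1L]] <- dplyr::mutate(h, trait = tr,
                                                   threshold = th$threshold)
        }
      }
    }
    report$epistasis_hits <- emit(
      if (length(epi) > 0) dplyr::bind_rows(epi) else
        tibble::tibble(chrom_i = integer(0), pos_i = numeric(0),
                       interval_i = character(0), chrom_j = integer(0),
                       pos_j = numeric(0), interval_j = character(0),
                       lod = numeric(0), a_i = numeric(0), a_j = numeric(0),
                       aa_ij = numeric(0), r2_pct = numeric(0),
                       dataset = character(0), trait = character(0),
                       threshold = numeric(0)),
      "epistasis_hits.csv")
  }

  # --- predict --------------------------------------------------------
  if (stage("predict")) {
    pc <- config$prediction
    stop_if_not(!is.null(sim) ||
                  all(c("TCB", "TCM") %in% unique(pheno$population)),
                "prediction stage needs TCB and TCM phenotypes")
    gpdat <- if (!is.null(sim)) ttc_gp_data(sim) else {
      sim_like <- structure(list(ril_geno = geno, phenotypes = pheno),
                            class = "ttc_sim")
      ttc_gp_data(sim_like)
    }
    kin <- gp_kinships(gpdat)
    vc <- cv <- list()
    for (tr in unique(gpdat$blues$trait)) {
      fit <- fit_gca_sca(gpdat, trait = tr, kinships = kin,
                         response = pc$response)
      vc[[tr]] <- dplyr::bind_cols(
        tibble::tibble(trait = tr), tidyr::pivot_wider(
          tibble::tibble(component = names(fit$sigma2),
                         estimate = unname(fit$sigma2)),
          names_from = "component", values_from = "estimate"),
        heritability(fit))
      cvr <- cross_validate(gpdat, trait = tr, kinships = kin,
                            n_folds = pc$n_folds, n_runs = pc$n_runs,
                            seed = substream_seed(seed, 4),
                            response = pc$response)
      cv[[tr]] <- tibble::tibble(trait = tr,
                                 accuracy_mean = mean(cvr$accuracy, na.rm = TRUE),
                                 accuracy_sd = sd(cvr$accuracy, na.rm = TRUE),
                                 n_runs = pc$n_runs, n_folds = pc$n_folds)
    }
    report$varcomps <- emit(dplyr::bind_rows(vc), "varcomps.csv")
    report$cv_summary <- emit(dplyr::bind_rows(cv), "cv_results.csv")
  }

  if (!is.null(outdir)) {
    json <- report
    json$blues <- NULL; json$transforms <- NULL; json$scan_profiles <- NULL
    jsonlite::write_json(json, file.path(outdir, "report.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  structure(report, class = "ttc_report")
}

#' @export
print.ttc_report <- function(x, ...) {
  cat("<ttc_report> seed", x$provenance$seed, "\n")
  for (nm in setdiff(names(x), "provenance")) {
    obj <- x[[nm]]
    cat(" -", nm, if (is.data.frame(obj)) paste0("(", nrow(obj), " rows)") else "",
        "\n")
  }
  invisible(x)
}
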