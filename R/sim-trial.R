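#' Trial design for a simulated triple testcross experiment
#'
#' Captures the field-trial dimensions the simulator reproduces: a
#' randomized complete block design with `n_blocks` blocks, `n_ril` base
#' lines, and family plots of `plants_per_family` plants for the segregating
#' TC(F) testcrosses (whose plot value is a family mean). Residual noise is
#' Gaussian and homoscedastic per trait; block effects are additive
#' constants.
#'
#' @param n_ril Number of recombinant inbred lines (>= 2).
#' @param n_blocks Number of blocks (>= 1).
#' @param plants_per_family Plants sampled per TC(F) family plot (>= 1).
#' @param residual_sd Plot-level residual standard deviation; a scalar, a
#'   vector named by trait, or `NULL` to calibrate from `h2_target` in
#'   [sim_ttc()].
#' @param block_effects Numeric vector of additive block effects (recycled /
#'   defaults to zeros).
#' @param tester_replicates Plots per block for the parents and their F1:
#'   in the emulated layout every column of a block carries the three
#'   testers, so they are replicated about ten times per block while each
#'   line or testcross family occupies one plot.
#' @param intermating_rounds Random-mating rounds in RIL development.
#' @param missing_rate Marker missingness rate (completely at random).
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_ril = 122, n_blocks = 3, plants_per_family = 8,
                         residual_sd = NULL, block_effects = NULL,
                         intermating_rounds = 4, missing_rate = 0,
                         tester_replicates = 10) {
  stop_if_not(is_scalar_number(n_ril) && n_ril >= 2, "`n_ril` must be >= 2")
  stop_if_not(is_scalar_number(n_blocks) && n_blocks >= 1, "`n_blocks` must be >= 1")
  stop_if_not(is_scalar_number(plants_per_family) && plants_per_family >= 1,
              "`plants_per_family` must be >= 1")
  stop_if_not(is.null(residual_sd) || all(residual_sd >= 0),
              "`residual_sd` must be >= 0")
  if (is.null(block_effects)) block_effects <- rep(0, n_blocks)
  stop_if_not(length(block_effects) == n_blocks,
              "`block_effects` must have length `n_blocks`")
  stop_if_not(is_scalar_number(tester_replicates) && tester_replicates >= 1,
              "`tester_replicates` must be >= 1")
  structure(list(n_ril = as.integer(n_ril), n_blocks = as.integer(n_blocks),
                 plants_per_family = as.integer(plants_per_family),
                 residual_sd = residual_sd, block_effects = block_effects,
                 intermating_rounds = as.integer(intermating_rounds),
                 missing_rate = missing_rate,
                 tester_replicates = as.integer(tester_replicates)),
            class = "trial_design")
}

#' Preset QTL architectures for seedling biomass-like traits
#'
#' Fixed architectures on the default 10-chromosome map emulating four
#' seedling biomass traits of a maize testcross study: leaf length (`LL`),
#' leaf width (`LW`), leaf area (`LA`) and seedling dry weight (`SDW`).
#' Baselines and effects are chosen so mid-parent heterosis is below 50%
#' for the leaf traits and around 150% for dry weight, with a mix of
#' additive, dominance and digenic epistatic (aa, dd, da) effects. The
#' `"polygenic"` preset draws `n_loci` purely additive loci spread evenly
#' over the genome (for genomic-prediction experiments).
#'
#' @param trait One of `"LL"`, `"LW"`, `"LA"`, `"SDW"`, `"polygenic"`.
#' @param map Map used to place polygenic loci (default [build_map()]).
#' @param n_loci Number of loci for the polygenic preset.
#' @param seed Seed for the polygenic effect draw.
#' @return A [qtl_architecture()].
#' @export
sim_architecture <- function(trait = c("LL", "LW", "LA", "SDW", "polygenic"),
                             map = build_map(), n_loci = 40, seed = 1) {
  trait <- match.arg(trait)
  if (trait == "polygenic") {
    map <- validate_map(map)
    span <- map |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(lo = min(.data$pos_cM), hi = max(.data$pos_cM))
    with_seed(seed, {
      chrom <- rep(span$chrom, length.out = n_loci)
      u <- runif(n_loci, 0.05, 0.95)
      pos <- span$lo[match(chrom, span$chrom)] +
        u * (span$hi - span$lo)[match(chrom, span$chrom)]
      a <- rnorm(n_loci, 0, 1)
      return(qtl_architecture(
        loci = tibble::tibble(chrom = chrom, pos_cM = pos, a = a, d = 0),
        mu = 10, map = map
      ))
    })
  }
  preset <- switch(trait,
    LL = list(mu = 50,
              loci = tibble::tibble(chrom = c(1, 4, 7),
                                    pos_cM = c(120, 310, 205),
                                    a = c(2.0, -2.5, 1.5),
                                    d = c(4.0, 3.5, 3.5)),
              pairs = tibble::tibble(locus_i = 1L, locus_j = 2L,
                                     kind = "aa", coefficient = -3.0)),
    LW = list(mu = 3,
              loci = tibble::tibble(chrom = c(2, 4, 7, 9),
                                    pos_cM = c(150, 320, 420, 500),
                                    a = c(0.12, 0.15, -0.12, 0.10),
                                    d = c(0.25, 0.30, 0.20, 0.15)),
              pairs = NULL),
    LA = list(mu = 100,
              loci = tibble::tibble(chrom = c(4, 4, 7, 9, 10),
                                    pos_cM = c(310, 580, 430, 300, 350),
                                    a = c(6, -4, -4, 3, 4),
                                    d = c(12, 8, 9, 6, 8)),
              pairs = tibble::tibble(locus_i = 1L, locus_j = 3L,
                                     kind = "da", coefficient = 3.0)),
    SDW = list(mu = 1.2,
               loci = tibble::tibble(chrom = c(4, 5, 7, 10),
                                     pos_cM = c(210, 380, 150, 420),
                                     a = c(-0.15, 0.10, -0.12, 0.08),
                                     d = c(0.40, 0.45, 0.25, 0.20)),
               pairs = tibble::tibble(locus_i = c(2L, 1L), locus_j = c(4L, 3L),
                                      kind = c("dd", "aa"),
                                      coefficient = c(0.2, -0.1)))
  )
  qtl_architecture(loci = preset$loci, pairs = preset$pairs, mu = preset$mu)
}

# x codes of TC(B)/TC(M) hybrids derived from homozygous RIL codes Q (+-1)
tc_codes <- function(Q, tester) {
  if (tester == "P1") (Q + 1) / 2 else (Q - 1) / 2
}

#' Simulate a full triple testcross dataset
#'
#' Generates RIL genotypes under the Haldane model, derives the three
#' testcross populations (line parents `P1`/`P2`, F1 tester), and simulates
#' plot-level phenotypes for parents, F1, the RILs per se (`IBM`) and the
#' testcross populations `TCB`, `TCM`, `TCF` in a randomized complete block
#' trial. TC(F) plot values are means of `plants_per_family` individually
#' sampled progenies (the F1 tester segregates). Residuals are Gaussian.
#'
#' @param arch A [qtl_architecture()] or a named list of them (one per trait).
#' @param map A `ttc_map` (default [build_map()]).
#' @param design A [trial_design()].
#' @param seed Integer seed; same seed reproduces the dataset exactly.
#' @param h2_target Optional entry-mean heritability used to calibrate the
#'   plot residual SD per trait when `design$residual_sd` is `NULL`: the SD
#'   is set so that `Vg / (Vg + sd^2 / n_blocks)` over the TC(B)+TC(M)
#'   hybrid genetic values equals the target. Default 0.25 (seedling traits
#'   are weakly heritable).
#' @return An object of class `ttc_sim`: list with `map`, `ril_geno`
#'   (character matrix), `phenotypes` (tibble `id`, `population`, `block`,
#'   `trait`, `value`), `truth` (named list of architectures), `qtl_codes`
#'   (per-trait matrices of RIL codes at the truth loci), `design`,
#'   `residual_sd`, `seed`.
#' @export
sim_ttc <- function(arch = sim_architecture("SDW"), map = build_map(),
                    design = trial_design(), seed = NULL, h2_target = NULL) {
  map <- validate_map(map)
  if (inherits(arch, "qtl_architecture")) arch <- list(trait1 = arch)
  stop_if_not(length(arch) > 0 && all(vapply(arch, inherits, TRUE, "qtl_architecture")),
              "`arch` must be (a list of) qtl_architecture objects")
  if (is.null(names(arch))) names(arch) <- paste0("trait", seq_along(arch))
  for (a in arch) qtl_architecture(a$loci, a$pairs, a$mu, map = map)  # span check

  chroms <- sort(unique(map$chrom))
  with_seed(seed, {
    # augmented positions: markers plus every truth locus
    aug <- lapply(chroms, function(cc) {
      mpos <- map$pos_cM[map$chrom == cc]
      qpos <- unlist(lapply(arch, function(a) a$loci$pos_cM[a$loci$chrom == cc]))
      sort(unique(c(mpos, qpos)))
    })
    names(aug) <- as.character(chroms)
    hap <- simulate_ril_haplotypes(aug, design$n_ril, design$intermating_rounds)

    marker_cols <- lapply(seq_along(chroms), function(ci) {
      mpos <- map$pos_cM[map$chrom == chroms[ci]]
      match(mpos, aug[[ci]])
    })
    G <- do.call(cbind, lapply(seq_along(chroms), function(ci) {
      hap[[ci]][, marker_cols[[ci]], drop = FALSE]
    }))
    colnames(G) <- unlist(lapply(chroms, function(cc) map$marker[map$chrom == cc]))
    ril_ids <- sprintf("RIL%03d", seq_len(design$n_ril))
    rownames(G) <- ril_ids
    ril_geno <- matrix(ifelse(G == 1L, "A", "B"), nrow(G), ncol(G),
                       dimnames = dimnames(G))
    if (design$missing_rate > 0) {
      drop <- runif(length(ril_geno)) < design$missing_rate
      ril_geno[drop] <- NA_character_
    }

    # per-trait RIL codes at truth loci (+1 hom-P1 / -1 hom-P2)
    qtl_codes <- lapply(arch, function(a) {
      if (nrow(a$loci) == 0) {
        return(matrix(numeric(), design$n_ril, 0,
                      dimnames = list(ril_ids, NULL)))
      }
      cols <- vapply(seq_len(nrow(a$loci)), function(k) {
        ci <- match(a$loci$chrom[k], chroms)
        2 * hap[[ci]][, match(a$loci$pos_cM[k], aug[[ci]])] - 1
      }, numeric(design$n_ril))
      cols <- matrix(cols, nrow = design$n_ril,
                     dimnames = list(ril_ids, NULL))
      cols
    })

    # residual SDs
    res_sd <- design$residual_sd
    if (is.null(res_sd)) {
      h2 <- h2_target %||% 0.25
      h2 <- rep(h2, length.out = length(arch))
      res_sd <- vapply(seq_along(arch), function(t) {
        Q <- qtl_codes[[t]]
        gv <- c(genotypic_value(tc_codes(Q, "P1"), arch[[t]]),
                genotypic_value(tc_codes(Q, "P2"), arch[[t]]))
        vg <- var(gv)
        if (vg == 0 || h2[t] >= 1) 0 else
          sqrt(design$n_blocks * vg * (1 - h2[t]) / h2[t])
      }, numeric(1))
    } else {
      res_sd <- rep(res_sd, length.out = length(arch))
    }
    names(res_sd) <- names(arch)

    rows <- list()
    for (t in seq_along(arch)) {
      a <- arch[[t]]
      trait <- names(arch)[t]
      L <- nrow(a$loci)
      Q <- qtl_codes[[t]]
      gv <- list(
        P1 = genotypic_value(matrix(1, 1, L), a),
        P2 = genotypic_value(matrix(-1, 1, L), a),
        F1 = genotypic_value(matrix(0, 1, L), a),
        IBM = genotypic_value(Q, a),
        TCB = genotypic_value(tc_codes(Q, "P1"), a),
        TCM = genotypic_value(tc_codes(Q, "P2"), a)
      )
      ids <- list(P1 = "P1", P2 = "P2", F1 = "F1",
                  IBM = ril_ids, TCB = ril_ids, TCM = ril_ids)
      # per-chromosome locus indexing for tester gametes in TC(F)
      loc_by_chrom <- split(seq_len(L), a$loci$chrom)
      for (b in seq_len(design$n_blocks)) {
        # TC(F): sample plants_per_family progeny per family in this block
        npl <- design$n_ril * design$plants_per_family
        gam <- matrix(1, npl, L)
        for (cc in names(loc_by_chrom)) {
          idx <- loc_by_chrom[[cc]]
          pos <- a$loci$pos_cM[idx]
          o <- order(pos)
          g <- f1_gametes(pos[o], npl)
          gam[, idx[o]] <- g
        }
        gam <- 2 * gam - 1
        Qp <- Q[rep(seq_len(design$n_ril), each = design$plants_per_family), ,
                drop = FALSE]
        Xp <- (Qp + gam) / 2
        gv_tcf_plants <- genotypic_value(Xp, a)
        gv_tcf <- rowsum(gv_tcf_plants,
                         rep(seq_len(design$n_ril),
                             each = design$plants_per_family))[, 1] /
          design$plants_per_family
        for (popn in c("P1", "P2", "F1", "IBM", "TCB", "TCM")) {
          reps <- if (popn %in% c("P1", "P2", "F1")) design$tester_replicates
                  else 1L
          g <- rep(gv[[popn]], times = reps)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = rep(ids[[popn]], times = reps), population = popn,
            block = b, trait = trait,
            value = unname(g + design$block_effects[b] +
                             rnorm(length(g), 0, res_sd[t]))
          )
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = ril_ids, population = "TCF", block = b, trait = trait,
          value = unname(gv_tcf + design$block_effects[b] +
                           rnorm(design$n_ril, 0, res_sd[t]))
        )
      }
    }
    phen <- dplyr::bind_rows(rows)
    structure(list(map = map, ril_geno = ril_geno, phenotypes = phen,
                   truth = arch, qtl_codes = qtl_codes, design = design,
                   residual_sd = res_sd, seed = seed),
              class = "ttc_sim")
  })
}

#' @export
print.ttc_sim <- function(x, ...) {
  cat("<ttc_sim>", nrow(x$ril_geno), "RILs x", ncol(x$ril_geno), "markers;",
      length(x$truth), "trait(s);", nrow(x$phenotypes), "plot records\n")
  invisible(x)
}
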