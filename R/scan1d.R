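# One-dimensional heterotic QTL scans (ICIM-style).
#
# The scan follows the inclusive-composite-interval-mapping idea: background
# markers are chosen once by stepwise regression on the full marker set, the
# response is adjusted by their joint coefficients (excluding markers near
# the current test position so the tested QTL's own effect is not absorbed),
# and the adjusted response is regressed on the conditional expected code at
# each grid position. LOD = (n/2) log10(RSS0 / RSS1).

impute_marker_codes <- function(X) {
  # column-mean imputation of missing +-1 codes
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx) > 0) X[idx] <- cm[idx[, 2]]
  X
}

align_response <- function(response, geno) {
  if (is.data.frame(response)) {
    stop_if_not(all(c("id", "value") %in% names(response)),
                "tibble responses need columns id, value")
    y <- setNames(response$value, response$id)
  } else {
    y <- response
  }
  if (!is.null(names(y)) && !is.null(rownames(geno))) {
    stop_if_not(all(names(y) %in% rownames(geno)),
                "response ids missing from the genotype matrix",
                class = "ttcqtl_invalid_input")
    full <- setNames(rep(NA_real_, nrow(geno)), rownames(geno))
    full[names(y)] <- y
    y <- full
  } else {
    stop_if_not(length(y) == nrow(geno),
                "unnamed response must match genotype rows",
                class = "ttcqtl_invalid_input")
  }
  y
}

# Precomputed structures shared by scans and permutations.
scan_cache <- function(geno, map, walk_step = 1) {
  map <- validate_map(map)
  grid <- scan_grid(map, walk_step)
  list(
    map = map,
    grid = grid,
    C = conditional_code_matrix(geno, map, grid),
    M = impute_marker_codes(marker_code_matrix(geno[, map$marker, drop = FALSE]))
  )
}

#' Stepwise selection of background markers
#'
#' Forward-backward stepwise linear regression of a response on marker
#' codes, used to pick cofactors that absorb background QTL variation in
#' genome scans. Missing codes are replaced by the marker mean; duplicated
#' (collinear) markers are skipped with a warning, keeping the first.
#'
#' @param y Numeric response vector.
#' @param X Numeric marker-code matrix (rows = individuals); `NA` allowed.
#' @param p_enter Entry p-value for the forward step (default 0.001, the
#'   conventional stringent inclusion probability for these scans).
#' @param p_exit Removal p-value for the backward step (default
#'   `2 * p_enter`).
#' @param max_markers Cap on the selected set size (default `n / 5`).
#' @return List with `index` (column indices), `markers` (names), `beta`
#'   (coefficients of the joint fit, without intercept), `intercept`, `r2`.
#' @export
select_background <- function(y, X, p_enter = 0.001, p_exit = 2 * p_enter,
                              max_markers = NULL) {
  ok <- is.finite(y)
  stop_if_not(sum(ok) >= 10, "need at least 10 observations")
  y <- y[ok]
  X <- impute_marker_codes(X[ok, , drop = FALSE])
  n <- length(y)
  max_markers <- max_markers %||% max(1L, floor(n / 5))
  sel <- integer(0)
  warned_collinear <- FALSE
  repeat {
    changed <- FALSE
    # forward step
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    r <- y - Q %*% crossprod(Q, y)
    Xr <- X - Q %*% crossprod(Q, X)
    s2x <- colSums(Xr^2)
    tol <- 1e-8 * n
    cand <- setdiff(which(s2x > tol), sel)
    if (any(s2x <= tol & !(seq_along(s2x) %in% sel)) && !warned_collinear &&
        length(sel) > 0) {
      rlang::warn("collinear markers skipped (keeping first of each group)")
      warned_collinear <- TRUE
    }
    if (length(cand) > 0 && length(sel) < max_markers) {
      beta <- colSums(Xr[, cand, drop = FALSE] * as.vector(r)) / s2x[cand]
      rss_red <- sum(r^2)
      rss_full <- rss_red - beta^2 * s2x[cand]
      df <- n - length(sel) - 2L
      tstat2 <- beta^2 * s2x[cand] / pmax(rss_full / df, 1e-300)
      pvals <- 2 * pt(-sqrt(tstat2), df)
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        sel <- c(sel, cand[best])
        changed <- TRUE
      }
    }
    # backward step
    if (length(sel) > 1) {
      fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      dfres <- n - length(sel) - 1L
      drop_p <- vapply(seq_along(sel), function(j) {
        fitj <- stats::lm.fit(cbind(1, X[, sel[-j], drop = FALSE]), y)
        rssj <- sum(fitj$residuals^2)
        fstat <- (rssj - rss) / (rss / dfres)
        pf(fstat, 1, dfres, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] > p_exit) {
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(sel) > 0) {
    fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
    beta <- fit$coefficients[-1]
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    list(index = sel, markers = colnames(X)[sel], beta = unname(beta),
         intercept = unname(fit$coefficients[1]), r2 = r2)
  } else {
    list(index = integer(0), markers = character(0), beta = numeric(0),
         intercept = mean(y), r2 = 0)
  }
}

# Core scan: returns lod/effect/rss at every grid position for response y.
scan1d_core <- function(y, cache, background, window_cM = 10) {
  n <- length(y)
  grid <- cache$grid
  C <- cache$C
  bg_idx <- background$index
  if (length(bg_idx) == 0) {
    groups <- list(seq_len(nrow(grid)))
    adj <- list(y)
  } else {
    bg_chrom <- cache$map$chrom[bg_idx]
    bg_pos <- cache$map$pos_cM[bg_idx]
    sig <- vapply(seq_len(nrow(grid)), function(p) {
      excl <- bg_chrom == grid$chrom[p] & abs(bg_pos - grid$pos_cM[p]) <= window_cM
      paste(which(!excl), collapse = ",")
    }, character(1))
    groups <- split(seq_len(nrow(grid)), sig)
    adj <- lapply(names(groups), function(s) {
      keep <- as.integer(strsplit(s, ",")[[1]])
      if (length(keep) == 0) y
      else y - cache$M[, bg_idx[keep], drop = FALSE] %*% background$beta[keep]
    })
  }
  lod <- effect <- rss1 <- rss0 <- numeric(nrow(grid))
  for (g in seq_along(groups)) {
    pos <- groups[[g]]
    ya <- as.vector(adj[[g]])
    yc <- ya - mean(ya)
    syy <- sum(yc^2)
    Cg <- C[, pos, drop = FALSE]
    Cc <- sweep(Cg, 2, colMeans(Cg))
    sxx <- colSums(Cc^2)
    sxy <- as.vector(crossprod(Cc, yc))
    poly <- sxx > 1e-10 * n
    r2 <- ifelse(poly, sxy^2 / (sxx * syy), 0)
    r2 <- pmin(r2, 1 - 1e-15)
    lod[pos] <- -(n / 2) * log10(1 - r2)
    effect[pos] <- ifelse(poly, sxy / sxx, NA_real_)
    rss0[pos] <- syy
    rss1[pos] <- syy * (1 - r2)
  }
  tibble::tibble(chrom = grid$chrom, pos_cM = grid$pos_cM, lod = lod,
                 effect = effect, rss0 = rss0, rss1 = rss1)
}

#' One-dimensional genome scan
#'
#' Scans a response (typically one of the Z1/Z2/Z3 transformations) along
#' the genome on a fixed cM grid, with stepwise-selected background markers
#' as cofactors. The response is adjusted by the background coefficients,
#' excluding background markers within `window_cM` of the test position, and
#' regressed on the conditional expected code at each position.
#'
#' @param response Numeric vector named by line id (or tibble `id`, `value`).
#' @param geno Character line-genotype matrix (`A`/`B`/`NA`).
#' @param map A `ttc_map`.
#' @param walk_step Scan step in cM (default 1).
#' @param p_enter,p_exit Stepwise entry/removal p-values for background
#'   selection.
#' @param window_cM Half-width of the cofactor exclusion window.
#' @param dataset Optional label (`"Z1"`, `"Z2"`, `"Z3"`, ...) stored with
#'   the profile.
#' @param cache Precomputed [scan_cache] (internal use, e.g. permutations).
#' @return A `ttc_scan` tibble: `chrom`, `pos_cM`, `lod`, `effect`, `rss0`,
#'   `rss1`, with the background selection, map and sample size in
#'   attributes.
#' @export
scan1d <- function(response, geno, map, walk_step = 1, p_enter = 0.001,
                   p_exit = 2 * p_enter, window_cM = 10, dataset = NULL,
                   cache = NULL) {
  cache <- cache %||% scan_cache(geno, map, walk_step)
  y <- align_response(response, geno)
  keep <- is.finite(y)
  stop_if_not(sum(keep) >= 10, "need at least 10 lines with response values")
  if (!all(keep)) {
    cache <- list(map = cache$map, grid = cache$grid,
                  C = cache$C[keep, , drop = FALSE],
                  M = cache$M[keep, , drop = FALSE])
    y <- y[keep]
  }
  bg <- select_background(y, cache$M, p_enter = p_enter, p_exit = p_exit)
  prof <- scan1d_core(y, cache, bg, window_cM = window_cM)
  attr(prof, "background") <- bg
  attr(prof, "map") <- cache$map
  attr(prof, "n") <- length(y)
  attr(prof, "dataset") <- dataset
  class(prof) <- unique(c("ttc_scan", class(prof)))
  prof
}

#' Permutation threshold for a one-dimensional scan
#'
#' Shuffles the response across lines `n_perm` times (each permutation uses
#' a reproducible sub-seed of `seed`), re-runs the scan (including
#' background reselection) and returns the empirical `1 - alpha` quantile
#' (type-7 interpolation) of the genome-wide maximum LOD.
#'
#' @inheritParams scan1d
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide significance level.
#' @param seed Master seed for the permutation streams.
#' @return List of class `ttc_perm_threshold`: `threshold`, `max_lods`,
#'   `alpha`, `n_perm`.
#' @export
permutation_threshold <- function(response, geno, map, n_perm = 1000,
                                  alpha = 0.05, seed = 1, walk_step = 1,
                                  p_enter = 0.001, p_exit = 2 * p_enter,
                                  window_cM = 10, cache = NULL) {
  stop_if_not(n_perm >= 100, "`n_perm` must be >= 100")
  cache <- cache %||% scan_cache(geno, map, walk_step)
  y <- align_response(response, geno)
  keep <- is.finite(y)
  if (!all(keep)) {
    cache <- list(map = cache$map, grid = cache$grid,
                  C = cache$C[keep, , drop = FALSE],
                  M = cache$M[keep, , drop = FALSE])
    y <- y[keep]
  }
  n <- length(y)
  perms <- vapply(seq_len(n_perm), function(k) {
    with_seed(substream_seed(seed, k), sample.int(n))
  }, integer(n))
  Yp <- matrix(y[perms], n, n_perm)

  # screen: which permutations select any background marker at p_enter
  Ms <- scale(cache$M)
  Ms[!is.finite(Ms)] <- 0
  Ys <- scale(Yp)
  r <- crossprod(Ms, Ys) / (n - 1)
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- sqrt(r2 * (n - 2) / (1 - r2))
  pmin_perm <- 2 * pt(-apply(tstat, 2, max), n - 2)
  empty_bg <- pmin_perm >= p_enter

  max_lods <- numeric(n_perm)
  if (any(empty_bg)) {
    Cc <- sweep(cache$C, 2, colMeans(cache$C))
    sxx <- colSums(Cc^2)
    poly <- sxx > 1e-10 * n
    Yb <- Yp[, empty_bg, drop = FALSE]
    Ybc <- sweep(Yb, 2, colMeans(Yb))
    syy <- colSums(Ybc^2)
    if (any(poly)) {
      num <- crossprod(Cc[, poly, drop = FALSE], Ybc)^2
      r2g <- sweep(sweep(num, 1, sxx[poly], "/"), 2, syy, "/")
      r2g <- pmin(r2g, 1 - 1e-15)
      max_lods[empty_bg] <- apply(-(n / 2) * log10(1 - r2g), 2, max)
    }
  }
  for (k in which(!empty_bg)) {
    bg <- select_background(Yp[, k], cache$M, p_enter = p_enter, p_exit = p_exit)
    max_lods[k] <- max(scan1d_core(Yp[, k], cache, bg, window_cM)$lod)
  }
  structure(list(threshold = unname(quantile(max_lods, 1 - alpha, type = 7)),
                 max_lods = max_lods, alpha = alpha, n_perm = n_perm),
            class = "ttc_perm_threshold")
}

#' Call QTLs from a scan profile
#'
#' Reports local maxima of the LOD profile above the genome-wide threshold.
#' Peaks on the same chromosome within `merge_cM` are merged, keeping the
#' higher LOD (ties resolved to the leftmost position). Each hit carries its
#' nearest typed flanking markers, a 1-LOD support interval and the
#' phenotypic variance explained at the peak,
#' `R2 = 100 (1 - RSS1 / RSS0)` from the single-QTL fit on the adjusted
#' response.
#'
#' @param profile A `ttc_scan` from [scan1d()].
#' @param threshold Genome-wide LOD threshold (a number or a
#'   `ttc_perm_threshold`).
#' @param merge_cM Peak merge radius in cM.
#' @return Tibble of hits: `chrom`, `pos_cM`, `lod`, `effect`, `r2_pct`,
#'   `ci_lo`, `ci_hi`, `flank_left`, `flank_right`, `dataset`. May be empty.
#' @export
call_qtls <- function(profile, threshold, merge_cM = 20) {
  if (inherits(threshold, "ttc_perm_threshold")) threshold <- threshold$threshold
  map <- attr(profile, "map")
  sig <- which(profile$lod >= threshold & profile$lod > 0)
  hits <- list()
  if (length(sig) > 0) {
    ord <- sig[order(-profile$lod[sig], profile$chrom[sig], profile$pos_cM[sig])]
    taken <- tibble::tibble(chrom = integer(0), pos_cM = numeric(0))
    for (p in ord) {
      if (nrow(taken) > 0 &&
          any(taken$chrom == profile$chrom[p] &
                abs(taken$pos_cM - profile$pos_cM[p]) <= merge_cM)) next
      taken <- dplyr::bind_rows(taken, tibble::tibble(
        chrom = profile$chrom[p], pos_cM = profile$pos_cM[p]))
      # 1-LOD support interval within the chromosome
      on_chr <- which(profile$chrom == profile$chrom[p])
      lods <- profile$lod[on_chr]
      pos <- profile$pos_cM[on_chr]
      j <- match(p, on_chr)
      lo <- j; while (lo > 1 && lods[lo - 1] >= lods[j] - 1) lo <- lo - 1
      hi <- j; while (hi < length(lods) && lods[hi + 1] >= lods[j] - 1) hi <- hi + 1
      mpos <- map$pos_cM[map$chrom == profile$chrom[p]]
      mnames <- map$marker[map$chrom == profile$chrom[p]]
      lefti <- max(1L, findInterval(profile$pos_cM[p] + 1e-9, mpos))
      righti <- if (mpos[lefti] >= profile$pos_cM[p] - 1e-9) lefti else
        min(length(mpos), lefti + 1L)
      hits[[length(hits) + 1L]] <- tibble::tibble(
        chrom = profile$chrom[p], pos_cM = profile$pos_cM[p],
        lod = profile$lod[p], effect = profile$effect[p],
        r2_pct = 100 * (1 - profile$rss1[p] / profile$rss0[p]),
        ci_lo = pos[lo], ci_hi = pos[hi],
        flank_left = mnames[lefti], flank_right = mnames[righti]
      )
    }
  }
  out <- if (length(hits) > 0) {
    dplyr::arrange(dplyr::bind_rows(hits), .data$chrom, .data$pos_cM)
  } else {
    tibble::tibble(chrom = integer(0), pos_cM = numeric(0), lod = numeric(0),
                   effect = numeric(0), r2_pct = numeric(0), ci_lo = numeric(0),
                   ci_hi = numeric(0), flank_left = character(0),
                   flank_right = character(0))
  }
  out$dataset <- rep(attr(profile, "dataset") %||% NA_character_, nrow(out))
  out
}

#' Estimate augmented additive, augmented dominance and epistatic effects
#'
#' At a genome position, regresses each transformation on the conditional
#' expected code `x` (in `[-1, 1]`) and converts the slopes to effect
#' conventions fixed by noise-free recovery of simulated architectures:
#' `a* = 2 b(Z1)` (the Z1 contrast between the two homozygous line classes),
#' `d* = -b(Z2)` (the Z2 class contrast equals `-2 d`), and `da = 2 b(Z3)`.
#' Positive `a*` means the parent-1 allele increases the trait.
#'
#' @param transforms Tibble from [ttc_transforms()] (single trait), columns
#'   `id`, `Z1`, `Z2`, `Z3`.
#' @param geno,map Line genotypes and map.
#' @param chrom,pos_cM Position at which to estimate.
#' @return One-row tibble `a_star`, `d_star`, `da`.
#' @export
estimate_effects_at <- function(transforms, geno, map, chrom, pos_cM) {
  stop_if_not(all(c("id", "Z1", "Z2", "Z3") %in% names(transforms)),
              "transforms need columns id, Z1, Z2, Z3")
  x <- conditional_code(geno, map, chrom, pos_cM)
  names(x) <- rownames(geno)
  x <- x[transforms$id]
  vx <- sum((x - mean(x))^2)
  stop_if_not(vx > 1e-10 * length(x),
              "monomorphic position: effects undefined",
              class = "ttcqtl_undefined_effect")
  slope <- function(z) sum((x - mean(x)) * (z - mean(z))) / vx
  tibble::tibble(a_star = 2 * slope(transforms$Z1),
                 d_star = -slope(transforms$Z2),
                 da = 2 * slope(transforms$Z3))
}

#' Classify the gene mode of a QTL
#'
#' Uses the dominance ratio `|d* / a*|`: additive (`A`) below 0.2, partially
#' dominant (`PD`) in \[0.2, 0.8), dominant (`D`) in \[0.8, 1.2),
#' overdominant (`OD`) at or above 1.2. A zero `a*` with non-zero `d*` is an
#' infinite ratio, hence `OD`; both zero is undefined (`NA` with a warning).
#'
#' @param a_star,d_star Numeric vectors of augmented effects.
#' @return Character vector of modes (`"A"`, `"PD"`, `"D"`, `"OD"`).
#' @export
classify_gene_mode <- function(a_star, d_star) {
  stop_if_not(all(is.finite(a_star)) && all(is.finite(d_star)),
              "effects must be finite")
  ratio <- ifelse(a_star == 0, ifelse(d_star == 0, NA_real_, Inf),
                  abs(d_star / a_star))
  if (anyNA(ratio)) rlang::warn("a* and d* both zero: gene mode undefined")
  dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    ratio < 0.2 ~ "A",
    ratio < 0.8 ~ "PD",
    ratio < 1.2 ~ "D",
    TRUE ~ "OD"
  )
}

#' Scan all three transformations and assemble a heterotic QTL table
#'
#' Runs Z1 (augmented additive), Z2 (augmented dominance) and Z3
#' (dominance x additive epistatic) scans with their own permutation
#' thresholds, calls QTLs, estimates `a*`, `d*` and `da` at each peak and
#' classifies gene modes.
#'
#' @param transforms Output of [ttc_transforms()]; a `trait` column is
#'   honoured.
#' @param geno,map Line genotypes and map.
#' @param n_perm,alpha Permutation settings per dataset.
#' @param seed Master seed (sub-streams per trait/dataset).
#' @param keep_profiles Attach the full LOD profiles as attribute
#'   `"profiles"` of the result.
#' @inheritParams scan1d
#' @return Tibble mirroring a heterotic-QTL summary table: `trait`,
#'   `dataset`, `chrom`, `pos_cM`, `interval`, `lod`, `a_star`, `d_star`,
#'   `da`, `r2_pct`, `gene_mode`, `threshold`.
#' @export
scan_heterotic_qtls <- function(transforms, geno, map, walk_step = 1,
                                n_perm = 1000, alpha = 0.05, seed = 1,
                                p_enter = 0.001, p_exit = 2 * p_enter,
                                window_cM = 10, keep_profiles = FALSE) {
  if (!"trait" %in% names(transforms)) transforms$trait <- "trait1"
  cache <- scan_cache(geno, map, walk_step)
  traits <- unique(transforms$trait)
  out <- list()
  profiles <- list()
  for (ti in seq_along(traits)) {
    tr <- dplyr::filter(transforms, .data$trait == traits[ti])
    for (di in 1:3) {
      ds <- c("Z1", "Z2", "Z3")[di]
      y <- setNames(tr[[ds]], tr$id)
      prof <- scan1d(y, geno, map, walk_step = walk_step, p_enter = p_enter,
                     p_exit = p_exit, window_cM = window_cM, dataset = ds,
                     cache = cache)
      thr <- permutation_threshold(y, geno, map, n_perm = n_perm,
                                   alpha = alpha,
                                   seed = substream_seed(seed, ti * 10 + di),
                                   walk_step = walk_step, p_enter = p_enter,
                                   p_exit = p_exit, window_cM = window_cM,
                                   cache = cache)
      if (keep_profiles) {
        profiles[[length(profiles) + 1L]] <- dplyr::mutate(
          tibble::as_tibble(prof)[, c("chrom", "pos_cM", "lod", "effect")],
          trait = traits[ti], dataset = ds, threshold = thr$threshold)
      }
      hits <- call_qtls(prof, thr)
      if (nrow(hits) == 0) next
      eff <- purrr::map_dfr(seq_len(nrow(hits)), function(h) {
        estimate_effects_at(tr, geno, map, hits$chrom[h], hits$pos_cM[h])
      })
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(trait = traits[ti], dataset = ds), hits[, c(
          "chrom", "pos_cM", "lod", "r2_pct", "flank_left", "flank_right")],
        eff,
        tibble::tibble(threshold = thr$threshold)
      )
    }
  }
  res <- if (length(out) == 0) {
    tibble::tibble(trait = character(0), dataset = character(0),
                   chrom = integer(0), pos_cM = numeric(0),
                   interval = character(0), lod = numeric(0),
                   a_star = numeric(0), d_star = numeric(0), da = numeric(0),
                   r2_pct = numeric(0), gene_mode = character(0),
                   threshold = numeric(0))
  } else {
    dplyr::bind_rows(out) |>
      dplyr::mutate(interval = paste0(.data$flank_left, "-", .data$flank_right),
                    gene_mode = classify_gene_mode(.data$a_star, .data$d_star)) |>
      dplyr::select("trait", "dataset", "chrom", "pos_cM", "interval", "lod",
                    "a_star", "d_star", "da", "r2_pct", "gene_mode",
                    "threshold")
  }
  if (keep_profiles) attr(res, "profiles") <- dplyr::bind_rows(profiles)
  res
}
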