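# Two-dimensional digenic epistasis scans.
#
# Additive x additive interactions are mapped in the H3 testcross means and
# dominance x dominance interactions in Z3. At each ordered position pair
# the full model (main effects + interaction + background cofactors) is
# compared with the reduced model without the interaction term:
# LOD = (n/2) log10(RSS_red / RSS_full).

pair_cache <- function(geno, map, walk_step = 5, min_sep_cM = 20) {
  map <- validate_map(map)
  grid <- scan_grid(map, walk_step)
  C <- conditional_code_matrix(geno, map, grid)
  M <- impute_marker_codes(marker_code_matrix(geno[, map$marker, drop = FALSE]))
  np <- nrow(grid)
  idx <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  keep <- grid$chrom[idx[, 1]] != grid$chrom[idx[, 2]] |
    abs(grid$pos_cM[idx[, 1]] - grid$pos_cM[idx[, 2]]) > min_sep_cM
  pairs <- tibble::tibble(i = idx[keep, 1], j = idx[keep, 2])
  stop_if_not(nrow(pairs) >= 1, "scan grid yields no admissible position pairs")
  list(map = map, grid = grid, C = C, M = M, pairs = pairs)
}

pair_scan_core <- function(y, cache, background, window_cM = 10,
                           cor_limit = 0.95) {
  n <- length(y)
  grid <- cache$grid
  C <- cache$C
  pairs <- cache$pairs
  tss <- sum((y - mean(y))^2)
  bg_idx <- background$index
  bg_chrom <- cache$map$chrom[bg_idx]
  bg_pos <- cache$map$pos_cM[bg_idx]
  m <- nrow(pairs)
  lod <- a_i <- a_j <- aa_ij <- r2 <- rep(NA_real_, m)
  skipped <- logical(m)
  for (k in seq_len(m)) {
    i <- pairs$i[k]; j <- pairs$j[k]
    xi <- C[, i]; xj <- C[, j]
    if (sd(xi) < 1e-8 || sd(xj) < 1e-8) {
      lod[k] <- 0
      next
    }
    if (abs(cor(xi, xj)) > cor_limit) {
      skipped[k] <- TRUE
      next
    }
    keep_bg <- if (length(bg_idx) > 0) {
      !((bg_chrom == grid$chrom[i] & abs(bg_pos - grid$pos_cM[i]) <= window_cM) |
          (bg_chrom == grid$chrom[j] & abs(bg_pos - grid$pos_cM[j]) <= window_cM))
    } else {
      logical(0)
    }
    Xb <- cache$M[, bg_idx[keep_bg], drop = FALSE]
    Xred <- cbind(1, Xb, xi, xj)
    Xfull <- cbind(Xred, xi * xj)
    fr <- stats::lm.fit(Xred, y)
    ff <- stats::lm.fit(Xfull, y)
    rssr <- sum(fr$residuals^2)
    rssf <- sum(ff$residuals^2)
    cf <- ff$coefficients
    nc <- length(cf)
    lod[k] <- (n / 2) * log10(max(rssr, 1e-300) / max(rssf, 1e-300))
    a_i[k] <- cf[nc - 2L]
    a_j[k] <- cf[nc - 1L]
    aa_ij[k] <- cf[nc]
    r2[k] <- 100 * (rssr - rssf) / tss
  }
  if (any(skipped)) {
    rlang::inform(paste(sum(skipped), "tightly linked pair(s) skipped"))
  }
  tibble::tibble(chrom_i = grid$chrom[pairs$i], pos_i = grid$pos_cM[pairs$i],
                 chrom_j = grid$chrom[pairs$j], pos_j = grid$pos_cM[pairs$j],
                 lod = lod, a_i = a_i, a_j = a_j, aa_ij = aa_ij,
                 r2_pct = r2, skipped = skipped)
}

#' Two-dimensional genome scan for digenic epistasis
#'
#' Scans all admissible position pairs (different chromosomes, or separated
#' by more than `min_sep_cM` on the same chromosome to avoid collinearity)
#' for an interaction between the conditional expected codes, with 1D
#' stepwise background markers as cofactors in both models (markers within
#' `window_cM` of either test locus excluded). The interaction coefficient
#' is interpreted as additive x additive when the response is H3 and
#' dominance x dominance when the response is Z3.
#'
#' @inheritParams scan1d
#' @param walk_step Grid step in cM (default 5).
#' @param min_sep_cM Minimum within-chromosome pair separation.
#' @param background Logical: select stepwise background cofactors.
#' @param cache Precomputed [pair_cache] (internal).
#' @return A `ttc_pairscan` tibble: `chrom_i`, `pos_i`, `chrom_j`, `pos_j`,
#'   `lod`, `a_i`, `a_j`, `aa_ij`, `r2_pct`, `skipped`.
#' @export
pair_scan <- function(response, geno, map, walk_step = 5, min_sep_cM = 20,
                      window_cM = 10, p_enter = 1e-04, p_exit = 2 * p_enter,
                      background = TRUE, dataset = NULL, cache = NULL) {
  cache <- cache %||% pair_cache(geno, map, walk_step, min_sep_cM)
  y <- align_response(response, geno)
  keep <- is.finite(y)
  stop_if_not(sum(keep) >= 10, "need at least 10 lines with response values")
  if (!all(keep)) {
    cache <- list(map = cache$map, grid = cache$grid,
                  C = cache$C[keep, , drop = FALSE],
                  M = cache$M[keep, , drop = FALSE], pairs = cache$pairs)
    y <- y[keep]
  }
  bg <- if (isTRUE(background)) {
    select_background(y, cache$M, p_enter = max(p_enter, 0.001),
                      p_exit = max(p_exit, 0.002))
  } else {
    list(index = integer(0), beta = numeric(0))
  }
  prof <- pair_scan_core(y, cache, bg, window_cM = window_cM)
  attr(prof, "map") <- cache$map
  attr(prof, "n") <- length(y)
  attr(prof, "dataset") <- dataset
  attr(prof, "background") <- bg
  class(prof) <- unique(c("ttc_pairscan", class(prof)))
  prof
}

#' Permutation threshold for the two-dimensional scan
#'
#' Permutes the response, records the grid-wide maximum interaction LOD per
#' permutation and returns the empirical `1 - alpha` quantile.
#'
#' @inheritParams pair_scan
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Grid-wide significance level.
#' @param seed Master seed (sub-seed per permutation).
#' @return List of class `ttc_perm_threshold`.
#' @export
pair_permutation_threshold <- function(response, geno, map, n_perm = 200,
                                       alpha = 0.05, seed = 1, walk_step = 5,
                                       min_sep_cM = 20, window_cM = 10,
                                       p_enter = 1e-04, p_exit = 2 * p_enter,
                                       background = TRUE, cache = NULL) {
  stop_if_not(n_perm >= 100, "`n_perm` must be >= 100")
  cache <- cache %||% pair_cache(geno, map, walk_step, min_sep_cM)
  y <- align_response(response, geno)
  keep <- is.finite(y)
  if (!all(keep)) {
    cache <- list(map = cache$map, grid = cache$grid,
                  C = cache$C[keep, , drop = FALSE],
                  M = cache$M[keep, , drop = FALSE], pairs = cache$pairs)
    y <- y[keep]
  }
  n <- length(y)
  perms <- vapply(seq_len(n_perm), function(k) {
    with_seed(substream_seed(seed, k), sample.int(n))
  }, integer(n))
  Yp <- matrix(y[perms], n, n_perm)

  use_bg <- isTRUE(background)
  p_enter_bg <- max(p_enter, 0.001)
  empty_bg <- rep(TRUE, n_perm)
  if (use_bg) {
    Ms <- scale(cache$M)
    Ms[!is.finite(Ms)] <- 0
    Ys <- scale(Yp)
    r <- crossprod(Ms, Ys) / (n - 1)
    r2 <- pmin(r^2, 1 - 1e-15)
    tstat <- sqrt(r2 * (n - 2) / (1 - r2))
    empty_bg <- 2 * pt(-apply(tstat, 2, max), n - 2) >= p_enter_bg
  }
  max_lods <- numeric(n_perm)
  if (any(empty_bg)) {
    # fixed designs: precompute orthonormal bases once per pair
    pre <- vector("list", nrow(cache$pairs))
    for (k in seq_len(nrow(cache$pairs))) {
      i <- cache$pairs$i[k]; j <- cache$pairs$j[k]
      xi <- cache$C[, i]; xj <- cache$C[, j]
      if (sd(xi) < 1e-8 || sd(xj) < 1e-8 || abs(cor(xi, xj)) > 0.95) next
      Qr <- qr.Q(qr(cbind(1, xi, xj)))
      Qf <- qr.Q(qr(cbind(1, xi, xj, xi * xj)))
      pre[[k]] <- list(Qr = Qr, Qf = Qf)
    }
    Yb <- Yp[, empty_bg, drop = FALSE]
    yty <- colSums(Yb^2)
    best <- rep(0, ncol(Yb))
    for (k in seq_len(nrow(cache$pairs))) {
      if (is.null(pre[[k]])) next
      rssr <- yty - colSums(crossprod(pre[[k]]$Qr, Yb)^2)
      rssf <- yty - colSums(crossprod(pre[[k]]$Qf, Yb)^2)
      lods <- (n / 2) * log10(pmax(rssr, 1e-300) / pmax(rssf, 1e-300))
      best <- pmax(best, lods)
    }
    max_lods[empty_bg] <- best
  }
  for (k in which(!empty_bg)) {
    bg <- select_background(Yp[, k], cache$M, p_enter = p_enter_bg,
                            p_exit = 2 * p_enter_bg)
    prof <- pair_scan_core(Yp[, k], cache, bg, window_cM = window_cM)
    max_lods[k] <- max(prof$lod, na.rm = TRUE)
  }
  structure(list(threshold = unname(quantile(max_lods, 1 - alpha, type = 7)),
                 max_lods = max_lods, alpha = alpha, n_perm = n_perm),
            class = "ttc_perm_threshold")
}

#' Call digenic epistatic interactions from a pair scan
#'
#' Reports grid maxima above the threshold; neighbouring significant pairs
#' whose loci both lie within `merge_cM` of a stronger pair are merged into
#' it. Flanking typed markers are reported for both loci.
#'
#' @param pairscan A `ttc_pairscan` from [pair_scan()].
#' @param threshold Number or `ttc_perm_threshold`.
#' @param merge_cM Merge radius in cM (applies to both coordinates).
#' @return Tibble of hits: locus coordinates and flanking intervals, `lod`,
#'   `a_i`, `a_j`, `aa_ij`, `r2_pct`, `dataset`.
#' @export
call_epistasis <- function(pairscan, threshold, merge_cM = 20) {
  if (inherits(threshold, "ttc_perm_threshold")) threshold <- threshold$threshold
  map <- attr(pairscan, "map")
  ps <- pairscan[!pairscan$skipped & is.finite(pairscan$lod) &
                   pairscan$lod >= threshold & pairscan$lod > 0, ]
  flank <- function(chrom, pos) {
    mpos <- map$pos_cM[map$chrom == chrom]
    mn <- map$marker[map$chrom == chrom]
    li <- max(1L, findInterval(pos + 1e-9, mpos))
    ri <- if (mpos[li] >= pos - 1e-9) li else min(length(mpos), li + 1L)
    paste0(mn[li], "-", mn[ri])
  }
  kept <- ps[0, ]
  if (nrow(ps) > 0) {
    ps <- ps[order(-ps$lod, ps$chrom_i, ps$pos_i, ps$pos_j), ]
    for (k in seq_len(nrow(ps))) {
      near <- function(c1, p1, c2, p2) c1 == c2 & abs(p1 - p2) <= merge_cM
      if (nrow(kept) > 0 &&
          any((near(kept$chrom_i, kept$pos_i, ps$chrom_i[k], ps$pos_i[k]) &
                 near(kept$chrom_j, kept$pos_j, ps$chrom_j[k], ps$pos_j[k])) |
                (near(kept$chrom_i, kept$pos_i, ps$chrom_j[k], ps$pos_j[k]) &
                   near(kept$chrom_j, kept$pos_j, ps$chrom_i[k], ps$pos_i[k])))) {
        next
      }
      kept <- dplyr::bind_rows(kept, ps[k, ])
    }
  }
  out <- kept
  out$interval_i <- vapply(seq_len(nrow(out)), function(k) {
    flank(out$chrom_i[k], out$pos_i[k])
  }, character(1))
  out$interval_j <- vapply(seq_len(nrow(out)), function(k) {
    flank(out$chrom_j[k], out$pos_j[k])
  }, character(1))
  out$dataset <- rep(attr(pairscan, "dataset") %||% NA_character_, nrow(out))
  tibble::as_tibble(out)[, c("chrom_i", "pos_i", "interval_i", "chrom_j",
                             "pos_j", "interval_j", "lod", "a_i", "a_j",
                             "aa_ij", "r2_pct", "dataset")]
}
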