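# Conditional expected marker codes on a cM grid.
#
# Scans walk the genome in fixed cM steps, so genotype information between
# typed markers is summarised as the conditional expectation of the +-1 code
# given the nearest informative flanking markers, assuming a homozygous line
# genome that follows a Markov chain along the chromosome with Haldane
# recombination fractions (no interference).

marker_code_matrix <- function(geno) {
  bad <- setdiff(unique(as.vector(geno)), c("A", "B", NA))
  stop_if_not(length(bad) == 0,
              paste("line genotypes must be coded A/B; found:",
                    paste(bad, collapse = ", ")))
  X <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  X[geno == "A"] <- 1
  X[geno == "B"] <- -1
  X
}

#' Genome scan grid
#'
#' Positions every `walk_step` cM along each chromosome (chromosome ends
#' always included).
#'
#' @param map A `ttc_map`.
#' @param walk_step Step in cM.
#' @return Tibble `chrom`, `pos_cM`.
#' @export
scan_grid <- function(map, walk_step = 1) {
  map <- validate_map(map)
  stop_if_not(is_scalar_number(walk_step) && walk_step > 0,
              "`walk_step` must be > 0")
  map |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::reframe(pos_cM = {
      lo <- min(.data$pos_cM); hi <- max(.data$pos_cM)
      p <- seq(lo, hi, by = walk_step)
      if (hi - p[length(p)] > 1e-9) p <- c(p, hi)
      p
    })
}

# n x n_positions matrix of conditional expected codes. `positions` is a
# tibble (chrom, pos_cM); geno a character A/B/NA matrix aligned with map.
conditional_code_matrix <- function(geno, map, positions) {
  map <- validate_map(map)
  stop_if_not(all(map$marker %in% colnames(geno)),
              "genotype matrix must contain every map marker")
  X <- marker_code_matrix(geno[, map$marker, drop = FALSE])
  out <- matrix(0, nrow(geno), nrow(positions))
  for (cc in unique(positions$chrom)) {
    mi <- which(map$chrom == cc)
    stop_if_not(length(mi) > 0, paste("no markers on chromosome", cc),
                class = "ttcqtl_invalid_argument")
    mpos <- map$pos_cM[mi]
    sel <- which(positions$chrom == cc)
    gpos <- positions$pos_cM[sel]
    stop_if_not(all(gpos >= min(mpos) - 1e-9 & gpos <= max(mpos) + 1e-9),
                "scan position lies outside the chromosome span",
                class = "ttcqtl_invalid_argument")
    Xc <- X[, mi, drop = FALSE]
    for (i in seq_len(nrow(X))) {
      obs <- which(!is.na(Xc[i, ]))
      if (length(obs) == 0L) next  # fully missing: marginal code 0
      opos <- mpos[obs]
      ox <- Xc[i, obs]
      li <- findInterval(gpos, opos)
      hasL <- li >= 1L
      hasR <- li < length(opos)
      code <- numeric(length(gpos))
      b <- hasL & hasR
      if (any(b)) {
        xL <- ox[li[b]]; xR <- ox[li[b] + 1L]
        rL <- haldane_r(gpos[b] - opos[li[b]])
        rR <- haldane_r(opos[li[b] + 1L] - gpos[b])
        pLA <- ifelse(xL > 0, 1 - rL, rL)
        pRA <- ifelse(xR > 0, 1 - rR, rR)
        pA <- pLA * pRA
        pB <- (1 - pLA) * (1 - pRA)
        code[b] <- (pA - pB) / (pA + pB)
      }
      lo <- hasL & !hasR
      if (any(lo)) {
        r <- haldane_r(gpos[lo] - opos[li[lo]])
        code[lo] <- (1 - 2 * r) * ox[li[lo]]
      }
      ro <- !hasL & hasR
      if (any(ro)) {
        r <- haldane_r(opos[li[ro] + 1L] - gpos[ro])
        code[ro] <- (1 - 2 * r) * ox[li[ro] + 1L]
      }
      out[i, sel] <- code
    }
  }
  rownames(out) <- rownames(geno)
  out
}

#' Conditional expected genotype code at a genome position
#'
#' At a typed marker the code is +1 (`A`) or -1 (`B`); between markers it is
#' the conditional expectation `P(A | flanks) - P(B | flanks)` under Haldane
#' recombination for an idealized homozygous line; lines with missing flanks
#' fall back to the single informative flank or, with no information on the
#' chromosome, to the marginal value 0.
#'
#' @param geno Character matrix of line genotypes (`A`/`B`/`NA`).
#' @param map A `ttc_map`.
#' @param chrom Chromosome id.
#' @param pos_cM Position in cM (must lie within the chromosome span).
#' @return Numeric vector of expected codes in `[-1, 1]`, one per line.
#' @export
conditional_code <- function(geno, map, chrom, pos_cM) {
  as.vector(conditional_code_matrix(
    geno, map, tibble::tibble(chrom = chrom, pos_cM = pos_cM)
  ))
}
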