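# RIL genome simulation under the Haldane (no-interference) model.
#
# A genome is represented per chromosome as a pair of haplotype matrices
# (individuals x loci, entries 1 = parent-1 allele, 0 = parent-2 allele).
# Meiosis is a Markov chain along each chromosome: the transmitted haplotype
# switches between the two parental haplotypes with probability equal to the
# Haldane recombination fraction of the adjacent-marker interval.

# One gamete per row of (H1, H2); rfrac has length ncol - 1.
meiose <- function(H1, H2, rfrac) {
  n <- nrow(H1)
  m <- ncol(H1)
  start <- sample(c(0L, 1L), n, replace = TRUE)
  if (m == 1L) {
    par <- matrix(start, n, 1L)
  } else {
    sw <- matrix(runif(n * (m - 1L)) < rep(rfrac, each = n), n, m - 1L)
    cum <- matrix(0L, n, m)
    for (k in 2:m) cum[, k] <- cum[, k - 1L] + sw[, k - 1L]
    par <- (start + cum) %% 2L
  }
  G <- H1
  G[par == 1L] <- H2[par == 1L]
  G
}

# Simulate fully homozygous RIL haplotypes at arbitrary chromosome positions.
# positions: list (one numeric vector per chromosome) of locus positions in cM.
# Returns a list of n x m_c matrices of {1, 0} alleles, one per chromosome.
# Rounds of random intermating follow the F2; fixation doubles one final
# gamete per individual (idealized single-seed-descent to full homozygosity).
simulate_ril_haplotypes <- function(positions, n, intermating_rounds = 4) {
  n <- as.integer(n)
  rfracs <- lapply(positions, function(p) haldane_r(diff(p)))
  n_chrom <- length(positions)
  f1 <- lapply(positions, function(p) {
    list(H1 = matrix(1L, n, length(p)), H2 = matrix(0L, n, length(p)))
  })
  # F2: both gametes from F1 parents
  pop <- lapply(seq_len(n_chrom), function(cc) {
    list(H1 = meiose(f1[[cc]]$H1, f1[[cc]]$H2, rfracs[[cc]]),
         H2 = meiose(f1[[cc]]$H1, f1[[cc]]$H2, rfracs[[cc]]))
  })
  # random intermating; parent draws are shared across chromosomes
  for (round in seq_len(intermating_rounds)) {
    mom <- sample.int(n, n, replace = TRUE)
    dad <- sample.int(n, n, replace = TRUE)
    clash <- which(mom == dad)
    while (length(clash) > 0 && n > 1L) {
      dad[clash] <- sample.int(n, length(clash), replace = TRUE)
      clash <- clash[mom[clash] == dad[clash]]
    }
    pop <- lapply(seq_len(n_chrom), function(cc) {
      list(H1 = meiose(pop[[cc]]$H1[mom, , drop = FALSE],
                       pop[[cc]]$H2[mom, , drop = FALSE], rfracs[[cc]]),
           H2 = meiose(pop[[cc]]$H1[dad, , drop = FALSE],
                       pop[[cc]]$H2[dad, , drop = FALSE], rfracs[[cc]]))
    })
  }
  # fixation: one gamete per individual, doubled
  lapply(seq_len(n_chrom), function(cc) {
    meiose(pop[[cc]]$H1, pop[[cc]]$H2, rfracs[[cc]])
  })
}

# One F1 gamete per requested row, at the given positions (used for the F1
# tester in TC(F) families). Returns n x m matrix of {1, 0}.
f1_gametes <- function(positions, n) {
  m <- length(positions)
  meiose(matrix(1L, n, m), matrix(0L, n, m), haldane_r(diff(positions)))
}

#' Simulate recombinant inbred line genotypes
#'
#' Draws fully homozygous RIL genomes from a biparental cross under the
#' Haldane (no crossover interference) model: an F2 generation, then
#' `intermating_rounds` rounds of random mating (emulating intermated RIL
#' populations such as IBM), then idealized fixation in which each final
#' gamete is doubled. Missing genotypes can be injected completely at random.
#'
#' @param map A `ttc_map` tibble.
#' @param n_ril Number of lines (>= 2).
#' @param intermating_rounds Rounds of random intermating after the F2.
#' @param seed Optional integer seed for reproducibility.
#' @param missing_rate Proportion of genotype calls set to missing (`NA`).
#' @return A character matrix (`n_ril` x markers) with entries `"A"`
#'   (parent-1 homozygote), `"B"` (parent-2 homozygote) or `NA`.
#' @export
simulate_rils <- function(map, n_ril, intermating_rounds = 4, seed = NULL,
                          missing_rate = 0) {
  map <- validate_map(map)
  stop_if_not(is_scalar_number(n_ril) && n_ril >= 2, "`n_ril` must be >= 2")
  stop_if_not(nrow(map) > 0, "map is empty")
  positions <- split(map$pos_cM, map$chrom)
  markers <- split(map$marker, map$chrom)
  with_seed(seed, {
    hap <- simulate_ril_haplotypes(positions, n_ril, intermating_rounds)
    G <- do.call(cbind, hap)
    colnames(G) <- unlist(markers, use.names = FALSE)
    geno <- matrix(ifelse(G == 1L, "A", "B"), nrow(G), ncol(G),
                   dimnames = list(sprintf("RIL%03d", seq_len(n_ril)),
                                   colnames(G)))
    if (missing_rate > 0) {
      drop <- runif(length(geno)) < missing_rate
      geno[drop] <- NA_character_
    }
    geno
  })
}

#' Derive testcross hybrid genotype codes
#'
#' Given homozygous line genotypes, returns the marker codes of their
#' testcross progenies: against tester `"P1"` (the parent-1 inbred) `A`
#' stays `A` and `B` becomes `H`; against `"P2"` the mirror image; against
#' the F1 tester every marker is `"S"` (segregating within the family, so a
#' family-level code does not exist and progenies are sampled individually
#' during phenotype simulation).
#'
#' @param ril_geno Character matrix of `"A"`/`"B"`/`NA` line genotypes.
#' @param tester One of `"P1"`, `"P2"`, `"F1"`.
#' @return Character matrix of hybrid codes in `A`, `H`, `B`, `S`, `NA`.
#' @export
make_testcross_genotypes <- function(ril_geno, tester = c("P1", "P2", "F1")) {
  tester <- match.arg(tester)
  if (is.vector(ril_geno)) ril_geno <- matrix(ril_geno, nrow = 1L)
  bad <- setdiff(unique(as.vector(ril_geno)), c("A", "B", NA))
  stop_if_not(length(bad) == 0,
              paste0("RIL genotypes must be homozygous (A/B); found: ",
                     paste(bad, collapse = ", ")),
              class = "ttcqtl_invalid_state")
  out <- ril_geno
  if (tester == "P1") {
    out[ril_geno == "B"] <- "H"
  } else if (tester == "P2") {
    out[ril_geno == "A"] <- "H"
  } else {
    out[!is.na(ril_geno)] <- "S"
  }
  out
}
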