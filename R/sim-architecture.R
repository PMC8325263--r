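#' Define a simulated QTL architecture
#'
#' A trait architecture is a baseline `mu`, a set of loci with additive and
#' dominance effects, and optional digenic epistatic pairs. The additive
#' effect `a` is half the difference between the two homozygotes (positive
#' `a` means the parent-1 allele increases the trait); `d` is the deviation
#' of the heterozygote from the homozygote midpoint. Pairs carry one of the
#' four digenic interaction kinds: `aa` (additive x additive), `ad`, `da`,
#' and `dd` (dominance x dominance).
#'
#' @param loci Tibble/data frame with columns `chrom`, `pos_cM`, `a`, `d`.
#' @param pairs Optional tibble with columns `locus_i`, `locus_j` (row
#'   indices into `loci`), `kind` (one of `"aa"`, `"ad"`, `"da"`, `"dd"`)
#'   and `coefficient` (trait units).
#' @param mu Baseline genotypic value (trait units).
#' @param map Optional `ttc_map`; when supplied, locus positions are checked
#'   to lie within the chromosome spans.
#' @return An object of class `qtl_architecture`.
#' @examples
#' qtl_architecture(loci = data.frame(chrom = 1, pos_cM = 50, a = 1, d = 0.5))
#' @export
qtl_architecture <- function(loci = NULL, pairs = NULL, mu = 0, map = NULL) {
  loci <- if (is.null(loci)) {
    tibble::tibble(chrom = integer(), pos_cM = numeric(),
                   a = numeric(), d = numeric())
  } else {
    tibble::as_tibble(loci)
  }
  if (!"d" %in% names(loci)) loci$d <- 0
  if (!"a" %in% names(loci)) loci$a <- 0
  stop_if_not(all(c("chrom", "pos_cM", "a", "d") %in% names(loci)),
              "loci need columns chrom, pos_cM, a, d")
  stop_if_not(all(is.finite(loci$a)) && all(is.finite(loci$d)),
              "locus effects must be finite")
  pairs <- if (is.null(pairs)) {
    tibble::tibble(locus_i = integer(), locus_j = integer(),
                   kind = character(), coefficient = numeric())
  } else {
    tibble::as_tibble(pairs)
  }
  stop_if_not(all(c("locus_i", "locus_j", "kind", "coefficient") %in% names(pairs)),
              "pairs need columns locus_i, locus_j, kind, coefficient")
  stop_if_not(all(pairs$kind %in% c("aa", "ad", "da", "dd")),
              "pair kind must be one of aa, ad, da, dd")
  stop_if_not(all(pairs$locus_i %in% seq_len(nrow(loci))) &&
                all(pairs$locus_j %in% seq_len(nrow(loci))),
              "pair members must reference declared loci")
  stop_if_not(all(pairs$locus_i != pairs$locus_j) || nrow(pairs) == 0,
              "a pair must involve two distinct loci")
  stop_if_not(all(is.finite(pairs$coefficient)), "pair coefficients must be finite")
  stop_if_not(is_scalar_number(mu), "`mu` must be a finite scalar")
  if (!is.null(map)) {
    map <- validate_map(map)
    span <- map |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(lo = min(.data$pos_cM), hi = max(.data$pos_cM))
    chk <- dplyr::left_join(loci, span, by = "chrom")
    stop_if_not(all(!is.na(chk$lo)) &&
                  all(chk$pos_cM >= chk$lo - 1e-9 & chk$pos_cM <= chk$hi + 1e-9),
                "locus positions must lie within the map span")
  }
  structure(list(loci = loci, pairs = pairs, mu = mu),
            class = "qtl_architecture")
}

#' @export
print.qtl_architecture <- function(x, ...) {
  cat("<qtl_architecture> mu =", x$mu, "|", nrow(x$loci), "loci,",
      nrow(x$pairs), "epistatic pairs\n")
  invisible(x)
}

#' Genotypic value of resolved plant genotypes
#'
#' Evaluates the two-locus genetic model
#' `mu + sum(a_i x_i + d_i z_i) + sum(coef * w_ij)` where `x` is +1 for the
#' parent-1 homozygote, 0 for the heterozygote, -1 for the parent-2
#' homozygote, `z = 1` for heterozygotes, and `w` is `x_i x_j` (aa),
#' `x_i z_j` (ad), `z_i x_j` (da) or `z_i z_j` (dd).
#'
#' @param X Numeric vector (one plant) or matrix (plants x loci) of codes in
#'   `{-1, 0, +1}`, columns ordered as `arch$loci` rows. Every truth locus
#'   must be resolved (no `NA`).
#' @param arch A [qtl_architecture()].
#' @return Numeric vector of genotypic values (one per plant).
#' @export
genotypic_value <- function(X, arch) {
  stop_if_not(inherits(arch, "qtl_architecture"), "`arch` must be a qtl_architecture")
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  stop_if_not(ncol(X) == nrow(arch$loci),
              "genotype must be resolved at every truth locus (column count mismatch)",
              class = "ttcqtl_invalid_state")
  stop_if_not(!anyNA(X),
              "genotype must be resolved at every truth locus (missing code)",
              class = "ttcqtl_invalid_state")
  stop_if_not(all(X %in% c(-1, 0, 1)),
              "genotype codes must be -1, 0 or +1 at every truth locus",
              class = "ttcqtl_invalid_state")
  Z <- (X == 0) + 0
  val <- rep(arch$mu, nrow(X))
  if (nrow(arch$loci) > 0) {
    val <- val + as.vector(X %*% arch$loci$a + Z %*% arch$loci$d)
  }
  if (nrow(arch$pairs) > 0) {
    for (k in seq_len(nrow(arch$pairs))) {
      i <- arch$pairs$locus_i[k]
      j <- arch$pairs$locus_j[k]
      w <- switch(arch$pairs$kind[k],
                  aa = X[, i] * X[, j],
                  ad = X[, i] * Z[, j],
                  da = Z[, i] * X[, j],
                  dd = Z[, i] * Z[, j])
      val <- val + arch$pairs$coefficient[k] * w
    }
  }
  val
}
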