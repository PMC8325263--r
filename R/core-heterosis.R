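#' Mid-parent heterosis
#'
#' `MPH (%) = (F1 - MP) / MP * 100`, where MP is the mean of the two
#' parents. The traits this design targets are strictly positive, so a
#' non-positive mid-parent value is an error rather than a silent NaN.
#'
#' @param f1,p1,p2 Numeric vectors (recycled to common length) of F1 and
#'   parental values.
#' @param trait Optional character vector of trait labels.
#' @return Tibble with `trait` (if given), `f1_value`, `mp_value`,
#'   `mph_percent`.
#' @examples
#' mph(2.5, 1, 1) # 150%
#' @export
mph <- function(f1, p1, p2, trait = NULL) {
  n <- max(length(f1), length(p1), length(p2))
  f1 <- rep_len(f1, n); p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  mp <- (p1 + p2) / 2
  stop_if_not(all(mp > 0), "mid-parent value must be > 0 for relative heterosis",
              class = "ttcqtl_domain_error")
  out <- tibble::tibble(f1_value = f1, mp_value = mp,
                        mph_percent = (f1 - mp) / mp * 100)
  if (!is.null(trait)) out <- dplyr::bind_cols(tibble::tibble(trait = rep_len(trait, n)), out)
  out
}

#' Mid-parent heterosis from a BLUE table
#'
#' Convenience wrapper extracting the `P1`, `P2` and `F1` population BLUEs
#' per trait and applying [mph()].
#'
#' @param blues Output of [compute_blues()].
#' @return Tibble with one row per trait.
#' @export
mph_from_blues <- function(blues) {
  wide <- blues |>
    dplyr::filter(.data$population %in% c("P1", "P2", "F1")) |>
    dplyr::select("population", "trait", "blue") |>
    tidyr::pivot_wider(names_from = "population", values_from = "blue")
  stop_if_not(all(c("P1", "P2", "F1") %in% names(wide)),
              "BLUE table must contain populations P1, P2 and F1")
  mph(wide$F1, wide$P1, wide$P2, trait = wide$trait)
}

#' Marker heterozygosity of hybrid genotypes
#'
#' Proportion of heterozygous (`H`) calls among non-missing markers.
#'
#' @param geno A character vector (one individual) or matrix (individuals x
#'   markers) with codes in `A`, `H`, `B`, `NA`.
#' @return For a vector, a single proportion (error if all calls are
#'   missing); for a matrix, a tibble `id`, `heterozygosity` (NA rows with a
#'   warning when an individual has no non-missing call).
#' @export
heterozygosity <- function(geno) {
  single <- is.vector(geno) && is.null(dim(geno))
  if (single) geno <- matrix(geno, nrow = 1L)
  bad <- setdiff(unique(as.vector(geno)), c("A", "H", "B", "S", NA))
  stop_if_not(length(bad) == 0,
              paste("invalid genotype codes:", paste(bad, collapse = ", ")))
  nh <- rowSums(geno == "H", na.rm = TRUE)
  nn <- rowSums(!is.na(geno))
  het <- ifelse(nn > 0, nh / nn, NA_real_)
  if (single) {
    stop_if_not(nn[1] > 0, "heterozygosity undefined: all markers missing",
                class = "ttcqtl_undefined_value")
    return(unname(het[1]))
  }
  if (anyNA(het)) rlang::warn("individuals with all markers missing: heterozygosity NA")
  tibble::tibble(id = rownames(geno) %||% as.character(seq_len(nrow(geno))),
                 heterozygosity = unname(het))
}
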