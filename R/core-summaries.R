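#' Pairwise Pearson correlations between traits
#'
#' Computes pairwise-complete Pearson correlations (with two-sided p-values)
#' between traits from a long table of per-individual values, e.g. BLUEs or
#' per-trait heterosis.
#'
#' @param tbl Long tibble with columns `id`, `trait` and a value column.
#' @param value Name of the value column (default `"blue"`, falling back to
#'   `"value"` or `"mph_percent"` when present).
#' @return Tibble `trait1`, `trait2`, `n`, `r`, `p_value` for every
#'   unordered trait pair (zero-variance pairs get `NA` with a warning).
#' @export
trait_correlations <- function(tbl, value = NULL) {
  value <- value %||% intersect(c("blue", "value", "mph_percent"), names(tbl))[1]
  stop_if_not(!is.na(value) && value %in% names(tbl),
              "could not find a value column")
  wide <- tbl |>
    dplyr::select("id", "trait", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "trait", values_from = dplyr::all_of(value))
  traits <- setdiff(names(wide), "id")
  stop_if_not(length(traits) >= 2, "need at least two traits")
  combs <- utils::combn(traits, 2)
  res <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
    x <- wide[[combs[1, k]]]
    y <- wide[[combs[2, k]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    stop_if_not(n >= 3, "need at least 3 paired observations per trait pair")
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      rlang::warn(paste("zero variance:", combs[1, k], "vs", combs[2, k]))
      return(tibble::tibble(trait1 = combs[1, k], trait2 = combs[2, k],
                            n = n, r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(trait1 = combs[1, k], trait2 = combs[2, k], n = n,
                   r = unname(ct$estimate), p_value = ct$p.value)
  })
  res
}

#' One-way ANOVA of population differences
#'
#' Tests, per trait, for differences among populations (one-way fixed-effects
#' ANOVA on per-genotype values, typically BLUEs).
#'
#' @param tbl Tibble with columns `population`, `trait` and a value column.
#' @param populations Populations to include (default: the testcross
#'   populations `TCB`, `TCM`, `TCF`).
#' @param value Value column name (default `"blue"`, falling back to `"value"`).
#' @return Tibble `trait`, `df_between`, `df_within`, `f_statistic`, `p_value`.
#' @export
population_anova <- function(tbl, populations = c("TCB", "TCM", "TCF"),
                             value = NULL) {
  value <- value %||% intersect(c("blue", "value"), names(tbl))[1]
  stop_if_not(!is.na(value) && value %in% names(tbl), "could not find a value column")
  tbl <- dplyr::filter(tbl, .data$population %in% populations,
                       is.finite(.data[[value]]))
  keep <- tbl |>
    dplyr::count(.data$trait, .data$population) |>
    dplyr::filter(.data$n >= 2)
  dropped <- dplyr::anti_join(dplyr::distinct(tbl, .data$trait, .data$population),
                              keep, by = c("trait", "population"))
  if (nrow(dropped) > 0) {
    rlang::warn("populations with < 2 members excluded from ANOVA")
    tbl <- dplyr::semi_join(tbl, keep, by = c("trait", "population"))
  }
  tbl |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(df, key) {
      stop_if_not(dplyr::n_distinct(df$population) >= 2,
                  "need at least two populations")
      y <- df[[value]]
      g <- factor(df$population)
      gm <- tapply(y, g, mean)
      ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
      ssw <- sum((y - gm[g])^2)
      dfb <- nlevels(g) - 1L
      dfw <- length(y) - nlevels(g)
      if (ssw <= 1e-12 * max(1, mean(y)^2) && ssb <= 1e-12 * max(1, mean(y)^2)) {
        # degenerate 0/0: identical values everywhere
        return(tibble::tibble(df_between = dfb, df_within = dfw,
                              f_statistic = NA_real_, p_value = 1))
      }
      f <- (ssb / dfb) / (ssw / dfw)
      tibble::tibble(df_between = dfb, df_within = dfw, f_statistic = f,
                     p_value = pf(f, dfb, dfw, lower.tail = FALSE))
    }) |>
    dplyr::ungroup()
}
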