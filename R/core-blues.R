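#' Best linear unbiased estimates of genotype means across blocks
#'
#' Fits, per trait, the two-way fixed-effects model
#' `value = genotype + block` (no interaction) to the plot table and returns
#' each genotype's marginal mean, i.e. its predicted value averaged over all
#' blocks. With balanced complete data this equals the plain mean across
#' blocks; with missing plots it is the least-squares (normal-equation)
#' solution. Genotypes are the `id` x `population` combinations so the same
#' line can appear both per se and in testcross populations.
#'
#' @param plot_tbl Tibble with columns `id`, `population`, `block`, `trait`,
#'   `value` (e.g. `sim$phenotypes` from [sim_ttc()]).
#' @param traits Optional character vector restricting the traits used.
#' @return A tibble with columns `id`, `population`, `trait`, `blue`,
#'   `n_blocks`.
#' @export
compute_blues <- function(plot_tbl, traits = NULL) {
  need <- c("id", "population", "block", "trait", "value")
  stop_if_not(all(need %in% names(plot_tbl)),
              paste("plot table needs columns", paste(need, collapse = ", ")))
  if (!is.null(traits)) plot_tbl <- dplyr::filter(plot_tbl, .data$trait %in% traits)
  plot_tbl <- dplyr::filter(plot_tbl, is.finite(.data$value))
  stop_if_not(nrow(plot_tbl) > 0, "no phenotype records to aggregate")

  out <- plot_tbl |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(df, key) {
      df$geno <- interaction(df$id, df$population, drop = TRUE, sep = "\r")
      df$blockf <- factor(df$block)
      nb <- nlevels(df$blockf)
      counts <- df |>
        dplyr::group_by(.data$geno) |>
        dplyr::summarise(n_blocks = dplyr::n_distinct(.data$block),
                         .groups = "drop")
      if (nb == 1L) {
        est <- df |>
          dplyr::group_by(geno = as.character(.data$geno)) |>
          dplyr::summarise(blue = mean(.data$value), .groups = "drop")
      } else if (nlevels(df$geno) == 1L) {
        # single genotype: the marginal mean is the plain mean over blocks
        est <- tibble::tibble(geno = levels(df$geno), blue = mean(df$value))
      } else {
        fit <- lm(value ~ 0 + geno + blockf, data = df,
                  contrasts = list(blockf = "contr.treatment"))
        cf <- coef(fit)
        gcoef <- cf[paste0("geno", levels(df$geno))]
        bcoef <- cf[paste0("blockf", levels(df$blockf)[-1])]
        bcoef[is.na(bcoef)] <- 0
        bmean <- mean(c(0, bcoef))
        est <- tibble::tibble(geno = levels(df$geno),
                              blue = unname(gcoef) + bmean)
      }
      est <- dplyr::left_join(est, counts,
                              by = c(geno = "geno")) |>
        tidyr::separate_wider_delim("geno", delim = "\r",
                                    names = c("id", "population"))
      dropped <- est$id[!is.finite(est$blue)]
      if (length(dropped) > 0) {
        rlang::warn(paste("genotypes without estimable BLUE dropped:",
                          paste(dropped, collapse = ", ")))
        est <- est[is.finite(est$blue), ]
      }
      est
    }) |>
    dplyr::ungroup() |>
    dplyr::select("id", "population", "trait", "blue", "n_blocks")
  out$blue <- unname(out$blue)
  names(out$blue) <- NULL
  out
}
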