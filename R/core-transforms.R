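#' Assemble per-line testcross triplets H1, H2, H3
#'
#' Extracts, per base line and trait, the BLUEs of its three testcross
#' families: `H1` against tester 1 (population `TCB`), `H2` against tester 2
#' (`TCM`) and `H3` against the F1 tester (`TCF`). Lines missing any member
#' are excluded (with a message).
#'
#' @param blues Output of [compute_blues()] (or any tibble with `id`,
#'   `population`, `trait`, `blue`).
#' @return Tibble `id`, `trait`, `H1`, `H2`, `H3`.
#' @export
ttc_triplets <- function(blues) {
  wide <- blues |>
    dplyr::filter(.data$population %in% c("TCB", "TCM", "TCF")) |>
    dplyr::select("id", "trait", "population", "blue") |>
    tidyr::pivot_wider(names_from = "population", values_from = "blue") |>
    dplyr::rename(H1 = "TCB", H2 = "TCM", H3 = "TCF")
  stop_if_not(all(c("H1", "H2", "H3") %in% names(wide)),
              "BLUE table must contain populations TCB, TCM and TCF")
  complete <- stats::complete.cases(wide[, c("H1", "H2", "H3")])
  if (any(!complete)) {
    rlang::inform(paste(sum(!complete),
                        "line(s) missing a testcross member were excluded"))
  }
  wide[complete, ]
}

#' The three triple-testcross linear transformations
#'
#' Per line `i`: `Z1 = (H1 + H2) / 2` (augmented additive signal),
#' `Z2 = H1 - H2` (augmented dominance signal) and `Z3 = H1 + H2 - 2 H3`
#' (epistatic signal; identically zero in expectation without epistasis).
#'
#' @param triplets Output of [ttc_triplets()] (columns `id`, `H1`, `H2`,
#'   `H3`, optionally `trait`).
#' @return The input tibble with `Z1`, `Z2`, `Z3` columns appended.
#' @export
ttc_transforms <- function(triplets) {
  stop_if_not(all(c("id", "H1", "H2", "H3") %in% names(triplets)),
              "triplets need columns id, H1, H2, H3")
  stop_if_not(!anyNA(triplets[, c("H1", "H2", "H3")]),
              "triplets must be complete; drop incomplete lines first")
  key <- if ("trait" %in% names(triplets)) triplets[, c("id", "trait")] else triplets["id"]
  stop_if_not(!anyDuplicated(key), "duplicated line ids in triplets",
              class = "ttcqtl_invalid_input")
  dplyr::mutate(triplets,
                Z1 = (.data$H1 + .data$H2) / 2,
                Z2 = .data$H1 - .data$H2,
                Z3 = .data$H1 + .data$H2 - 2 * .data$H3)
}
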