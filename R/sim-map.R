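#' Build an evenly spaced genetic map
#'
#' Constructs a marker map with `n_chrom` chromosomes, each carrying
#' `markers_per_chrom` markers evenly spaced from 0 to `chrom_length_cM`.
#' The default dimensions emulate a maize intermated-RIL linkage map with
#' roughly 1600 markers over ~6900 cM (mean adjacent interval ~4.3 cM).
#'
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome (>= 2 unless the map is a
#'   single-marker toy; positions are deterministic given the arguments).
#' @param chrom_length_cM Chromosome length in centimorgans.
#' @return A tibble of class `ttc_map` with columns `marker`, `chrom`
#'   (integer), `pos_cM`.
#' @examples
#' build_map(2, 3, 100)
#' @export
build_map <- function(n_chrom = 10, markers_per_chrom = 163,
                      chrom_length_cM = 694) {
  stop_if_not(is_scalar_number(n_chrom) && n_chrom >= 1,
              "`n_chrom` must be a positive number")
  stop_if_not(is_scalar_number(markers_per_chrom) && markers_per_chrom >= 1,
              "`markers_per_chrom` must be a positive number")
  stop_if_not(is_scalar_number(chrom_length_cM) && chrom_length_cM > 0,
              "`chrom_length_cM` must be > 0")
  n_chrom <- as.integer(n_chrom)
  m <- as.integer(markers_per_chrom)
  pos <- if (m == 1L) 0 else seq(0, chrom_length_cM, length.out = m)
  map <- tibble::tibble(
    chrom = rep(seq_len(n_chrom), each = m),
    pos_cM = rep(pos, times = n_chrom)
  )
  map$marker <- sprintf("c%dm%03d", map$chrom, rep(seq_len(m), times = n_chrom))
  map <- map[, c("marker", "chrom", "pos_cM")]
  new_ttc_map(map)
}

new_ttc_map <- function(map) {
  class(map) <- unique(c("ttc_map", class(tibble::as_tibble(map))))
  map
}

#' Validate a genetic map
#'
#' Checks the `ttc_map` contract: globally unique marker names, at least one
#' marker per chromosome, and positions strictly increasing within each
#' chromosome after collapsing ties closer than `tol`.
#'
#' @param map A tibble with columns `marker`, `chrom`, `pos_cM`.
#' @param tol Deduplication tolerance in cM.
#' @return The map (invisibly), ordered by chromosome and position.
#' @export
validate_map <- function(map, tol = 1e-9) {
  stop_if_not(all(c("marker", "chrom", "pos_cM") %in% names(map)),
              "map must have columns marker, chrom, pos_cM")
  stop_if_not(!anyDuplicated(map$marker), "marker names must be globally unique")
  stop_if_not(all(is.finite(map$pos_cM)), "marker positions must be finite")
  map <- dplyr::arrange(map, .data$chrom, .data$pos_cM)
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos_cM) > tol) || dplyr::n() == 1L) |>
    dplyr::filter(!.data$ok)
  stop_if_not(nrow(bad) == 0,
              "marker positions must be strictly increasing within chromosomes")
  invisible(new_ttc_map(map))
}

#' Summarise a genetic map
#'
#' Total map length, marker counts and mean adjacent-marker intervals, per
#' chromosome and overall. The overall mean interval is total length divided
#' by (markers - chromosomes), i.e. the mean over all adjacent intervals.
#'
#' @param map A `ttc_map` tibble.
#' @return A list with `overall` (one-row tibble: `n_chrom`, `n_markers`,
#'   `total_cM`, `mean_interval_cM`) and `by_chromosome` (per-chromosome
#'   tibble with `chrom`, `n_markers`, `length_cM`, `mean_interval_cM`).
#' @export
map_summary <- function(map) {
  map <- validate_map(map)
  by_chrom <- map |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      length_cM = max(.data$pos_cM) - min(.data$pos_cM),
      mean_interval_cM = ifelse(dplyr::n() > 1L,
                                .data$length_cM[1] / (dplyr::n() - 1L), NA_real_),
      .groups = "drop"
    )
  n_markers <- nrow(map)
  n_chrom <- nrow(by_chrom)
  total <- sum(by_chrom$length_cM)
  denom <- n_markers - n_chrom
  if (denom <= 0) {
    rlang::warn("map has no adjacent-marker intervals; mean interval undefined")
    mean_int <- NA_real_
  } else {
    mean_int <- total / denom
  }
  list(
    overall = tibble::tibble(n_chrom = n_chrom, n_markers = n_markers,
                             total_cM = total, mean_interval_cM = mean_int),
    by_chromosome = by_chrom
  )
}
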