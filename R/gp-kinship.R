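#' Encode marker genotypes numerically and impute missing values
#'
#' Maps `A` to +1, `B` to -1 and `H` to 0, then replaces missing values by
#' the marker (column) mean of the observed codes. Columns with no observed
#' genotype are dropped with a warning; zero-variance (monomorphic) columns
#' are flagged.
#'
#' @param geno Character matrix with codes in `A`, `B`, `H`, `NA`.
#' @param allow_het Permit `H` codes (set `FALSE` for inbred line panels,
#'   where a heterozygous call is an error).
#' @return List: `M` (numeric matrix, no missing values), `imputed`
#'   (count), `zero_variance` (marker names), `dropped` (all-missing
#'   markers).
#' @export
encode_and_impute <- function(geno, allow_het = TRUE) {
  bad <- setdiff(unique(as.vector(geno)), c("A", "B", "H", NA))
  stop_if_not(length(bad) == 0,
              paste("invalid genotype codes:", paste(bad, collapse = ", ")))
  if (!allow_het) {
    stop_if_not(!any(geno == "H", na.rm = TRUE),
                "heterozygous calls are not allowed for inbred lines")
  }
  M <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  M[geno == "A"] <- 1
  M[geno == "B"] <- -1
  M[geno == "H"] <- 0
  all_missing <- colSums(!is.na(M)) == 0
  if (any(all_missing)) {
    rlang::warn(paste(sum(all_missing), "marker(s) with no observed genotype dropped"))
    M <- M[, !all_missing, drop = FALSE]
  }
  n_imp <- sum(is.na(M))
  M <- impute_marker_codes(M)
  v <- colMeans(M^2) - colMeans(M)^2
  list(M = M, imputed = n_imp,
       zero_variance = colnames(M)[v <= 1e-12],
       dropped = colnames(geno)[all_missing])
}

#' Build GCA/SCA genomic relationship matrices
#'
#' Each marker matrix column is centered and standardized to unit variance
#' (population SD, divisor `n`); zero-variance columns are dropped and the
#' marker count `N` decremented accordingly. The maternal and paternal
#' relationship matrices are `G = W W' / N`; the SCA kernel `G_S` is the
#' elementwise (Hadamard) product of the maternal and paternal relationship
#' matrices expanded to the hybrid level through the parent map.
#'
#' @param lines_M Encoded maternal-line marker matrix (rows named by line).
#' @param testers_M Encoded tester marker matrix (rows named by tester;
#'   with only two testers `G_P` is the degenerate 2 x 2 case, accepted
#'   with a warning).
#' @param hybrid_map Tibble with columns `hybrid_id`, `maternal`,
#'   `paternal` mapping each hybrid to its parents.
#' @return Object of class `ttc_kinship`: `G_M`, `G_P` (parent level),
#'   `K_M`, `K_P`, `G_S` (hybrid level), `N` (marker counts used),
#'   `hybrid_map`.
#' @export
build_kinships <- function(lines_M, testers_M, hybrid_map) {
  stop_if_not(nrow(lines_M) >= 2, "need at least 2 maternal lines")
  stop_if_not(all(c("hybrid_id", "maternal", "paternal") %in% names(hybrid_map)),
              "hybrid_map needs columns hybrid_id, maternal, paternal")
  stop_if_not(all(hybrid_map$maternal %in% rownames(lines_M)),
              "every maternal parent must be in `lines_M`")
  stop_if_not(all(hybrid_map$paternal %in% rownames(testers_M)),
              "every paternal parent must be in `testers_M`")
  if (nrow(testers_M) < 3) {
    rlang::warn("fewer than 3 testers: paternal relationship matrix is degenerate")
  }
  std <- function(M) {
    mu <- colMeans(M)
    sdv <- sqrt(colMeans(M^2) - mu^2)  # population SD (divisor n)
    keep <- sdv > 1e-12
    W <- sweep(sweep(M[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
    W
  }
  W_M <- std(lines_M)
  W_P <- std(testers_M)
  stop_if_not(ncol(W_M) >= 1, "no polymorphic markers among maternal lines")
  G_M <- tcrossprod(W_M) / ncol(W_M)
  G_P <- if (ncol(W_P) >= 1) tcrossprod(W_P) / ncol(W_P) else
    diag(nrow(testers_M))
  dimnames(G_M) <- list(rownames(lines_M), rownames(lines_M))
  dimnames(G_P) <- list(rownames(testers_M), rownames(testers_M))
  mi <- match(hybrid_map$maternal, rownames(G_M))
  pi <- match(hybrid_map$paternal, rownames(G_P))
  K_M <- G_M[mi, mi, drop = FALSE]
  K_P <- G_P[pi, pi, drop = FALSE]
  G_S <- K_M * K_P
  dimnames(K_M) <- dimnames(K_P) <- dimnames(G_S) <-
    list(hybrid_map$hybrid_id, hybrid_map$hybrid_id)
  structure(list(G_M = G_M, G_P = G_P, K_M = K_M, K_P = K_P, G_S = G_S,
                 N = c(M = ncol(W_M), P = ncol(W_P)),
                 hybrid_map = hybrid_map),
            class = "ttc_kinship")
}

#' Assemble genomic-prediction data from a simulated TTC dataset
#'
#' Extracts the pieces the GCA/SCA GBLUP machinery needs from a [sim_ttc()]
#' object: the maternal line genotypes, the two inbred tester genotypes
#' (parent 1 all `A`, parent 2 all `B`), the hybrid-parent map for the
#' TC(B) and TC(M) populations, the per-hybrid BLUEs and the plot-level
#' records.
#'
#' @param sim A `ttc_sim` object.
#' @param traits Traits to keep (default all).
#' @return Object of class `ttc_gp_data`: `lines` and `testers` (character
#'   genotype matrices), `hybrid_map`, `blues` (tibble `hybrid_id`, `trait`,
#'   `value`), `plots` (tibble `hybrid_id`, `block`, `trait`, `value`).
#' @export
ttc_gp_data <- function(sim, traits = NULL) {
  stop_if_not(inherits(sim, "ttc_sim"), "`sim` must be a ttc_sim")
  testers <- rbind(
    P1 = rep("A", ncol(sim$ril_geno)),
    P2 = rep("B", ncol(sim$ril_geno))
  )
  colnames(testers) <- colnames(sim$ril_geno)
  ril_ids <- rownames(sim$ril_geno)
  hybrid_map <- tibble::tibble(
    hybrid_id = c(paste0("TCB:", ril_ids), paste0("TCM:", ril_ids)),
    maternal = c(ril_ids, ril_ids),
    paternal = rep(c("P1", "P2"), each = length(ril_ids))
  )
  ph <- dplyr::filter(sim$phenotypes, .data$population %in% c("TCB", "TCM"))
  if (!is.null(traits)) ph <- dplyr::filter(ph, .data$trait %in% traits)
  ph$hybrid_id <- paste0(ph$population, ":", ph$id)
  blues <- compute_blues(ph) |>
    dplyr::mutate(hybrid_id = paste0(.data$population, ":", .data$id)) |>
    dplyr::select("hybrid_id", "trait", value = "blue")
  structure(list(lines = sim$ril_geno, testers = testers,
                 hybrid_map = hybrid_map, blues = blues,
                 plots = ph[, c("hybrid_id", "block", "trait", "value")]),
            class = "ttc_gp_data")
}

#' Default kinships for a `ttc_gp_data` object
#'
#' Encodes and imputes the line and tester genotypes (optionally restricted
#' to a marker subset) and builds the GCA/SCA kernels.
#'
#' @param data A [ttc_gp_data()] object.
#' @param markers Optional character vector of marker names to use.
#' @return A `ttc_kinship`.
#' @export
gp_kinships <- function(data, markers = NULL) {
  lines <- data$lines
  testers <- data$testers
  if (!is.null(markers)) {
    stop_if_not(length(markers) >= 1, "marker subset is empty")
    stop_if_not(all(markers %in% colnames(lines)), "unknown markers in subset")
    lines <- lines[, markers, drop = FALSE]
    testers <- testers[, markers, drop = FALSE]
  }
  build_kinships(encode_and_impute(lines, allow_het = FALSE)$M,
                 encode_and_impute(testers, allow_het = FALSE)$M,
                 data$hybrid_map)
}
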