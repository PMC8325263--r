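# Plain-text dataset exchange: RFC-4180 CSV via readr, truth as JSON.
# Genotype cells use the code alphabet {A, B, H, -} with "-" for missing.

#' Write a simulated TTC dataset to CSV/JSON files
#'
#' Writes `map.csv` (`marker`, `chrom`, `pos_cM`), `genotypes.csv` (first
#' column `id`, one column per marker, cells in `A`/`B`/`H`/`-`),
#' `phenotypes.csv` (`id`, `population`, `block`, `trait`, `value`) and
#' `truth.json` (per-trait loci, pairs and baseline).
#'
#' @param sim A `ttc_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  stop_if_not(inherits(sim, "ttc_sim"), "`sim` must be a ttc_sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("map.csv", "genotypes.csv", "phenotypes.csv",
                            "truth.json"))
  readr::write_csv(tibble::as_tibble(sim$map), paths[1])
  write_genotypes(sim$ril_geno, paths[2])
  readr::write_csv(sim$phenotypes, paths[3])
  truth <- lapply(sim$truth, function(a) {
    list(mu = a$mu, loci = a$loci, pairs = a$pairs)
  })
  jsonlite::write_json(truth, paths[4], dataframe = "columns", digits = NA)
  invisible(paths)
}

#' @rdname write_sim_dataset
#' @param geno Character genotype matrix (`A`/`B`/`H`/`NA`).
#' @param path File path.
#' @export
write_genotypes <- function(geno, path) {
  g <- geno
  g[is.na(g)] <- "-"
  tbl <- tibble::as_tibble(as.data.frame(g, stringsAsFactors = FALSE))
  tbl <- dplyr::bind_cols(tibble::tibble(id = rownames(geno)), tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Read dataset files
#'
#' `read_genetic_map()`, `read_genotypes()` and `read_phenotypes()` read the
#' CSV formats written by [write_sim_dataset()]. Genotype cells `-` become
#' `NA`.
#'
#' @param path File path.
#' @return A `ttc_map` tibble, a character matrix, or a phenotype tibble.
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           marker = readr::col_character(),
                           chrom = readr::col_integer(),
                           pos_cM = readr::col_double()))
  validate_map(tibble::tibble(marker = map$marker, chrom = map$chrom,
                              pos_cM = map$pos_cM))
}

#' @rdname read_genetic_map
#' @export
read_genotypes <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  stop_if_not(names(tbl)[1] == "id", "genotype file must start with an `id` column")
  g <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(g) <- tbl$id
  g[g == "-"] <- NA_character_
  bad <- setdiff(unique(as.vector(g)), c("A", "B", "H", NA))
  stop_if_not(length(bad) == 0,
              paste("unknown genotype codes:", paste(bad, collapse = ", ")))
  g
}

#' @rdname read_genetic_map
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    population = readr::col_character(),
                    block = readr::col_integer(),
                    trait = readr::col_character(),
                    value = readr::col_double()))
}

#' Validate dataset files before analysis
#'
#' Checks genotype code alphabets, agreement between map and genotype
#' markers, phenotype population labels and duplicated ids. Fatal issues
#' make downstream stages impossible; warnings do not.
#'
#' @param map_file,geno_file,pheno_file Paths to the three CSV files.
#' @return Tibble of diagnostics (`level` in `info`/`warning`/`fatal`,
#'   `message`), with attribute `ok` (`FALSE` when any fatal issue).
#' @export
validate_ttc_inputs <- function(map_file, geno_file, pheno_file) {
  diags <- list()
  note <- function(level, msg) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(level = level, message = msg)
  }
  map <- tryCatch(read_genetic_map(map_file), error = function(e) {
    note("fatal", paste("map:", conditionMessage(e))); NULL
  })
  geno <- tryCatch({
    tbl <- readr::read_csv(geno_file, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    stop_if_not(names(tbl)[1] == "id", "first column must be `id`")
    g <- as.matrix(tbl[, -1, drop = FALSE]); rownames(g) <- tbl$id
    g[g == "-"] <- NA_character_
    g
  }, error = function(e) {
    note("fatal", paste("genotypes:", conditionMessage(e))); NULL
  })
  pheno <- tryCatch(read_phenotypes(pheno_file), error = function(e) {
    note("fatal", paste("phenotypes:", conditionMessage(e))); NULL
  })
  if (!is.null(geno)) {
    bad <- setdiff(unique(as.vector(geno)), c("A", "B", "H", NA))
    if (length(bad) > 0) {
      note("fatal", paste("unknown genotype codes:", paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(rownames(geno))) note("fatal", "duplicated genotype ids")
  }
  if (!is.null(map) && !is.null(geno)) {
    extra <- setdiff(colnames(geno), map$marker)
    missing <- setdiff(map$marker, colnames(geno))
    if (length(extra) > 0) {
      note("fatal", paste(length(extra), "genotyped marker(s) absent from the map"))
    }
    if (length(missing) > 0) {
      note("warning", paste(length(missing), "map marker(s) not genotyped"))
    }
  }
  if (!is.null(pheno)) {
    known <- c("P1", "P2", "F1", "IBM", "TCB", "TCM", "TCF")
    odd <- setdiff(unique(pheno$population), known)
    if (length(odd) > 0) {
      note("fatal", paste("unknown population labels:",
                          paste(odd, collapse = ", ")))
    }
    if (!is.null(geno)) {
      orphans <- setdiff(unique(pheno$id[pheno$population %in%
                                           c("IBM", "TCB", "TCM", "TCF")]),
                         rownames(geno))
      if (length(orphans) > 0) {
        note("warning",
             paste(length(orphans), "phenotyped line id(s) not genotyped"))
      }
    }
  }
  out <- if (length(diags) > 0) dplyr::bind_rows(diags) else
    tibble::tibble(level = character(0), message = character(0))
  if (nrow(out) == 0) {
    out <- tibble::tibble(level = "info", message = "all checks passed")
  }
  attr(out, "ok") <- !any(out$level == "fatal")
  out
}
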