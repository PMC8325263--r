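test_that("BLUEs equal plain means on balanced data and the normal-equation
           solution otherwise", {
  tbl <- tibble::tibble(id = "g1", population = "IBM", block = 1:3,
                        trait = "t", value = c(4, 5, 6))
  expect_equal(compute_blues(tbl)$blue, 5)

  one <- tibble::tibble(id = "g1", population = "IBM", block = 1,
                        trait = "t", value = 7.3)
  expect_equal(compute_blues(one)$blue, 7.3)

  # unbalanced: 3 genotypes x 2 blocks with one plot removed
  ub <- tidyr::expand_grid(id = c("g1", "g2", "g3"), block = 1:2) |>
    dplyr::mutate(population = "IBM", trait = "t",
                  value = c(10, 11, 8, 10, 6, 5))
  ub <- ub[-2, ]  # drop g1 in block 2
  got <- compute_blues(ub)
  want <- oracle_blues(data.frame(geno = ub$id, block = ub$block,
                                  value = ub$value))
  expect_equal(setNames(got$blue, got$id), want, tolerance = 1e-12)
})

test_that("mid-parent heterosis follows the exact formula", {
  expect_equal(mph(5, 5, 5)$mph_percent, 0)
  expect_equal(mph(2.5, 1, 1)$mph_percent, 150)
  expect_equal(mph(1, 2, 2)$mph_percent, -50)
  expect_error(mph(1, 0, 0), "mid-parent")
  expect_error(mph(1, 2, -2), "mid-parent")
})

test_that("Z transformations satisfy definitions, linearity and
           reconstruction", {
  tr <- tibble::tibble(id = c("r1", "r2"), H1 = c(3, 4), H2 = c(3, 2),
                       H3 = c(3, 3))
  z <- ttc_transforms(tr)
  expect_equal(z$Z1, c(3, 3))
  expect_equal(z$Z2, c(0, 2))
  expect_equal(z$Z3, c(0, 0))

  set.seed(1)
  h <- tibble::tibble(id = sprintf("r%02d", 1:20), H1 = rnorm(20),
                      H2 = rnorm(20), H3 = rnorm(20))
  hp <- dplyr::mutate(h, H1 = rnorm(20), H2 = rnorm(20), H3 = rnorm(20))
  a <- 1.7; b <- -0.4
  lin <- ttc_transforms(dplyr::mutate(h, H1 = a * h$H1 + b * hp$H1,
                                      H2 = a * h$H2 + b * hp$H2,
                                      H3 = a * h$H3 + b * hp$H3))
  z1 <- ttc_transforms(h); z2 <- ttc_transforms(hp)
  for (col in c("Z1", "Z2", "Z3")) {
    expect_equal(lin[[col]], a * z1[[col]] + b * z2[[col]], tolerance = 1e-12)
  }
  # reconstruction identities
  expect_equal(z1$Z1 + z1$Z2 / 2, h$H1, tolerance = 1e-12)
  expect_equal(z1$Z1 - z1$Z2 / 2, h$H2, tolerance = 1e-12)
  expect_equal(z1$Z1 - z1$Z3 / 2, h$H3, tolerance = 1e-12)

  expect_error(ttc_transforms(h[c(1, 1, 2), ]), "duplicated")
})

test_that("noise-free single-locus triplets match the enumeration oracle", {
  map <- tiny_map()
  arch <- qtl_architecture(loci = data.frame(chrom = 1, pos_cM = 40,
                                             a = 1, d = 0.5))
  des <- trial_design(n_ril = 16, n_blocks = 1, plants_per_family = 5000,
                      residual_sd = 0)
  s <- sim_ttc(arch, map = map, design = des, seed = 8)
  z <- ttc_transforms(ttc_triplets(compute_blues(s$phenotypes)))
  q <- unname(s$qtl_codes[[1]][z$id, 1])
  # (H1, H2) are deterministic: hom-P1 -> (1, 0.5), hom-P2 -> (0.5, -1)
  expect_equal(z$H1, ifelse(q > 0, oracle_h1(1, arch), oracle_h1(-1, arch)))
  expect_equal(z$H2, ifelse(q > 0, oracle_h2(1, arch), oracle_h2(-1, arch)))
  expect_equal(unique(z$Z1[q > 0]), 0.75)
  expect_equal(unique(z$Z2[q > 0]), 0.5)
  # class contrasts recover a and d
  expect_equal(mean(z$Z1[q > 0]) - mean(z$Z1[q < 0]), 1)
  expect_equal(-(mean(z$Z2[q > 0]) - mean(z$Z2[q < 0])) / 2, 0.5)
  # Z3 is sampling noise only here (no epistasis)
  expect_lt(max(abs(z$Z3)), 3 * sqrt(max(sapply(c(1, -1), function(qq) {
    oracle_tcf(qq, arch)$var
  })) / 5000) * 2)
})

test_that("heterozygosity counts H among non-missing calls", {
  expect_equal(heterozygosity(c("A", "H", "H", "B")), 0.5)
  expect_equal(heterozygosity(c("A", "A")), 0)
  expect_equal(heterozygosity(c("H", NA)), 1)
  expect_error(heterozygosity(c(NA_character_, NA)), "missing")
})

test_that("trait correlations are pairwise-complete Pearson", {
  tbl <- tibble::tibble(id = rep(c("i1", "i2", "i3"), 2),
                        trait = rep(c("x", "y"), each = 3),
                        blue = c(1, 2, 3, 1, 2, 4))
  res <- trait_correlations(tbl)
  expect_equal(res$r, 0.9819805, tolerance = 1e-6)

  same <- tibble::tibble(id = rep(c("i1", "i2", "i3"), 2),
                         trait = rep(c("x", "y"), each = 3),
                         blue = c(1, 2, 3, 1, 2, 3))
  expect_equal(trait_correlations(same)$r, 1)
  neg <- tibble::tibble(id = rep(c("i1", "i2", "i3"), 2),
                        trait = rep(c("x", "y"), each = 3),
                        blue = c(1, 2, 3, -1, -2, -3))
  expect_equal(trait_correlations(neg)$r, -1)
})

test_that("population ANOVA agrees with textbook sums of squares", {
  set.seed(2)
  tbl <- tibble::tibble(
    id = sprintf("g%02d", 1:30), trait = "t",
    population = rep(c("TCB", "TCM", "TCF"), each = 10),
    blue = rnorm(30) + rep(c(0, 0.5, 1), each = 10))
  got <- population_anova(tbl)
  want <- oracle_anova(tbl$blue, tbl$population)
  expect_equal(got$f_statistic, want$f, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  # two groups: F equals squared t
  two <- dplyr::filter(tbl, population != "TCF")
  got2 <- population_anova(two)
  tt <- t.test(blue ~ population, data = two, var.equal = TRUE)
  expect_equal(got2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-12)

  # degenerate: identical values guard to p = 1
  flat <- dplyr::mutate(tbl, blue = 2)
  expect_equal(population_anova(flat)$p_value, 1)
})
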