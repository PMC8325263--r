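test_that("genotypic_value implements the two-locus model", {
  a1 <- qtl_architecture(loci = data.frame(chrom = 1, pos_cM = 10, a = 1, d = 0.5))
  expect_equal(genotypic_value(1, a1), 1)
  expect_equal(genotypic_value(0, a1), 0.5)
  expect_equal(genotypic_value(-1, a1), -1)

  loci2 <- data.frame(chrom = c(1, 1), pos_cM = c(10, 60), a = 0, d = 0)
  aa <- qtl_architecture(loci2, pairs = data.frame(
    locus_i = 1, locus_j = 2, kind = "aa", coefficient = 2))
  expect_equal(genotypic_value(c(1, 1), aa), 2)
  expect_equal(genotypic_value(c(1, -1), aa), -2)

  dd <- qtl_architecture(loci2, pairs = data.frame(
    locus_i = 1, locus_j = 2, kind = "dd", coefficient = 1))
  expect_equal(genotypic_value(c(0, 0), dd), 1)
  expect_equal(genotypic_value(c(1, 0), dd), 0)

  expect_error(genotypic_value(c(1, NA), dd), "resolved")
  expect_error(genotypic_value(2, a1), "resolved|codes")
})

test_that("architecture validation rejects malformed inputs", {
  expect_error(qtl_architecture(
    loci = data.frame(chrom = 1, pos_cM = 10, a = Inf, d = 0)), "finite")
  expect_error(qtl_architecture(
    loci = data.frame(chrom = 1, pos_cM = 10, a = 1, d = 0),
    pairs = data.frame(locus_i = 1, locus_j = 2, kind = "aa",
                       coefficient = 1)), "declared loci")
  expect_error(qtl_architecture(
    loci = data.frame(chrom = 1, pos_cM = 500, a = 1, d = 0),
    map = tiny_map()), "span")
})

test_that("noise-free trials reproduce genotypic values exactly", {
  map <- tiny_map()
  des <- trial_design(n_ril = 10, n_blocks = 3, plants_per_family = 4,
                      residual_sd = 0)
  # no QTL: every plot equals the baseline
  s0 <- sim_ttc(qtl_architecture(mu = 5), map = map, design = des, seed = 1)
  expect_true(all(s0$phenotypes$value == 5))

  # one a=1, d=1 locus: P1 = 6, P2 = 4, F1 = 6 (MPH 20% downstream)
  a11 <- qtl_architecture(loci = data.frame(chrom = 1, pos_cM = 40, a = 1, d = 1),
                          mu = 5)
  s1 <- sim_ttc(a11, map = map, design = des, seed = 2)
  ph <- s1$phenotypes
  expect_equal(unique(ph$value[ph$population == "P1"]), 6)
  expect_equal(unique(ph$value[ph$population == "P2"]), 4)
  expect_equal(unique(ph$value[ph$population == "F1"]), 6)
  m <- mph_from_blues(compute_blues(ph))
  expect_equal(m$mph_percent, 20)
})

test_that("block effects are additive constants", {
  map <- tiny_map()
  des <- trial_design(n_ril = 5, n_blocks = 2, plants_per_family = 2,
                      residual_sd = 0, block_effects = c(0, 3))
  s <- sim_ttc(qtl_architecture(mu = 1), map = map, design = des, seed = 1)
  ph <- s$phenotypes
  expect_equal(unique(ph$value[ph$block == 1]), 1)
  expect_equal(unique(ph$value[ph$block == 2]), 4)
})

test_that("TC(F) family means approach the enumeration oracle", {
  map <- tiny_map()
  arch <- qtl_architecture(loci = data.frame(chrom = 1, pos_cM = 40, a = 1, d = 0),
                           mu = 0)
  des <- trial_design(n_ril = 12, n_blocks = 1, plants_per_family = 4000,
                      residual_sd = 0)
  s <- sim_ttc(arch, map = map, design = des, seed = 3)
  ph <- dplyr::filter(s$phenotypes, population == "TCF")
  q <- s$qtl_codes[[1]]
  for (i in seq_len(nrow(q))) {
    o <- oracle_tcf(q[i, ], arch)   # hom-P1 family mean -> mu + a/2
    se <- sqrt(o$var / 4000)
    expect_lt(abs(ph$value[ph$id == rownames(q)[i]] - o$mean),
              4 * se + 1e-9)
  }
  expect_equal(oracle_tcf(c(1), arch)$mean, 0.5)  # hom-P1, a=1: mu + 1/2
})

test_that("datasets are byte-identical under a fixed seed", {
  map <- tiny_map()
  arch <- sim_architecture("LW")
  arch$loci$chrom <- c(1, 1, 2, 2)
  arch$loci$pos_cM <- c(20, 70, 30, 80)
  des <- trial_design(n_ril = 15, n_blocks = 2, plants_per_family = 3)
  s1 <- sim_ttc(arch, map = map, design = des, seed = 4, h2_target = 0.3)
  s2 <- sim_ttc(arch, map = map, design = des, seed = 4, h2_target = 0.3)
  s3 <- sim_ttc(arch, map = map, design = des, seed = 5, h2_target = 0.3)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$ril_geno, s2$ril_geno)
  expect_false(identical(s1$phenotypes$value, s3$phenotypes$value))
})

test_that("preset architectures give the intended heterosis pattern", {
  map <- build_map()
  des <- trial_design(n_ril = 6, n_blocks = 1, plants_per_family = 2,
                      residual_sd = 0)
  archs <- lapply(c(LL = "LL", LW = "LW", LA = "LA", SDW = "SDW"),
                  sim_architecture)
  s <- sim_ttc(archs, map = map, design = des, seed = 1)
  m <- mph_from_blues(compute_blues(s$phenotypes))
  expect_true(all(m$mph_percent > 0))
  expect_lt(max(m$mph_percent[m$trait != "SDW"]), 50)
  expect_gt(m$mph_percent[m$trait == "SDW"], 100)
})
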