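epi_sim <- function(kind = "aa", coefficient = 2, plants = 2000, n_ril = 60,
                    seed = 41) {
  map <- tiny_map(2, 4, 60)  # markers every 20 cM
  arch <- qtl_architecture(
    loci = data.frame(chrom = c(1, 2), pos_cM = c(20, 40), a = 0, d = 0),
    pairs = data.frame(locus_i = 1, locus_j = 2, kind = kind,
                       coefficient = coefficient))
  des <- trial_design(n_ril = n_ril, n_blocks = 1, plants_per_family = plants,
                      residual_sd = 0)
  sim <- sim_ttc(arch, map = map, design = des, seed = seed)
  list(sim = sim, map = map, arch = arch,
       z = ttc_transforms(ttc_triplets(compute_blues(sim$phenotypes))))
}

test_that("an additive x additive pair is mapped in H3 with the
           enumeration-oracle effect", {
  es <- epi_sim("aa", coefficient = 2)
  y <- setNames(es$z$H3, es$z$id)
  ps <- pair_scan(y, es$sim$ril_geno, es$map, walk_step = 20, dataset = "H3")
  top <- ps[which.max(ps$lod), ]
  expect_equal(c(top$chrom_i, top$pos_i), c(1, 20))
  expect_equal(c(top$chrom_j, top$pos_j), c(2, 40))
  # oracle: regress exact family means on the +-1 line codes
  q <- es$sim$qtl_codes[[1]][es$z$id, ]
  h3_exact <- vapply(seq_len(nrow(q)), function(i) {
    oracle_tcf(q[i, ], es$arch)$mean
  }, numeric(1))
  ofit <- lm(h3_exact ~ q[, 1] * q[, 2])
  expect_equal(top$aa_ij, unname(coef(ofit)[4]), tolerance = 0.05)
  # unlinked loci: expected interaction is coefficient / 4
  expect_equal(unname(coef(ofit)[4]), 2 / 4, tolerance = 1e-9)
})

test_that("a dominance x dominance pair is mapped in Z3 with null main
           effects", {
  es <- epi_sim("dd", coefficient = 1, plants = 4000)
  y <- setNames(es$z$Z3, es$z$id)
  ps <- pair_scan(y, es$sim$ril_geno, es$map, walk_step = 20, dataset = "Z3")
  top <- ps[which.max(ps$lod), ]
  expect_equal(c(top$chrom_i, top$pos_i, top$chrom_j, top$pos_j),
               c(1, 20, 2, 40))
  # Z3 expectation is (c/2) q_i q_j: interaction c/2, main effects ~ 0
  expect_equal(top$aa_ij, 0.5, tolerance = 0.1)
  expect_lt(abs(top$a_i), 0.1)
  expect_lt(abs(top$a_j), 0.1)
})

test_that("the interaction fit is symmetric in the two loci", {
  es <- epi_sim("aa", coefficient = 2)
  y <- setNames(es$z$H3, es$z$id)
  ps <- pair_scan(y, es$sim$ril_geno, es$map, walk_step = 20,
                  background = FALSE)
  top <- ps[which.max(ps$lod), ]
  x1 <- conditional_code(es$sim$ril_geno, es$map, top$chrom_i, top$pos_i)
  x2 <- conditional_code(es$sim$ril_geno, es$map, top$chrom_j, top$pos_j)
  yy <- y[rownames(es$sim$ril_geno)]
  f12 <- lm(yy ~ x1 + x2 + x1:x2)
  f21 <- lm(yy ~ x2 + x1 + x2:x1)
  n <- length(yy)
  lod_direct <- (n / 2) * log10(sum(resid(lm(yy ~ x1 + x2))^2) /
                                  sum(resid(f12)^2))
  expect_equal(top$lod, lod_direct, tolerance = 1e-9)
  expect_equal(unname(coef(f12)[4]), unname(coef(f21)[4]), tolerance = 1e-12)
  expect_equal(top$aa_ij, unname(coef(f12)[4]), tolerance = 1e-9)
})

test_that("interaction LOD ignores added pure main-effect signal", {
  es <- epi_sim("aa", coefficient = 2)
  y <- setNames(es$z$H3, es$z$id)
  g <- es$sim$ril_geno
  ps <- pair_scan(y, g, es$map, walk_step = 20, background = FALSE)
  x1 <- conditional_code(g, es$map, 1, 20)
  y2 <- y + 3 * x1[match(names(y), rownames(g))]
  ps2 <- pair_scan(y2, g, es$map, walk_step = 20, background = FALSE)
  k <- which(ps$pos_i == 20 & ps$chrom_i == 1 & ps$chrom_j == 2 &
               ps$pos_j == 40)
  expect_equal(ps$lod[k], ps2$lod[k], tolerance = 1e-9)
  expect_equal(ps$aa_ij[k], ps2$aa_ij[k], tolerance = 1e-9)
})

test_that("pair permutation thresholds are empirical quantiles and the null
           is controlled", {
  es <- epi_sim("aa", coefficient = 0)  # no epistasis
  set.seed(9)
  y <- setNames(rnorm(60), es$z$id)
  th <- pair_permutation_threshold(y, es$sim$ril_geno, es$map, n_perm = 100,
                                   alpha = 0.05, seed = 2, walk_step = 20)
  th1 <- pair_permutation_threshold(y, es$sim$ril_geno, es$map, n_perm = 100,
                                    alpha = 1, seed = 2, walk_step = 20)
  expect_equal(th1$threshold, min(th$max_lods))
  expect_lte(th1$threshold, th$threshold)

  # null rejection rate near alpha over independent null responses
  cache <- ttcqtl:::pair_cache(es$sim$ril_geno, es$map, 20, 20)
  rej <- vapply(1:40, function(i) {
    yy <- setNames(rnorm(60), es$z$id)
    ths <- pair_permutation_threshold(yy, es$sim$ril_geno, es$map,
                                      n_perm = 100, alpha = 0.05,
                                      seed = 100 + i, walk_step = 20,
                                      cache = cache)
    ps <- pair_scan(yy, es$sim$ril_geno, es$map, walk_step = 20,
                    cache = cache)
    max(ps$lod, na.rm = TRUE) > ths$threshold
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 40) + 0.05)
})

test_that("call_epistasis reports planted pairs and merges neighbours", {
  map <- tiny_map(3, 4, 60)
  arch <- qtl_architecture(
    loci = data.frame(chrom = c(1, 2, 2, 3), pos_cM = c(20, 40, 0, 20),
                      a = 0, d = 0),
    pairs = data.frame(locus_i = c(1, 3), locus_j = c(2, 4),
                       kind = "aa", coefficient = c(2, 2)))
  des <- trial_design(n_ril = 80, n_blocks = 1, plants_per_family = 500,
                      residual_sd = 0)
  sim <- sim_ttc(arch, map = map, design = des, seed = 51)
  z <- ttc_transforms(ttc_triplets(compute_blues(sim$phenotypes)))
  ps <- pair_scan(setNames(z$H3, z$id), sim$ril_geno, map, walk_step = 20,
                  dataset = "H3")
  hits <- call_epistasis(ps, threshold = 5)
  expect_equal(nrow(hits), 2L)
  key <- paste(hits$chrom_i, hits$pos_i, hits$chrom_j, hits$pos_j)
  expect_setequal(key, c("1 20 2 40", "2 0 3 20"))
  expect_true(all(grepl("-", hits$interval_i)))
  expect_equal(nrow(call_epistasis(ps, threshold = 1e6)), 0L)
})
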