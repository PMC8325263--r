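noise_free_sim <- function(a = 1, d = 0.5, pos = 40, chrom = 1, n_ril = 80,
                           seed = 21, map = tiny_map(2, 6, 100)) {
  arch <- qtl_architecture(loci = data.frame(chrom = chrom, pos_cM = pos,
                                             a = a, d = d))
  des <- trial_design(n_ril = n_ril, n_blocks = 1, plants_per_family = 2,
                      residual_sd = 0)
  sim <- sim_ttc(arch, map = map, design = des, seed = seed)
  list(sim = sim,
       z = ttc_transforms(ttc_triplets(compute_blues(sim$phenotypes))))
}

test_that("stepwise background selection finds a perfectly explanatory
           marker and controls entry under pure noise", {
  map <- tiny_map(2, 6, 100)
  g <- simulate_rils(map, 122, seed = 3)
  X <- ttcqtl:::marker_code_matrix(g)
  # response exactly equal to one marker's codes
  sel <- select_background(X[, 5], X)
  expect_true(colnames(X)[5] %in% sel$markers)
  expect_equal(sel$r2, 1, tolerance = 1e-12)

  # pure-noise responses rarely admit any marker at p_enter = 0.001
  set.seed(11)
  empty <- vapply(1:200, function(i) {
    length(select_background(rnorm(122), X)$index) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.97)

  # a strong marker-resident QTL (locus h2 ~ 0.5) is recovered
  set.seed(12)
  hit <- vapply(1:100, function(i) {
    y <- X[, 8] + rnorm(122, sd = 1)
    any(select_background(y, X)$index %in% 7:9)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("noise-free scans recover simulated effects exactly", {
  nf <- noise_free_sim(a = 1, d = 0.5, pos = 40)
  g <- nf$sim$ril_geno
  map <- nf$sim$map
  y1 <- setNames(nf$z$Z1, nf$z$id)
  prof <- scan1d(y1, g, map, walk_step = 2, dataset = "Z1")
  peak <- prof[which.max(prof$lod), ]
  expect_equal(peak$chrom, 1L)
  expect_equal(peak$pos_cM, 40)
  # a* = 2 * slope on the +-1 code
  expect_equal(2 * peak$effect, 1, tolerance = 1e-9)
  # noise-free single QTL explains everything at its position
  expect_equal(100 * (1 - peak$rss1 / peak$rss0), 100, tolerance = 1e-6)

  y2 <- setNames(nf$z$Z2, nf$z$id)
  prof2 <- scan1d(y2, g, map, walk_step = 2, dataset = "Z2")
  peak2 <- prof2[which.max(prof2$lod), ]
  expect_equal(peak2$pos_cM, 40)
  expect_equal(-peak2$effect, 0.5, tolerance = 1e-9)

  eff <- estimate_effects_at(nf$z, g, map, 1, 40)
  expect_equal(eff$a_star, 1, tolerance = 1e-9)
  expect_equal(eff$d_star, 0.5, tolerance = 1e-9)
})

test_that("scan LOD is invariant to affine transforms of the response", {
  nf <- noise_free_sim()
  y <- setNames(nf$z$Z1 + rnorm(length(nf$z$Z1), sd = 0.2), nf$z$id)
  p1 <- scan1d(y, nf$sim$ril_geno, nf$sim$map, walk_step = 5)
  p2 <- scan1d(2.7 * y - 13, nf$sim$ril_geno, nf$sim$map, walk_step = 5)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
})

test_that("call_qtls separates distant peaks, merges near ones and reports
           flanking markers", {
  map <- tiny_map(1, 11, 200)  # markers every 20 cM
  arch <- qtl_architecture(loci = data.frame(chrom = 1, pos_cM = c(40, 120),
                                             a = c(1, 1), d = 0))
  des <- trial_design(n_ril = 100, n_blocks = 1, plants_per_family = 2,
                      residual_sd = 0)
  sim <- sim_ttc(arch, map = map, design = des, seed = 31)
  z <- ttc_transforms(ttc_triplets(compute_blues(sim$phenotypes)))
  prof <- scan1d(setNames(z$Z1, z$id), sim$ril_geno, map, walk_step = 2,
                 dataset = "Z1")
  hits <- call_qtls(prof, threshold = 3)
  expect_equal(nrow(hits), 2L)
  expect_true(all(abs(hits$pos_cM - c(40, 120)) <= 5))
  expect_equal(hits$flank_left[1], map$marker[map$pos_cM == 40])
  # nothing above an unreachable threshold
  expect_equal(nrow(call_qtls(prof, threshold = 1e6)), 0L)
})

test_that("permutation thresholds behave like empirical quantiles", {
  nf <- noise_free_sim(n_ril = 60, map = tiny_map(1, 6, 100))
  set.seed(5)
  y <- setNames(rnorm(60), nf$z$id)
  th <- permutation_threshold(y, nf$sim$ril_geno, nf$sim$map, n_perm = 100,
                              alpha = 0.05, seed = 7, walk_step = 10)
  th1 <- permutation_threshold(y, nf$sim$ril_geno, nf$sim$map, n_perm = 100,
                               alpha = 1, seed = 7, walk_step = 10)
  expect_equal(th1$threshold, min(th$max_lods))
  th2 <- permutation_threshold(y, nf$sim$ril_geno, nf$sim$map, n_perm = 100,
                               alpha = 0.2, seed = 7, walk_step = 10)
  expect_lte(th2$threshold, th$threshold)  # monotone in alpha
  # reproducible under the same master seed
  thr <- permutation_threshold(y, nf$sim$ril_geno, nf$sim$map, n_perm = 100,
                               alpha = 0.05, seed = 7, walk_step = 10)
  expect_identical(th$max_lods, thr$max_lods)
})

test_that("gene modes follow the dominance-ratio cutpoints", {
  expect_equal(classify_gene_mode(1, 0.1), "A")
  expect_equal(classify_gene_mode(1, 0.5), "PD")
  expect_equal(classify_gene_mode(1, 1.0), "D")
  expect_equal(classify_gene_mode(1, 1.3), "OD")
  expect_equal(classify_gene_mode(0.1, 0.5), "OD")  # ratio 5
  expect_equal(classify_gene_mode(0, 0.3), "OD")    # infinite ratio
  expect_equal(classify_gene_mode(c(1, 2), c(0.1, 2.6)), c("A", "OD"))
  expect_warning(m0 <- classify_gene_mode(0, 0), "undefined")
  expect_true(is.na(m0))
  # boundary values land in the upper class (half-open intervals)
  expect_equal(classify_gene_mode(1, 0.2), "PD")
  expect_equal(classify_gene_mode(1, 0.8), "D")
  expect_equal(classify_gene_mode(1, 1.2), "OD")
})

test_that("the assembled QTL table classifies a dominant locus correctly", {
  nf <- noise_free_sim(a = 1, d = 1, pos = 40, n_ril = 60,
                       map = tiny_map(1, 6, 100))
  tab <- scan_heterotic_qtls(nf$z, nf$sim$ril_geno, nf$sim$map,
                             walk_step = 5, n_perm = 100, seed = 3)
  z1 <- dplyr::filter(tab, dataset == "Z1")
  expect_gte(nrow(z1), 1L)
  expect_equal(z1$a_star[1], 1, tolerance = 1e-6)
  expect_equal(z1$d_star[1], 1, tolerance = 1e-6)
  expect_equal(z1$gene_mode[1], "D")
})
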