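toy_factorial <- function(n_lines = 3, n_testers = 3, n_mark = 40, seed = 1) {
  set.seed(seed)
  lines <- matrix(sample(c("A", "B"), n_lines * n_mark, TRUE), n_lines, n_mark,
                  dimnames = list(paste0("l", seq_len(n_lines)),
                                  paste0("m", seq_len(n_mark))))
  testers <- matrix(sample(c("A", "B"), n_testers * n_mark, TRUE), n_testers,
                    n_mark, dimnames = list(paste0("t", seq_len(n_testers)),
                                            paste0("m", seq_len(n_mark))))
  hm <- tidyr::expand_grid(maternal = rownames(lines),
                           paternal = rownames(testers))
  hm$hybrid_id <- paste0(hm$maternal, ":", hm$paternal)
  kin <- suppressWarnings(build_kinships(encode_and_impute(lines)$M,
                                         encode_and_impute(testers)$M, hm))
  list(lines = lines, testers = testers, hm = hm, kin = kin)
}

as_gp_data <- function(toy, y) {
  structure(list(lines = toy$lines, testers = toy$testers,
                 hybrid_map = toy$hm,
                 blues = tibble::tibble(hybrid_id = toy$hm$hybrid_id,
                                        trait = "t", value = unname(y)),
                 plots = NULL),
            class = "ttc_gp_data")
}

test_that("REML collapses to zero variance for a constant response", {
  n <- 20
  K <- list(g = diag(n))
  fit <- reml_fit(rep(3, n), K)
  expect_true(all(fit$sigma2 <= 1e-6))
  expect_true(fit$converged)
})

test_that("REML matches the ANOVA estimators on a balanced one-way layout", {
  set.seed(7)
  g <- 8; r <- 5
  grp <- rep(seq_len(g), each = r)
  u <- rnorm(g, 0, sqrt(3))
  y <- 10 + u[grp] + rnorm(g * r, 0, 2)
  Z <- outer(grp, seq_len(g), "==") + 0
  fit <- reml_fit(y, list(g = tcrossprod(Z)))
  msb <- sum(r * (tapply(y, grp, mean) - mean(y))^2) / (g - 1)
  msw <- sum((y - ave(y, grp))^2) / (g * r - g)
  expect_equal(unname(fit$sigma2["g"]), (msb - msw) / r, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["residual"]), msw, tolerance = 1e-6)
})

test_that("the EM path is monotone in the restricted likelihood", {
  toy <- toy_factorial(seed = 4)
  set.seed(5)
  y <- rnorm(9, 10, 2)
  K <- list(gca_m = toy$kin$K_M, gca_p = toy$kin$K_P, sca = toy$kin$G_S)
  fit <- suppressWarnings(reml_fit(y, K, method = "em", max_iter = 50,
                                   tol = 1e-12))
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
})

test_that("non-PSD kernels are refused with the offending eigenvalue", {
  K <- diag(5); K[1, 2] <- K[2, 1] <- 2
  expect_error(reml_fit(rnorm(5), list(bad = K)), "not PSD")
})

test_that("variance components are recovered from data simulated under the
           GCA/SCA model", {
  nl <- 122
  toy <- toy_factorial(n_lines = nl, n_testers = 2, n_mark = 200, seed = 8)
  truth <- c(2, 1, 1, 4)
  n <- nrow(toy$hm)
  ch <- lapply(list(toy$kin$K_M, toy$kin$K_P, toy$kin$G_S), function(K) {
    e <- eigen(K, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  })
  set.seed(9)
  est <- replicate(60, {
    y <- 10 + sqrt(truth[1]) * ch[[1]] %*% rnorm(n) +
      sqrt(truth[2]) * ch[[2]] %*% rnorm(n) +
      sqrt(truth[3]) * ch[[3]] %*% rnorm(n) + rnorm(n, 0, sqrt(truth[4]))
    fit <- suppressWarnings(reml_fit(as.vector(y), list(
      gca_m = toy$kin$K_M, gca_p = toy$kin$K_P, sca = toy$kin$G_S),
      check_psd = FALSE))
    fit$sigma2
  })
  m <- rowMeans(est)
  # total variance and the dominant components are close to truth; the
  # 2-tester GCA/SCA split is weakly identified, so compare the sums too
  expect_lt(abs(m["gca_m"] - truth[1]) / truth[1], 0.15)
  expect_lt(abs(m["residual"] - truth[4]) / truth[4], 0.15)
  expect_lt(abs(sum(m) - sum(truth)) / sum(truth), 0.1)
})

test_that("heritability follows the variance-component formulas", {
  vc <- c(gca_m = 2, gca_p = 1, sca = 1, residual = 4)
  h <- heritability(vc)
  expect_equal(h$h2, 0.375)
  expect_equal(h$H2, 0.5)
  expect_equal(heritability(c(gca_m = 1, gca_p = 2, sca = 0, residual = 0)),
               tibble::tibble(h2 = 1, H2 = 1))
  expect_equal(heritability(c(gca_m = 0, gca_p = 0, sca = 2, residual = 2))$h2,
               0)
  expect_error(heritability(c(gca_m = 0, gca_p = 0, sca = 0, residual = 0)),
               "zero")
  expect_error(heritability(c(gca_m = -1, gca_p = 0, sca = 0, residual = 1)),
               ">= 0")
})

test_that("GBLUP predictions agree with a dense mixed-model-equation solve", {
  toy <- toy_factorial(seed = 1)
  sig <- c(gca_m = 2, gca_p = 1, sca = 1.5, residual = 4)
  set.seed(2)
  y <- rnorm(9, 10, 2); names(y) <- toy$hm$hybrid_id
  obs <- toy$hm$hybrid_id[c(1, 2, 3, 5, 6, 9)]
  gpd <- as_gp_data(toy, y)
  fit <- suppressWarnings(fit_gca_sca(gpd, trait = "t", kinships = toy$kin,
                                      train = obs, init = unname(sig),
                                      max_iter = 0))
  pred <- predict(fit)

  # Harville non-inverse mixed-model equations (valid for singular G),
  # solved with a pseudo-inverse: an algebraically different route
  oi <- match(obs, toy$hm$hybrid_id)
  X <- matrix(1, 6, 1)
  Zm <- outer(toy$hm$maternal[oi], rownames(toy$lines), "==") + 0
  Zp <- outer(toy$hm$paternal[oi], rownames(toy$testers), "==") + 0
  Zs <- outer(oi, 1:9, "==") + 0
  Z <- cbind(Zm, Zp, Zs)
  B <- matrix(0, 15, 15)
  B[1:3, 1:3] <- sig[1] * toy$kin$G_M
  B[4:6, 4:6] <- sig[2] * toy$kin$G_P
  B[7:15, 7:15] <- sig[3] * toy$kin$G_S
  se <- sig[4]
  Cmat <- rbind(cbind(crossprod(X) / se, crossprod(X, Z) %*% B / se),
                cbind(B %*% crossprod(Z, X) / se,
                      B %*% crossprod(Z) %*% B / se + B))
  rhs <- rbind(crossprod(X, y[obs]) / se, B %*% crossprod(Z, y[obs]) / se)
  sol <- MASS::ginv(Cmat) %*% rhs
  u <- B %*% sol[-1]
  pred_mme <- sol[1] + u[1:3][match(toy$hm$maternal, rownames(toy$lines))] +
    u[4:6][match(toy$hm$paternal, rownames(toy$testers))] + u[7:15]
  expect_equal(pred$predicted, as.vector(pred_mme), tolerance = 1e-8)
  expect_equal(fit$beta, sol[1], tolerance = 1e-8)
})

test_that("with zero SCA variance predictions are additive in the parental
           combining abilities", {
  toy <- toy_factorial(seed = 6)
  set.seed(3)
  y <- rnorm(9, 5, 1); names(y) <- toy$hm$hybrid_id
  gpd <- as_gp_data(toy, y)
  fit <- suppressWarnings(fit_gca_sca(gpd, trait = "t", kinships = toy$kin,
                                      init = c(2, 1, 0, 3), max_iter = 0))
  p <- predict(fit)
  P <- matrix(p$predicted, 3, 3, byrow = TRUE)  # lines x testers (grid order)
  # interaction contrasts vanish: p[i,j] - p[i,j'] does not depend on i
  for (j in 2:3) {
    expect_equal(diff(P[, 1] - P[, j]), c(0, 0), tolerance = 1e-10)
  }
  expect_error(predict(fit, hybrids = "nope"), "kinship universe")
})
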