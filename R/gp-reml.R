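# REML estimation of variance components for kernel-structured mixed models,
# by average-information updates with EM fallback, and GBLUP prediction
# through the corresponding mixed-model equations.

#' Restricted maximum likelihood for variance-component models
#'
#' Fits `y = X b + sum_k u_k + e` with `u_k ~ N(0, K_k s2_k)` and
#' `e ~ N(0, I s2_e)` by REML. Updates are average-information steps with a
#' fallback to EM whenever an AI step would leave the parameter space or
#' decrease the restricted likelihood; non-negativity is enforced by
#' boundary projection. Convergence is declared when the relative change in
#' restricted log-likelihood falls below `tol`.
#'
#' @param y Numeric response.
#' @param K Named list of symmetric positive semidefinite kernels
#'   (`n x n`).
#' @param X Fixed-effect design matrix (default intercept only).
#' @param init Optional initial variance components (length `K` + 1).
#' @param max_iter,tol Iteration cap (default 200) and relative
#'   log-likelihood tolerance (default 1e-8).
#' @param method `"ai"` (average information with EM fallback) or `"em"`
#'   (pure EM, monotone in the restricted likelihood).
#' @param check_psd Verify kernels are PSD before fitting.
#' @return List: `sigma2` (named, last element `residual`), `logLik`,
#'   `ll_trace` (restricted log-likelihood per accepted iterate),
#'   `iterations`, `converged`, `beta` (GLS fixed effects), `Vinv_r`
#'   (internal solve of the residual projection, reused by prediction).
#' @export
reml_fit <- function(y, K, X = NULL, init = NULL, max_iter = 200, tol = 1e-8,
                     method = c("ai", "em"), check_psd = TRUE) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stop_if_not(n > ncol(X), "need more observations than fixed effects")
  stop_if_not(length(K) >= 1, "need at least one kernel")
  if (is.null(names(K))) names(K) <- paste0("K", seq_along(K))
  for (nm in names(K)) {
    stop_if_not(all(dim(K[[nm]]) == n), paste("kernel", nm, "has wrong dimension"))
    if (check_psd) {
      ev <- min(eigen(K[[nm]], symmetric = TRUE, only.values = TRUE)$values)
      stop_if_not(ev > -1e-6 * n,
                  sprintf("kernel %s is not PSD (min eigenvalue %.3g)", nm, ev),
                  class = "ttcqtl_not_psd")
    }
  }
  vy <- var(y)
  nk <- length(K)
  comp_names <- c(names(K), "residual")
  if (vy < 1e-28) {
    return(list(sigma2 = setNames(rep(0, nk + 1), comp_names), logLik = NA_real_,
                iterations = 0L, converged = TRUE, beta = qr.coef(qr(X), y),
                Vinv_r = rep(0, n)))
  }
  theta <- init %||% rep(vy / (nk + 1), nk + 1)
  theta <- pmax(theta, 0)
  theta[nk + 1] <- max(theta[nk + 1], 1e-6 * vy)

  eval_state <- function(theta) {
    V <- diag(theta[nk + 1], n)
    for (k in seq_len(nk)) if (theta[k] > 0) V <- V + theta[k] * K[[k]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViX_i <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(XtViX_i)) return(NULL)
    P <- Vi - ViX %*% XtViX_i %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(R))) +
                    determinant(XtViX, logarithm = TRUE)$modulus[1] +
                    sum(y * Py))
    list(P = P, Py = Py, ll = as.numeric(ll), Vi = Vi, XtViX_i = XtViX_i,
         ViX = ViX)
  }

  st <- eval_state(theta)
  stop_if_not(!is.null(st), "initial variance matrix is singular")
  converged <- FALSE
  iter <- 0L
  ll_trace <- st$ll
  floor_resid <- 1e-10 * vy
  while (iter < max_iter) {
    iter <- iter + 1L
    # score and EM ingredients
    U <- matrix(0, n, nk + 1)
    trPK <- yPKPy <- numeric(nk + 1)
    for (k in seq_len(nk)) {
      U[, k] <- K[[k]] %*% st$Py
      trPK[k] <- sum(st$P * K[[k]])
      yPKPy[k] <- sum(st$Py * U[, k])
    }
    U[, nk + 1] <- st$Py
    trPK[nk + 1] <- sum(diag(st$P))
    yPKPy[nk + 1] <- sum(st$Py^2)
    score <- -0.5 * (trPK - yPKPy)
    em_step <- theta + theta^2 * (yPKPy - trPK) / n

    proposal <- NULL
    if (method == "ai") {
      AI <- 0.5 * crossprod(U, st$P %*% U)
      AIr <- AI + diag(1e-8 * max(diag(AI), 1), nk + 1)
      delta <- tryCatch(solve(AIr, score), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.vector(delta)
        cand <- pmax(cand, 0)
        cand[nk + 1] <- max(cand[nk + 1], floor_resid)
        stc <- eval_state(cand)
        if (!is.null(stc) && is.finite(stc$ll) && stc$ll >= st$ll - 1e-10) {
          proposal <- list(theta = cand, st = stc)
        }
      }
    }
    if (is.null(proposal)) {
      cand <- pmax(em_step, 0)
      cand[nk + 1] <- max(cand[nk + 1], floor_resid)
      stc <- eval_state(cand)
      if (is.null(stc)) break
      proposal <- list(theta = cand, st = stc)
    }
    dll <- proposal$st$ll - st$ll
    theta <- proposal$theta
    st <- proposal$st
    ll_trace <- c(ll_trace, st$ll)
    if (abs(dll) < tol * (1 + abs(st$ll))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn("REML did not converge; returning last iterate")
  }
  beta <- st$XtViX_i %*% crossprod(X, st$Vi %*% y)
  list(sigma2 = setNames(pmax(theta, 0), comp_names), logLik = st$ll,
       ll_trace = ll_trace, iterations = iter, converged = converged,
       beta = as.vector(beta), Vinv_r = as.vector(st$Py))
}

#' Fit the GCA/SCA GBLUP model
#'
#' Fits `y = mu + Z_M g_M + Z_P g_P + Z_S s + e` with
#' `g_M ~ N(0, G_M s2_GCA_M)`, `g_P ~ N(0, G_P s2_GCA_P)` and
#' `s ~ N(0, G_S s2_SCA)` by REML. The response is either per-hybrid BLUEs
#' (`response = "blues"`) or plot-level values with an additional random
#' block effect (`response = "plots"`).
#'
#' @param data A [ttc_gp_data()] object.
#' @param trait Trait to fit (default the first in the data).
#' @param kinships Optional [build_kinships()] result (built from all
#'   markers when `NULL`).
#' @param response `"blues"` (block-averaged hybrid means, the default) or
#'   `"plots"` (plot-level with a random block effect).
#' @param train Optional character vector of hybrid ids used for REML
#'   training (kernels always span all hybrids; only phenotypes are
#'   restricted).
#' @param fixed Optional matrix of fixed covariates, rows named by hybrid
#'   id (e.g. QTL marker codes).
#' @param ... Passed to [reml_fit()].
#' @return Object of class `ttc_gblup` with the variance components, the
#'   heritabilities and everything needed by `predict()`.
#' @export
fit_gca_sca <- function(data, trait = NULL, kinships = NULL,
                        response = c("blues", "plots"), train = NULL,
                        fixed = NULL, ...) {
  response <- match.arg(response)
  stop_if_not(inherits(data, "ttc_gp_data"), "`data` must be a ttc_gp_data")
  kin <- kinships %||% gp_kinships(data)
  trait <- trait %||% data$blues$trait[1]
  tbl <- if (response == "blues") data$blues else data$plots
  tbl <- dplyr::filter(tbl, .data$trait == !!trait)
  stop_if_not(nrow(tbl) > 0, paste("no records for trait", trait))
  hyb_order <- kin$hybrid_map$hybrid_id
  stop_if_not(all(tbl$hybrid_id %in% hyb_order),
              "phenotyped hybrids missing from the kinships")
  train <- train %||% unique(tbl$hybrid_id)
  obs <- dplyr::filter(tbl, .data$hybrid_id %in% train)
  hi <- match(obs$hybrid_id, hyb_order)
  K <- list(gca_m = kin$K_M[hi, hi, drop = FALSE],
            gca_p = kin$K_P[hi, hi, drop = FALSE],
            sca = kin$G_S[hi, hi, drop = FALSE])
  if (response == "plots") {
    b <- factor(obs$block)
    Zb <- stats::model.matrix(~ 0 + b)
    K$block <- tcrossprod(Zb)
  }
  X <- matrix(1, nrow(obs), 1)
  if (!is.null(fixed)) {
    stop_if_not(all(obs$hybrid_id %in% rownames(fixed)),
                "fixed covariates must cover all phenotyped hybrids")
    X <- cbind(X, fixed[obs$hybrid_id, , drop = FALSE])
  }
  fit <- reml_fit(obs$value, K, X = X, ...)
  structure(list(trait = trait, response = response, sigma2 = fit$sigma2,
                 logLik = fit$logLik, iterations = fit$iterations,
                 converged = fit$converged, beta = fit$beta,
                 Vinv_r = fit$Vinv_r, obs = obs, obs_index = hi,
                 fixed = fixed, kinships = kin, n = nrow(obs)),
            class = "ttc_gblup")
}

#' @export
print.ttc_gblup <- function(x, ...) {
  cat("<ttc_gblup>", x$trait, "|", x$response, "response, n =", x$n, "\n")
  print(round(x$sigma2, 4))
  h <- heritability(x)
  cat(sprintf("h2 = %.3f, H2 = %.3f (logLik %.3f, %d iters%s)\n", h$h2, h$H2,
              x$logLik, x$iterations, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Narrow- and broad-sense heritability from GCA/SCA variance components
#'
#' `h2 = (s2_GCA_M + s2_GCA_P) / (s2_GCA_M + s2_GCA_P + s2_SCA + s2_R)` and
#' `H2 = (s2_GCA_M + s2_GCA_P + s2_SCA) / (same denominator)`. A block
#' variance component, when present, is excluded from the denominator.
#'
#' @param x A `ttc_gblup` fit or a named numeric vector with elements
#'   `gca_m`, `gca_p`, `sca`, `residual`.
#' @return One-row tibble with `h2` and `H2`.
#' @export
heritability <- function(x) {
  s <- if (inherits(x, "ttc_gblup")) x$sigma2 else x
  stop_if_not(all(c("gca_m", "gca_p", "sca", "residual") %in% names(s)),
              "need components gca_m, gca_p, sca, residual")
  stop_if_not(all(s >= 0), "variance components must be >= 0")
  denom <- s[["gca_m"]] + s[["gca_p"]] + s[["sca"]] + s[["residual"]]
  stop_if_not(denom > 0, "all variance components are zero",
              class = "ttcqtl_undefined_value")
  tibble::tibble(h2 = (s[["gca_m"]] + s[["gca_p"]]) / denom,
                 H2 = (s[["gca_m"]] + s[["gca_p"]] + s[["sca"]]) / denom)
}

#' Predict genetic values of hybrids from a fitted GCA/SCA model
#'
#' BLUP of `g_M + g_P + s` for the requested hybrids given the training
#' phenotypes, at the REML variance-component estimates:
#' `u_hat = C V^{-1} (y - X b)` with `C` the genetic covariance between the
#' target hybrids and the training observations. Hybrids must be in the
#' kinship universe (only phenotypes were masked).
#'
#' @param object A `ttc_gblup`.
#' @param hybrids Character vector of hybrid ids (default: all hybrids in
#'   the kinships).
#' @param ... Unused.
#' @return Tibble `hybrid_id`, `predicted` (intercept + fixed covariates +
#'   genetic BLUP).
#' @export
predict.ttc_gblup <- function(object, hybrids = NULL, ...) {
  kin <- object$kinships
  hybrids <- hybrids %||% kin$hybrid_map$hybrid_id
  ni <- match(hybrids, kin$hybrid_map$hybrid_id)
  stop_if_not(!anyNA(ni), "hybrid absent from the kinship universe")
  hi <- object$obs_index
  s <- object$sigma2
  C <- s[["gca_m"]] * kin$K_M[ni, hi, drop = FALSE] +
    s[["gca_p"]] * kin$K_P[ni, hi, drop = FALSE] +
    s[["sca"]] * kin$G_S[ni, hi, drop = FALSE]
  u <- as.vector(C %*% object$Vinv_r)
  Xn <- matrix(1, length(hybrids), 1)
  if (!is.null(object$fixed)) {
    stop_if_not(all(hybrids %in% rownames(object$fixed)),
                "fixed covariates missing for some hybrids")
    Xn <- cbind(Xn, object$fixed[hybrids, , drop = FALSE])
  }
  tibble::tibble(hybrid_id = hybrids,
                 predicted = as.vector(Xn %*% object$beta) + u)
}
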