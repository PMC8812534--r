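# Fast robust-t engine used by the resampling loop.
#
# By Frisch-Waugh, the full-model OLS coefficient on the treatment indicator
# equals the coefficient from regressing Y on the treatment residualized
# against the other regressors, and the full-model residuals equal the
# residuals of that partitioned regression. The HC0 sandwich element for the
# treatment coefficient is therefore sum(dt^2 e^2) / (dt'dt)^2 with dt the
# residualized treatment; HC1 rescales by n / (n - K) with K the full-model
# parameter count. This reproduces sandwich::vcovHC() exactly (tested) while
# letting hundreds of permutations be evaluated with matrix algebra.
#
# Yt: n x m residualized outcomes; Dt: n x B residualized treatment columns.
# Returns a B x m matrix of |t| statistics.
engine_abs_t <- function(Yt, Dt, n, K, hc_type = "HC1") {
  dd <- colSums(Dt^2)                         # B
  Bmat <- crossprod(Dt, Yt) / dd              # B x m coefficients
  A1 <- crossprod(Dt^2, Yt^2)                 # sum dt^2 y^2
  A2 <- crossprod(Dt^3, Yt)                   # sum dt^3 y
  A3 <- colSums(Dt^4)                         # sum dt^4
  meat <- A1 - 2 * Bmat * A2 + Bmat^2 * A3    # sum dt^2 e^2
  fac <- if (hc_type == "HC1") n / (n - K) else 1
  v <- fac * meat / dd^2
  abs(Bmat) / sqrt(v)
}

#' Westfall-Young free stepdown adjusted p-values
#'
#' Resampling-based family-wise error control over a family of ITT outcomes.
#' The algorithm: (1) compute the observed robust |t| of the treatment
#' coefficient for every family member; (2) for each resample, permute the
#' treatment indicator within site strata (covariates and outcomes held
#' fixed, valid under randomization), refit all member models and record the
#' permuted |t|; (3) free stepdown: order observed |t| descending and set the
#' k-th ordered member's adjusted p to the proportion of resamples in which
#' the successive maximum of permuted |t| over members ranked k..m reaches
#' the observed |t|; (4) enforce monotonicity of adjusted p down the
#' ordering. Deterministic given `seed`.
#'
#' @param outcomes Data frame or matrix (rows aligned to `data`), one column
#'   per family member, no missing values.
#' @param data Analytic-sample cohort rows (imputed when `covariates = TRUE`)
#'   with `arm` and `site` columns.
#' @param covariates Adjust member models for [itt_covariates()]?
#' @param n_resamples Number of permutations (production default 10,000; a
#'   warning is issued below 100).
#' @param seed Mandatory integer seed for the permutation stream.
#' @param hc_type `"HC1"` (default) or `"HC0"`.
#' @return Data frame, one row per member in input order: `outcome`, `t`
#'   (observed robust |t|), `p_unadjusted` (normal-approximation p from the
#'   robust t, as reported by [fit_itt()]), `p_perm` (per-member permutation
#'   p), `p_wy` (free stepdown adjusted p).
#' @export
westfall_young <- function(outcomes, data, covariates = TRUE,
                           n_resamples = 10000, seed, hc_type = c("HC1", "HC0")) {
  hc_type <- match.arg(hc_type)
  if (missing(seed)) stopf("seed is mandatory for the resampling stream")
  if (n_resamples < 1) stopf("n_resamples must be >= 1")
  if (n_resamples < 100) warning("n_resamples < 100: adjusted p-values will be coarse")
  Y <- as.matrix(as.data.frame(outcomes))
  if (anyNA(Y)) {
    bad <- colnames(Y)[colSums(is.na(Y)) > 0]
    stopf("family member(s) with undefined outcome values: %s", paste(bad, collapse = ", "))
  }
  m <- ncol(Y)
  n <- nrow(Y)
  stopifnot(n == nrow(data), m >= 1)
  data <- droplevels(as.data.frame(data))

  d <- as.numeric(as.character(data$arm) == "high")
  rhs <- "factor(site)"
  if (covariates) {
    covs <- intersect(itt_covariates(), names(data))
    if (anyNA(data[covs])) stopf("covariates contain missing values; run impute_covariates() first")
    rhs <- paste(c(rhs, covs), collapse = " + ")
  }
  X0 <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = as.data.frame(data))
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) stopf("collinear covariate design")
  Q <- qr.Q(qr0)
  K <- ncol(X0) + 1L  # full-model parameter count incl. treatment

  Yt <- Y - Q %*% crossprod(Q, Y)
  dt <- d - Q %*% crossprod(Q, d)
  if (sum(dt^2) < 1e-10) stopf("treatment indicator is collinear with the design")
  t_obs <- drop(engine_abs_t(Yt, matrix(dt, ncol = 1), n, K, hc_type))

  site <- data$site
  strata <- split(seq_len(n), site)
  B <- as.integer(n_resamples)
  Tstar <- matrix(0, B, m)
  with_seed(as.integer(seed), {
    chunk <- 500L
    done <- 0L
    while (done < B) {
      nb <- min(chunk, B - done)
      P <- matrix(0, n, nb)
      for (b in seq_len(nb)) {
        dp <- numeric(n)
        for (s in strata) dp[s] <- d[sample(s)]
        P[, b] <- dp
      }
      Dt <- P - Q %*% crossprod(Q, P)
      Tstar[done + seq_len(nb), ] <- engine_abs_t(Yt, Dt, n, K, hc_type)
      done <- done + nb
    }
  })

  p_perm <- colMeans(Tstar >= matrix(t_obs, B, m, byrow = TRUE))

  ord <- order(t_obs, decreasing = TRUE)
  Tord <- Tstar[, ord, drop = FALSE]
  if (m > 1) for (k in (m - 1):1) Tord[, k] <- pmax(Tord[, k], Tord[, k + 1])
  p_wy_ord <- vapply(seq_len(m), function(k) mean(Tord[, k] >= t_obs[ord[k]]), numeric(1))
  p_wy_ord <- cummax(p_wy_ord)
  p_wy <- numeric(m)
  p_wy[ord] <- p_wy_ord

  data.frame(outcome = colnames(Y), t = t_obs,
             p_unadjusted = 2 * stats::pnorm(-t_obs),
             p_perm = p_perm, p_wy = p_wy,
             stringsAsFactors = FALSE, row.names = NULL)
}
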