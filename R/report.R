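#' ITT results table over the eight band outcomes
#'
#' Runs the full analysis surface for the four absolute-power and four
#' relative-power outcomes: per-arm means (SD), OLS with site fixed effects
#' without and with covariates (robust SEs), the covariate-adjusted
#' standardized effect size, the unadjusted p-value, and the Westfall-Young
#' adjusted p-value with absolute and relative power treated as two separate
#' families.
#'
#' @param outcomes Data frame of per-child outcomes aligned to `data`, with
#'   columns `abs_theta`, `abs_alpha`, `abs_beta`, `abs_gamma`, `rel_theta`,
#'   `rel_alpha`, `rel_beta`, `rel_gamma`.
#' @param data Imputed analytic-sample cohort rows.
#' @param n_resamples Permutations for the Westfall-Young adjustment.
#' @param seed Seed for the resampling stream.
#' @param hc_type Robust covariance flavor.
#' @return Data frame, 8 rows: `outcome`, `mean_low`, `sd_low`, `mean_high`,
#'   `sd_high`, `coef_unadj`, `se_unadj`, `coef_adj`, `se_adj`,
#'   `effect_size`, `p_unadjusted`, `p_wy`, `n`.
#' @export
make_table2 <- function(outcomes, data, n_resamples = 10000, seed = 1L,
                        hc_type = "HC1") {
  wanted <- c(paste0("abs_", c("alpha", "beta", "gamma", "theta")),
              paste0("rel_", c("alpha", "beta", "gamma", "theta")))
  missing_o <- setdiff(wanted, names(outcomes))
  if (length(missing_o)) stopf("missing outcome column(s): %s", paste(missing_o, collapse = ", "))
  arm <- factor(as.character(data$arm), levels = c("low", "high"))

  families <- list(absolute = grep("^abs_", wanted, value = TRUE),
                   relative = grep("^rel_", wanted, value = TRUE))
  wy <- lapply(seq_along(families), function(i) {
    westfall_young(outcomes[families[[i]]], data, covariates = TRUE,
                   n_resamples = n_resamples, seed = as.integer(seed) + i,
                   hc_type = hc_type)
  })
  wy <- do.call(rbind, wy)

  rows <- lapply(wanted, function(o) {
    y <- outcomes[[o]]
    f0 <- fit_itt(y, data, covariates = FALSE, hc_type = hc_type, outcome_name = o)
    f1 <- fit_itt(y, data, covariates = TRUE, hc_type = hc_type, outcome_name = o)
    data.frame(
      outcome = o,
      mean_low = mean(y[arm == "low"]), sd_low = stats::sd(y[arm == "low"]),
      mean_high = mean(y[arm == "high"]), sd_high = stats::sd(y[arm == "high"]),
      coef_unadj = f0$coef, se_unadj = f0$se,
      coef_adj = f1$coef, se_adj = f1$se,
      effect_size = effect_size(f1),
      p_unadjusted = f1$p,
      p_wy = wy$p_wy[match(o, wy$outcome)],
      n = f1$n, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized-spectrum display data
#'
#' Tabulates the per-bin arm-mean z-scores and their difference (high minus
#' low) from [standardize_bins()] output, annotated with the band each bin
#' belongs to.
#'
#' @param std Output of [standardize_bins()].
#' @param bands Band definitions used for annotation.
#' @return Data frame with 48 rows: `freq_lo`, `band`, `z_low`, `z_high`,
#'   `diff`.
#' @export
fig1_data <- function(std, bands = default_bands()) {
  b <- check_bands_tile(bands)
  cur <- std$curves
  cur$band <- vapply(cur$freq_lo, function(f) {
    b$band[b$lo_hz <= f & f < b$hi_hz]
  }, character(1))
  cur[c("freq_lo", "band", "z_low", "z_high", "diff")]
}

#' Approximate 2-D scalp coordinates for the 10-20 montage
#'
#' Flattened head-circle coordinates (nose up, unit radius) for the 19 scalp
#' labels used here, for plotting topographic maps.
#'
#' @return Data frame: `channel`, `x`, `y`.
#' @export
montage_coords <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T7", "C3", "Cz", "C4", "T8",
                "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.42, 0, 0.42, 0.81,
          -1, -0.5, 0, 0.5, 1,
          -0.81, -0.42, 0, 0.42, 0.81, -0.31, 0.31),
    y = c(0.95, 0.95, 0.59, 0.55, 0.5, 0.55, 0.59,
          0, 0, 0, 0, 0,
          -0.59, -0.55, -0.5, -0.55, -0.59, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

#' Topographic map data: per-channel per-band mean power by arm
#'
#' Aggregates per-child channel-level band power into arm means per channel
#' and band, attaches 10-20 plotting coordinates, and flags
#' reference-adjacent temporal channels (whose values, when shown at all, are
#' interpolated from surrounding electrodes for visualization only).
#'
#' @param chan_bp Data frame of per-child channel band power: columns `id`,
#'   `channel`, `band`, `absolute`.
#' @param arm_lookup Data frame `id`, `arm` mapping children to arms.
#' @return Long data frame: `channel`, `band`, `arm`, `mean_power`, `x`,
#'   `y`, `reference_adjacent`.
#' @export
topomap_data <- function(chan_bp, arm_lookup) {
  coords <- montage_coords()
  unknown <- setdiff(unique(chan_bp$channel), coords$channel)
  if (length(unknown)) stopf("unknown montage label(s): %s", paste(unknown, collapse = ", "))
  chan_bp$arm <- as.character(arm_lookup$arm[match(chan_bp$id, arm_lookup$id)])
  agg <- stats::aggregate(absolute ~ channel + band + arm, data = chan_bp, FUN = mean)
  names(agg)[names(agg) == "absolute"] <- "mean_power"
  i <- match(agg$channel, coords$channel)
  agg$x <- coords$x[i]
  agg$y <- coords$y[i]
  agg$reference_adjacent <- agg$channel %in% c("T7", "T8")
  agg[order(agg$band, agg$arm, agg$channel), ]
}
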