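#' Dryness stopping rule for a weighing series
#'
#' Scans successive weighings in time order and declares the sample dry at
#' the first pair whose absolute relative weight change is strictly below
#' the threshold (0.5% in the emulated protocol).  The dry weight is the
#' later weighing of the first qualifying pair.  The criterion is relative,
#' so it is invariant to a uniform rescaling of all weights; weight
#' increases between weighings (possible under balance noise) are handled
#' through the absolute change.
#'
#' @param time Weighing times in hours, strictly increasing.
#' @param weight Weights in g, positive, same length as `time` (at least 2).
#'   Alternatively `time` may be a two-column data frame / matrix of
#'   `(time, weight)` with `weight` missing.
#' @param threshold Relative-change threshold (default 0.005).
#'
#' @return A list of class `"dryness_result"` with elements `is_dry`,
#'   `end_index` (index of the dry weighing, `NA` if never dry),
#'   `end_time`, `dry_weight` and `last_relative_change` (the relative
#'   change of the final pair examined).
#' @export
#' @examples
#' check_dryness(c(0, 24, 48, 72), c(10, 5, 3, 2.99))
check_dryness <- function(time, weight = NULL, threshold = 0.005) {
  if (is.null(weight)) {
    m <- as.data.frame(time)
    if (ncol(m) < 2L) abort_validation("`time` must provide time and weight columns")
    weight <- m[[2L]]
    time <- m[[1L]]
  }
  if (length(time) != length(weight))
    abort_validation("`time` and `weight` must have the same length")
  if (length(weight) < 2L)
    abort_validation("at least two weighings are needed to assess dryness")
  if (any(!is.finite(weight)) || any(weight <= 0))
    abort_validation("weights must be positive and finite")
  if (any(diff(time) <= 0))
    abort_validation("weighing times must be strictly increasing")
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)

  rel <- abs(diff(weight)) / weight[-length(weight)]
  hit <- which(rel < threshold)
  if (length(hit)) {
    i <- hit[1L] + 1L
    res <- list(is_dry = TRUE, end_index = i, end_time = time[i],
                dry_weight = weight[i], last_relative_change = rel[i - 1L])
  } else {
    res <- list(is_dry = FALSE, end_index = NA_integer_, end_time = NA_real_,
                dry_weight = NA_real_,
                last_relative_change = rel[length(rel)])
  }
  structure(res, class = "dryness_result")
}

#' @export
print.dryness_result <- function(x, ...) {
  if (x$is_dry)
    cat(sprintf("dry at weighing %d (t = %g h): dry weight %.4g g (last change %.3g%%)\n",
                x$end_index, x$end_time, x$dry_weight,
                100 * x$last_relative_change))
  else
    cat(sprintf("not dry: last relative change %.3g%%\n",
                100 * x$last_relative_change))
  invisible(x)
}

#' Gravimetric water content on a mass basis
#'
#' `wc = (Ww - Wd) / Ww`, the fraction of the wet weight lost on complete
#' dehydration.
#'
#' @param Ww Wet weight in g (before drying), positive.
#' @param Wd Dry weight in g (after drying), `0 <= Wd <= Ww`.
#' @return Fraction in `[0, 1]`.  Vectorized over `Ww`/`Wd`.
#' @export
#' @examples
#' mass_water_content(10, 2.92)  # 0.708
mass_water_content <- function(Ww, Wd) {
  if (any(!is.finite(Ww)) || any(Ww <= 0))
    abort_validation("`Ww` must be positive and finite")
  if (any(!is.finite(Wd)) || any(Wd < 0))
    abort_validation("`Wd` must be non-negative and finite")
  if (any(Wd > Ww))
    abort_validation("`Wd` exceeds `Ww`: evaporation cannot add mass")
  (Ww - Wd) / Ww
}

#' Gravimetric water content on a volume basis
#'
#' The water mass `Ww - Wd` is converted to a water volume through the
#' density of water and referred to the measured wet-sample volume:
#' `wc_volume = ((Ww - Wd) / rho_water) / Vw` (with g and cm^3 converted
#' internally to SI).  Measurement error can push the result above 1; such
#' values are returned as-is with a warning rather than clipped.
#'
#' @inheritParams mass_water_content
#' @param Vw Wet-sample volume in cm^3, positive.
#' @param rho_water Density of water in kg/m^3 (default 997).
#' @return Volume fraction of water (usually in `[0, 1]`).
#' @export
#' @examples
#' volume_water_content(10, 2.92, Vw = 9.44)
volume_water_content <- function(Ww, Wd, Vw, rho_water = RHO_WATER) {
  if (any(!is.finite(Vw)) || any(Vw <= 0))
    abort_validation("`Vw` must be positive and finite")
  check_number(rho_water, "rho_water", lower = 0, strict_lower = TRUE)
  wc_m <- mass_water_content(Ww, Wd)  # validates the weights
  m_water_kg <- (Ww - Wd) * 1e-3
  V_w_m3 <- Vw * 1e-6
  wc <- (m_water_kg / rho_water) / V_w_m3
  if (any(wc > 1))
    warning("volume-basis water content exceeds 1 for ",
            sum(wc > 1), " sample(s); kept as-is (measurement error)")
  wc
}

#' Aggregate per-sample water contents into a tissue summary
#'
#' Mass basis: mean and sample standard deviation across samples.  Volume
#' basis: mean across samples with a combined uncertainty
#' `sqrt(sd_across_samples^2 + u_instrument^2)`, where the instrument term
#' propagates, to first order, the balance readability (a uniform
#' half-width, taken as `readability / sqrt(3)` on each of `Ww` and `Wd`)
#' and the relative volume uncertainty through the volume-basis formula.
#' This propagation is a documented reconstruction of a standard
#' first-order rule, not a published formula.
#'
#' @param samples Data frame with one row per sample and columns `Ww`,
#'   `Wd`, `Vw` (g, g, cm^3).  Columns `wc_mass` / `wc_volume` are
#'   recomputed if absent.
#' @param tissue Tissue label for the summary row.
#' @param readability Balance readability in g.
#' @param volume_rel_uncertainty Relative standard uncertainty of the
#'   volume measurement.
#' @param rho_water Density of water in kg/m^3.
#'
#' @return A list of class `"water_content"` with the tissue label, the
#'   per-sample table, `wc_mass_mean`, `wc_mass_sd`, `wc_volume_mean`,
#'   `wc_volume_uncertainty`, `n_samples` and `single_sample` (flag set
#'   when only one sample is available, in which case the across-sample sd
#'   is reported as 0 with a warning).
#' @export
#' @examples
#' s <- data.frame(Ww = c(10, 10.2, 9.8), Wd = c(2.9, 3.0, 2.85),
#'                 Vw = c(9.4, 9.6, 9.2))
#' aggregate_tissue(s, tissue = "muscle")
aggregate_tissue <- function(samples, tissue = "tissue",
                             readability = 0.01,
                             volume_rel_uncertainty = 0.07,
                             rho_water = RHO_WATER) {
  if (!is.data.frame(samples) || nrow(samples) < 1L)
    abort_validation("`samples` must be a data frame with at least one row")
  if (!all(c("Ww", "Wd", "Vw") %in% names(samples)))
    abort_validation("`samples` needs columns Ww, Wd, Vw")
  samples$wc_mass <- mass_water_content(samples$Ww, samples$Wd)
  samples$wc_volume <- volume_water_content(samples$Ww, samples$Wd,
                                            samples$Vw, rho_water)
  n <- nrow(samples)
  single <- n == 1L
  if (single)
    warning("single sample for tissue '", tissue,
            "': across-sample sd reported as 0")
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0

  # first-order instrument term on the volume basis, averaged over samples
  u_w <- readability / sqrt(3)
  u_inst <- sqrt((u_w^2 + u_w^2) / (rho_water / 1000 * samples$Vw)^2 +
                   (samples$wc_volume * volume_rel_uncertainty)^2)

  structure(
    list(tissue = tissue,
         per_sample = samples,
         wc_mass_mean = mean(samples$wc_mass),
         wc_mass_sd = sd0(samples$wc_mass),
         wc_volume_mean = mean(samples$wc_volume),
         wc_volume_uncertainty = sqrt(sd0(samples$wc_volume)^2 +
                                        mean(u_inst)^2),
         n_samples = n,
         single_sample = single),
    class = "water_content")
}

#' @export
print.water_content <- function(x, ...) {
  cat(sprintf("%s: water content %.1f%% +/- %.2f%% (mass), %.1f%% +/- %.2f%% (volume), n = %d\n",
              x$tissue, 100 * x$wc_mass_mean, 100 * x$wc_mass_sd,
              100 * x$wc_volume_mean, 100 * x$wc_volume_uncertainty,
              x$n_samples))
  invisible(x)
}

#' Estimate per-tissue water content from weighing campaigns
#'
#' Runs the full dehydration analysis on a campaign data frame: for every
#' sample the dryness stopping rule ([check_dryness()]) determines the dry
#' weight, the wet weight is the weighing at time 0, and per-sample mass-
#' and volume-basis water contents are aggregated per tissue with
#' [aggregate_tissue()].  Samples that never satisfy the stopping rule are
#' dropped with a warning.
#'
#' @param campaigns Campaign data frame (see [read_campaigns()] for the
#'   column contract).
#' @param threshold Dryness threshold passed to [check_dryness()].
#' @inheritParams aggregate_tissue
#' @return A data frame with one row per tissue and columns `tissue`,
#'   `wc_mass_mean`, `wc_mass_sd`, `wc_vol_mean`, `wc_vol_unc`,
#'   `n_samples`.  The per-tissue `"water_content"` objects are attached
#'   as attribute `"details"`.
#' @export
estimate_water_content <- function(campaigns, threshold = 0.005,
                                   readability = 0.01,
                                   volume_rel_uncertainty = 0.07,
                                   rho_water = RHO_WATER) {
  cols <- c("tissue", "sample_id", "time_h", "weight_g", "volume_cm3")
  if (!is.data.frame(campaigns) || nrow(campaigns) == 0L)
    abort_validation("`campaigns` must be a non-empty data frame")
  if (!all(cols %in% names(campaigns)))
    abort_validation("`campaigns` must have columns %s",
                     paste(cols, collapse = ", "))

  tissues <- unique(campaigns$tissue)
  details <- vector("list", length(tissues))
  names(details) <- tissues
  rows <- vector("list", length(tissues))
  for (k in seq_along(tissues)) {
    sub <- campaigns[campaigns$tissue == tissues[k], , drop = FALSE]
    per <- lapply(split(sub, sub$sample_id), function(s) {
      s <- s[order(s$time_h), , drop = FALSE]
      dr <- check_dryness(s$time_h, s$weight_g, threshold)
      if (!dr$is_dry) return(NULL)
      data.frame(sample_id = s$sample_id[1L], Ww = s$weight_g[1L],
                 Wd = dr$dry_weight, Vw = s$volume_cm3[1L],
                 stringsAsFactors = FALSE)
    })
    dropped <- vapply(per, is.null, logical(1))
    if (any(dropped))
      warning(sum(dropped), " sample(s) of tissue '", tissues[k],
              "' never reached dryness and were dropped")
    per <- do.call(rbind, per[!dropped])
    if (is.null(per) || nrow(per) == 0L)
      abort_validation("no sample of tissue '%s' reached dryness", tissues[k])
    wc <- aggregate_tissue(per, tissue = tissues[k], readability = readability,
                           volume_rel_uncertainty = volume_rel_uncertainty,
                           rho_water = rho_water)
    details[[k]] <- wc
    rows[[k]] <- data.frame(tissue = tissues[k],
                            wc_mass_mean = wc$wc_mass_mean,
                            wc_mass_sd = wc$wc_mass_sd,
                            wc_vol_mean = wc$wc_volume_mean,
                            wc_vol_unc = wc$wc_volume_uncertainty,
                            n_samples = wc$n_samples,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Percentage-of-initial-weight series for one sample
#'
#' Normalizes a sample's weighing series by its initial (time 0) weight,
#' reproducing the percentage-weight-versus-time view of the drying
#' process.  The first value is exactly 100.
#'
#' @param campaign Data frame with columns `time_h` and `weight_g` for a
#'   single sample (extra columns are ignored).
#' @return Data frame with columns `time_h` and `percent`.
#' @export
#' @examples
#' percent_weight_series(data.frame(time_h = c(0, 24), weight_g = c(10, 5)))
percent_weight_series <- function(campaign) {
  if (!all(c("time_h", "weight_g") %in% names(campaign)))
    abort_validation("`campaign` needs columns time_h and weight_g")
  campaign <- campaign[order(campaign$time_h), , drop = FALSE]
  if (campaign$time_h[1L] != 0)
    abort_validation("the series must include the pre-oven weighing at t = 0")
  data.frame(time_h = campaign$time_h,
             percent = 100 * campaign$weight_g / campaign$weight_g[1L])
}
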