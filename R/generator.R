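#' Configuration for a synthetic weighing campaign
#'
#' Bundles and validates all parameters of the synthetic dehydration
#' experiment: a set of cubic tissue samples is weighed, dried in an oven,
#' and re-weighed on a fixed schedule until the weight stops changing.
#'
#' @param tissue_name Label for the tissue.
#' @param true_wc_mass True mass-basis water content of the tissue, a
#'   fraction in `[0, 1]`.  The generated dry weight is
#'   `Ww * (1 - true_wc_mass)`.
#' @param n_samples Number of samples cut from the tissue (the emulated
#'   protocol used 4 or 5).
#' @param initial_weight_mean Mean wet weight in g.  The default, 20 g,
#'   corresponds to a 2.5 x 2.5 x 3 cm cube at a density close to that of
#'   soft tissue.
#' @param initial_weight_cv Coefficient of variation of the wet weight
#'   across samples (dimensionless).
#' @param drying_time_constant Time constant of the exponential drying
#'   kinetics, in hours (see [drying_curve()]).
#' @param schedule Weighing times in hours; strictly increasing, starting
#'   at 0 (the pre-oven weighing), with at least two entries.
#' @param noise_sd Standard deviation of the additive Gaussian weighing
#'   noise in g, applied before quantization.
#' @param readability Balance readability in g (default 0.01 = 10 mg).
#' @param sample_density Tissue density in kg/m^3, used to derive the
#'   initial sample volume from the wet weight.
#' @param volume_rel_uncertainty Relative standard uncertainty of the
#'   volume measurement; the generated volume carries a multiplicative
#'   Gaussian error of this magnitude.
#' @param seed Integer seed; fixing it makes [simulate_campaigns()]
#'   bit-for-bit reproducible.
#'
#' @details The numeric defaults (densities, weights, noise, time
#'   constants) are synthetic assumptions chosen to be realistic for the
#'   emulated protocol; they are not measured values.  Per-tissue defaults
#'   are available through [tissue_presets()].
#'
#' @return An object of class `"campaign_config"` (a validated list).
#' @seealso [simulate_campaigns()], [tissue_presets()]
#' @export
#' @examples
#' campaign_config("muscle", true_wc_mass = 0.708, seed = 1)
campaign_config <- function(tissue_name,
                            true_wc_mass,
                            n_samples = 5L,
                            initial_weight_mean = 20,
                            initial_weight_cv = 0.10,
                            drying_time_constant = 15,
                            schedule = c(0, 24, 120, 216, 312, 408, 504),
                            noise_sd = 0.02,
                            readability = 0.01,
                            sample_density = 1060,
                            volume_rel_uncertainty = 0.07,
                            seed = NULL) {
  if (!is.character(tissue_name) || length(tissue_name) != 1L)
    abort_validation("`tissue_name` must be a single string")
  check_number(true_wc_mass, "true_wc_mass", lower = 0, upper = 1)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != round(n_samples))
    abort_validation("`n_samples` must be a positive integer")
  check_number(initial_weight_mean, "initial_weight_mean", lower = 0,
               strict_lower = TRUE)
  check_number(initial_weight_cv, "initial_weight_cv", lower = 0)
  check_number(drying_time_constant, "drying_time_constant", lower = 0,
               strict_lower = TRUE)
  if (!is.numeric(schedule) || length(schedule) < 2L)
    abort_validation(
      "`schedule` needs at least two weighing times (the dryness rule compares successive weighings)")
  if (schedule[1L] != 0)
    abort_validation("`schedule` must start at 0 (pre-oven weighing)")
  if (any(diff(schedule) <= 0))
    abort_validation("`schedule` must be strictly increasing")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(readability, "readability", lower = 0, strict_lower = TRUE)
  check_number(sample_density, "sample_density", lower = 0, strict_lower = TRUE)
  check_number(volume_rel_uncertainty, "volume_rel_uncertainty", lower = 0)
  if (!is.null(seed)) {
    check_number(seed, "seed")
    seed <- as.integer(seed)
  }
  structure(
    list(tissue_name = tissue_name,
         n_samples = as.integer(n_samples),
         true_wc_mass = true_wc_mass,
         initial_weight_mean = initial_weight_mean,
         initial_weight_cv = initial_weight_cv,
         drying_time_constant = drying_time_constant,
         schedule = as.numeric(schedule),
         noise_sd = noise_sd,
         readability = readability,
         sample_density = sample_density,
         volume_rel_uncertainty = volume_rel_uncertainty,
         seed = seed),
    class = "campaign_config")
}

#' @export
print.campaign_config <- function(x, ...) {
  cat("Synthetic weighing-campaign configuration\n")
  cat(sprintf("  tissue: %s  (true mass-basis water content %.3f)\n",
              x$tissue_name, x$true_wc_mass))
  cat(sprintf("  samples: %d, wet weight %.3g g (CV %.2g)\n",
              x$n_samples, x$initial_weight_mean, x$initial_weight_cv))
  cat(sprintf("  drying time constant: %g h; schedule (h): %s\n",
              x$drying_time_constant, paste(x$schedule, collapse = ", ")))
  cat(sprintf("  noise sd %g g, readability %g g, density %g kg/m^3\n",
              x$noise_sd, x$readability, x$sample_density))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Per-tissue generator presets
#'
#' Default campaign configurations for the five tissues of the emulated
#' dehydration experiment.  True mass-basis water contents follow the
#' measured tissue summaries (muscle 70.8%, liver 74.4%, heart 79.3%,
#' kidney 65.1%, fat 6.2%); densities are standard literature soft-tissue
#' values; drying time constants are chosen so that, noise-free, the
#' sub-0.5% stopping rule fires at 48 h for fat and at 120 h for the
#' high-water tissues, as observed in the emulated protocol.
#'
#' @param tissue Optional tissue name; if given, the preset
#'   `campaign_config` for that tissue alone is returned.
#' @param seed Optional seed stored in each returned configuration.
#'
#' @return A named list of [campaign_config()] objects, or a single one if
#'   `tissue` is supplied.
#' @export
#' @examples
#' names(tissue_presets())
#' tissue_presets("fat")$schedule
tissue_presets <- function(tissue = NULL, seed = NULL) {
  long <- c(0, 24, 120, 216, 312, 408, 504)
  spec <- list(
    muscle = list(wc = 0.708, density = 1060, tau = 15, sched = long, n = 5L),
    liver  = list(wc = 0.744, density = 1060, tau = 15, sched = long, n = 5L),
    heart  = list(wc = 0.793, density = 1060, tau = 15, sched = long, n = 5L),
    kidney = list(wc = 0.651, density = 1050, tau = 15, sched = long, n = 5L),
    fat    = list(wc = 0.062, density = 920,  tau = 7,
                  sched = c(0, 24, 48, 72), n = 4L))
  presets <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    campaign_config(nm, true_wc_mass = s$wc, n_samples = s$n,
                    initial_weight_mean = 18.75 * s$density / 1000,
                    drying_time_constant = s$tau, schedule = s$sched,
                    sample_density = s$density, seed = seed)
  })
  names(presets) <- names(spec)
  if (is.null(tissue)) return(presets)
  if (!tissue %in% names(presets))
    abort_validation("unknown tissue preset: '%s'", tissue)
  presets[[tissue]]
}

#' Simulate dehydration weighing campaigns
#'
#' Generates `n_samples` weighing campaigns with the statistical structure
#' assumed by the water-content analysis: each sample's wet weight is drawn
#' around the configured mean, the dry weight is set by the true mass-basis
#' water content, and every scheduled weighing is the noise-free
#' [drying_curve()] value plus Gaussian balance noise, quantized to the
#' balance readability.  The initial volume is derived from the wet weight
#' and the tissue density with a multiplicative Gaussian error.
#'
#' @param config A [campaign_config()].
#'
#' @return A data frame with one row per weighing and columns `tissue`,
#'   `sample_id`, `time_h`, `weight_g`, `volume_cm3` (volume repeated on
#'   every row of a sample).  The generating truth is attached as
#'   attribute `"truth"` (a data frame with the per-sample noise-free
#'   `Ww_true`, `Wd_true` and `true_wc_mass`) and the configuration as
#'   attribute `"config"`.  With a non-`NULL` seed the output is
#'   bit-for-bit reproducible.
#' @export
#' @examples
#' cfg <- campaign_config("muscle", true_wc_mass = 0.708, seed = 42)
#' head(simulate_campaigns(cfg))
simulate_campaigns <- function(config) {
  if (!inherits(config, "campaign_config"))
    abort_validation("`config` must be a `campaign_config` object")
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(config$seed)
  }
  n_t <- length(config$schedule)
  rows <- vector("list", config$n_samples)
  truth <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    Ww <- -1
    while (Ww <= 0)
      Ww <- stats::rnorm(1, config$initial_weight_mean,
                         config$initial_weight_cv * config$initial_weight_mean)
    Wd <- Ww * (1 - config$true_wc_mass)
    vol <- Ww / (config$sample_density / 1000) *
      (1 + stats::rnorm(1, 0, config$volume_rel_uncertainty))
    w_true <- drying_curve(config$schedule, Ww, max(Wd, 1e-12),
                           config$drying_time_constant)
    w_obs <- quantize_weight(
      pmax(w_true + stats::rnorm(n_t, 0, config$noise_sd), config$readability),
      config$readability)
    sid <- sprintf("%s_%02d", config$tissue_name, i)
    rows[[i]] <- data.frame(tissue = config$tissue_name, sample_id = sid,
                            time_h = config$schedule, weight_g = w_obs,
                            volume_cm3 = vol, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(sample_id = sid, Ww_true = Ww, Wd_true = Wd,
                             true_wc_mass = config$true_wc_mass,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "config") <- config
  out
}

#' Read and write weighing-campaign CSV files
#'
#' The campaign CSV dialect has the header
#' `tissue,sample_id,time_h,weight_g,volume_cm3`, one row per weighing,
#' with the initial volume repeated on every row of a sample.
#' `write_campaigns()` also records the generator configuration (including
#' the seed) as a YAML side-car file when the data frame carries one.
#'
#' @param campaigns Campaign data frame as produced by
#'   [simulate_campaigns()] or read back by `read_campaigns()`.
#' @param file Path of the CSV file.
#' @param config_file Path of the YAML metadata file, or `NULL` to skip
#'   writing it.  Defaults to `file` with a `.yaml` extension when the
#'   campaign carries a configuration.
#' @return `read_campaigns()` returns the campaign data frame;
#'   `write_campaigns()` invisibly returns `file`.
#' @export
write_campaigns <- function(campaigns, file,
                            config_file = paste0(sub("\\.csv$", "", file), ".yaml")) {
  cols <- c("tissue", "sample_id", "time_h", "weight_g", "volume_cm3")
  if (!all(cols %in% names(campaigns)))
    abort_validation("`campaigns` must have columns %s", paste(cols, collapse = ", "))
  utils::write.csv(campaigns[cols], file, row.names = FALSE, quote = FALSE)
  cfg <- attr(campaigns, "config")
  if (!is.null(cfg) && !is.null(config_file)) {
    meta <- unclass(cfg)
    meta$package_version <- as.character(utils::packageVersion("aquaperm"))
    yaml::write_yaml(meta, config_file)
  }
  invisible(file)
}

#' @rdname write_campaigns
#' @export
read_campaigns <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  cols <- c("tissue", "sample_id", "time_h", "weight_g", "volume_cm3")
  if (nrow(df) == 0L) abort_validation("campaign file '%s' is empty", file)
  if (!all(cols %in% names(df)))
    abort_validation("campaign file '%s' must have columns %s", file,
                     paste(cols, collapse = ", "))
  # allow the volume to be blank after the first row of each sample
  df$volume_cm3 <- stats::ave(df$volume_cm3, df$sample_id,
                              FUN = function(v) {
                                v[is.na(v)] <- v[!is.na(v)][1L]
                                v
                              })
  df[cols]
}

#' Read a campaign configuration from YAML
#'
#' @param file Path to a YAML file with `campaign_config` fields.
#' @return A [campaign_config()] object.
#' @export
read_campaign_config <- function(file) {
  y <- yaml::read_yaml(file)
  keep <- intersect(names(formals(campaign_config)), names(y))
  do.call(campaign_config, y[keep])
}
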