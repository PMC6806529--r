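#' Simulation configuration for the synthetic phenomic study
#'
#' Builds and validates the configuration that drives the synthetic-data
#' generators. The defaults describe the study conditions the pipeline is
#' designed for: a mutant library screened by kinetic imaging across a drug
#' dose series (0, 2.5, 5, 7.5, 15 ug/mL) in a fermentable ("glycolytic")
#' and a non-fermentable ("respiratory") medium, with 768 replicate reference
#' cultures per medium for standardization.
#'
#' Planted interaction effects are parameterised on the natural scale of the
#' L parameter: `effect_l_h` is the mean displacement, in hours, of the time
#' to half-carrying-capacity at the maximum dose for a planted enhancer
#' (suppressors are mirrored). Under the default intensity noise this places
#' planted effects far above the reference-interaction standard deviation, so
#' downstream z-scores separate cleanly from the null.
#'
#' @param n_strains number of mutant strains in the library.
#' @param n_reference_cultures total reference cultures per medium; they are
#'   split evenly across doses, and cultures sharing a replicate index across
#'   doses form a reference dose-series for the null interaction distribution.
#' @param doses ascending drug concentrations (ug/mL); the first must be 0.
#' @param media character vector of the two metabolic contexts.
#' @param sampling_interval imaging interval in hours.
#' @param horizon last imaging time in hours; must exceed the reference time
#'   to half-carrying-capacity at dose 0 in every medium, otherwise growth
#'   curves are unidentifiable and the configuration is rejected.
#' @param noise_sd additive Gaussian intensity noise (image-intensity units),
#'   truncated so intensities stay non-negative.
#' @param fraction_no_growth fraction of strains that are respiratory
#'   deficient (petite-like): flat baseline intensity in respiratory medium
#'   at every dose, normal growth in glycolytic medium.
#' @param fraction_enhancer,fraction_suppressor fractions of strains planted
#'   with positive / negative dose-by-gene interaction on L (enhancers are
#'   slowed more than the reference by the drug; suppressors less). Each
#'   planted strain also carries a matching opposite-signed K interaction.
#' @param effect_l_h mean |L displacement| at the maximum dose for planted
#'   strains, hours.
#' @param effect_sd_h between-strain SD of the planted effect size, hours.
#' @param effect_k_frac planted K interaction at the maximum dose, as a
#'   fraction of the reference carrying capacity (applied with sign opposite
#'   to the L effect: strains slowed more also plateau lower).
#' @param shift_sd_h SD of the per-strain baseline L offset at dose 0
#'   (the "shift" on the L scale), hours.
#' @param shift_sd_frac_k SD of the per-strain baseline K offset, as a
#'   fraction of the reference carrying capacity.
#' @param culture_sd_h,culture_sd_k culture-to-culture biological jitter of
#'   l and K (applied to every culture, including references).
#' @param reference named list, one entry per medium, each a numeric vector
#'   `c(K=, r=, l=)` of reference-strain logistic parameters at dose 0.
#' @param dose_slope_l named numeric, hours of L increase per ug/mL in the
#'   reference response, per medium.
#' @param dose_slope_k named numeric, K change (intensity units) per ug/mL in
#'   the reference response, per medium (negative: the drug lowers plateau).
#' @param replicates replicates per (strain, medium, dose) culture.
#' @param seed master seed; all sub-generators derive child seeds from it
#'   (see [child_seed()]).
#'
#' @return an object of class `"sim_config"` (a validated named list).
#' @seealso [simulate_phenomics()], [simulate_bundle()]
#' @export
sim_config <- function(n_strains = 96,
                       n_reference_cultures = 768,
                       doses = c(0, 2.5, 5, 7.5, 15),
                       media = c("glycolytic", "respiratory"),
                       sampling_interval = 2,
                       horizon = 48,
                       noise_sd = 2,
                       fraction_no_growth = 0.05,
                       fraction_enhancer = 0.10,
                       fraction_suppressor = 0.10,
                       effect_l_h = 3,
                       effect_sd_h = 0.5,
                       effect_k_frac = 0.10,
                       shift_sd_h = 0.75,
                       shift_sd_frac_k = 0.04,
                       culture_sd_h = 0.15,
                       culture_sd_k = 2,
                       reference = list(
                         glycolytic  = c(K = 200, r = 0.35, l = 12),
                         respiratory = c(K = 150, r = 0.20, l = 20)),
                       dose_slope_l = c(glycolytic = 0.30, respiratory = 0.45),
                       dose_slope_k = c(glycolytic = -3.0, respiratory = -2.5),
                       replicates = 1,
                       seed = 1) {
  cfg <- list(n_strains = as.integer(n_strains),
              n_reference_cultures = as.integer(n_reference_cultures),
              doses = as.numeric(doses), media = as.character(media),
              sampling_interval = sampling_interval, horizon = horizon,
              noise_sd = noise_sd,
              fraction_no_growth = fraction_no_growth,
              fraction_enhancer = fraction_enhancer,
              fraction_suppressor = fraction_suppressor,
              effect_l_h = effect_l_h, effect_sd_h = effect_sd_h,
              effect_k_frac = effect_k_frac,
              shift_sd_h = shift_sd_h, shift_sd_frac_k = shift_sd_frac_k,
              culture_sd_h = culture_sd_h, culture_sd_k = culture_sd_k,
              reference = reference,
              dose_slope_l = dose_slope_l, dose_slope_k = dose_slope_k,
              replicates = as.integer(replicates),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_strains < 1L) stop("n_strains must be >= 1")
  if (is.unsorted(cfg$doses, strictly = TRUE))
    stop("doses must be strictly ascending")
  if (cfg$doses[1] != 0) stop("the first dose must be 0 (untreated)")
  props <- c(cfg$fraction_no_growth, cfg$fraction_enhancer,
             cfg$fraction_suppressor)
  if (any(props < 0 | props > 1))
    stop("planted fractions must lie in [0, 1]")
  if (cfg$fraction_enhancer + cfg$fraction_suppressor + cfg$fraction_no_growth > 1)
    stop("planted fractions sum to more than 1")
  if (cfg$horizon <= cfg$sampling_interval)
    stop("horizon must exceed the sampling interval")
  if (length(cfg$media) < 1L) stop("at least one medium is required")
  missing_ref <- setdiff(cfg$media, names(cfg$reference))
  if (length(missing_ref))
    stop("no reference parameters for medium: ",
         paste(missing_ref, collapse = ", "))
  for (m in cfg$media) {
    p <- cfg$reference[[m]]
    if (any(!is.finite(p)) || p["K"] <= 0 || p["r"] <= 0 || p["l"] < 0)
      stop("invalid reference parameters for medium '", m, "'")
    if (cfg$horizon <= p["l"])
      stop("horizon (", cfg$horizon, " h) too short: reference strain in '",
           m, "' reaches K/2 only at ", p["l"],
           " h at dose 0; growth fits would be unidentifiable")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$replicates < 1L) stop("replicates must be >= 1")
  invisible(cfg)
}

#' Derive a child seed from the master seed
#'
#' Every sub-generator (time series, GO annotations, pharmacogenomic
#' datasets, clustering restarts) consumes its own seed derived
#' deterministically from the master seed, so adding a stage never perturbs
#' the random stream of another. The derivation is
#' `(seed + 104729 * k) mod (2^31 - 1)` with a fixed integer offset `k` per
#' stage (104729 is the 10000th prime).
#'
#' @param seed master integer seed.
#' @param k integer offset identifying the sub-generator.
#' @return an integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic phenomic study configuration\n")
  cat(sprintf("  strains: %d  (+%d reference cultures/medium)\n",
              x$n_strains, x$n_reference_cultures))
  cat(sprintf("  doses (ug/mL): %s\n", paste(x$doses, collapse = ", ")))
  cat(sprintf("  media: %s\n", paste(x$media, collapse = ", ")))
  cat(sprintf("  imaging: every %g h to %g h, noise sd %g\n",
              x$sampling_interval, x$horizon, x$noise_sd))
  cat(sprintf("  planted: %.0f%% enhancers, %.0f%% suppressors, %.0f%% no-growth\n",
              100 * x$fraction_enhancer, 100 * x$fraction_suppressor,
              100 * x$fraction_no_growth))
  cat(sprintf("  effect size: %g +/- %g h (L at max dose); seed %d\n",
              x$effect_l_h, x$effect_sd_h, x$seed))
  invisible(x)
}
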