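#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. The defaults are the
#' operational definitions used throughout: a long gastric-mill-timed IC burst
#' lasts at least 1 s; slow (gastric) burst detection uses a 2 s interspike
#' interval ceiling and fast (pyloric/gastropyloric) detection a 0.25 s
#' ceiling; a pyloric cycle counts as interrupted when its period reaches 150%
#' of the mean control period, control cycles being those with fewer than 10
#' IC spikes; phase profiles use 100 bins; clustering retains 10 principal
#' components and k = 3 clusters; bootstrap intervals use 10,000 resamples;
#' the phase significance heuristic uses alpha = 0.01 and requires at least 2
#' consecutive significant bins.
#'
#' @param long_ic_burst_min_s minimum duration (s) of a long IC burst.
#' @param slow_isi_ceiling_s ISI ceiling (s) for LG, DG and gastric-timed IC.
#' @param fast_isi_ceiling_s ISI ceiling (s) for pyloric/gastropyloric neurons.
#' @param interruption_threshold pyloric period, as a fraction of the mean
#'   control period, at or above which a cycle is flagged interrupted.
#' @param control_ic_spike_max a pyloric cycle is a control cycle when its IC
#'   spike count is strictly below this value.
#' @param phase_bins number of phase bins per gastric cycle.
#' @param n_pca_components principal components retained before clustering.
#' @param k_clusters number of k-means clusters.
#' @param bootstrap_iterations bootstrap resamples for confidence intervals.
#' @param alpha_phase significance threshold for per-bin phase comparisons.
#' @param min_consecutive_bins minimum run of significant bins to report.
#' @param rng_seed integer seed for stochastic stages.
#' @return An object of class `gm_config` (a named list).
#' @export
#' @examples
#' cfg <- gm_config()
#' cfg$slow_isi_ceiling_s
gm_config <- function(long_ic_burst_min_s = 1.0,
                      slow_isi_ceiling_s = 2.0,
                      fast_isi_ceiling_s = 0.25,
                      interruption_threshold = 1.5,
                      control_ic_spike_max = 10L,
                      phase_bins = 100L,
                      n_pca_components = 10L,
                      k_clusters = 3L,
                      bootstrap_iterations = 10000L,
                      alpha_phase = 0.01,
                      min_consecutive_bins = 2L,
                      rng_seed = 1L) {
  stopifnot(long_ic_burst_min_s > 0, slow_isi_ceiling_s > 0,
            fast_isi_ceiling_s > 0, interruption_threshold > 0,
            control_ic_spike_max > 0, phase_bins >= 2,
            n_pca_components >= 1, k_clusters >= 2,
            bootstrap_iterations >= 1, alpha_phase > 0, alpha_phase < 1,
            min_consecutive_bins >= 1)
  structure(list(
    long_ic_burst_min_s = long_ic_burst_min_s,
    slow_isi_ceiling_s = slow_isi_ceiling_s,
    fast_isi_ceiling_s = fast_isi_ceiling_s,
    interruption_threshold = interruption_threshold,
    control_ic_spike_max = as.integer(control_ic_spike_max),
    phase_bins = as.integer(phase_bins),
    n_pca_components = as.integer(n_pca_components),
    k_clusters = as.integer(k_clusters),
    bootstrap_iterations = as.integer(bootstrap_iterations),
    alpha_phase = alpha_phase,
    min_consecutive_bins = as.integer(min_consecutive_bins),
    rng_seed = as.integer(rng_seed)
  ), class = "gm_config")
}

#' @export
print.gm_config <- function(x, ...) {
  cat("Gastric mill analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Closed whitelist of identified STG neurons accepted by the package.
STG_NEURONS <- c("IC", "PD", "LPG", "LG", "DG", "AM", "VD", "MG", "GM")

#' Neuron-class-specific ISI ceiling
#'
#' Returns the interspike-interval ceiling used to delimit bursts for a given
#' neuron: 2 s for the slow gastric-mill neurons LG and DG, and for the IC
#' neuron when extracting its gastric-mill-timed (long) bursts; 0.25 s for all
#' other (pyloric and gastropyloric) neurons, including IC in pyloric context.
#'
#' @param neuron one of the identified STG neuron labels.
#' @param gastric_context logical; `TRUE` when extracting gastric-mill-timed
#'   bursts from the IC neuron.
#' @param cfg a [gm_config()].
#' @return ISI ceiling in seconds.
#' @export
isi_ceiling <- function(neuron, gastric_context = FALSE, cfg = gm_config()) {
  neuron <- match.arg(neuron, STG_NEURONS)
  if (neuron %in% c("LG", "DG")) return(cfg$slow_isi_ceiling_s)
  if (neuron == "IC" && isTRUE(gastric_context)) return(cfg$slow_isi_ceiling_s)
  cfg$fast_isi_ceiling_s
}
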