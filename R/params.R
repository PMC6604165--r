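#' Pipeline parameters
#'
#' Collects every tunable threshold of the peak-calling pipeline with the
#' method's defaults: candidates need at least `min_excess` more ChIP
#' fragments than depth-scaled input, shape filtering uses `shape_*`, and
#' acceptance requires both Poisson tests at `alpha_p`, both fold changes at
#' `min_fold`, and both BH-FDR values at `alpha_fdr`.
#'
#' @param min_excess Minimum ChIP-minus-scaled-input fragment excess for a
#'   candidate peak (inclusive). Default 4.
#' @param local_window_bp Width in bp of the window centered on the dyad used
#'   to estimate the local ChIP background rate. Default 10000.
#' @param effective_genome_size Mappable genome size in bp, used only to
#'   floor the background rate. Default 2.7e9 (human).
#' @param alpha_p P-value threshold applied to both Poisson tests. Default 0.01.
#' @param min_fold Fold-change threshold applied to both enrichment ratios.
#'   Default 4.
#' @param alpha_fdr Benjamini-Hochberg FDR threshold applied to both test
#'   families. Default 0.01.
#' @param pseudocount Pseudocount added to numerator and denominator of the
#'   fold changes. Default 0.5.
#' @param shape_n_bins Odd number of equal-width bins for within-nucleosome
#'   midpoint profiles. Default 21.
#' @param shape_a_max Maximum absolute asymmetry (center-of-mass offset in
#'   half-widths) before a peak is discarded as oblique. Default 0.5.
#' @param shape_d_min Minimum center-vs-flank coverage ratio before a peak is
#'   discarded as U-shaped. Default 0.5.
#' @param shape_min_reads Minimum profile total for the shape statistics to
#'   be evaluated; sparser candidates pass through to the statistical tests.
#'   Default 10.
#' @param tss_window_bp Half-width of the TSS window for occupancy summaries
#'   and histone codes. Default 2000.
#'
#' @return A list of class `nucpeak_params`.
#' @export
#' @examples
#' p <- nucpeak_params(min_excess = 6)
#' p$min_excess
nucpeak_params <- function(min_excess = 4,
                           local_window_bp = 10000,
                           effective_genome_size = 2.7e9,
                           alpha_p = 0.01,
                           min_fold = 4,
                           alpha_fdr = 0.01,
                           pseudocount = 0.5,
                           shape_n_bins = 21,
                           shape_a_max = 0.5,
                           shape_d_min = 0.5,
                           shape_min_reads = 10,
                           tss_window_bp = 2000) {
  stopifnot(min_excess >= 0, local_window_bp > 0, effective_genome_size > 0,
            alpha_p > 0, alpha_p <= 1, min_fold > 0, alpha_fdr > 0,
            alpha_fdr <= 1, pseudocount >= 0, shape_n_bins >= 3,
            shape_n_bins %% 2 == 1, shape_a_max >= 0, shape_d_min >= 0,
            shape_min_reads >= 0, tss_window_bp > 0)
  structure(list(min_excess = min_excess,
                 local_window_bp = local_window_bp,
                 effective_genome_size = effective_genome_size,
                 alpha_p = alpha_p,
                 min_fold = min_fold,
                 alpha_fdr = alpha_fdr,
                 pseudocount = pseudocount,
                 shape_n_bins = as.integer(shape_n_bins),
                 shape_a_max = shape_a_max,
                 shape_d_min = shape_d_min,
                 shape_min_reads = shape_min_reads,
                 tss_window_bp = tss_window_bp),
            class = "nucpeak_params")
}
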