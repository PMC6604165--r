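# Crosslinking-artifact shape filtering. Formaldehyde crosslinking can pile
# ChIP fragments off the dyad ("oblique") or at both nucleosome edges with a
# dip at the dyad ("U-shaped"); neither pattern is compatible with a genuine
# nucleosomal mark, whose fragment midpoints concentrate around the dyad.
# Both patterns are scored on a binned within-nucleosome midpoint profile.

#' Within-nucleosome midpoint profile
#'
#' Bins ChIP fragment midpoints falling inside the nucleosome interval into
#' `n_bins` equal-width bins. A midpoint exactly on an interior bin boundary
#' goes to the right bin; the last bin is closed. Intervals narrower than
#' `n_bins` bp get the largest odd bin count that fits.
#'
#' @param frags ChIP fragment table.
#' @param nuc One-row nucleosome (a row of a `nuc_map`).
#' @param n_bins Odd number of bins >= 3, default 21.
#' @return Integer vector of bin counts.
#' @export
profile_nucleosome <- function(frags, nuc, n_bins = 21) {
  if (n_bins < 3 || n_bins %% 2 == 0) stop("n_bins must be odd and >= 3")
  width <- nuc$end - nuc$start
  if (width < n_bins) {
    n_bins <- as.integer(width)
    if (n_bins %% 2 == 0) n_bins <- n_bins - 1L
    n_bins <- max(n_bins, 1L)
  }
  mids <- frags$midpoint[frags$chrom == nuc$chrom &
                         frags$midpoint >= nuc$start &
                         frags$midpoint < nuc$end]
  bw <- width / n_bins
  idx <- pmin(n_bins, floor((mids - nuc$start) / bw) + 1L)
  tabulate(idx, nbins = n_bins)
}

#' Asymmetry score of a midpoint profile
#'
#' Center-of-mass offset from the central bin in units of the half-width:
#' `(mean bin index - central index) / ((n_bins - 1) / 2)`. Symmetric
#' profiles score 0; all mass in the last bin scores +1, in the first -1.
#'
#' @param bins Profile vector with positive total.
#' @return Score in `[-1, 1]`.
#' @export
#' @examples
#' asymmetry_score(c(1, 2, 4, 2, 1))  # 0
#' asymmetry_score(c(0, 0, 1, 3, 6))  # 0.75
asymmetry_score <- function(bins) {
  total <- sum(bins)
  if (total <= 0) stop("asymmetry undefined for an empty profile")
  n <- length(bins)
  com <- sum(seq_len(n) * bins) / total
  center <- (n + 1) / 2
  (com - center) / ((n - 1) / 2)
}

#' Dip score (center-vs-flank coverage ratio) of a midpoint profile
#'
#' Mean count over the central third of bins divided by the mean over the
#' two flanking thirds. Around 1 for flat coverage, much less than 1 for a
#' U-shape, much greater than 1 for a dyad-peaked profile. Zero flank
#' coverage returns `Inf` (a dyad-peaked profile, never filtered as
#' U-shaped).
#'
#' @param bins Profile vector with positive total.
#' @return Non-negative ratio, possibly `Inf`.
#' @export
#' @examples
#' dip_score(c(6, 6, 6, 0, 0, 0, 6, 6, 6))  # 0: pure U
dip_score <- function(bins) {
  total <- sum(bins)
  if (total <= 0) stop("dip score undefined for an empty profile")
  n <- length(bins)
  f <- floor(n / 3)
  if (f < 1) return(Inf)
  center <- bins[(f + 1):(n - f)]
  flank <- c(bins[1:f], bins[(n - f + 1):n])
  if (mean(flank) == 0) return(Inf)
  mean(center) / mean(flank)
}

.shape_verdict <- function(bins, a_max, d_min, min_reads) {
  total <- sum(bins)
  if (total < min_reads)
    return(list(asymmetry = NA_real_, dip_ratio = NA_real_,
                verdict = "low_coverage_pass"))
  a <- asymmetry_score(bins)
  d <- dip_score(bins)
  verdict <- if (abs(a) > a_max) "oblique" else if (d < d_min) "u_shaped" else "ok"
  list(asymmetry = a, dip_ratio = d, verdict = verdict)
}

#' Score and apply the shape filters to candidate peaks
#'
#' Profiles each candidate nucleosome from the ChIP midpoints, scores
#' asymmetry and dip ratio, and removes candidates judged oblique
#' (`|asymmetry| > a_max`) or U-shaped (`dip_ratio < d_min`). Candidates
#' with fewer than `shape_min_reads` profile fragments are not evaluable
#' and pass through (`low_coverage_pass`) — the statistical tests judge
#' them. Filtering is idempotent and independent of candidate order.
#'
#' @param candidates Candidate table from [call_candidates()].
#' @param chip ChIP fragment table (source of the profiles).
#' @param params [nucpeak_params()] (keys `shape_n_bins`, `shape_a_max`,
#'   `shape_d_min`, `shape_min_reads`).
#' @return List with `passed` (candidate rows surviving the filter) and
#'   `verdicts` (per-candidate `nucleosome_id`, `asymmetry`, `dip_ratio`,
#'   `verdict`).
#' @export
apply_shape_filters <- function(candidates, chip, params = nucpeak_params()) {
  n <- nrow(candidates)
  verdicts <- data.frame(nucleosome_id = integer(n), asymmetry = numeric(n),
                         dip_ratio = numeric(n), verdict = character(n),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    nuc <- candidates[i, ]
    bins <- profile_nucleosome(chip, nuc, n_bins = params$shape_n_bins)
    v <- .shape_verdict(bins, params$shape_a_max, params$shape_d_min,
                        params$shape_min_reads)
    verdicts[i, ] <- data.frame(nuc$id, v$asymmetry, v$dip_ratio, v$verdict,
                                stringsAsFactors = FALSE)
  }
  keep <- verdicts$verdict %in% c("ok", "low_coverage_pass")
  list(passed = candidates[keep, , drop = FALSE], verdicts = verdicts)
}
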