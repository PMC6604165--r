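# Per-nucleosome counting and candidate calling. ChIP and input fragments
# are reduced to midpoints, assigned to nucleosomes by containment, and the
# candidate gate keeps nucleosomes with at least `min_excess` more ChIP
# fragments than depth-scaled input.

#' Count fragments and estimate backgrounds per nucleosome
#'
#' Builds the per-nucleosome count table the statistical tests run on: raw
#' ChIP and input fragment counts (midpoint containment), input counts
#' scaled by the depth ratio `N_chip / N_input`, the local ChIP background
#' expectation `lambda_local` (see [local_lambda()]) and the input-derived
#' expectation `lambda_input = max(input_count_scaled, lambda_floor)` where
#' the floor is the genome-wide ChIP rate over one nucleosome width.
#'
#' @param chip,input Fragment tables ([read_fragments()]).
#' @param map Nucleosome map.
#' @param params [nucpeak_params()].
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   truncate background windows; inferred from the data when omitted.
#' @return `data.frame` with one row per nucleosome: map columns plus
#'   `chip_count`, `input_count_raw`, `input_count_scaled`, `lambda_local`,
#'   `lambda_input`, `excess`.
#' @export
nucleosome_counts <- function(chip, input, map, params = nucpeak_params(),
                              chrom_sizes = NULL) {
  .check_map(map)
  if (nrow(map) == 0L) stop("empty nucleosome map")
  n_chip <- library_size(chip)
  n_input <- library_size(input)
  missing_chrom <- setdiff(unique(c(chip$chrom, input$chrom)), unique(map$chrom))
  if (length(missing_chrom))
    warning("fragments on chromosome(s) absent from the map skipped: ",
            paste(missing_chrom, collapse = ", "))
  chip_count <- tabulate(assign_fragments(chip, map), nbins = nrow(map))
  input_count <- tabulate(assign_fragments(input, map), nbins = nrow(map))
  scale <- n_chip / n_input
  out <- as.data.frame(map)
  out$chip_count <- chip_count
  out$input_count_raw <- input_count
  out$input_count_scaled <- input_count * scale
  out$lambda_local <- local_lambda(chip, map,
                                   window_bp = params$local_window_bp,
                                   effective_genome_size = params$effective_genome_size,
                                   chrom_sizes = chrom_sizes)
  width <- out$end - out$start
  floor_rate <- n_chip * width / params$effective_genome_size
  out$lambda_input <- pmax(out$input_count_scaled, floor_rate)
  out$excess <- out$chip_count - out$input_count_scaled
  attr(out, "n_chip") <- n_chip
  attr(out, "n_input") <- n_input
  out
}

#' Local ChIP background expectation per nucleosome
#'
#' For each nucleosome, counts ChIP fragment midpoints in a window of
#' `window_bp` centered on the dyad, excluding midpoints inside the
#' nucleosome's own interval, and rescales the count to the nucleosome width:
#' `lambda = count_outside * width / (window_len - own_len)`. Windows are
#' truncated at chromosome boundaries with the denominator renormalized, and
#' the result is floored at the genome-wide rate
#' `N_chip * width / effective_genome_size`.
#'
#' @param chip ChIP fragment table.
#' @param map Nucleosome map.
#' @param window_bp Window width (must be at least the nucleosome width).
#' @param effective_genome_size Mappable genome size for the floor.
#' @param chrom_sizes Optional named chromosome lengths; inferred as the max
#'   coordinate seen per chromosome when omitted.
#' @return Numeric vector of expectations, one per nucleosome.
#' @export
local_lambda <- function(chip, map, window_bp = 10000,
                         effective_genome_size = 2.7e9, chrom_sizes = NULL) {
  .check_map(map)
  width <- map$end - map$start
  if (any(window_bp < width)) stop("window_bp must be >= nucleosome width")
  n_chip <- library_size(chip)
  if (is.null(chrom_sizes)) {
    ends <- c(tapply(map$end, map$chrom, max),
              if (nrow(chip)) tapply(chip$end, chip$chrom, max))
    chrom_sizes <- tapply(unlist(ends), rep(names(ends), 1L), max)
  }
  lam <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    mi <- which(map$chrom == ch)
    mids <- chip$midpoint[chip$chrom == ch]
    clen <- chrom_sizes[[ch]]
    lo <- pmax(0, map$dyad[mi] - window_bp / 2)
    hi <- pmin(clen, map$dyad[mi] + window_bp / 2)
    in_win <- .count_in_windows(mids, lo, hi)
    own_lo <- pmax(lo, map$start[mi]); own_hi <- pmin(hi, map$end[mi])
    own <- .count_in_windows(mids, own_lo, own_hi)
    denom <- (hi - lo) - pmax(0, own_hi - own_lo)
    lam[mi] <- ifelse(denom > 0, (in_win - own) * width[mi] / denom, 0)
  }
  floor_rate <- n_chip * width / effective_genome_size
  pmax(lam, floor_rate)
}

#' Call candidate peaks by fragment excess
#'
#' Keeps nucleosomes whose ChIP count exceeds the depth-scaled input count
#' by at least `min_excess` fragments (boundary inclusive). This is the
#' initial peak call; shape filtering and the Poisson tests run downstream.
#'
#' @param counts Table from [nucleosome_counts()].
#' @param min_excess Minimum excess, default 4.
#' @return Subset of `counts` in (chrom, start) order.
#' @export
call_candidates <- function(counts, min_excess = 4) {
  cand <- counts[counts$excess >= min_excess, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
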