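# Double Poisson testing. Each shape-passed candidate is tested one-sided
# against two backgrounds — the local ChIP rate around the nucleosome and
# the depth-scaled input count — and must clear p-value, fold-change and
# BH-FDR thresholds in BOTH comparisons to be accepted.

#' Upper-tail Poisson p-value
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, computed via the survival function
#' at `k - 1` for numerical stability. `P(X >= 0) = 1` by construction.
#'
#' @param k Non-negative integer count(s).
#' @param lambda Positive Poisson mean(s).
#' @return P-value(s) in `(0, 1]`.
#' @export
#' @examples
#' poisson_upper_tail(1, 1)  # 1 - exp(-1)
poisson_upper_tail <- function(k, lambda) {
  if (any(k < 0)) stop("k must be >= 0")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (monotone, capped at 1), preserving input
#' order. Thin validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Adjusted vector of the same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

.reject_checks <- c("p_local", "p_input", "fold_local", "fold_input",
                    "fdr_local", "fdr_input")

#' Test shape-passed candidates against both backgrounds
#'
#' For every candidate of one mark: upper-tail Poisson p-values of the ChIP
#' count against `lambda_local` and against `lambda_input`; fold changes
#' `(chip + c) / (lambda_local + c)` and `(chip + c) / (input_scaled + c)`
#' with pseudocount `c`; BH-FDR computed separately over the local and the
#' input p-value families (all candidates of the mark genome-wide — shape-
#' rejected candidates are excluded upstream and never enter the families).
#' A peak is accepted iff both p-values are at most `alpha_p`, both folds at
#' least `min_fold` and both FDRs at most `alpha_fdr`; rejections carry the
#' first failed condition.
#'
#' @param candidates Shape-passed candidate table (from
#'   [apply_shape_filters()]`$passed`), i.e. rows of [nucleosome_counts()].
#' @param params [nucpeak_params()].
#' @return `candidates` with columns `p_local`, `p_input`, `fold_local`,
#'   `fold_input`, `fdr_local`, `fdr_input`, `status`, `reject_reason`.
#' @export
test_peaks <- function(candidates, params = nucpeak_params()) {
  df <- candidates
  n <- nrow(df)
  c0 <- params$pseudocount
  if (n == 0L) {
    for (cc in c("p_local", "p_input", "fold_local", "fold_input",
                 "fdr_local", "fdr_input")) df[[cc]] <- numeric(0)
    df$status <- character(0); df$reject_reason <- character(0)
    return(df)
  }
  df$p_local <- poisson_upper_tail(df$chip_count, df$lambda_local)
  df$p_input <- poisson_upper_tail(df$chip_count, df$lambda_input)
  df$fold_local <- (df$chip_count + c0) / (df$lambda_local + c0)
  df$fold_input <- (df$chip_count + c0) / (df$input_count_scaled + c0)
  df$fdr_local <- benjamini_hochberg(df$p_local)
  df$fdr_input <- benjamini_hochberg(df$p_input)
  fail <- cbind(p_local = df$p_local > params$alpha_p,
                p_input = df$p_input > params$alpha_p,
                fold_local = df$fold_local < params$min_fold,
                fold_input = df$fold_input < params$min_fold,
                fdr_local = df$fdr_local > params$alpha_fdr,
                fdr_input = df$fdr_input > params$alpha_fdr)
  first_fail <- apply(fail, 1L, function(z) {
    i <- which(z)
    if (length(i)) .reject_checks[i[1]] else NA_character_
  })
  df$status <- ifelse(is.na(first_fail), "accepted", "rejected")
  df$reject_reason <- first_fail
  df
}
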