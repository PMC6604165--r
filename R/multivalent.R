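# Multivalent mark joining. Because every mark is called against the same
# nucleosome map, per-mark calls join exactly on nucleosome id; a
# nucleosome's category is its accepted mark set rendered canonically, with
# the field's named aliases for the dominant active combinations.

.category_aliases <- c("H3K4me3+H3K9ac+H3K27ac" = "T",
                       "H3K4me3+H3K9ac" = "D",
                       "H3K4me3" = "A")

#' Canonical category label for a mark set
#'
#' Marks are sorted into the canonical mark order (see [histone_marks()];
#' unknown marks follow alphabetically) and joined with "+". Three sets have
#' field aliases: T = H3K4me3/H3K9ac/H3K27ac, D = H3K4me3/H3K9ac,
#' A = H3K4me3.
#'
#' @param marks Character vector (one set) or list of such vectors.
#' @param mark_order Canonical ordering of mark names.
#' @return Character label(s).
#' @export
#' @examples
#' category_label(c("H3K27ac", "H3K4me3", "H3K9ac"))  # "T"
category_label <- function(marks, mark_order = histone_marks()) {
  if (!is.list(marks)) marks <- list(marks)
  vapply(marks, function(m) {
    if (length(m) == 0L) stop("category requires a non-empty mark set")
    m <- unique(m)
    lev <- c(mark_order, sort(setdiff(m, mark_order)))
    key <- paste(m[order(match(m, lev))], collapse = "+")
    if (key %in% names(.category_aliases)) .category_aliases[[key]] else key
  }, character(1))
}

#' Join accepted per-mark calls into multivalent calls per nucleosome
#'
#' @param accepted Named list: mark name -> vector of accepted nucleosome
#'   ids (all against the same map).
#' @param map The shared nucleosome map.
#' @return `data.frame` with one row per nucleosome carrying at least one
#'   mark: `nucleosome_id`, `chrom`, `start`, `end`, `dyad`, `marks`
#'   ("+"-joined canonical set), `category`, `n_marks`.
#' @export
join_marks <- function(accepted, map) {
  .check_map(map)
  ids <- unlist(accepted, use.names = FALSE)
  if (length(ids) && any(!ids %in% map$id))
    stop("accepted ids outside the nucleosome map: ",
         paste(head(setdiff(ids, map$id), 5), collapse = ", "))
  per_id <- split(rep(names(accepted), lengths(accepted)), ids)
  if (length(per_id) == 0L)
    return(data.frame(nucleosome_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(), dyad = numeric(),
                      marks = character(), category = character(),
                      n_marks = integer(), stringsAsFactors = FALSE))
  uid <- as.integer(names(per_id))
  mark_sets <- lapply(per_id, unique)
  m <- map[match(uid, map$id), ]
  out <- data.frame(nucleosome_id = uid, chrom = m$chrom, start = m$start,
                    end = m$end, dyad = m$dyad,
                    marks = vapply(mark_sets, function(s)
                      paste(s[order(match(s, c(histone_marks(), sort(s))))],
                            collapse = "+"), character(1)),
                    category = category_label(mark_sets),
                    n_marks = lengths(mark_sets),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nucleosomes whose dyad lies within a window of any TSS
#' @keywords internal
.tss_proximal <- function(map, genes, window_bp) {
  prox <- logical(nrow(map))
  for (ch in unique(genes$chrom)) {
    mi <- which(map$chrom == ch)
    if (!length(mi)) next
    tss <- sort(genes$tss[genes$chrom == ch])
    # nearest TSS distance via findInterval on the sorted TSS vector
    d <- map$dyad[mi]
    idx <- findInterval(d, tss)
    lo <- ifelse(idx >= 1, d - tss[pmax(idx, 1)], Inf)
    hi <- ifelse(idx < length(tss), tss[pmin(idx + 1, length(tss))] - d, Inf)
    prox[mi] <- pmin(lo, hi) <= window_bp
  }
  prox
}

#' Genome-wide and TSS-proximal occupancy per category
#'
#' Counts nucleosomes per multivalent category over the whole map and within
#' `window_bp` of any TSS (dyad distance, inclusive). Genome-wide fractions
#' use the map size as denominator; near-TSS fractions use the number of
#' TSS-proximal nucleosomes.
#'
#' @param calls Multivalent calls from [join_marks()].
#' @param map Nucleosome map.
#' @param genes Gene table from [read_genes()].
#' @param window_bp TSS window half-width, default 2000.
#' @return `data.frame`: `category`, `n_genome`, `frac_genome`, `n_tss`,
#'   `frac_tss`, plus attributes `n_nucleosomes` and `n_tss_proximal`.
#' @export
occupancy_summary <- function(calls, map, genes, window_bp = 2000) {
  .check_map(map)
  prox <- .tss_proximal(map, genes, window_bp)
  n_prox <- sum(prox)
  cats <- sort(unique(calls$category))
  call_prox <- prox[match(calls$nucleosome_id, map$id)]
  out <- data.frame(category = cats,
                    n_genome = as.integer(table(factor(calls$category, cats))),
                    stringsAsFactors = FALSE)
  out$frac_genome <- out$n_genome / nrow(map)
  out$n_tss <- as.integer(table(factor(calls$category[call_prox], cats)))
  out$frac_tss <- if (n_prox > 0) out$n_tss / n_prox else 0
  attr(out, "n_nucleosomes") <- nrow(map)
  attr(out, "n_tss_proximal") <- n_prox
  out
}
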