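# Interval primitives. All coordinates are 0-based half-open (BED
# convention); the nucleosome map is the fixed coordinate system every later
# stage joins on, so it is sorted, overlap-trimmed and given stable ids at
# construction time.

#' Construct a fragment table
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `midpoint`
#'   where `midpoint = floor((start + end) / 2)`.
#' @export
#' @examples
#' fragments("chr1", 100, 300)$midpoint  # 200
fragments <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(end <= start))
    stop("fragments require 0 <= start < end")
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             midpoint = floor((start + end) / 2),
             stringsAsFactors = FALSE)
}

#' Construct a nucleosome map
#'
#' Sorts calls by (chrom, start), trims overlapping intervals at the midpoint
#' of the overlap so the map partitions covered bases (guaranteeing each
#' fragment midpoint lands in at most one nucleosome), drops intervals
#' emptied by trimming, and assigns stable integer ids `1..n` in coordinate
#' order. Dyads falling outside their trimmed interval are reset to the
#' interval midpoint.
#'
#' @param chrom,start,end Interval vectors, 0-based half-open.
#' @param dyad Optional dyad positions; defaults to interval midpoints.
#' @param occupancy Optional numeric MNase support per nucleosome.
#' @return A `data.frame` of class `nuc_map` with columns `id`, `chrom`,
#'   `start`, `end`, `dyad`, `occupancy`.
#' @export
#' @examples
#' m <- nucleosome_map(c("chr1", "chr1"), c(100, 200), c(250, 350))
#' m[, c("start", "end")]  # trimmed to [100,225) and [225,350)
nucleosome_map <- function(chrom, start, end, dyad = NULL, occupancy = NA_real_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(end <= start))
    stop("nucleosome intervals require 0 <= start < end")
  if (is.null(dyad)) dyad <- floor((start + end) / 2)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   dyad = as.numeric(dyad),
                   occupancy = rep_len(as.numeric(occupancy), length(start)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  # trim overlaps at the overlap midpoint, per chromosome
  if (nrow(df) > 1L) {
    for (i in seq_len(nrow(df) - 1L)) {
      j <- i + 1L
      if (df$chrom[i] == df$chrom[j] && df$start[j] < df$end[i]) {
        cut <- floor((df$start[j] + min(df$end[i], df$end[j])) / 2)
        cut <- max(df$start[i] + 1, min(cut, df$end[j] - 1))
        df$end[i] <- min(df$end[i], cut)
        df$start[j] <- max(df$start[j], cut)
      }
    }
    keep <- df$end > df$start
    if (!all(keep)) {
      warning(sum(!keep), " nucleosome call(s) emptied by overlap trimming; dropped")
      df <- df[keep, , drop = FALSE]
    }
  }
  off <- df$dyad < df$start | df$dyad >= df$end
  df$dyad[off] <- floor((df$start[off] + df$end[off]) / 2)
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df[, c("id", "chrom", "start", "end", "dyad", "occupancy")],
            class = c("nuc_map", "data.frame"))
}

.check_map <- function(map) {
  if (!inherits(map, "nuc_map")) stop("not a nucleosome map; use nucleosome_map()")
  o <- order(map$chrom, map$start)
  if (!identical(o, seq_len(nrow(map)))) stop("nucleosome map is unsorted")
  invisible(map)
}

#' Assign fragments to nucleosomes by midpoint containment
#'
#' A fragment belongs to the nucleosome whose half-open interval contains its
#' midpoint. Because the map partitions covered bases, each fragment maps to
#' at most one nucleosome; fragments whose midpoint is outside every
#' nucleosome (or on a chromosome absent from the map) get `NA`. The lookup
#' is a per-chromosome binary search over sorted interval starts.
#'
#' @param frags Fragment table from [fragments()] or [read_fragments()].
#' @param map Nucleosome map from [nucleosome_map()] or
#'   [read_nucleosome_map()].
#' @return Integer vector of nucleosome ids (or `NA`) parallel to `frags`.
#' @export
assign_fragments <- function(frags, map) {
  .check_map(map)
  if (nrow(map) == 0L) stop("empty nucleosome map")
  out <- rep(NA_integer_, nrow(frags))
  for (ch in unique(frags$chrom)) {
    fi <- which(frags$chrom == ch)
    mi <- which(map$chrom == ch)
    if (length(mi) == 0L) next
    idx <- findInterval(frags$midpoint[fi], map$start[mi])
    hit <- idx > 0L
    hit[hit] <- frags$midpoint[fi][hit] < map$end[mi][idx[hit]]
    out[fi[hit]] <- map$id[mi[idx[hit]]]
  }
  out
}

# count of values in x (sorted not required) falling in [lo, hi) per query;
# lo, hi are parallel vectors. Used for window counting.
.count_in_windows <- function(x, lo, hi) {
  xs <- sort(x)
  findInterval(hi - 1e-9, xs) - findInterval(lo - 1e-9, xs)
}
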