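# Independent brute-force oracles. Each one re-derives a pipeline quantity
# by exhaustive scanning or direct summation, sharing no code with the
# implementation it checks.

# P(X >= k) by direct series summation with the Poisson term recurrence
brute_pois_upper <- function(k, lambda) {
  term <- exp(-lambda)  # P(X = 0)
  i <- 0
  total <- if (k <= 0) term else 0
  repeat {
    i <- i + 1
    term <- term * lambda / i
    if (i >= k) total <- total + term
    if (i > k && term < 1e-18) break
    if (i > 10000) break
  }
  min(1, total)
}

# BH step-up executed by hand: adjusted_(i) = min_{j >= i} p_(j) * m / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ps[i:m] * m / (i:m)[seq_len(m - i + 1)])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# fragment -> nucleosome by scanning every nucleosome for containment
brute_assign <- function(frags, map) {
  vapply(seq_len(nrow(frags)), function(i) {
    hit <- which(map$chrom == frags$chrom[i] &
                 map$start <= frags$midpoint[i] &
                 frags$midpoint[i] < map$end)
    if (length(hit)) map$id[hit[1]] else NA_integer_
  }, integer(1))
}

brute_count <- function(frags, map) {
  a <- brute_assign(frags, map)
  vapply(map$id, function(id) sum(a == id, na.rm = TRUE), integer(1))
}

# local background by direct summation over all chip midpoints
brute_local_lambda <- function(chip, map, window_bp, egs, chrom_len) {
  n_chip <- nrow(chip)
  vapply(seq_len(nrow(map)), function(i) {
    nuc <- map[i, ]
    lo <- max(0, nuc$dyad - window_bp / 2)
    hi <- min(chrom_len, nuc$dyad + window_bp / 2)
    mids <- chip$midpoint[chip$chrom == nuc$chrom]
    in_win <- sum(mids >= lo & mids < hi)
    own <- sum(mids >= max(lo, nuc$start) & mids < min(hi, nuc$end))
    width <- nuc$end - nuc$start
    denom <- (hi - lo) - max(0, min(hi, nuc$end) - max(lo, nuc$start))
    max(if (denom > 0) (in_win - own) * width / denom else 0,
        n_chip * width / egs)
  }, numeric(1))
}

# per-gene code slots by scanning every nucleosome
brute_codes <- function(calls, map, genes, window_bp) {
  out <- list()
  for (g in seq_len(nrow(genes))) {
    gi <- genes[g, ]
    rows <- NULL
    for (i in seq_len(nrow(map))) {
      if (map$chrom[i] != gi$chrom) next
      if (abs(map$dyad[i] - gi$tss) > window_bp) next
      off <- if (gi$strand == "+") map$dyad[i] - gi$tss else gi$tss - map$dyad[i]
      cat <- calls$category[calls$nucleosome_id == map$id[i]]
      if (length(cat) == 0) cat <- "unmarked"
      rows <- rbind(rows, data.frame(gene_id = gi$gene_id,
                                     nucleosome_id = map$id[i],
                                     offset_bp = off,
                                     side = if (off >= 0) "down" else "up",
                                     category = cat,
                                     stringsAsFactors = FALSE))
    }
    if (!is.null(rows)) out[[g]] <- rows[order(rows$offset_bp), ]
  }
  do.call(rbind, out)
}

brute_occupancy <- function(calls, map, genes, window_bp) {
  prox <- vapply(seq_len(nrow(map)), function(i)
    any(genes$chrom == map$chrom[i] &
          abs(genes$tss - map$dyad[i]) <= window_bp), logical(1))
  cats <- sort(unique(calls$category))
  data.frame(
    category = cats,
    n_genome = vapply(cats, function(cc) sum(calls$category == cc), integer(1)),
    n_tss = vapply(cats, function(cc)
      sum(calls$category == cc &
            prox[match(calls$nucleosome_id, map$id)]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
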