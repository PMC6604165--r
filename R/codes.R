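# TSS-anchored histone codes: for each gene, the strand-oriented string of
# per-nucleosome categories in a window around the TSS, the per-category
# upstream/downstream counts, a fixed-width one-hot featurization, k-means
# clustering of the patterns, and correlation of mark counts with
# expression.

#' Extract histone codes around gene TSSs
#'
#' For every gene, takes the nucleosomes whose dyad falls within
#' `[tss - window_bp, tss + window_bp]` (inclusive), orders them 5' to 3' in
#' the direction of transcription, and labels each slot with the
#' nucleosome's multivalent category or `"unmarked"`. A dyad exactly at the
#' TSS counts as downstream. Genes whose chromosome is absent from the map
#' yield zero slots and are flagged.
#'
#' @param calls Multivalent calls from [join_marks()].
#' @param map Nucleosome map the calls were made against.
#' @param genes Gene table from [read_genes()].
#' @param window_bp Window half-width, default 2000.
#' @return Object of class `histone_codes`: list with `slots` (long table:
#'   `gene_id`, `slot` 1..L in transcription order, `nucleosome_id`,
#'   `offset_bp` signed dyad-to-TSS distance, positive downstream, `side`
#'   up/down, `category`) and `genes` (`gene_id`, `strand`, `n_slots`,
#'   `n_upstream`, `n_downstream`, `flagged`).
#' @export
extract_codes <- function(calls, map, genes, window_bp = 2000) {
  .check_map(map)
  cat_by_id <- setNames(calls$category, calls$nucleosome_id)
  slot_rows <- vector("list", nrow(genes))
  gene_rows <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gi <- genes[g, ]
    mi <- which(map$chrom == gi$chrom &
                map$dyad >= gi$tss - window_bp &
                map$dyad <= gi$tss + window_bp)
    flagged <- !gi$chrom %in% map$chrom
    if (length(mi)) {
      # offset in transcription direction: positive = downstream of TSS
      off <- if (gi$strand == "+") map$dyad[mi] - gi$tss else gi$tss - map$dyad[mi]
      o <- order(off)
      mi <- mi[o]; off <- off[o]
      side <- ifelse(off >= 0, "down", "up")  # dyad at TSS -> downstream
      cat <- cat_by_id[as.character(map$id[mi])]
      cat[is.na(cat)] <- "unmarked"
      slot_rows[[g]] <- data.frame(gene_id = gi$gene_id,
                                   slot = seq_along(mi),
                                   nucleosome_id = map$id[mi],
                                   offset_bp = off, side = side,
                                   category = unname(cat),
                                   stringsAsFactors = FALSE)
    }
    n_up <- if (length(mi)) sum(slot_rows[[g]]$side == "up") else 0L
    gene_rows[[g]] <- data.frame(gene_id = gi$gene_id, strand = gi$strand,
                                 n_slots = length(mi), n_upstream = n_up,
                                 n_downstream = length(mi) - n_up,
                                 flagged = flagged, stringsAsFactors = FALSE)
  }
  structure(list(slots = do.call(rbind, slot_rows),
                 genes = do.call(rbind, gene_rows)),
            class = "histone_codes")
}

#' Per-gene category counts upstream/downstream of the TSS
#'
#' @param codes [extract_codes()] result.
#' @param categories Categories to count; defaults to all observed marked
#'   categories. The pseudo-category `"codes"` (always included) counts all
#'   marked slots regardless of category.
#' @return `data.frame`: `gene_id`, `category`, `up`, `down`, `total`, with
#'   one row per gene x category (zero-filled).
#' @export
code_counts <- function(codes, categories = NULL) {
  s <- codes$slots
  if (is.null(s)) s <- data.frame(gene_id = character(), side = character(),
                                  category = character())
  marked <- s[s$category != "unmarked", , drop = FALSE]
  if (is.null(categories)) categories <- sort(unique(marked$category))
  categories <- union(categories, "codes")
  gene_ids <- codes$genes$gene_id
  out <- expand.grid(gene_id = gene_ids, category = categories,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cnt <- function(rows) {
    up <- table(factor(rows$gene_id[rows$side == "up"], gene_ids))
    down <- table(factor(rows$gene_id[rows$side == "down"], gene_ids))
    list(up = as.integer(up), down = as.integer(down))
  }
  out$up <- 0L; out$down <- 0L
  for (cc in categories) {
    rows <- if (cc == "codes") marked else marked[marked$category == cc, ]
    k <- cnt(rows)
    sel <- out$category == cc
    out$up[sel] <- k$up[match(out$gene_id[sel], gene_ids)]
    out$down[sel] <- k$down[match(out$gene_id[sel], gene_ids)]
  }
  out$total <- out$up + out$down
  out[order(out$gene_id, out$category), ]
}

#' Fixed-width one-hot code matrix for clustering
#'
#' Keeps the `slots_per_side` nucleosomes nearest the TSS on each side (in
#' transcription order), padding missing slots with `"absent"`, and one-hot
#' encodes each slot over the category alphabet. Column order is
#' deterministic: slot u<S>..u1, d1..d<S>, each expanded alphabetically over
#' the alphabet.
#'
#' @param codes [extract_codes()] result.
#' @param slots_per_side Slots kept each side of the TSS, default 15.
#' @param alphabet Category alphabet; defaults to categories observed in the
#'   codes plus `"unmarked"` and `"absent"`.
#' @return Numeric matrix, one row per gene (rownames = gene ids); each
#'   slot block has exactly one 1.
#' @export
build_code_matrix <- function(codes, slots_per_side = 15, alphabet = NULL) {
  s <- codes$slots
  if (is.null(alphabet))
    alphabet <- sort(unique(c(if (!is.null(s)) s$category, "unmarked")))
  alphabet <- union(alphabet, "absent")
  gene_ids <- codes$genes$gene_id
  S <- slots_per_side
  slot_names <- c(paste0("u", S:1), paste0("d", 1:S))
  lab <- matrix("absent", nrow = length(gene_ids), ncol = 2 * S,
                dimnames = list(gene_ids, slot_names))
  if (!is.null(s)) {
    for (g in seq_along(gene_ids)) {
      rows <- s[s$gene_id == gene_ids[g], , drop = FALSE]
      up <- rows[rows$side == "up", , drop = FALSE]
      down <- rows[rows$side == "down", , drop = FALSE]
      # nearest-to-TSS slots: upstream rows are ordered ..., -2, -1
      up <- tail(up, S); down <- head(down, S)
      if (nrow(up)) lab[g, (S - nrow(up) + 1):S] <- up$category
      if (nrow(down)) lab[g, (S + 1):(S + nrow(down))] <- down$category
    }
  }
  cols <- as.vector(outer(sort(alphabet), slot_names,
                          function(a, sl) paste0(sl, ".", a)))
  cols <- cols[order(match(sub("\\..*", "", cols), slot_names))]
  mat <- matrix(0, nrow = length(gene_ids), ncol = length(cols),
                dimnames = list(gene_ids, cols))
  for (j in seq_len(2 * S))
    mat[cbind(seq_along(gene_ids),
              match(paste0(slot_names[j], ".", lab[, j]), cols))] <- 1
  mat
}

#' Cluster histone-code patterns by k-means
#'
#' Runs `stats::kmeans` on the one-hot code matrix with a fixed seed and
#' `nstart` restarts, then renumbers cluster labels by descending size so
#' reports are stable.
#'
#' @param mat Matrix from [build_code_matrix()].
#' @param k Number of clusters, default 13.
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @param nstart Random restarts, default 10.
#' @return `data.frame` `gene_id`, `cluster`, with attributes `sizes` and
#'   `fractions` (per renumbered cluster).
#' @export
cluster_codes <- function(mat, k = 13, seed = 1, nstart = 10) {
  if (k < 2) stop("k must be >= 2")
  n_distinct <- nrow(unique(mat))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the ", n_distinct, " distinct code rows")
  set.seed(seed)
  km <- kmeans(mat, centers = k, nstart = nstart, iter.max = 100)
  sizes <- table(km$cluster)
  relabel <- setNames(rank(-as.integer(sizes), ties.method = "first"),
                      names(sizes))
  cluster <- as.integer(relabel[as.character(km$cluster)])
  out <- data.frame(gene_id = rownames(mat), cluster = cluster,
                    stringsAsFactors = FALSE)
  new_sizes <- table(factor(cluster, levels = seq_len(k)))
  attr(out, "sizes") <- as.integer(new_sizes)
  attr(out, "fractions") <- as.numeric(new_sizes) / nrow(mat)
  out
}

#' Relate mark counts near the TSS to gene expression
#'
#' Per gene: counts of each requested category (and of all marked slots,
#' `codes`) upstream/downstream/total, joined with expression. When cluster
#' assignments are supplied, per-cluster medians of expression and of each
#' count are computed, along with Spearman correlations between
#' cluster-median expression and cluster-median counts for T and codes
#' (up, down, total) — the quantities the method uses to ask whether
#' downstream trivalent marks track transcription.
#'
#' @param codes [extract_codes()] result.
#' @param expression `data.frame` `gene_id`, `rpkm` ([read_expression()]).
#' @param clusters Optional [cluster_codes()] result.
#' @param categories Categories to count, default `c("T", "D", "A")`.
#' @return List: `per_gene` (wide count table with `rpkm`), `per_cluster`
#'   (cluster medians, or `NULL`), `correlations` (`data.frame` `feature`,
#'   `spearman_rho`, or `NULL`), `n_missing_expression`.
#' @export
count_marks_vs_expression <- function(codes, expression, clusters = NULL,
                                      categories = c("T", "D", "A")) {
  counts <- code_counts(codes, categories = categories)
  wide <- codes$genes[, "gene_id", drop = FALSE]
  for (cc in union(categories, "codes")) {
    sub <- counts[counts$category == cc, ]
    i <- match(wide$gene_id, sub$gene_id)
    for (side in c("up", "down", "total"))
      wide[[paste0(cc, "_", side)]] <- sub[[side]][i]
  }
  i <- match(wide$gene_id, expression$gene_id)
  n_missing <- sum(is.na(i))
  if (n_missing)
    message(n_missing, " gene(s) without expression excluded")
  wide$rpkm <- expression$rpkm[i]
  per_gene <- wide[!is.na(wide$rpkm), , drop = FALSE]
  per_cluster <- NULL
  correlations <- NULL
  if (!is.null(clusters)) {
    per_gene$cluster <- clusters$cluster[match(per_gene$gene_id,
                                               clusters$gene_id)]
    num_cols <- setdiff(names(per_gene), c("gene_id", "cluster"))
    per_cluster <- do.call(rbind, lapply(split(per_gene, per_gene$cluster),
      function(d) {
        row <- as.data.frame(lapply(d[num_cols], median))
        cbind(cluster = d$cluster[1], n_genes = nrow(d), row)
      }))
    rownames(per_cluster) <- NULL
    feats <- c("T_up", "T_down", "T_total", "codes_up", "codes_down",
               "codes_total")
    feats <- intersect(feats, names(per_cluster))
    rho <- vapply(feats, function(f) {
      x <- per_cluster[[f]]; y <- per_cluster$rpkm
      if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
      suppressWarnings(cor(x, y, method = "spearman"))
    }, numeric(1))
    correlations <- data.frame(feature = feats, spearman_rho = unname(rho),
                               stringsAsFactors = FALSE)
  }
  list(per_gene = per_gene, per_cluster = per_cluster,
       correlations = correlations, n_missing_expression = n_missing)
}
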