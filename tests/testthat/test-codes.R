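make_calls <- function(map, ids, cats) {
  data.frame(nucleosome_id = ids, category = cats, stringsAsFactors = FALSE)
}

test_that("codes are oriented 5'->3' and a dyad at the TSS is downstream", {
  map <- tiny_tiled_map(30)
  tss <- map$dyad[15]
  # marked nucleosomes at dyads tss-400 ("A", 2 slots upstream) and
  # tss+400 ("T"): spacing is 200 so offsets are in steps of 200
  id_up <- 13L; id_dn <- 17L
  calls <- make_calls(map, c(id_up, id_dn), c("A", "T"))
  genes <- data.frame(gene_id = "g+", chrom = "chr1", tss = tss, strand = "+",
                      stringsAsFactors = FALSE)
  codes <- extract_codes(calls, map, genes, window_bp = 500)
  expect_equal(codes$slots$category,
               c("A", "unmarked", "unmarked", "unmarked", "T"))
  expect_equal(codes$slots$side,
               c("up", "up", "down", "down", "down"))  # offset 0 -> down
  cc <- code_counts(codes, categories = c("T", "A"))
  tt <- cc[cc$category == "T", ]
  expect_equal(c(tt$up, tt$down, tt$total), c(0L, 1L, 1L))

  # the mirrored layout on the minus strand yields the identical code
  genes_m <- data.frame(gene_id = "g-", chrom = "chr1", tss = tss,
                        strand = "-", stringsAsFactors = FALSE)
  calls_m <- make_calls(map, c(17L, 13L), c("A", "T"))
  codes_m <- extract_codes(calls_m, map, genes_m, window_bp = 500)
  expect_equal(codes_m$slots$category, codes$slots$category)
  expect_equal(codes_m$slots$side, codes$slots$side)
  expect_equal(codes_m$slots$offset_bp, codes$slots$offset_bp)
})

test_that("codes are translation invariant and match the brute-force scan", {
  sim <- tss_sim()
  calls <- join_marks(sim$truth$per_mark, sim$map)
  codes <- extract_codes(calls, sim$map, sim$genes, 2000)
  brute <- brute_codes(calls, sim$map, sim$genes, 2000)
  got <- codes$slots[order(codes$slots$gene_id, codes$slots$offset_bp),
                     c("gene_id", "nucleosome_id", "offset_bp", "side",
                       "category")]
  brute <- brute[order(brute$gene_id, brute$offset_bp), ]
  rownames(got) <- rownames(brute) <- NULL
  expect_equal(got, brute)
  expect_equal(codes$genes$n_upstream + codes$genes$n_downstream,
               codes$genes$n_slots)

  shift <- 5000
  map_t <- nucleosome_map(sim$map$chrom, sim$map$start + shift,
                          sim$map$end + shift, dyad = sim$map$dyad + shift)
  genes_t <- transform(sim$genes, tss = tss + shift)
  codes_t <- extract_codes(calls, map_t, genes_t, 2000)
  expect_equal(codes_t$slots$category, codes$slots$category)
  expect_equal(codes_t$slots$offset_bp, codes$slots$offset_bp)

  # gene on a chromosome missing from the map: zero slots, flagged
  genes_x <- data.frame(gene_id = "gx", chrom = "chrZ", tss = 1000,
                        strand = "+", stringsAsFactors = FALSE)
  codes_x <- extract_codes(calls, sim$map, genes_x)
  expect_equal(codes_x$genes$n_slots, 0L)
  expect_true(codes_x$genes$flagged)
})

test_that("code matrix is fixed-width one-hot with absent-padding", {
  map <- tiny_tiled_map(30)
  calls <- make_calls(map, c(10L, 16L), c("T", "A"))
  genes <- data.frame(gene_id = c("g1", "g2", "gempty"), chrom = "chr1",
                      tss = c(map$dyad[13], map$dyad[13], 59000),
                      strand = "+", stringsAsFactors = FALSE)
  codes <- extract_codes(calls, map, genes, window_bp = 800)
  mat <- build_code_matrix(codes, slots_per_side = 5)
  expect_equal(nrow(mat), 3)
  # every slot block sums to exactly 1
  slot_of <- sub("\\..*", "", colnames(mat))
  for (s in unique(slot_of))
    expect_equal(unname(rowSums(mat[, slot_of == s, drop = FALSE])),
                 rep(1, 3))
  # identical codes -> identical rows; no-slot gene is all absent/padding
  expect_equal(unname(mat["g1", ]), unname(mat["g2", ]))
  absent_cols <- grepl("\\.absent$", colnames(mat))
  expect_equal(sum(mat["gempty", absent_cols]), 10)
})

test_that("k-means recovers planted archetypes and is seed-deterministic", {
  map <- tiny_tiled_map(40)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                      tss = map$dyad[seq(2, 40, by = 2)],
                      strand = "+", stringsAsFactors = FALSE)
  # archetype 1: nucleosome at the TSS marked T; archetype 2: unmarked
  arch1 <- genes$gene_id[1:10]
  anchor_ids <- match(genes$tss, map$dyad)
  calls <- make_calls(map, anchor_ids[1:10], rep("T", 10))
  codes <- extract_codes(calls, map, genes, window_bp = 300)
  mat <- build_code_matrix(codes, slots_per_side = 2)
  cl <- cluster_codes(mat, k = 2, seed = 9)
  in1 <- cl$cluster[cl$gene_id %in% arch1]
  in2 <- cl$cluster[!cl$gene_id %in% arch1]
  expect_equal(length(unique(in1)), 1)
  expect_equal(length(unique(in2)), 1)
  expect_true(unique(in1) != unique(in2))
  # duplicated rows land together; same seed reproduces labels exactly
  expect_equal(cl$cluster[1], cl$cluster[2])
  cl2 <- cluster_codes(mat, k = 2, seed = 9)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(cluster_codes(mat, k = 50, seed = 1), "distinct")
  # labels are renumbered by descending cluster size
  expect_true(all(diff(attr(cl, "sizes")) <= 0))
})

test_that("mark counts vs expression: medians, correlations, exclusions", {
  map <- tiny_tiled_map(60)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:12), chrom = "chr1",
                      tss = map$dyad[seq(5, 60, by = 5)][1:12],
                      strand = "+", stringsAsFactors = FALSE)
  anchor <- match(genes$tss, map$dyad)
  # gene i gets i %% 4 downstream T nucleosomes
  t_down <- seq_len(12) %% 4
  ids <- unlist(mapply(function(a, k) if (k > 0) a + 0:(k - 1) else NULL,
                       anchor, t_down))
  calls <- make_calls(map, as.integer(ids), rep("T", length(ids)))
  codes <- extract_codes(calls, map, genes, window_bp = 900)
  expr <- data.frame(gene_id = genes$gene_id, rpkm = 10 * t_down,
                     stringsAsFactors = FALSE)
  clusters <- data.frame(gene_id = genes$gene_id, cluster = t_down + 1,
                         stringsAsFactors = FALSE)  # cluster by true count
  res <- count_marks_vs_expression(codes, expr, clusters)
  # expression was constructed monotone in downstream T count
  rho <- res$correlations
  expect_equal(rho$spearman_rho[rho$feature == "T_down"], 1)
  # medians equal the sort-and-middle oracle
  for (cl in unique(res$per_cluster$cluster)) {
    vals <- sort(res$per_gene$rpkm[res$per_gene$cluster == cl])
    n <- length(vals)
    mid <- if (n %% 2 == 1) vals[(n + 1) / 2] else mean(vals[n / 2 + 0:1])
    expect_equal(res$per_cluster$rpkm[res$per_cluster$cluster == cl], mid)
  }

  # all-zero expression: correlations undefined -> NA
  expr0 <- transform(expr, rpkm = 0)
  res0 <- count_marks_vs_expression(codes, expr0, clusters)
  expect_true(all(is.na(res0$correlations$spearman_rho)))

  # genes without expression are excluded and counted
  expr_m <- expr[1:9, ]
  expect_message(res_m <- count_marks_vs_expression(codes, expr_m, clusters),
                 "3 gene")
  expect_equal(nrow(res_m$per_gene), 9)
  expect_equal(res_m$n_missing_expression, 3)
})
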