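test_that("per-nucleosome counting matches direct placement and the oracle", {
  map <- tiny_tiled_map(10)
  # ten fragments with midpoints inside nucleosome 3 only
  mid3 <- map$dyad[3]
  frags <- fragments("chr1", mid3 - 10 - 0:9, mid3 + 10 + 0:9)
  counts <- tabulate(assign_fragments(frags, map), nbins = nrow(map))
  expect_equal(counts, c(0, 0, 10, rep(0, 7)))

  frags2 <- random_fragments(500, max_pos = 2200, seed = 23)
  expect_equal(tabulate(assign_fragments(frags2, map), nbins = nrow(map)),
               brute_count(frags2, map))
})

test_that("uniform fragments spread evenly over a tiling within Poisson noise", {
  map <- tiny_tiled_map(10, width = 190, spacing = 200)
  set.seed(9)
  n <- 5000
  # midpoints uniform over the full tiled span (2 bp fragments: mid = start+1)
  start <- floor(runif(n, 24, 2014))
  frags <- fragments("chr1", start, start + 2)
  counts <- tabulate(assign_fragments(frags, map), nbins = 10)
  expected <- sum(counts) / 10
  expect_true(all(abs(counts - expected) < 3 * sqrt(expected)))
})

test_that("local lambda: floor, uniform case, truncation, and oracle equality", {
  map <- tiny_tiled_map(20)
  # no background at all -> genome-rate floor
  empty <- fragments(character(0), numeric(0), numeric(0))
  attr(empty, "library_size") <- 1000
  lam <- local_lambda(empty, map, window_bp = 2000,
                      effective_genome_size = 1e6,
                      chrom_sizes = c(chr1 = 4000))
  expect_equal(lam, rep(1000 * 147 / 1e6, 20))

  # uniform rate r per bp -> lambda close to 147 r
  set.seed(31)
  r <- 0.05
  n <- round(r * 100000)
  start <- floor(runif(n, 0, 99900))
  unif <- fragments("chr1", start, start + 100)
  map2 <- nucleosome_map("chr1", 50000, 50147)
  lam2 <- local_lambda(unif, map2, window_bp = 10000,
                       effective_genome_size = 2.7e9,
                       chrom_sizes = c(chr1 = 100000))
  expect_lt(abs(lam2 - 147 * r) / (147 * r), 0.1)

  # 20 windows, including ones truncated at the chromosome edge, vs oracle
  chip <- random_fragments(2000, max_pos = 4200, seed = 12)
  expect_equal(local_lambda(chip, map, window_bp = 3000,
                            effective_genome_size = 2.7e9,
                            chrom_sizes = c(chr1 = 4200)),
               brute_local_lambda(chip, map, 3000, 2.7e9, 4200))
  expect_error(local_lambda(chip, map, window_bp = 100), "window_bp")
})

test_that("candidate gate is inclusive at the excess boundary and oracle-exact", {
  counts <- data.frame(id = 1:4, chrom = "chr1",
                       start = c(0, 200, 400, 600), end = c(147, 347, 547, 747),
                       chip_count = c(10, 9, 20, 3),
                       input_count_scaled = c(6, 6, 2, 0))
  counts$excess <- counts$chip_count - counts$input_count_scaled
  cand <- call_candidates(counts, min_excess = 4)
  expect_equal(cand$id, c(1L, 3L))  # 10-6 = 4 kept (inclusive), 9-6 = 3 not

  set.seed(77)
  tab <- data.frame(id = 1:200, chrom = "chr1", start = 200 * (0:199),
                    end = 200 * (0:199) + 147,
                    chip_count = rpois(200, 6),
                    input_count_scaled = runif(200, 0, 8))
  tab$excess <- tab$chip_count - tab$input_count_scaled
  for (t in c(0, 2, 4, 8)) {
    expect_setequal(call_candidates(tab, t)$id,
                    tab$id[tab$chip_count - tab$input_count_scaled >= t])
  }
  # monotonicity: raising min_excess never adds candidates
  ids_by_t <- lapply(c(0, 2, 4, 8), function(t) call_candidates(tab, t)$id)
  for (i in 2:4) expect_true(all(ids_by_t[[i]] %in% ids_by_t[[i - 1]]))
})

test_that("input scaling is the depth ratio and counts ignore fragment order", {
  sim <- tiny_sim()
  chip <- sim$chip[[1]]
  counts <- nucleosome_counts(chip, sim$input, sim$map)
  expect_equal(counts$input_count_scaled,
               counts$input_count_raw * nrow(chip) / nrow(sim$input))

  # equal library sizes: scaled equals raw
  counts_eq <- nucleosome_counts(chip, chip, sim$map)
  expect_equal(counts_eq$input_count_scaled, counts_eq$input_count_raw)

  # permuting fragment order changes nothing
  set.seed(2)
  chip_perm <- chip[sample(nrow(chip)), ]
  attr(chip_perm, "library_size") <- nrow(chip_perm)
  counts_perm <- nucleosome_counts(chip_perm, sim$input, sim$map)
  expect_equal(counts_perm$chip_count, counts$chip_count)

  expect_lte(sum(counts$chip_count), library_size(chip))
  expect_error(nucleosome_counts(chip, sim$input, sim$map[0, ]), "empty")
})
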