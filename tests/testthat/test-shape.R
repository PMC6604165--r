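one_nuc <- function(start = 1000, width = 147) {
  m <- nucleosome_map("chr1", start, start + width)
  m[1, ]
}

mids_to_frags <- function(mids, chrom = "chr1") {
  # [m, m+1) has midpoint exactly m
  fragments(chrom, mids, mids + 1)
}

test_that("profiles bin midpoints with right-closed boundaries", {
  nuc <- one_nuc(0, 147)
  # everything at the dyad lands in the central bin
  bins <- profile_nucleosome(mids_to_frags(rep(73, 12)), nuc, n_bins = 21)
  expect_equal(bins[11], 12)
  expect_equal(sum(bins), 12)

  # a midpoint exactly on a bin boundary goes to the right bin
  nuc2 <- one_nuc(0, 100)
  bins2 <- profile_nucleosome(mids_to_frags(60), nuc2, n_bins = 5)
  expect_equal(which(bins2 == 1), 4L)  # 60/20 = bin boundary 3|4

  # binning equals exhaustive per-midpoint arithmetic
  set.seed(19)
  mids <- sample(0:146, 200, replace = TRUE)
  bins3 <- profile_nucleosome(mids_to_frags(mids), nuc, n_bins = 21)
  manual <- tabulate(pmin(21, floor(mids / (147 / 21)) + 1), 21)
  expect_equal(bins3, manual)
  expect_equal(sum(bins3), 200)

  # uniform midpoints give near-equal bins (multinomial noise)
  set.seed(20)
  binsu <- profile_nucleosome(mids_to_frags(sample(0:146, 4200, TRUE)),
                              nuc, n_bins = 21)
  expect_true(all(abs(binsu - 200) < 4 * sqrt(200)))

  expect_error(profile_nucleosome(mids_to_frags(10), nuc, n_bins = 4), "odd")
  # narrow nucleosome: bin count reduced to fit
  narrow <- one_nuc(0, 9)
  expect_length(profile_nucleosome(mids_to_frags(4), narrow, n_bins = 21), 9)
})

test_that("asymmetry is the normalized center-of-mass offset", {
  expect_equal(asymmetry_score(c(1, 2, 4, 2, 1)), 0)
  expect_equal(asymmetry_score(c(rep(0, 20), 5)), 1)
  expect_equal(asymmetry_score(c(5, rep(0, 20))), -1)
  expect_equal(asymmetry_score(c(0, 0, 1, 3, 6)), 0.75)
  expect_error(asymmetry_score(c(0, 0, 0)), "empty")
})

test_that("dip ratio contrasts the central third with the flanks", {
  expect_equal(dip_score(rep(4, 9)), 1)
  expect_equal(dip_score(c(6, 6, 6, 0, 0, 0, 6, 6, 6)), 0)
  expect_equal(dip_score(c(0, 0, 0, 6, 6, 6, 0, 0, 0)), Inf)
  expect_error(dip_score(rep(0, 9)), "empty")
})

test_that("mirrored profiles flip asymmetry sign and keep the dip ratio", {
  set.seed(6)
  for (i in 1:20) {
    bins <- rpois(21, 3) + 1
    expect_equal(asymmetry_score(rev(bins)), -asymmetry_score(bins))
    expect_equal(dip_score(rev(bins)), dip_score(bins))
  }
})

test_that("shape filters remove planted artifacts and only those", {
  sim <- simulate_dataset(sim_config(seed = 29, marks = "H3K4me3",
                                     n_marked = 170, n_artifacts = 30))
  chip <- sim$chip$H3K4me3
  counts <- nucleosome_counts(chip, sim$input, sim$map)
  cand <- call_candidates(counts, 4)
  flt <- apply_shape_filters(cand, chip)
  removed <- flt$verdicts$nucleosome_id[
    flt$verdicts$verdict %in% c("oblique", "u_shaped")]
  expect_setequal(removed, sim$truth$artifacts$nucleosome_id)
  # planted shapes are recognized as the planted class
  v <- flt$verdicts[match(sim$truth$artifacts$nucleosome_id,
                          flt$verdicts$nucleosome_id), ]
  expect_equal(v$verdict, sim$truth$artifacts$shape)

  # idempotent and order-independent
  again <- apply_shape_filters(flt$passed, chip)
  expect_equal(nrow(again$passed), nrow(flt$passed))
  shuf <- cand[rev(seq_len(nrow(cand))), ]
  flt2 <- apply_shape_filters(shuf, chip)
  expect_setequal(flt2$passed$id, flt$passed$id)
})

test_that("sparse candidates pass as low_coverage and thresholds are monotone", {
  nuc <- one_nuc(0, 147)
  cand <- cbind(nuc, chip_count = 5)
  # 5 fragments piled on the far edge: oblique in shape but below min_reads
  chip <- mids_to_frags(rep(140, 5))
  flt <- apply_shape_filters(cand, chip, nucpeak_params(shape_min_reads = 10))
  expect_equal(flt$verdicts$verdict, "low_coverage_pass")
  expect_equal(nrow(flt$passed), 1)

  flt2 <- apply_shape_filters(cand, chip, nucpeak_params(shape_min_reads = 5))
  expect_equal(flt2$verdicts$verdict, "oblique")

  # tightening a_max / raising d_min never re-admits a removed candidate
  sim <- tiny_sim()
  chip_s <- sim$chip$H3K4me3
  counts <- nucleosome_counts(chip_s, sim$input, sim$map)
  cand_s <- call_candidates(counts, 4)
  loose <- apply_shape_filters(cand_s, chip_s,
                               nucpeak_params(shape_a_max = 0.7,
                                              shape_d_min = 0.3))
  tight <- apply_shape_filters(cand_s, chip_s,
                               nucpeak_params(shape_a_max = 0.4,
                                              shape_d_min = 0.7))
  expect_true(all(tight$passed$id %in% loose$passed$id))
})
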