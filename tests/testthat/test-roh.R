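test_that("binning tiles the chromosome and assigns sites by the floor rule", {
  x <- vt(cbind(S1 = c(1L, 1L, 1L, 1L)),
          pos = c(1L, 10000L, 10001L, 29999L))
  track <- bin_genome(x, "S1", c(chr1 = 30e6))
  expect_equal(nrow(track), 3000)
  expect_equal(track$raw_snp_count[1], 2L)  # pos 1 and pos 10,000
  expect_equal(track$raw_snp_count[2], 1L)  # pos 10,001 opens bin [10000,20000)
  expect_equal(track$raw_snp_count[3], 1L)
  expect_equal(sum(track$raw_snp_count), 4L)
  expect_error(bin_genome(vt(cbind(S1 = 1L), pos = 40e6), "S1",
                          c(chr1 = 30e6)), "beyond")
})

test_that("a site-free genome yields all-zero bins", {
  x <- vt(matrix(integer(0), 0, 1, dimnames = list(NULL, "S1")))
  track <- bin_genome(x, "S1", c(chr1 = 1e5))
  expect_equal(track$raw_snp_count, rep(0L, 10))
})

test_that("raw counts are conserved through binning", {
  set.seed(31)
  pos <- sort(sample.int(5e6, 2000))
  x <- vt(cbind(S1 = rep(1L, 2000)), pos = pos)
  track <- bin_genome(x, "S1", c(chr1 = 5e6))
  expect_equal(sum(track$raw_snp_count), 2000L)
})

test_that("scaling extrapolates counts from covered sites to the full bin", {
  cov <- data.frame(chrom = "chr1", start = c(0L, 10000L, 20000L),
                    covered = c(5000L, 10000L, 0L))
  x <- vt(cbind(S1 = rep(1L, 12)),
          pos = c(seq(1, 5000, length.out = 6),
                  seq(10001, 20000, length.out = 6)))
  track <- scale_bins(bin_genome(x, "S1", c(chr1 = 3e4), coverage = cov))
  expect_equal(track$scaled_snp_count[1], 12)   # 6 SNPs, half covered
  expect_equal(track$scaled_snp_count[2], 6)    # 6 SNPs, fully covered
  expect_true(is.na(track$scaled_snp_count[3])) # uncovered bin: no signal
  expect_false(track$retained[3])
  expect_true(all(track$scaled_snp_count >= track$raw_snp_count,
                  na.rm = TRUE))
})

test_that("bin retention applies the coverage and sex-chromosome rules", {
  cov <- data.frame(chrom = c("chr1", "chr1", "X"),
                    start = c(0L, 10000L, 0L),
                    covered = c(999L, 1000L, 10000L))
  x <- vt(matrix(integer(0), 0, 1, dimnames = list(NULL, "S1")))
  track <- bin_genome(x, "S1", c(chr1 = 2e4, X = 1e4), coverage = cov)
  track <- filter_bins(scale_bins(track))
  expect_equal(track$retained, c(FALSE, TRUE, FALSE))
})

test_that("the genomic average is the mean over retained bins, ROH bins included", {
  expect_equal(genomic_average(bt(c(10, 14))), 12)
  expect_equal(genomic_average(bt(rep(7, 5))), 7)
  expect_equal(genomic_average(bt(c(0, 0, 36))), 12)
  track <- bt(c(5, 100), retained = c(TRUE, FALSE))
  expect_equal(genomic_average(track), 5)
  expect_error(genomic_average(bt(numeric(0))), "no retained")
})

test_that("ROH calls respect the run-length minimum and the strict cutoff", {
  # 20 zero bins in a diverse background
  track <- bt(c(rep(12, 10), rep(0, 20), rep(12, 70)))
  rohs <- call_rohs(track, genomic_avg = 12)
  expect_equal(nrow(rohs), 1)
  expect_equal(rohs$start, 10 * 10000)
  expect_equal(rohs$end, 30 * 10000)
  expect_equal(rohs$n_bins, 20L)
  expect_equal(rohs$length, 200000L)
  # 19 bins do not qualify
  track19 <- bt(c(rep(12, 10), rep(0, 19), rep(12, 71)))
  expect_equal(nrow(call_rohs(track19, genomic_avg = 12)), 0)
  # strict inequality at the cutoff 0.33 * 12 = 3.96
  at_cut <- bt(c(rep(12, 20), rep(3.96, 20), rep(3.95, 20), rep(12, 20)))
  rohs <- call_rohs(at_cut, genomic_avg = 12)
  expect_equal(nrow(rohs), 1)
  expect_equal(rohs$start, 40 * 10000)
  expect_equal(rohs$n_bins, 20L)
})

test_that("a non-retained bin terminates a run; gap tolerance can bridge one", {
  scaled <- c(rep(0, 15), 12, rep(0, 15), rep(12, 20))
  track <- bt(scaled)
  expect_equal(nrow(call_rohs(track, genomic_avg = 12)), 0)
  bridged <- call_rohs(track, genomic_avg = 12, max_gap_bins = 1)
  expect_equal(nrow(bridged), 1)
  expect_equal(bridged$n_bins, 31L)
  # same geometry but the middle bin is not retained: never bridged
  track2 <- bt(scaled, retained = c(rep(TRUE, 15), FALSE, rep(TRUE, 35)))
  expect_equal(nrow(call_rohs(track2, genomic_avg = 12,
                              max_gap_bins = 1)), 0)
})

test_that("runs never span chromosomes", {
  track <- rbind(bt(rep(0, 15), chrom = "chr1"),
                 bt(rep(0, 15), chrom = "chr2"))
  attr(track, "bin_size") <- 10000L
  expect_equal(nrow(call_rohs(track, genomic_avg = 12)), 0)
})

test_that("the caller agrees with a brute-force scan on random tracks", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(40:200, 1)
    scaled <- rpois(n, sample(c(1, 3, 6, 12), 1)) +
      ifelse(runif(n) < 0.3, 0, runif(n))
    retained <- runif(n) > 0.1
    track <- bt(scaled, retained = retained)
    min_bins <- sample(c(3L, 5L, 20L), 1)
    avg <- mean(scaled)
    got <- call_rohs(track, genomic_avg = avg, min_bins = min_bins)
    qual <- retained & scaled < 0.33 * avg
    want <- brute_force_runs(qual, retained, min_bins)
    expect_equal(got$start, (want$first - 1L) * 10000L, info = seed)
    expect_equal(got$end, want$last * 10000L, info = seed)
  }
})

test_that("lowering frac or raising min_bins never yields more ROHs", {
  set.seed(77)
  for (rep in 1:10) {
    scaled <- rpois(150, 4) + runif(150)
    track <- bt(scaled)
    base <- nrow(call_rohs(track, genomic_avg = mean(scaled),
                           min_bins = 5L, frac = 0.33))
    fewer_frac <- nrow(call_rohs(track, genomic_avg = mean(scaled),
                                 min_bins = 5L, frac = 0.2))
    longer_min <- nrow(call_rohs(track, genomic_avg = mean(scaled),
                                 min_bins = 10L, frac = 0.33))
    expect_lte(fewer_frac, base)
    expect_lte(longer_min, base)
  }
})

test_that("length classification uses half-open categories", {
  rohs <- data.frame(chrom = "chr1", start = 0,
                     end = c(3e5, 5e5, 2e6, 7e6),
                     n_bins = c(30L, 50L, 200L, 700L),
                     length = c(3e5, 5e5, 2e6, 7e6))
  cls <- classify_lengths(rohs)
  expect_equal(cls$category[1], "0.2-0.5 Mb")
  expect_equal(cls$n_rohs, c(1L, 1L, 0L, 1L, 1L))
  expect_equal(sum(cls$total_bp), sum(rohs$length))
  # exactly 0.5 Mb falls in the second category
  expect_equal(cls$n_rohs[2], 1L)
  empty <- classify_lengths(rohs[0, ])
  expect_equal(empty$n_rohs, rep(0L, 5))
  too_short <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                          n_bins = 10L, length = 1e5)
  expect_error(classify_lengths(too_short), "shorter")
})

test_that("diversity outside ROHs excludes ROH bins and defaults to the average", {
  track <- bt(c(rep(0, 20), 12, 12))
  rohs <- call_rohs(track, genomic_avg = 12)
  expect_equal(diversity_outside(track, rohs), 12)
  expect_equal(diversity_outside(track, rohs[0, ]), genomic_average(track))
  all_roh <- bt(rep(0, 25))
  expect_error(diversity_outside(all_roh, call_rohs(all_roh,
                                                    genomic_avg = 12)),
               "inside a ROH")
})

test_that("cohort summaries reproduce group means and flag single samples", {
  stats <- data.frame(n_rohs = c(10, 20, 30), mean_length_kb = c(1, 2, 3),
                      pi = c(5, 6, 7))
  s <- summarize_cohort(stats)
  expect_equal(s$mean_n_rohs, 20)
  expect_equal(s$sd_n_rohs, 10)
  g <- summarize_cohort(stats, group = c("a", "a", "b"))
  expect_equal(g$mean_pi[g$group == "b"], 7)
  expect_true(is.na(g$sd_pi[g$group == "b"]))
  expect_error(summarize_cohort(stats[0, ]), "empty")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(54.5), 55)
  expect_equal(round_half_away(-54.5), -55)
  expect_equal(round_half_away(116.857), 117)
  expect_equal(round_half_away(1.926, 1), 1.9)
  expect_equal(round_half_away(2.25, 1), 2.3)
})
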