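test_that("a fully homozygous chromosome yields one spanning segment", {
  vt <- make_fixture(list(chr1 = c(a = strrep("0", 300))), spacing = 1e4)
  seg <- call_roh(vt, "a")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 300)
  expect_equal(seg$length_bp, 299 * 1e4 + 1)
  expect_equal(seg$n_het, 0)
})

test_that("10% heterozygosity defeats every scanning window", {
  g <- rep("0", 300); g[seq(10, 300, 10)] <- "1"
  vt <- make_fixture(list(chr1 = c(a = paste(g, collapse = ""))),
                     spacing = 1e4)
  expect_equal(nrow(call_roh(vt, "a")), 0)
})

test_that("chromosomes shorter than one window are skipped with a message", {
  vt <- make_fixture(list(chr1 = c(a = strrep("0", 30))))
  expect_message(seg <- call_roh(vt, "a"), "skipped")
  expect_equal(nrow(seg), 0)
})

test_that("call_roh equals the literal-definition oracle on random fixtures", {
  for (sd in 1:25) {
    vt <- random_roh_fixture(sd, max_snps = 1200)
    got <- call_roh(vt, 1)
    want <- oracle_roh(vt, 1)
    expect_identical(got, want)
    # every reported segment satisfies all four acceptance predicates
    p <- roh_params()
    if (nrow(got)) {
      expect_true(all(got$length_bp >= p$min_kb * 1000))
      expect_true(all(got$n_snps >= p$min_snps))
      expect_true(all(got$length_bp / got$n_snps <=
                        p$max_kb_per_snp * 1000))
      expect_true(all(got$end >= got$start))
      expect_equal(got$length_bp, got$end - got$start + 1)
    }
  }
})

test_that("summarize_roh computes NROH, SROH, FROH and the size classes", {
  segs <- data.frame(sample = "w1", chrom = "chr1",
                     start = c(1, 1, 1), end = c(5e5, 2e6, 1.2e7),
                     length_bp = c(5e5, 2e6, 1.2e7),
                     n_snps = c(200, 500, 3000), n_het = 0)
  pr <- summarize_roh(segs, genome_length = 2222501653)
  expect_equal(pr$NROH, 3)
  expect_equal(pr$SROH, 5e5 + 2e6 + 1.2e7)
  expect_equal(pr$FROH, pr$SROH / 2222501653)
  expect_equal(pr$SROH_short, 5e5)
  expect_equal(pr$SROH_intermediate, 2e6)
  expect_equal(pr$SROH_long, 1.2e7)
  expect_equal(pr$SROH_short + pr$SROH_intermediate + pr$SROH_long,
               pr$SROH)
  # boundary lengths go to the longer class
  b <- summarize_roh(data.frame(sample = "w", chrom = "c", start = 1,
                                end = 1e6, length_bp = 1e6, n_snps = 300,
                                n_het = 0))
  expect_equal(b$SROH_intermediate, 1e6)
  expect_equal(b$SROH_short, 0)
  # published-scale arithmetic
  expect_equal(round(909.47e6 / 2222501653, 3), 0.409)
  expect_equal(round(713.03e6 / 2222501653, 3), 0.321)
  expect_error(summarize_roh(segs, genome_length = 0), "positive")
})

test_that("ROH dating follows L = 100/(2t) cM and round-trips", {
  rec <- recombination_model(1.3459)
  expect_equal(round(roh_age(1e6, rec)), 37)
  expect_equal(round(roh_age(1e7, rec)), 4)
  expect_gte(roh_age(1e5, rec), 350)
  # 50 cM run coalesces one generation ago
  expect_equal(roh_age(50 / 1.3459 * 1e6, rec), 1)
  expect_equal(round(length_for_age(7, rec) / 1e6, 1), 5.3)
  expect_equal(round(length_for_age(5, rec) / 1e6, 1), 7.4)
  for (t in 1:100)
    expect_equal(roh_age(length_for_age(t, rec), rec), t)
  # strictly decreasing in length
  ages <- roh_age(seq(1e5, 1e7, length.out = 50), rec)
  expect_true(all(diff(ages) < 0))
  expect_error(roh_age(0), "positive")
  expect_error(length_for_age(-1), "positive")
})

test_that("bottleneck window fraction pools segment length in the band", {
  segs <- data.frame(sample = "w", chrom = "c", start = 1,
                     end = c(1e6, 3e6, 1e7),
                     length_bp = c(1e6, 3e6, 1e7),
                     n_snps = 100, n_het = 0)
  # band [2, 5] Mb via a rate that maps t = 18 -> 2 Mb, t = 7 -> 5 Mb
  expect_equal(bottleneck_window_fraction(
    segs, g_old = 18, g_recent = 12, post_gens = 5,
    rec = recombination_model(100 / 36 / 2)),
    3 / 14, tolerance = 1e-6)
  expect_true(is.na(bottleneck_window_fraction(segs[0, ], 18, 12)))
  all_in <- data.frame(sample = "w", chrom = "c", start = 1, end = 3e6,
                       length_bp = 3e6, n_snps = 100, n_het = 0)
  expect_equal(bottleneck_window_fraction(all_in, 18, 12), 1)
  # default rate reproduces the 2.06 - 5.31 Mb band
  expect_equal(round(length_for_age(18) / 1e6, 2), 2.06)
  expect_equal(round(length_for_age(7) / 1e6, 2), 5.31)
})

test_that("generation-to-year conversion anchors the bottleneck calendar", {
  expect_equal(generations_to_years(18, 4, 2010), 1938)
  expect_equal(generations_to_years(12, 3, 2010), 1974)
  expect_equal(generations_to_years(0, 3, 2010), 2010)
})

test_that("a simulated bottleneck leaves excess SROH in its dated band", {
  # 10 seeds x (bottleneck at generations 12-18 vs constant-N control),
  # pooled one-sided comparison; realistic mu so IBD tracts stay intact
  band <- c(length_for_age(18), length_for_age(7))
  pooled <- c(bn = 0, ct = 0)
  for (sd in 1:10) {
    for (arm in c("bn", "ct")) {
      traj <- if (arm == "bn")
        data.frame(start = c(0, 12, 18), end = c(12, 18, Inf),
                   N = c(30, 25, 100))
      else data.frame(start = 0, end = Inf, N = 100)
      cfg <- sim_config(n_chromosomes = 4, chrom_length = 1e7, mu = 5e-8,
                        ne_trajectory = traj,
                        class_probs = c(NEUTRAL = 1, LOW = 0,
                                        MODERATE = 0, HIGH = 0),
                        sample_size = 8, n_pedigree_pairs = 0,
                        burn_in = 50, seed = sd)
      sim <- simulate_population(cfg)
      vt <- subset_variants(sim$variants,
                            samples = ingroup_samples(sim$variants))
      segs <- suppressMessages(call_roh_all(vt))
      pooled[arm] <- pooled[arm] +
        sum(segs$length_bp[segs$length_bp >= band[1] &
                             segs$length_bp <= band[2]])
    }
  }
  expect_gt(pooled["bn"], pooled["ct"])
})
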