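test_that("make_fixture builds exact tables and rejects bad symbols", {
  vt <- make_fixture(list(chr1 = c(a = "012.0", b = "00122"),
                          chr2 = c(a = "11", b = "02")))
  expect_equal(n_sites(vt), 7)
  expect_equal(n_samples(vt), 2)
  expect_identical(unname(vt$geno[4, "a"]), NA_integer_)
  expect_identical(vt$geno[, "b"], c(0L, 0L, 1L, 2L, 2L, 0L, 2L),
                   ignore_attr = TRUE)
  expect_error(make_fixture(list(chr1 = c(a = "01x"))), "malformed")
  empty <- make_fixture(list(chr1 = c(a = "", b = "")))
  expect_equal(n_sites(empty), 0)
})

test_that("identical config and seed give byte-identical output", {
  s1 <- simulate_population(quick_sim(seed = 9))
  s2 <- simulate_population(quick_sim(seed = 9))
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_population(quick_sim(seed = 10))
  expect_false(identical(s1$variants$geno, s3$variants$geno))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(ne_trajectory = data.frame(
    start = 0, end = Inf, N = 0)), "non-positive")
  expect_error(sim_config(ne_trajectory = data.frame(
    start = 0, end = 50, N = 30)), "cover")
  expect_error(sim_config(class_probs = c(NEUTRAL = 0.5, LOW = 0.1,
                                          MODERATE = 0.1, HIGH = 0.1)),
               "sum to 1")
})

test_that("a bottleneck tuple splices correctly into the trajectory", {
  cfg <- sim_config(ne_trajectory = data.frame(start = 0, end = Inf,
                                               N = 100),
                    bottleneck = c(12, 18, 25))
  tr <- cfg$ne_trajectory
  expect_equal(tr$start, c(0, 12, 18))
  expect_equal(tr$N, c(100, 25, 100))
})

test_that("emitted sites are polymorphic, sorted, and truth-aligned", {
  sim <- simulate_population(quick_sim(seed = 2))
  vt <- sim$variants
  ing <- ingroup_samples(vt)
  ds <- rowSums(vt$geno[, ing])
  expect_true(all(ds > 0 & ds < 2 * length(ing)))
  expect_true(all(vt$ref != vt$alt))
  expect_true(all(sim$truth$ancestral %in% c("A", "C", "G", "T")))
  expect_length(sim$truth$class, n_sites(vt))
  expect_true(all(is.na(sim$truth$sift) == (sim$truth$class != "MODERATE")))
  # derived allele is always one of ref/alt
  der <- ifelse(sim$truth$ancestral == vt$ref, vt$alt,
                ifelse(sim$truth$ancestral == vt$alt, vt$ref, NA))
  expect_false(anyNA(der))
})

test_that("pedigree offspring are Mendelian-consistent with their parent", {
  sim <- simulate_population(quick_sim(seed = 4, n_pedigree_pairs = 2))
  expect_equal(nrow(sim$truth$pedigree), 2)
  for (k in seq_len(2)) {
    ct <- pair_counts(sim$variants, sim$truth$pedigree$parent[k],
                      sim$truth$pedigree$offspring[k])
    expect_identical(ct$n_ibs0, 0L)  # no opposite homozygotes, ever
  }
})

test_that("outgroup disagreement with the ancestral state grows with divergence", {
  stats <- vapply(c(1e4, 2e5), function(div) {
    sim <- simulate_population(quick_sim(seed = 6,
                                         outgroup_divergence = div))
    pol <- polarize(sim$variants, outgroup_alleles(sim), seed = 1)
    c(mismatch = mean(outgroup_alleles(sim) != sim$truth$ancestral),
      ties = mean(pol$confidence == "tie_random"))
  }, c(0, 0))
  expect_lt(stats["mismatch", 1], stats["mismatch", 2])
  expect_lt(stats["ties", 1], stats["ties", 2])
})

test_that("neutral constant-N heterozygosity sits at mutation-drift equilibrium", {
  # 4 N mu / (1 + 4 N mu) per bp, averaged over samples and 3 seeds
  N <- 30; mu <- 1e-6; L <- 2 * 5e6
  ho <- vapply(1:3, function(sd) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length = 5e6, mu = mu,
                      ne_trajectory = data.frame(start = 0, end = Inf,
                                                 N = N),
                      class_probs = c(NEUTRAL = 1, LOW = 0, MODERATE = 0,
                                      HIGH = 0),
                      sample_size = 6, burn_in = 30, seed = 40 + sd)
    vt <- simulate_population(cfg)$variants
    mean(vapply(ingroup_samples(vt), function(s)
      individual_heterozygosity(vt, s, callable_total = L), 0))
  }, 0)
  expected <- 4 * N * mu / (1 + 4 * N * mu)
  expect_lt(abs(mean(ho) - expected) / expected, 0.25)
})

test_that("write_sim emits VCF, sidecar annotations and truth JSON", {
  sim <- simulate_population(quick_sim(seed = 3))
  d <- withr::local_tempdir()
  write_sim(sim, d)
  expect_setequal(list.files(d),
                  c("sim.vcf", "annotations.tsv", "truth.json"))
  vt2 <- read_vcf(file.path(d, "sim.vcf"),
                  annotation_path = file.path(d, "annotations.tsv"))
  expect_identical(unname(vt2$geno), unname(sim$variants$geno))
  expect_identical(vt2$annotation$impact,
                   sim_annotations(sim)$impact)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$class, sim$truth$class)
})
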