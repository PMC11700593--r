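make_vcf_text <- function(lines, contigs = "chr1") {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=10000000>", contigs),
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Annotation">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    lines)
}

test_that("read_vcf decodes GT, missing calls and multi-allelic records", {
  txt <- make_vcf_text(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT\t1/1\t./.",
    "chr1\t300\t.\tG\tA,T\t50\tPASS\t.\tGT\t0/1\t1/2"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(txt, f)
  vt <- read_vcf(f)
  expect_equal(n_sites(vt), 3)
  expect_identical(vt$geno[1, ], c(s1 = 0L, s2 = 1L))
  expect_identical(vt$geno[2, ], c(s1 = 2L, s2 = NA_integer_))
  # allele index 2 is uncodable as a biallelic dosage -> missing
  expect_identical(vt$geno[3, ], c(s1 = 1L, s2 = NA_integer_))
  expect_identical(vt$multiallelic, c(FALSE, FALSE, TRUE))
})

test_that("read_vcf rejects unsorted bodies and unknown contigs", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(make_vcf_text(c(
    "chr1\t200\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t100\t.\tC\tT\t50\tPASS\t.\tGT\t0/0\t0/1")), f)
  expect_error(suppressWarnings(read_vcf(f)), "sorted")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(make_vcf_text(
    "chr9\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/1"), f2)
  expect_error(suppressWarnings(read_vcf(f2)), "contig")
})

test_that("snpEff-style ANN impact strings are parsed when present", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(make_vcf_text(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\tANN=G|missense_variant|MODERATE|X\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT\t50\tPASS\tANN=T|synonymous_variant|LOW|Y\tGT\t0/0\t0/1")), f)
  vt <- read_vcf(f)
  expect_identical(vt$annotation$impact, c("MODERATE", "LOW"))
})

test_that("write_vcf / read_vcf round-trip is exact, plain and gzip", {
  sim <- simulate_population(quick_sim(seed = 11))
  vt <- sim$variants
  for (ext in c(".vcf", ".vcf.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_vcf(vt, f)
    back <- read_vcf(f)
    expect_identical(unname(back$geno), unname(vt$geno))
    expect_identical(back$pos, vt$pos)
    expect_identical(back$chrom, vt$chrom)
    expect_identical(unname(back$depth), unname(vt$depth))
  }
})

test_that("site filters drop sites for the documented reasons", {
  # 20 samples; site 2 has alt frequency 0.04 among 50 present alleles
  n <- 25
  g1 <- c(rep(1L, 3), rep(0L, n - 3))          # maf 3/50 = 0.06: kept
  g2 <- c(rep(1L, 2), rep(0L, 23))             # maf 2/50 = 0.04: removed
  g3 <- c(rep(1L, 10), rep(NA, 5), rep(0L, 10))  # 20/25 = 0.8 present
  vt <- variant_table(chrom = rep("chr1", 3), pos = c(100, 200, 300),
                      ref = rep("A", 3), alt = rep("G", 3),
                      geno = rbind(g1, g2, g3),
                      samples = sprintf("s%02d", 1:n))
  out <- apply_site_filters(vt, filter_config())
  expect_equal(n_sites(out$variants), 1)
  rep_ <- setNames(out$report$removed, out$report$criterion)
  expect_equal(unname(rep_["maf"]), 1)
  expect_equal(unname(rep_["missingness"]), 1)
})

test_that("an empty table filters to an empty table with a warning", {
  empty <- make_fixture(list(chr1 = c(a = "", b = "")))
  expect_warning(out <- apply_site_filters(empty), "empty")
  expect_equal(n_sites(out$variants), 0)
})

test_that("filtering is idempotent and masks low-depth calls first", {
  sim <- simulate_population(quick_sim(seed = 12))
  vt <- subset_variants(sim$variants,
                        samples = ingroup_samples(sim$variants))
  vt$depth[1, 1] <- 2L  # below min_dp -> masked before missingness test
  f1 <- apply_site_filters(vt, filter_config())
  expect_true(is.na(f1$variants$geno[1, 1]) ||
                f1$variants$pos[1] != vt$pos[1])
  f2 <- apply_site_filters(f1$variants, filter_config())
  expect_true(all(f2$report$removed == 0))
  expect_equal(n_sites(f2$variants), n_sites(f1$variants))
})

test_that("r2 matches hand computations and flags degenerate input", {
  vt <- make_fixture(list(chr1 = c(a = "00", b = "01", c = "10", d = "11")))
  expect_equal(r2(vt, 1, 2), 0)            # (0,0,1,1) vs (0,1,0,1)
  vt2 <- make_fixture(list(chr1 = c(a = "00", b = "11", c = "22")))
  expect_equal(r2(vt2, 1, 2), 1)           # identical dosage vectors
  vt3 <- make_fixture(list(chr1 = c(a = "00", b = "01")))
  expect_true(is.na(r2(vt3, 1, 2)))        # site 1 monomorphic
  # statistically independent sites: permutation-averaged r2 ~ null floor
  set.seed(1)
  n <- 40
  x <- sample(0:2, n, replace = TRUE)
  y <- sample(0:2, n, replace = TRUE)
  r2s <- replicate(300, {
    g <- rbind(x, sample(y))
    vtp <- variant_table(chrom = c("chr1", "chr1"), pos = c(1, 2),
                         ref = c("A", "A"), alt = c("G", "G"), geno = g,
                         samples = sprintf("s%02d", 1:n))
    r2(vtp, 1, 2)
  })
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 0.01)
})

test_that("ld_prune keeps one of a duplicated pair and satisfies the
           exhaustive post-condition on random instances", {
  vt <- make_fixture(list(chr1 = c(a = "00", b = "11", c = "22")),
                     pos = list(chr1 = c(100, 200)))
  kept <- ld_prune(vt)
  expect_length(kept, 1)
  expect_equal(kept, 1)  # equal MAF -> drop the larger position
  # all pairwise r2 <= 0.5 -> nothing removed
  vt2 <- make_fixture(list(chr1 = c(a = "001", b = "010", c = "100",
                                    d = "111", e = "201")),
                      spacing = 3000)
  expect_equal(ld_prune(vt2), seq_len(3))
  # random 10-site toys: no violating pair survives within the window
  for (sd in 1:8) {
    set.seed(sd)
    base <- sample(0:2, 12, replace = TRUE)
    g <- vapply(1:10, function(i) {
      if (runif(1) < 0.5) {
        v <- base
        flip <- runif(12) < 0.2
        v[flip] <- sample(0:2, sum(flip), replace = TRUE)
        v
      } else sample(0:2, 12, replace = TRUE)
    }, integer(12))
    vtr <- variant_table(chrom = rep("chr1", 10),
                         pos = sort(sample(1:9000, 10)),
                         ref = rep("A", 10), alt = rep("G", 10),
                         geno = t(g), samples = sprintf("s%02d", 1:12))
    kept <- ld_prune(vtr)
    for (a in seq_along(kept)) for (b in seq_len(a - 1)) {
      if (abs(vtr$pos[kept[a]] - vtr$pos[kept[b]]) < 10000) {
        v <- r2(vtr, kept[a], kept[b])
        if (!is.na(v)) expect_lte(v, 0.5)
      }
    }
  }
})
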