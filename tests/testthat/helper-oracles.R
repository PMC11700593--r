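# Independent brute-force oracles and fixture generators.  These re-derive
# expected values straight from the definitions, with naive loops, and are
# deliberately structured differently from the package implementations.

# --- ROH: literal re-implementation of the four detection steps ----------
oracle_roh <- function(vt, sample, params = roh_params()) {
  if (is.character(sample)) sample <- match(sample, vt$samples)
  ws <- params$window_snps
  out <- list()
  for (cc in unique(vt$chrom)) {
    idx <- which(vt$chrom == cc)
    M <- length(idx)
    if (M < ws) next
    d <- vt$geno[idx, sample]
    p <- as.numeric(vt$pos[idx])
    W <- M - ws + 1L
    # step 1: window acceptance
    acc <- logical(W)
    for (w in seq_len(W)) {
      win <- d[w:(w + ws - 1L)]
      acc[w] <- sum(win == 1L, na.rm = TRUE) <= params$window_het_max &&
        sum(is.na(win)) <= params$window_missing_max
    }
    # step 2: per-SNP hit fraction over covering windows
    elig <- logical(M)
    for (i in seq_len(M)) {
      cover <- intersect(seq(i - ws + 1L, i), seq_len(W))
      elig[i] <- length(cover) > 0 &&
        mean(acc[cover]) >= params$hit_threshold
    }
    # steps 3+4: runs, gap splitting, acceptance predicates
    run <- integer(0)
    flush <- function(run) {
      if (!length(run)) return(NULL)
      start <- p[run[1]]; end <- p[run[length(run)]]
      len <- end - start + 1
      if (len >= params$min_kb * 1000 && length(run) >= params$min_snps &&
          len / length(run) <= params$max_kb_per_snp * 1000)
        data.frame(sample = vt$samples[sample], chrom = cc, start = start,
                   end = end, length_bp = len, n_snps = length(run),
                   n_het = sum(d[run] == 1L, na.rm = TRUE))
      else NULL
    }
    for (i in seq_len(M)) {
      if (!elig[i]) {
        out[[length(out) + 1L]] <- flush(run); run <- integer(0)
      } else if (length(run) &&
                 p[i] - p[run[length(run)]] > params$gap_kb * 1000) {
        out[[length(out) + 1L]] <- flush(run); run <- i
      } else {
        run <- c(run, i)
      }
    }
    out[[length(out) + 1L]] <- flush(run)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      length_bp = numeric(), n_snps = integer(),
                      n_het = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# random genotype fixtures with ROH-like structure (runs of homozygosity
# interleaved with het-rich stretches, variable spacing, occasional gaps)
random_roh_fixture <- function(seed, max_snps = 2000) {
  set.seed(seed)
  M <- sample(60:max_snps, 1)
  gaps <- sample(c(2000, 5000, 10000, 20000), M, replace = TRUE)
  gaps[runif(M) < 0.005] <- 1.5e6  # rare gap-splitting jumps
  pos <- cumsum(gaps)
  d <- integer(M)
  i <- 1L
  while (i <= M) {
    blk <- min(M - i + 1L, sample(30:400, 1))
    in_roh <- runif(1) < 0.5
    seg <- if (in_roh) {
      s <- sample(c(0L, 2L), blk, replace = TRUE, prob = c(0.7, 0.3))
      s[runif(blk) < 0.005] <- 1L           # rare genotyping error
      s
    } else {
      sample(c(0L, 1L, 2L), blk, replace = TRUE, prob = c(0.45, 0.4, 0.15))
    }
    seg[runif(blk) < 0.02] <- NA_integer_   # missing calls
    d[i:(i + blk - 1L)] <- seg
    i <- i + blk
  }
  str <- paste(ifelse(is.na(d), ".", as.character(d)), collapse = "")
  make_fixture(list(chr1 = c(s1 = str)), pos = list(chr1 = pos))
}

# --- pi: exhaustive allele-pair comparison per site ----------------------
oracle_window_pi <- function(vt, samples, window_bp = 1e5) {
  tot <- 0
  for (k in seq_len(n_sites(vt))) {
    g <- vt$geno[k, samples]
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    alleles <- unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2 - x))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      diffs <- diffs + (alleles[a] != alleles[b])
    tot <- tot + diffs / choose(n, 2)
  }
  unname(tot / window_bp)
}

# --- exact MWU: bitmask enumeration with pairwise-win statistic ----------
oracle_mwu <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  vals <- c(a, b)
  ustat <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y)
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- ustat(a, b)
  mu <- n1 * n2 / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    u <- ustat(vals[bits == 1L], vals[bits == 0L])
    total <- total + 1L
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# --- small simulation worlds used across tests ---------------------------
quick_sim <- function(seed = 1, sample_size = 6, ...) {
  sim_config(n_chromosomes = 2, chrom_length = 5e6, mu = 5e-7,
             ne_trajectory = data.frame(start = 0, end = Inf, N = 30),
             sample_size = sample_size, burn_in = 20, seed = seed, ...)
}
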