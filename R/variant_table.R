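#' Construct a variant table
#'
#' The central genotype container: a sites-by-samples matrix of alternate
#' allele dosages (0, 1, 2 or `NA` for missing) together with per-site
#' coordinates, alleles and optional QUAL / depth, and per-sample ids and
#' population labels.  Sites must be sorted by chromosome with strictly
#' increasing positions inside each chromosome.
#'
#' @param chrom character vector of chromosome ids, one per site; sites of a
#'   chromosome must be contiguous.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single-base reference / alternate alleles per site.
#' @param geno integer matrix, sites x samples, values in `{0,1,2,NA}`.
#' @param qual optional numeric per-site quality (`NA` allowed).
#' @param depth optional integer matrix of per-call read depths, same shape
#'   as `geno`.
#' @param samples character vector of sample ids (defaults to
#'   `colnames(geno)`).
#' @param populations character vector of population labels per sample;
#'   defaults to `"POP"`.  The label `"OUT"` marks outgroup columns, which
#'   are ignored by ingroup statistics.
#' @param multiallelic optional logical per-site flag marking records that
#'   carried more than one alternate allele on input.
#' @return An object of class `variant_table`.
#' @seealso [make_fixture()], [read_vcf()], [simulate_population()]
#' @export
variant_table <- function(chrom, pos, ref, alt, geno, qual = NULL,
                          depth = NULL, samples = colnames(geno),
                          populations = NULL, multiallelic = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- length(pos)
  if (is.null(samples)) samples <- sprintf("sample_%02d", seq_len(ncol(geno)))
  if (is.null(populations)) populations <- rep("POP", ncol(geno))
  if (is.null(multiallelic)) multiallelic <- rep(FALSE, n_sites)
  vt <- structure(list(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = if (is.null(qual)) NULL else as.numeric(qual),
    geno = geno,
    depth = depth,
    samples = as.character(samples),
    populations = as.character(populations),
    multiallelic = as.logical(multiallelic)
  ), class = "variant_table")
  colnames(vt$geno) <- vt$samples
  if (!is.null(vt$depth)) {
    vt$depth <- as.matrix(vt$depth)
    storage.mode(vt$depth) <- "integer"
    colnames(vt$depth) <- vt$samples
  }
  validate_variant_table(vt)
  vt
}

validate_variant_table <- function(vt) {
  n <- length(vt$pos)
  stopifnot(length(vt$chrom) == n, length(vt$ref) == n, length(vt$alt) == n,
            nrow(vt$geno) == n, ncol(vt$geno) == length(vt$samples),
            length(vt$populations) == length(vt$samples))
  if (!is.null(vt$qual)) stopifnot(length(vt$qual) == n)
  if (!is.null(vt$depth)) stopifnot(all(dim(vt$depth) == dim(vt$geno)))
  bad <- !(vt$geno %in% c(0L, 1L, 2L) | is.na(vt$geno))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (n > 1) {
    r <- rle(vt$chrom)
    if (anyDuplicated(r$values))
      stop("sites of one chromosome must be contiguous")
    d <- diff(vt$pos)
    same <- vt$chrom[-1] == vt$chrom[-n]
    if (any(same & d <= 0))
      stop("positions must be strictly increasing within each chromosome")
  }
  invisible(vt)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d sites x %d samples (%d chromosome%s)\n",
              n_sites(x), n_samples(x), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1) "" else "s"))
  ing <- sum(x$populations != "OUT")
  if (ing < n_samples(x))
    cat(sprintf("  %d ingroup + %d outgroup samples\n", ing,
                n_samples(x) - ing))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param vt a [variant_table()].
#' @return integer count.
#' @export
n_sites <- function(vt) length(vt$pos)

#' @rdname n_sites
#' @export
n_samples <- function(vt) length(vt$samples)

#' Subset a variant table
#'
#' @param vt a [variant_table()].
#' @param sites integer or logical index of sites to keep (order preserved).
#' @param samples integer, logical or character index of samples to keep.
#' @return A new `variant_table`.
#' @export
subset_variants <- function(vt, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(vt))
  if (is.null(samples)) samples <- seq_len(n_samples(vt))
  if (is.character(samples)) samples <- match(samples, vt$samples)
  variant_table(
    chrom = vt$chrom[sites], pos = vt$pos[sites], ref = vt$ref[sites],
    alt = vt$alt[sites],
    geno = vt$geno[sites, samples, drop = FALSE],
    qual = if (is.null(vt$qual)) NULL else vt$qual[sites],
    depth = if (is.null(vt$depth)) NULL
            else vt$depth[sites, samples, drop = FALSE],
    samples = vt$samples[samples], populations = vt$populations[samples],
    multiallelic = vt$multiallelic[sites]
  )
}

#' Indices of ingroup (non-outgroup) samples
#' @param vt a [variant_table()].
#' @return integer vector of column indices with population label != "OUT".
#' @export
ingroup_samples <- function(vt) which(vt$populations != "OUT")

#' Build a deterministic genotype fixture
#'
#' Turns explicit per-sample genotype strings into a [variant_table()], for
#' constructing exact test cases.  Each string is a sequence over
#' `0` (hom ref), `1` (het), `2` (hom alt) and `.` (missing), one character
#' per site.
#'
#' @param spec named list: one element per chromosome, each a named character
#'   vector of genotype strings (names are sample ids; all strings of one
#'   chromosome must have equal length and all chromosomes must share the
#'   same sample set).
#' @param pos optional list parallel to `spec` giving integer positions per
#'   chromosome; defaults to `start, start+spacing, ...`.
#' @param spacing,start default position grid (bp) when `pos` is absent.
#' @param populations optional per-sample population labels.
#' @return A `variant_table` with `ref = "A"`, `alt = "G"` placeholders.
#' @examples
#' make_fixture(list(chr1 = c(a = "012.", b = "0110")))
#' @export
make_fixture <- function(spec, pos = NULL, spacing = 10000L, start = 10000L,
                         populations = NULL) {
  stopifnot(is.list(spec))
  if (length(spec) == 0 || all(nchar(unlist(spec)) == 0)) {
    return(variant_table(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         geno = matrix(integer(), 0,
                                       length(spec[[1]] %||% character())),
                         samples = names(spec[[1]] %||% character()),
                         populations = populations))
  }
  samples <- names(spec[[1]])
  chrom <- character(); posv <- integer(); rows <- list()
  for (ci in seq_along(spec)) {
    strs <- spec[[ci]]
    if (!identical(names(strs), samples))
      stop("all chromosomes must list the same samples in the same order")
    len <- unique(nchar(strs))
    if (length(len) != 1)
      stop("genotype strings of one chromosome must have equal length")
    chars <- do.call(cbind, lapply(strs, function(s) strsplit(s, "")[[1]]))
    ok <- chars %in% c("0", "1", "2", ".")
    if (!all(ok))
      stop("malformed genotype symbol: ",
           paste(unique(chars[!ok]), collapse = " "))
    g <- suppressWarnings(matrix(as.integer(chars), nrow = len))
    p <- if (!is.null(pos)) as.integer(pos[[ci]])
         else as.integer(start + spacing * (seq_len(len) - 1L))
    stopifnot(length(p) == len)
    chrom <- c(chrom, rep(names(spec)[ci] %||% paste0("chr", ci), len))
    posv <- c(posv, p)
    rows[[ci]] <- g
  }
  geno <- do.call(rbind, rows)
  colnames(geno) <- samples
  variant_table(chrom = chrom, pos = posv,
                ref = rep("A", length(posv)), alt = rep("G", length(posv)),
                geno = geno, samples = samples, populations = populations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
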