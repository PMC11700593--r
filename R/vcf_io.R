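#' Read a multi-sample VCF into a variant table
#'
#' Parsing is delegated to Bioconductor's `VariantAnnotation::readVcf()`;
#' the records are then mapped onto the dosage representation used
#' throughout this package.  Multi-allelic records are kept (flagged via the
#' `multiallelic` field) with dosages counting copies of the *first*
#' alternate allele; calls carrying a higher-numbered allele are set to
#' missing.  Plain-gzip input is transparently decompressed.
#'
#' @param path VCF file (`.vcf` or `.vcf.gz`), VCF 4.x with a GT FORMAT
#'   field; DP is used when present.
#' @param annotation_path optional sidecar TSV with columns
#'   `chrom, pos, impact, sift_score`; matched by chromosome and position
#'   and attached as the `annotation` field (see [classify_impact()]).
#'   When absent, a snpEff-style `ANN` INFO field is parsed instead if the
#'   VCF carries one (impact of the first transcript).
#' @param populations optional per-sample population labels.
#' @return A [variant_table()]; errors on unsorted positions.
#' @export
read_vcf <- function(path, annotation_path = NULL, populations = NULL) {
  stopifnot(file.exists(path))
  src <- path
  if (grepl("\\.gz$", path)) {
    # plain gzip (not bgzf): decompress to a temp file for readVcf
    tmp <- tempfile(fileext = ".vcf")
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    writeLines(readLines(con), tmp)
    src <- tmp
  }
  vcf <- VariantAnnotation::readVcf(src, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  n <- length(pos)
  if (n > 1) {
    r <- rle(chrom)
    if (anyDuplicated(r$values)) stop("VCF records are not grouped by chromosome")
    same <- chrom[-1] == chrom[-n]
    if (any(same & diff(pos) <= 0)) stop("VCF positions are not sorted")
  }
  hdr_contigs <- rownames(VariantAnnotation::meta(
    VariantAnnotation::header(vcf))$contig %||% NULL)
  if (!is.null(hdr_contigs) && length(hdr_contigs) &&
      !all(unique(chrom) %in% hdr_contigs))
    stop("unknown contig in VCF body: ",
         paste(setdiff(unique(chrom), hdr_contigs), collapse = ", "))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt_all <- as.character(BiocGenerics::unlist(altl))
  first_idx <- cumsum(c(1L, head(n_alt, -1L)))
  alt1 <- rep(NA_character_, n)
  alt1[n_alt > 0] <- alt_all[first_idx[n_alt > 0]]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  geno <- matrix(.gt_to_dosage(as.vector(gt)), nrow = n)
  dp <- VariantAnnotation::geno(vcf)$DP
  if (!is.null(dp)) { dp <- matrix(as.integer(dp), nrow = n) }
  qual <- VariantAnnotation::qual(vcf)
  vt <- variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt1,
                      geno = geno, qual = qual, depth = dp,
                      samples = colnames(gt), populations = populations,
                      multiallelic = n_alt > 1)
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- read_annotations(annotation_path, vt)
  } else {
    info <- VariantAnnotation::info(vcf)
    if ("ANN" %in% colnames(info)) ann <- .ann_to_table(info$ANN, vt)
  }
  vt$annotation <- ann
  vt
}

# vectorized GT string -> dosage via lookup on unique values
.gt_to_dosage <- function(gt) {
  u <- unique(gt)
  du <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (any(is.na(ai)) || any(ai > 1L)) return(NA_integer_)
    sum(ai)
  }, integer(1))
  unname(du[match(gt, u)])
}

# snpEff ANN strings -> annotation table (first transcript's impact)
.ann_to_table <- function(ann, vt) {
  first <- vapply(as.list(ann), function(x)
    if (length(x) == 0 || is.na(x[1])) NA_character_ else x[1], "")
  impact <- vapply(strsplit(first, "\\|"), function(f)
    if (length(f) >= 3) f[3] else NA_character_, "")
  data.table::data.table(chrom = vt$chrom, pos = vt$pos,
                         impact = impact, sift_score = NA_real_)
}

#' Read a sidecar annotation TSV
#'
#' @param path TSV with columns `chrom, pos, impact, sift_score`
#'   (`sift_score` may be `NA` outside MODERATE sites).
#' @param vt optional [variant_table()]: when given, rows are aligned to its
#'   sites (unannotated sites get `NA` impact).
#' @return A `data.table` with one row per site of `vt` (or per TSV row).
#' @export
read_annotations <- function(path, vt = NULL) {
  ann <- data.table::fread(path, colClasses = list(
    character = "chrom", integer = "pos"))
  stopifnot(all(c("chrom", "pos", "impact") %in% names(ann)))
  if (!"sift_score" %in% names(ann)) ann$sift_score <- NA_real_
  if (is.null(vt)) return(ann)
  key <- paste(vt$chrom, vt$pos)
  m <- match(key, paste(ann$chrom, ann$pos))
  data.table::data.table(chrom = vt$chrom, pos = vt$pos,
                         impact = ann$impact[m],
                         sift_score = as.numeric(ann$sift_score[m]))
}

#' Write a variant table as VCF 4.2
#'
#' Emits GT (and DP when present) with contig header lines; `.gz` paths are
#' gzip-compressed.  Round-trips dosages, positions and missingness exactly
#' through [read_vcf()].
#'
#' @param vt a [variant_table()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @param chrom_lengths optional named vector of contig lengths; defaults to
#'   the largest observed position per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, chrom_lengths = NULL) {
  chroms <- unique(vt$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc)
      max(vt$pos[vt$chrom == cc]), 0L)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poperosion",
    sprintf("##contig=<ID=%s,length=%d>", chroms,
            as.integer(chrom_lengths[chroms])),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(vt$depth))
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")
  )
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", n_sites(vt), n_samples(vt))
  ok <- !is.na(vt$geno)
  gt[ok] <- gt_code[as.character(vt$geno[ok])]
  if (!is.null(vt$depth)) {
    dp <- ifelse(is.na(vt$depth), ".", as.character(vt$depth))
    cells <- matrix(paste(gt, dp, sep = ":"), nrow(gt))
    fmt <- "GT:DP"
  } else {
    cells <- gt
    fmt <- "GT"
  }
  qual <- if (is.null(vt$qual)) rep(".", n_sites(vt))
          else ifelse(is.na(vt$qual), ".", format(vt$qual, trim = TRUE))
  body <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, qual, "PASS", ".",
                fmt, sep = "\t")
  if (n_sites(vt) > 0)
    body <- paste(body, apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(hdr, body), con)
  invisible(path)
}
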