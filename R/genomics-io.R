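#' Read a VCF into a genotype matrix
#'
#' Loads a VCF v4.x (via \pkg{vcfR}), keeping biallelic SNP records only;
#' multi-allelic and non-SNP records are skipped and counted. Haploid GT
#' tokens (single allele, as emitted for hemizygous females on Z) are
#' accepted and encoded as dosage \{0, 2\} with the haploid flag set;
#' `./.` and `.` become missing.
#'
#' @param path VCF file path (plain or gzipped).
#' @param sex optional named character vector of sample sexes ("M"/"F").
#' @return A [geno_matrix()] with attribute `"skipped"` (count of skipped
#'   records).
#' @export
read_vcf <- function(path, sex = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip) message("read_vcf: skipped ", n_skip,
                      " multi-allelic or non-SNP records")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  tokens <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
              "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "0" = 0L, "1" = 2L)
  flat <- gsub(":.*", "", as.vector(gt))
  miss <- is.na(flat) | flat %in% c("./.", ".|.", ".")
  dos <- tokens[flat]
  bad <- which(!miss & is.na(dos))
  if (length(bad)) {
    rec <- ((bad[1] - 1) %% nrow(gt)) + 1
    stop("read_vcf: malformed GT token '", flat[bad[1]], "' at record ", rec,
         " (", fix[rec, "CHROM"], ":", fix[rec, "POS"], ")")
  }
  dos[miss] <- NA_integer_
  hap <- !miss & !grepl("[/|]", flat)
  dosage <- t(matrix(dos, nrow = nrow(gt)))
  haploid <- t(matrix(hap, nrow = nrow(gt)))
  rownames(dosage) <- colnames(gt)
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  sites$sex_linked <- as.logical(colSums(haploid) > 0)
  sx <- rep(NA_character_, nrow(dosage))
  if (!is.null(sex)) sx <- unname(sex[rownames(dosage)])
  gm <- geno_matrix(dosage, sites, sex = sx, haploid = haploid)
  attr(gm, "skipped") <- n_skip
  gm
}

#' Write a genotype matrix as a plain-text GT-only VCF v4.2
#'
#' Haploid calls are written as single-allele GT tokens; missing calls as
#' `./.` (diploid) or `.` (haploid). Positions are 1-based.
#'
#' @param x a [geno_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  n <- nrow(x$dosage); m <- ncol(x$dosage)
  gt_dip <- c("0/0", "0/1", "1/1")
  gt_hap <- c("0", NA, "1")
  body <- character(m)
  gt <- matrix("./.", n, m)
  for (d in 0:2) gt[!x$haploid & !is.na(x$dosage) & x$dosage == d] <- gt_dip[d + 1]
  gt[x$haploid] <- "."
  for (d in c(0L, 2L)) gt[x$haploid & !is.na(x$dosage) & x$dosage == d] <- gt_hap[d + 1]
  s <- x$sites
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=hzgenomics",
    paste0("##contig=<ID=", unique(s$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(x$dosage)), collapse = "\t"))
  recs <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(recs, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Site-level filtering with fixed rule order
#'
#' Applies, in order: biallelic SNP check, minor-allele-count, depth (only
#' when a depth matrix is supplied; a no-op with a warning otherwise, since
#' GT-only VCFs carry no DP), and per-site missingness. Two named profiles
#' are provided: `"wgs"` (MAC >= 4, mean depth in [2, 50], <= 20% missing)
#' and `"amplicon"` (<= 50% missing only).
#'
#' @param x a [geno_matrix()].
#' @param profile `"wgs"`, `"amplicon"`, or NULL to use explicit thresholds.
#' @param min_mac minimum minor allele count (sites below are removed).
#' @param min_depth,max_depth mean-depth bounds per site.
#' @param max_missing maximum fraction of missing calls per site.
#' @param depth optional numeric matrix of per-call depths (samples x sites).
#' @return list with `geno` (filtered matrix) and `report` (per-rule removal
#'   counts).
#' @export
filter_sites <- function(x, profile = NULL, min_mac = 0,
                         min_depth = -Inf, max_depth = Inf,
                         max_missing = 1, depth = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("wgs", "amplicon"))
    if (profile == "wgs") {
      min_mac <- 4; min_depth <- 2; max_depth <- 50; max_missing <- 0.2
    } else {
      max_missing <- 0.5
    }
  }
  keep <- rep(TRUE, ncol(x$dosage))
  report <- list()
  snp <- nchar(x$sites$ref) == 1 & nchar(x$sites$alt) == 1
  report$non_biallelic_snp <- sum(keep & !snp)
  keep <- keep & snp

  ac <- allele_counts(x)
  mac <- pmin(ac$alt_count, ac$n_alleles - ac$alt_count)
  fail <- keep & mac < min_mac
  report$minor_allele_count <- sum(fail)
  keep <- keep & !fail

  if (is.finite(min_depth) || is.finite(max_depth)) {
    if (is.null(depth)) {
      warning("depth thresholds requested but no depth matrix supplied; ",
              "depth rules skipped")
      report$depth <- 0L
    } else {
      md <- colMeans(depth, na.rm = TRUE)
      fail <- keep & (md < min_depth | md > max_depth)
      report$depth <- sum(fail)
      keep <- keep & !fail
    }
  } else report$depth <- 0L

  fmiss <- colMeans(is.na(x$dosage))
  fail <- keep & fmiss > max_missing
  report$missingness <- sum(fail)
  keep <- keep & !fail

  report$retained <- sum(keep)
  if (!any(keep)) warning("filter_sites: no sites survived filtering")
  list(geno = x[, keep], report = report, kept = which(keep))
}

# allele-frequency-standardized genotype correlation (GCTA-style GRM):
# Z_ij = (g_ij - 2 p_j) / sqrt(2 p_j (1 - p_j)), K = Z Z' / m.
# Missing entries are mean-imputed (zero after centering). Full sibs have
# expected off-diagonal ~0.5, duplicates ~1.
grm_matrix <- function(x) {
  g <- if (inherits(x, "geno_matrix")) x$dosage else x
  p <- colMeans(g, na.rm = TRUE) / 2
  use <- p > 0 & p < 1 & !is.na(p)
  g <- g[, use, drop = FALSE]; p <- p[use]
  z <- sweep(g, 2, 2 * p)
  z[is.na(z)] <- 0
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  tcrossprod(z) / ncol(z)
}

#' Sample-level filtering: depth, missingness, relatedness
#'
#' Removes samples failing a mean-depth floor (when depth data exist) or
#' an all-missing check, then resolves related pairs: relatedness is the
#' allele-frequency-standardized genotype correlation (GRM off-diagonal);
#' for each pair above `max_relatedness` exactly one member is removed —
#' the one with more missing data, ties broken by removing the
#' later-sorting sample id.
#'
#' @param x a [geno_matrix()].
#' @param min_mean_depth mean-depth floor per sample (needs `depth`).
#' @param max_relatedness relatedness threshold in [0, 1], or NULL to skip.
#' @param depth optional numeric matrix of per-call depths.
#' @return list with `geno`, `report` (removed ids per rule), and the
#'   relatedness matrix used (if computed).
#' @export
filter_samples <- function(x, min_mean_depth = 2, max_relatedness = NULL,
                           depth = NULL) {
  ids <- sample_ids(x)
  removed <- list(depth = character(0), missing = character(0),
                  related = character(0))
  keep <- rep(TRUE, length(ids))
  if (!is.null(depth)) {
    md <- rowMeans(depth, na.rm = TRUE)
    removed$depth <- ids[md < min_mean_depth]
    keep <- keep & md >= min_mean_depth
  }
  fmiss <- rowMeans(is.na(x$dosage))
  removed$missing <- ids[keep & fmiss >= 1]
  keep <- keep & fmiss < 1
  rel <- NULL
  if (!is.null(max_relatedness)) {
    if (max_relatedness < 0 || max_relatedness > 1)
      stop("max_relatedness must lie in [0, 1]")
    sub <- x[which(keep), ]
    rel <- grm_matrix(sub)
    ut <- which(upper.tri(rel) & rel > max_relatedness, arr.ind = TRUE)
    if (nrow(ut)) {
      ord <- order(rel[ut], decreasing = TRUE)
      ut <- ut[ord, , drop = FALSE]
      sub_ids <- sample_ids(sub)
      sub_miss <- rowMeans(is.na(sub$dosage))
      alive <- rep(TRUE, length(sub_ids))
      for (k in seq_len(nrow(ut))) {
        i <- ut[k, 1]; j <- ut[k, 2]
        if (!alive[i] || !alive[j]) next
        drop <- if (sub_miss[i] > sub_miss[j]) i
                else if (sub_miss[j] > sub_miss[i]) j
                else if (sub_ids[i] > sub_ids[j]) i else j
        alive[drop] <- FALSE
        removed$related <- c(removed$related, sub_ids[drop])
      }
      keep[match(sub_ids[!alive], ids)] <- FALSE
    }
  }
  list(geno = x[which(keep), ], report = removed, relatedness = rel)
}

#' Polarize genotypes against a reference individual or group
#'
#' Re-encodes dosages so that 0 means homozygous for the allele the
#' reference carries (Baltimore-like), 1 stays heterozygote, and 2 means
#' homozygous for the other species' allele. With a single reference
#' sample, sites where the reference is heterozygous or missing are flagged
#' unpolarized and dropped from the output; with a reference group the
#' group's majority allele is used (ties unpolarized).
#'
#' @param x a [geno_matrix()].
#' @param reference sample id, or character vector of ids for a group
#'   consensus.
#' @return A polarized [geno_matrix()] containing only polarizable sites,
#'   with attributes `"swapped"` (logical per retained site),
#'   `"unpolarized"` (original indices of dropped sites), and `"kept"`.
#' @export
encode_polarized <- function(x, reference) {
  stopifnot(all(reference %in% sample_ids(x)))
  if (length(reference) == 1) {
    rd <- x$dosage[reference, ]
    swap <- !is.na(rd) & rd == 2L
    ok <- !is.na(rd) & rd != 1L
  } else {
    sub <- x[reference, ]
    ac <- allele_counts(sub)
    swap <- !is.na(ac$freq) & ac$freq > 0.5
    ok <- !is.na(ac$freq) & ac$freq != 0.5
  }
  out <- x[, which(ok)]
  sw <- swap[ok]
  out$dosage[, sw] <- 2L - out$dosage[, sw, drop = FALSE]
  tmp <- out$sites$ref[sw]
  out$sites$ref[sw] <- out$sites$alt[sw]
  out$sites$alt[sw] <- tmp
  attr(out, "swapped") <- sw
  attr(out, "unpolarized") <- which(!ok)
  attr(out, "kept") <- which(ok)
  out
}

#' Greedy sliding-window LD pruning
#'
#' Removes, within sliding windows of `window` SNPs advanced by `step`,
#' the later member of any pair with squared genotype correlation above
#' `r2_max`. Used to prepare admixture input.
#'
#' @param x a [geno_matrix()].
#' @param window window size in SNPs.
#' @param step step size in SNPs.
#' @param r2_max maximum allowed r-squared.
#' @return A pruned [geno_matrix()] with attribute `"kept"`.
#' @export
ld_prune <- function(x, window = 50, step = 10, r2_max = 0.2) {
  g <- x$dosage
  p <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- p[j]
  m <- ncol(g)
  keep <- rep(TRUE, m)
  starts <- seq(1, max(1, m - 1), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1, m)
    idx <- idx[keep[idx]]
    idx <- idx[apply(g[, idx, drop = FALSE], 2, stats::sd) > 0]
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(g[, idx, drop = FALSE]))^2
    cc[is.na(cc)] <- 0
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      hits <- which(cc[a, ] > r2_max)
      hits <- hits[hits > a & keep[idx[hits]]]
      keep[idx[hits]] <- FALSE
    }
  }
  out <- x[, which(keep)]
  attr(out, "kept") <- which(keep)
  out
}

#' Read gene/exon feature intervals from GFF3 or BED
#'
#' Uses \pkg{rtracklayer} when available; otherwise falls back to a plain
#' reader for tab-separated BED (0-based half-open, converted to 1-based
#' inclusive) and GFF3. Intervals are returned 1-based inclusive and sorted
#' per chromosome.
#'
#' @param path file path ending in .gff, .gff3, or .bed.
#' @return data.frame with `chrom`, `start`, `end`, `type`, `name`.
#' @export
read_features <- function(path) {
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    df$type <- if (!is.null(gr$type)) as.character(gr$type) else "region"
    nm <- if (!is.null(gr$Name)) gr$Name else if (!is.null(gr$name)) gr$name
          else if (!is.null(gr$ID)) gr$ID else NA
    df$name <- as.character(nm)
  } else if (is_bed) {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    df <- data.frame(chrom = raw[[1]], start = raw[[2]] + 1, end = raw[[3]],
                     type = "region",
                     name = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
                     stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE, quote = "")
    nm <- sub(".*(?:Name|ID)=([^;]+).*", "\\1", raw[[9]])
    df <- data.frame(chrom = raw[[1]], start = raw[[4]], end = raw[[5]],
                     type = raw[[3]], name = nm, stringsAsFactors = FALSE)
  }
  stopifnot(all(df$start <= df$end))
  df[order(df$chrom, df$start), ]
}

#' Build feature intervals in code
#'
#' Convenience constructor for annotation tables matching [read_features()].
#'
#' @param chrom,start,end,type,name vectors of equal length (1-based
#'   inclusive coordinates).
#' @return sorted data.frame of feature intervals.
#' @export
feature_intervals <- function(chrom, start, end, type = "gene", name = NULL) {
  if (is.null(name)) name <- sprintf("feat%03d", seq_along(chrom))
  stopifnot(all(start <= end))
  df <- data.frame(chrom = chrom, start = start, end = end, type = type,
                   name = name, stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), ]
}
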