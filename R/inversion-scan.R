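#' Local PCA in non-overlapping SNP windows
#'
#' For each window of `window_snps` consecutive SNPs (per chromosome;
#' incomplete trailing windows dropped), computes the centered sample
#' covariance (mean-imputing missing dosages within the window), normalizes
#' it to unit trace so windows are compared by structure rather than raw
#' variance, and stores its top-k eigenpairs as a rank-k reconstruction.
#'
#' @param x a [geno_matrix()].
#' @param window_snps SNPs per window.
#' @param k eigenpairs retained.
#' @return list of class `local_pca_map`: per window `chrom`, `start`,
#'   `end`, `sites`, `values` (top-k eigenvalues, equal to variance
#'   fractions after trace normalization), `vectors` (samples x k).
#' @export
local_pca_windows <- function(x, window_snps = 100L, k = 2L) {
  s <- x$sites
  wins <- list()
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    nw <- length(idx) %/% window_snps
    if (nw == 0) {
      warning("chromosome ", ch, " has fewer than ", window_snps,
              " SNPs; no windows")
      next
    }
    for (b in seq_len(nw)) {
      j <- idx[((b - 1) * window_snps + 1):(b * window_snps)]
      g <- x$dosage[, j, drop = FALSE]
      p <- colMeans(g, na.rm = TRUE)
      for (cjj in which(colSums(is.na(g)) > 0))
        g[is.na(g[, cjj]), cjj] <- p[cjj]
      g <- sweep(g, 2, colMeans(g))
      C <- tcrossprod(g) / max(1, window_snps - 1)
      tr <- sum(diag(C))
      if (tr > 0) C <- C / tr
      eg <- eigen(C, symmetric = TRUE)
      wins[[length(wins) + 1]] <- list(
        chrom = ch, start = s$pos[j[1]], end = s$pos[j[length(j)]],
        sites = j, values = eg$values[seq_len(k)],
        vectors = eg$vectors[, seq_len(k), drop = FALSE])
    }
  }
  structure(list(windows = wins, k = k, window_snps = window_snps,
                 n_samples = nrow(x$dosage)),
            class = "local_pca_map")
}

# Frobenius distance between rank-k covariance reconstructions; invariant
# to eigenvector sign flips and rotations within degenerate eigenspaces.
lpca_distance_matrix <- function(map) {
  w <- map$windows
  nw <- length(w)
  D <- matrix(0, nw, nw)
  sq <- vapply(w, function(x) sum(x$values^2), 0)
  for (i in seq_len(nw)) {
    for (j in seq_len(nw)) {
      if (j <= i) next
      cross <- crossprod(w[[i]]$vectors, w[[j]]$vectors)  # k x k
      term <- sum((w[[i]]$values %o% w[[j]]$values) * cross^2)
      d2 <- sq[i] + sq[j] - 2 * term
      D[i, j] <- D[j, i] <- sqrt(max(d2, 0))
    }
  }
  D
}

#' MDS outlier scan over a local-PCA map
#'
#' Embeds the pairwise Frobenius distances between windowed rank-k
#' covariance reconstructions by classical MDS, flags windows whose
#' absolute first MDS coordinate exceeds its `percentile` quantile, and
#' groups flagged windows into maximal contiguous clusters (runs tolerate
#' up to `gap` unflagged windows, since percentile thresholds fragment true
#' runs).
#'
#' @param map a [local_pca_windows()] result.
#' @param ndim MDS dimensions retained.
#' @param percentile outlier threshold quantile on the scanned |MDS axis|.
#' @param gap gap tolerance (windows) when building clusters.
#' @param axis MDS axis to scan (default 1), or `"auto"` to scan the axis
#'   with the heaviest outlier tail (largest kurtosis) among the `ndim`
#'   retained — classical MDS orders axes by eigenvalue, so the axis
#'   carrying a localized anomaly is not always the first.
#' @param grow_ratio secondary (hysteresis) threshold as a fraction of the
#'   hard threshold: each cluster's span is extended through adjacent
#'   windows whose |MDS| coordinate exceeds `grow_ratio * threshold`,
#'   counteracting the fragmentation that a hard 99th-percentile cut
#'   imposes on genuinely contiguous anomalies. `NULL` disables growth.
#'   Cluster `n_windows` always counts only the hard-threshold outlier
#'   windows.
#' @return list of class `mds_outliers`: `mds` (window coordinates),
#'   `axis` (the axis scanned), `threshold`, `flag`, `clusters` (chrom,
#'   start, end, n_windows, n_variants), `windows` summary table.
#' @export
mds_outlier_scan <- function(map, ndim = 2, percentile = 0.99, gap = 2,
                             axis = 1, grow_ratio = 0.5) {
  w <- map$windows
  if (length(w) < 20) stop("need at least 20 windows for an MDS scan")
  D <- lpca_distance_matrix(map)
  if (max(D) < 1e-12) {
    warning("degenerate (all-equal) window distances; zero outliers")
    mds <- matrix(0, length(w), ndim)
    axis <- 1L
    thr <- 0
    flag <- rep(FALSE, length(w))
  } else {
    mds <- stats::cmdscale(D, k = ndim)
    if (identical(axis, "auto")) {
      kurt <- apply(mds, 2, function(v) {
        s2 <- stats::var(v)
        if (s2 == 0) 0 else mean((v - mean(v))^4) / s2^2
      })
      axis <- which.max(kurt)
    }
    thr <- stats::quantile(abs(mds[, axis]), percentile, names = FALSE)
    flag <- abs(mds[, axis]) > thr
  }
  tab <- data.frame(chrom = vapply(w, `[[`, "", "chrom"),
                    start = vapply(w, `[[`, 0, "start"),
                    end = vapply(w, `[[`, 0, "end"),
                    n_snps = lengths(lapply(w, `[[`, "sites")),
                    mds1 = mds[, 1], mds_scan = mds[, axis], flag = flag,
                    stringsAsFactors = FALSE)
  soft <- if (!is.null(grow_ratio) && any(flag)) grow_ratio * thr else Inf
  clusters <- list()
  for (ch in unique(tab$chrom)) {
    idx <- which(tab$chrom == ch)
    fl <- which(flag[idx])
    if (!length(fl)) next
    runs <- split(fl, cumsum(c(1, diff(fl) > gap + 1)))
    for (r in runs) {
      lo <- min(r); hi <- max(r)
      # hysteresis growth through adjacent soft-threshold windows
      while (lo > 1 && abs(tab$mds_scan[idx[lo - 1]]) > soft) lo <- lo - 1
      while (hi < length(idx) && abs(tab$mds_scan[idx[hi + 1]]) > soft)
        hi <- hi + 1
      span <- idx[lo]:idx[hi]
      clusters[[length(clusters) + 1]] <- data.frame(
        chrom = ch, start = tab$start[idx[lo]],
        end = tab$end[idx[hi]], n_windows = length(r),
        n_variants = sum(tab$n_snps[span]), stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters)
              else data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0), n_windows = integer(0),
                              n_variants = integer(0))
  structure(list(mds = mds, axis = axis, threshold = thr, flag = flag,
                 clusters = clusters, windows = tab),
            class = "mds_outliers")
}

simple_silhouette <- function(v, cl) {
  ks <- sort(unique(cl))
  if (length(ks) < 2) return(0)
  s <- vapply(seq_along(v), function(i) {
    own <- cl[i]
    a <- mean(abs(v[i] - v[cl == own & seq_along(v) != i]))
    if (is.nan(a)) a <- 0
    b <- min(vapply(ks[ks != own], function(k) mean(abs(v[i] - v[cl == k])), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Karyotype individuals for a putative inversion
#'
#' PCA over the SNPs of the candidate region, 1-D k-means (k = 3) on PC1
#' (the inversion-dosage axis), middle cluster labeled AB. Attaches each
#' sample's observed heterozygosity over the region SNPs and a validation
#' report: one-sided Mann-Whitney test that AB heterozygosity exceeds both
#' homozygote classes, and a count of females assigned AB (impossible for
#' a Z-linked inversion, where females are hemizygous). Calls carry a
#' low-confidence flag when the three clusters are poorly separated
#' (mean silhouette < 0.2).
#'
#' @param x a [geno_matrix()].
#' @param region list/row with `chrom`, `start`, `end`, or an integer
#'   vector of site indices.
#' @param min_snps minimum region SNPs required.
#' @param anchor_a optional sample ids of known A-orientation homozygotes
#'   (e.g. allopatric parental-A individuals); fixes which end cluster is
#'   labeled AA (otherwise the lower-PC1 cluster is AA, an arbitrary
#'   orientation).
#' @return list of class `karyotype_calls`: `calls` (data.frame id, sex,
#'   pc1, heterozygosity, karyotype), `het_test_p`, `female_ab`,
#'   `low_confidence`, `silhouette`, `var_frac_pc1`.
#' @export
karyotype_individuals <- function(x, region, min_snps = 50,
                                  anchor_a = NULL) {
  s <- x$sites
  idx <- if (is.numeric(region)) as.integer(region)
         else which(s$chrom == region$chrom & s$pos >= region$start &
                    s$pos <= region$end)
  if (length(idx) < min_snps)
    stop("region has ", length(idx), " SNPs; need >= ", min_snps)
  sub <- x[, idx]
  pca <- genotype_pca(sub, n_axes = 2, scale = FALSE)
  pc1 <- pca$scores[, 1]
  centers <- stats::quantile(pc1, c(0.05, 0.5, 0.95), names = FALSE)
  if (length(unique(centers)) < 3)
    centers <- seq(min(pc1), max(pc1), length.out = 3)
  km <- suppressWarnings(stats::kmeans(pc1, centers = matrix(centers, 3, 1)))
  ord <- order(km$centers)
  lab <- c("AA", "AB", "BB")[match(km$cluster, ord)]
  if (!is.null(anchor_a)) {
    ia <- match(anchor_a, sample_ids(x))
    ia <- ia[!is.na(ia)]
    if (length(ia) && mean(lab[ia] == "BB") > mean(lab[ia] == "AA")) {
      lab <- chartr("AB", "BA", lab)                 # swap end labels
      lab[lab == "BA"] <- "AB"
    }
  }
  d <- sub$dosage; dip <- !is.na(d) & !sub$haploid
  het <- rowSums(d == 1 & dip, na.rm = TRUE) / pmax(rowSums(dip), 1)
  sil <- simple_silhouette(pc1, km$cluster)
  is_ab <- lab == "AB"
  p_het <- if (any(is_ab) && any(!is_ab))
    suppressWarnings(stats::wilcox.test(het[is_ab], het[!is_ab],
                                        alternative = "greater")$p.value)
    else NA_real_
  female_ab <- sum(is_ab & !is.na(x$sex) & x$sex == "F")
  calls <- data.frame(id = sample_ids(x), sex = x$sex, pc1 = pc1,
                      heterozygosity = het, karyotype = lab,
                      stringsAsFactors = FALSE)
  structure(list(calls = calls, het_test_p = p_het, female_ab = female_ab,
                 low_confidence = sil < 0.2, silhouette = sil,
                 var_frac_pc1 = pca$var_frac[1], sites = idx),
            class = "karyotype_calls")
}

#' Estimate the span of a rearrangement from MDS-outlier clusters
#'
#' Merges same-chromosome outlier clusters whose gaps are at most
#' `merge_gap` bp and reports one span per chromosome as
#' [min start, max end]; the length is the coordinate difference end -
#' start.
#'
#' @param outliers an [mds_outlier_scan()] result (or its `clusters`
#'   data.frame).
#' @param merge_gap maximum gap (bp) between clusters merged into one span.
#' @return data.frame: `chrom`, `start`, `end`, `length_bp`, `n_clusters`.
#' @export
estimate_inversion_span <- function(outliers, merge_gap = 5e6) {
  cl <- if (inherits(outliers, "mds_outliers")) outliers$clusters else outliers
  if (!nrow(cl)) stop("no outlier clusters to span")
  out <- list()
  for (ch in unique(cl$chrom)) {
    sub <- cl[cl$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(1, sub$start[-1] - sub$end[-nrow(sub)] > merge_gap))
    for (g in unique(grp)) {
      s <- sub[grp == g, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(s$start), end = max(s$end),
        length_bp = max(s$end) - min(s$start), n_clusters = nrow(s),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genes overlapping a genomic span
#'
#' @param features feature intervals (see [feature_intervals()]); rows of
#'   type `gene` are used when present.
#' @param span list/row with `chrom`, `start`, `end`.
#' @param flank symmetric flank in bp added to the span.
#' @return character vector of gene names.
#' @export
genes_in_span <- function(features, span, flank = 0) {
  f <- if (any(features$type == "gene"))
    features[features$type == "gene", , drop = FALSE] else features
  gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end))
  q <- GenomicRanges::GRanges(span$chrom,
    IRanges::IRanges(max(1, span$start - flank), span$end + flank))
  unique(f$name[GenomicRanges::countOverlaps(gr, q) > 0])
}

#' Gene-set enrichment by Fisher's exact test with BH correction
#'
#' For each gene set, builds the 2x2 table (in set x in region) over the
#' background universe and reports the two-sided Fisher exact p and the
#' Benjamini-Hochberg q-value.
#'
#' @param region_genes character vector of genes in the query region.
#' @param gene_sets named list of character vectors.
#' @param background character vector: the gene universe.
#' @return data.frame: set, overlap, set_size, background_size, p, q.
#' @export
enrichment_test <- function(region_genes, gene_sets, background) {
  if (!length(background)) stop("empty background gene universe")
  region_genes <- intersect(region_genes, background)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    a <- length(intersect(set, region_genes))
    b <- length(setdiff(set, region_genes))
    c <- length(setdiff(region_genes, set))
    d <- length(background) - a - b - c
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, 2))$p.value
    data.frame(set = nm, overlap = a, set_size = length(set),
               background_size = length(background), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
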