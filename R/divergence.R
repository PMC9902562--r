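#' Per-site Weir-Cockerham F_ST between two groups
#'
#' Variance-components estimator (the two-population case of the classic
#' a / (a + b + c) form). Haploid calls contribute a single allele and
#' cannot be heterozygous; sample sizes are expressed in effective
#' individuals (called alleles / 2) so mixed diploid/hemizygous groups are
#' handled. Estimates may be negative; sites fixed for opposite alleles
#' with no missing data return exactly 1; sites monomorphic across both
#' groups (and with no heterozygotes) are undefined and returned as NA.
#'
#' @param x a [geno_matrix()].
#' @param group_a,group_b sample ids (disjoint).
#' @return list with `per_site` (numeric per site), the variance components
#'   `a`, `b`, `c`, and `weighted` — the genome-wide ratio-of-sums estimate
#'   sum(a) / sum(a + b + c).
#' @export
wc_fst <- function(x, group_a, group_b) {
  stopifnot(!any(group_a %in% group_b))
  comp <- function(ids) {
    sub <- x[ids, ]
    ac <- allele_counts(sub)
    het <- colSums(sub$dosage == 1L & !sub$haploid, na.rm = TRUE)
    list(n = ac$n_alleles / 2, p = ac$freq, het = het)
  }
  A <- comp(group_a); B <- comp(group_b)
  n1 <- A$n; n2 <- B$n; p1 <- A$p; p2 <- B$p
  h1 <- ifelse(n1 > 0, A$het / n1, NA); h2 <- ifelse(n2 > 0, B$het / n2, NA)
  r <- 2
  nbar <- (n1 + n2) / r
  nC <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nC) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- a / denom
  # a fixed difference with no missing heterozygosity information is exactly
  # 1 by construction; floating-point cancellation in b can leave 1 - eps
  # when group sizes differ, so the boundary case is set explicitly
  fixed_diff <- !is.na(p1) & !is.na(p2) & abs(p1 - p2) == 1 & h1 == 0 & h2 == 0
  fst[fixed_diff] <- 1
  bad <- is.na(p1) | is.na(p2) | n1 * 2 < 2 | n2 * 2 < 2 | !is.finite(denom) |
    denom == 0
  fst[bad] <- NA_real_
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  ok <- !is.na(a)
  list(per_site = fst, a = a, b = b, c = cc,
       weighted = sum(a[ok]) / sum(a[ok] + b[ok] + cc[ok]))
}

# Tajima (1989) constants and D from segregating sites S, summed per-site
# pairwise diversity pi_sum, and haplotype count n.
tajima_d <- function(S, pi_sum, n) {
  if (is.na(n) || n < 2 || is.na(S) || S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  num <- pi_sum - S / a1
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (den == 0) {
    # n = 2: all variance constants vanish and pi = S/a1 exactly, so the
    # statistic is identically zero rather than undefined
    return(if (abs(num) < 1e-12) 0 else NA_real_)
  }
  num / den
}

group_window_stats <- function(sub, idx, window_bp) {
  ac <- allele_counts(sub[, idx])
  n_all <- ac$n_alleles; k <- ac$alt_count
  ok <- n_all >= 2
  pd <- ifelse(ok, 2 * k * (n_all - k) / (n_all * (n_all - 1)), NA)
  pi_sum <- sum(pd, na.rm = TRUE)
  S <- sum(ok & k > 0 & k < n_all)
  n_hap <- if (any(ok)) round(mean(n_all[ok])) else NA
  c(pi = pi_sum / window_bp, tajd = tajima_d(S, pi_sum, n_hap))
}

#' Windowed divergence and diversity statistics
#'
#' Computes, on a fixed base-pair grid (default 50 kb), the per-window SNP
#' count, the unweighted mean of defined per-site Weir-Cockerham F_ST
#' values (negative values retained), the weighted ratio-of-sums F_ST, a
#' fixed-SNP flag (any per-site F_ST exactly 1), and per-group nucleotide
#' diversity (average pairwise difference per bp) and Tajima's D (standard
#' a1..e2 constants, n = mean called allele count). Windows with fewer
#' than `min_snps` SNPs carry a `dropped` flag and are excluded from
#' percentile computations downstream.
#'
#' @param x a [geno_matrix()].
#' @param group_a,group_b sample id vectors.
#' @param window window size in bp.
#' @param min_snps minimum SNPs for a window to enter percentile pools.
#' @return data.frame of class `window_stats`.
#' @export
windowed_stats <- function(x, group_a, group_b, window = 50000L,
                           min_snps = 10L) {
  fst <- wc_fst(x, group_a, group_b)
  s <- x$sites
  win <- (s$pos - 1) %/% window
  key <- paste(s$chrom, win, sep = ":")
  groups <- split(seq_len(nrow(s)), key)
  sub_a <- x[group_a, ]; sub_b <- x[group_b, ]
  rows <- lapply(groups, function(idx) {
    ps <- fst$per_site[idx]
    a <- fst$a[idx]; b <- fst$b[idx]; cc <- fst$c[idx]
    ok <- !is.na(a)
    ga <- group_window_stats(sub_a, idx, window)
    gb <- group_window_stats(sub_b, idx, window)
    data.frame(
      chrom = s$chrom[idx[1]],
      start = win[idx[1]] * window + 1,
      end = (win[idx[1]] + 1) * window,
      sex_linked = s$sex_linked[idx[1]],
      n_snps = length(idx),
      mean_fst = if (any(!is.na(ps))) mean(ps, na.rm = TRUE) else NA_real_,
      weighted_fst = if (any(ok)) sum(a[ok]) / sum(a[ok] + b[ok] + cc[ok])
                     else NA_real_,
      contains_fixed = any(!is.na(ps) & ps == 1),
      pi_a = ga["pi"], pi_b = gb["pi"],
      tajd_a = ga["tajd"], tajd_b = gb["tajd"],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start), ]
  out$dropped <- out$n_snps < min_snps
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Dual-comparison elevated-window detection
#'
#' A window is called elevated when it is autosomal, not dropped, its
#' allopatric mean F_ST exceeds the 99th percentile of windowed mean F_ST,
#' it contains at least one fixed SNP (per-site F_ST = 1), and its mean
#' F_ST in the backcross comparison also exceeds that comparison's own
#' 99th percentile. Divergence elevated purely by drift in allopatry is
#' expected to erode under hybrid-zone gene flow, so requiring elevation in
#' both comparisons targets regions plausibly maintaining reproductive
#' isolation. Sex-linked (Z) windows are excluded from the call set but
#' summarized descriptively, and an aggregate joint-percentile summary over
#' autosomes plus Z is also reported.
#'
#' @param allopatric,backcross matching [windowed_stats()] tables from the
#'   allopatric and backcrossed comparisons.
#' @param percentile percentile defining elevation (default 0.99).
#' @return list with `threshold`, `threshold_backcross`, `elevated`
#'   (data.frame of called windows), `per_chrom` elevated fractions,
#'   `z_fraction`, `autosome_fraction`, and `aggregate_fraction` (joint
#'   percentile over all chromosomes).
#' @export
detect_elevated_windows <- function(allopatric, backcross, percentile = 0.99) {
  if (!identical(allopatric[c("chrom", "start")], backcross[c("chrom", "start")]))
    stop("window grids of the two comparisons do not match")
  auto <- !allopatric$sex_linked
  pool_a <- allopatric$mean_fst[auto & !allopatric$dropped]
  pool_b <- backcross$mean_fst[auto & !backcross$dropped]
  thr_a <- stats::quantile(pool_a, percentile, na.rm = TRUE, names = FALSE)
  thr_b <- stats::quantile(pool_b, percentile, na.rm = TRUE, names = FALSE)
  call <- auto & !allopatric$dropped & !backcross$dropped &
    !is.na(allopatric$mean_fst) & allopatric$mean_fst > thr_a &
    allopatric$contains_fixed &
    !is.na(backcross$mean_fst) & backcross$mean_fst > thr_b
  per_chrom <- tapply(call[auto & !allopatric$dropped],
                      allopatric$chrom[auto & !allopatric$dropped], mean)
  zwin <- allopatric$sex_linked & !allopatric$dropped
  z_fraction <- if (any(zwin))
    mean(allopatric$mean_fst[zwin] > thr_a, na.rm = TRUE) else NA_real_
  pool_all <- allopatric$mean_fst[!allopatric$dropped]
  thr_all <- stats::quantile(pool_all, percentile, na.rm = TRUE, names = FALSE)
  aggregate_fraction <- mean(pool_all > thr_all, na.rm = TRUE)
  list(threshold = thr_a, threshold_backcross = thr_b,
       elevated = allopatric[call, , drop = FALSE],
       n_elevated = sum(call),
       n_tested = sum(auto & !allopatric$dropped & !backcross$dropped),
       per_chrom = per_chrom,
       autosome_fraction = mean(call[auto & !allopatric$dropped]),
       z_fraction = z_fraction,
       aggregate_fraction = aggregate_fraction)
}

#' Select a four-category ancestry-informative-marker panel
#'
#' Categories: `fixed` — drawn uniformly at random (seeded) from sites with
#' per-site F_ST = 1; `background` — sites inside windows whose mean F_ST
#' falls in the 55-65th percentile band of non-dropped windows, at least
#' 50 kb from every exon, greedily thinned left-to-right to enforce >= 50 kb
#' pairwise spacing; `melanin` — supplied GWAS candidate sites; `inversion`
#' — supplied inversion-linked sites. A category that cannot be filled
#' yields a partial panel with a warning naming the shortfall.
#'
#' @param x a [geno_matrix()].
#' @param per_site numeric per-site F_ST (from [wc_fst()]).
#' @param windows a [windowed_stats()] table.
#' @param exons feature intervals (type `exon`; all rows used if untyped).
#' @param gwas_hits integer site indices of melanin GWAS candidates.
#' @param inversion_snps integer site indices linked to the inversion.
#' @param sizes named target sizes per category.
#' @param band background percentile band (window-level mean F_ST).
#' @param spacing_bp minimum spacing / exon distance for background sites.
#' @param seed RNG seed for the fixed-category draw.
#' @return data.frame panel (`chrom`, `pos`, `site`, `category`, `stat`).
#' @export
select_aim_panel <- function(x, per_site, windows, exons,
                             gwas_hits = integer(0),
                             inversion_snps = integer(0),
                             sizes = c(fixed = 30, background = 30,
                                       melanin = 56, inversion = 34),
                             band = c(0.55, 0.65), spacing_bp = 50000L,
                             seed = 1L) {
  set.seed(seed)
  s <- x$sites
  panel <- list()
  shortfall <- character(0)
  take <- function(idx, category, k) {
    if (length(idx) < k) shortfall <<- c(shortfall,
      sprintf("%s: wanted %d, eligible %d", category, k, length(idx)))
    idx <- idx[seq_len(min(k, length(idx)))]
    if (length(idx))
      data.frame(chrom = s$chrom[idx], pos = s$pos[idx], site = idx,
                 category = category, stat = per_site[idx],
                 stringsAsFactors = FALSE)
  }
  fixed_pool <- which(!is.na(per_site) & per_site == 1)
  fixed_pool <- fixed_pool[sample.int(max(length(fixed_pool), 1))[
    seq_len(length(fixed_pool))]]
  panel$fixed <- take(fixed_pool, "fixed", sizes["fixed"])

  pool <- windows$mean_fst[!windows$dropped]
  lo <- stats::quantile(pool, band[1], na.rm = TRUE)
  hi <- stats::quantile(pool, band[2], na.rm = TRUE)
  wok <- !windows$dropped & !is.na(windows$mean_fst) &
    windows$mean_fst >= lo & windows$mean_fst <= hi
  in_band <- rep(FALSE, nrow(s))
  for (w in which(wok)) {
    in_band <- in_band | (s$chrom == windows$chrom[w] &
                          s$pos >= windows$start[w] & s$pos <= windows$end[w])
  }
  cand <- which(in_band)
  if (length(cand) && nrow(exons)) {
    ex <- if (any(exons$type == "exon"))
      exons[exons$type == "exon", , drop = FALSE] else exons
    gr_ex <- GenomicRanges::GRanges(ex$chrom,
      IRanges::IRanges(pmax(1, ex$start - spacing_bp), ex$end + spacing_bp))
    gr_cand <- GenomicRanges::GRanges(s$chrom[cand],
      IRanges::IRanges(s$pos[cand], s$pos[cand]))
    near <- GenomicRanges::countOverlaps(gr_cand, gr_ex) > 0
    cand <- cand[!near]
  }
  # greedy left-to-right spacing within chromosome
  keep <- logical(length(cand))
  last_chrom <- ""; last_pos <- -Inf
  for (i in seq_along(cand)) {
    ch <- s$chrom[cand[i]]; p <- s$pos[cand[i]]
    if (ch != last_chrom || p - last_pos >= spacing_bp) {
      keep[i] <- TRUE; last_chrom <- ch; last_pos <- p
    }
  }
  panel$background <- take(cand[keep], "background", sizes["background"])
  panel$melanin <- take(gwas_hits, "melanin", sizes["melanin"])
  panel$inversion <- take(inversion_snps, "inversion", sizes["inversion"])
  if (length(shortfall))
    warning("partial AIM panel: ", paste(shortfall, collapse = "; "))
  out <- do.call(rbind, panel[!vapply(panel, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
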