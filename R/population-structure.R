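#' Genotype PCA
#'
#' Eigen-analysis of the centered (and, by default, Patterson-scaled:
#' per-site division by sqrt(p(1-p))) genotype matrix. Missing dosages are
#' mean-imputed per site and monomorphic sites dropped. Deterministic up to
#' axis sign.
#'
#' @param x a [geno_matrix()] or dosage matrix.
#' @param n_axes number of axes to return.
#' @param scale Patterson-style per-site scaling on/off.
#' @return list of class `pca_result`: `scores` (samples x axes),
#'   `var_frac` per axis, `sites_used`.
#' @export
genotype_pca <- function(x, n_axes = 10, scale = TRUE) {
  g <- if (inherits(x, "geno_matrix")) x$dosage else as.matrix(x)
  p <- colMeans(g, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- 2 * p[j]
  poly <- p > 0 & p < 1 & apply(g, 2, stats::sd) > 0
  if (!any(poly)) stop("genotype_pca: no informative (polymorphic) sites")
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  z <- sweep(g, 2, colMeans(g))
  if (scale) z <- sweep(z, 2, sqrt(p * (1 - p)), `/`)
  if (n_axes > nrow(z)) {
    warning("fewer samples than requested axes; truncating")
    n_axes <- nrow(z)
  }
  sv <- svd(z, nu = n_axes, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- rownames(g)
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  structure(list(scores = scores,
                 var_frac = sv$d[seq_len(n_axes)]^2 / sum(sv$d^2),
                 sites_used = which(poly)),
            class = "pca_result")
}

admix_loglik <- function(g, Q, F, const = sum(lchoose(2, g))) {
  pi <- Q %*% F
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  sum(g * log(pi) + (2 - g) * log(1 - pi)) + const
}

#' K-component admixture estimation by binomial-likelihood EM
#'
#' Fits the classic unsupervised admixture model: genotype dosages are
#' binomial(2, sum_k Q_ik F_kj). Alternating EM updates of ancestry
#' fractions Q and component allele frequencies F; the log-likelihood is
#' non-decreasing across iterations and a violation beyond 1e-8 aborts the
#' run. Component labels are aligned so component 1 tracks the supplied
#' parental-A anchor samples. Optional site-resampling bootstrap gives
#' per-sample Q standard errors.
#'
#' @param x a [geno_matrix()] or complete dosage matrix (no missing calls;
#'   LD-pruned input recommended, see [ld_prune()]).
#' @param K number of components.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed RNG seed (initialization, bootstrap).
#' @param n_bootstrap bootstrap replicates (0 to skip).
#' @param anchors optional list with elements `A` and `B`: sample ids fixing
#'   the component labels.
#' @return list of class `admixture_fit`: `Q`, `F`, `loglik` (trajectory),
#'   `iterations`, `converged`, `Q_se` (if bootstrapped).
#' @export
admixture_fit <- function(x, K = 2, tol = 1e-6, max_iter = 5000, seed = 1,
                          n_bootstrap = 0, anchors = NULL) {
  g <- if (inherits(x, "geno_matrix")) x$dosage else as.matrix(x)
  if (anyNA(g)) stop("admixture_fit requires a missing-free dosage matrix")
  set.seed(seed)
  n <- nrow(g); m <- ncol(g)
  Q <- matrix(stats::rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
  F <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  ll <- numeric(0)
  conv <- FALSE
  em_core <- function(g, Q, F, max_iter, tol, track = TRUE) {
    n <- nrow(g); m <- ncol(g)
    g2 <- 2 - g
    ll_const <- sum(lchoose(2, g))
    ll <- numeric(0)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      pi <- Q %*% F
      pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
      R1 <- g / pi          # expected alt-allele responsibilities scale
      R2 <- g2 / (1 - pi)
      # F update: F_kj <- F_kj S1_kj / (F_kj S1_kj + (1-F_kj) S2_kj)
      S1 <- t(crossprod(R1, Q))   # K x m: sum_i R1_ij Q_ik
      S2 <- t(crossprod(R2, Q))
      Fnum <- F * S1
      Fden <- Fnum + (1 - F) * S2
      # Q update: Q_ik <- Q_ik (R1 F' + R2 (1-F)')_ik / (2m), renormalized
      Anum <- Q * (R1 %*% t(F) + R2 %*% t(1 - F))
      Q <- Anum / (2 * m)
      Q <- Q / rowSums(Q)                    # renormalization is part of the update
      F <- Fnum / pmax(Fden, 1e-12)
      F <- pmin(pmax(F, 1e-9), 1 - 1e-9)
      ll_it <- admix_loglik(g, Q, F, const = ll_const)
      if (track && length(ll) && ll_it < ll[length(ll)] - 1e-8)
        stop("EM log-likelihood decreased by more than 1e-8")
      ll <- c(ll, ll_it)
      if (length(ll) > 1 && ll_it - ll[length(ll) - 1] < tol) {
        conv <- TRUE
        break
      }
    }
    list(Q = Q, F = F, ll = ll, conv = conv, iterations = length(ll))
  }
  fit <- em_core(g, Q, F, max_iter, tol)
  if (!fit$conv) warning("admixture_fit: not converged at max_iter; ",
                         "best fit returned")
  Q <- fit$Q; F <- fit$F
  # label alignment: component 1 anchored to parental-A samples
  if (!is.null(anchors) && K == 2 && !is.null(rownames(g))) {
    ia <- match(anchors$A, rownames(g))
    ia <- ia[!is.na(ia)]
    if (length(ia) && mean(Q[ia, 1]) < mean(Q[ia, 2])) {
      Q <- Q[, 2:1, drop = FALSE]; F <- F[2:1, , drop = FALSE]
    }
  }
  colnames(Q) <- paste0("Q", seq_len(K))
  rownames(Q) <- rownames(g)
  Q_se <- NULL
  if (n_bootstrap > 0) {
    boots <- replicate(n_bootstrap, {
      j <- sample.int(m, m, replace = TRUE)
      bf <- em_core(g[, j, drop = FALSE], Q, F[, j, drop = FALSE],
                    max_iter = 50, tol = tol, track = FALSE)
      bq <- bf$Q
      if (!is.null(anchors) && K == 2) {
        ia <- match(anchors$A, rownames(g)); ia <- ia[!is.na(ia)]
        if (length(ia) && mean(bq[ia, 1]) < mean(bq[ia, 2]))
          bq <- bq[, 2:1, drop = FALSE]
      }
      bq
    }, simplify = "array")
    Q_se <- apply(boots, c(1, 2), stats::sd)
    dimnames(Q_se) <- dimnames(Q)
  }
  structure(list(Q = Q, F = F, loglik = fit$ll, iterations = fit$iterations,
                 converged = fit$conv, Q_se = Q_se),
            class = "admixture_fit")
}

#' Windowed admixture along the genome
#'
#' Splits each chromosome's SNPs, in coordinate order, into chunks of
#' `chunk_snps` (the last chunk may be short; chunks under `min_snps` are
#' skipped with a warning) and fits the K=2 admixture model per chunk, with
#' component labels aligned across chunks through the parental anchors.
#'
#' @param x a [geno_matrix()] with no missing calls.
#' @param chunk_snps SNPs per chunk.
#' @param K components.
#' @param min_snps minimum SNPs for a chunk to be fitted.
#' @param anchors parental anchor list (see [admixture_fit()]).
#' @param ... passed to [admixture_fit()].
#' @return list with `track` (data.frame chunk x sample Q for component 2,
#'   i.e. the B/Bullock's-like fraction) and `fits`.
#' @export
windowed_admixture <- function(x, chunk_snps = 100000L, K = 2,
                               min_snps = 100L, anchors = NULL, ...) {
  s <- x$sites
  fits <- list(); rows <- list()
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    nchunk <- ceiling(length(idx) / chunk_snps)
    for (b in seq_len(nchunk)) {
      j <- idx[((b - 1) * chunk_snps + 1):min(b * chunk_snps, length(idx))]
      if (length(j) < min_snps) {
        warning("chunk ", ch, "#", b, " has fewer than ", min_snps,
                " SNPs; skipped")
        next
      }
      f <- admixture_fit(x[, j], K = K, anchors = anchors, ...)
      key <- paste0(ch, "#", b)
      fits[[key]] <- f
      rows[[key]] <- data.frame(chrom = ch, chunk = b,
                                start = s$pos[j[1]],
                                end = s$pos[j[length(j)]],
                                sample = rownames(f$Q),
                                q_b = f$Q[, min(2, K)],
                                stringsAsFactors = FALSE)
    }
  }
  track <- do.call(rbind, rows)
  rownames(track) <- NULL
  list(track = track, fits = fits)
}

#' Classify hybrids from hybrid index and interspecific heterozygosity
#'
#' Over called fixed ancestry-informative markers (polarized so dosage 2 =
#' Bullock's-like), computes each sample's hybrid index (fraction of
#' Bullock's alleles; haploid calls contribute one allele) and
#' interspecific heterozygosity (fraction of called diploid markers
#' heterozygous), then assigns genotypic classes by configurable
#' thresholds: parental (HI <= 0.05 or >= 0.95, het <= 0.1), F1
#' (0.4 <= HI <= 0.6, het >= 0.85), backcross bands on either side, and F2
#' otherwise. Samples with fewer than `min_called` called markers are
#' `unknown`.
#'
#' @param x a polarized [geno_matrix()].
#' @param fixed_aims integer site indices of fixed diagnostic markers.
#' @param min_called minimum called markers per sample.
#' @param parental_hi,parental_het,f1_hi,f1_het class thresholds.
#' @return data.frame: `id`, `hybrid_index`, `heterozygosity`, `n_called`,
#'   `class`.
#' @export
classify_hybrids <- function(x, fixed_aims, min_called = 10,
                             parental_hi = 0.05, parental_het = 0.1,
                             f1_hi = c(0.4, 0.6), f1_het = 0.85) {
  if (!length(fixed_aims)) stop("no fixed AIMs supplied")
  sub <- x[, fixed_aims]
  d <- sub$dosage; hap <- sub$haploid
  called <- !is.na(d)
  alleles <- ifelse(hap, 1, 2) * called
  bull <- ifelse(hap, d / 2, d); bull[!called] <- 0
  hi <- rowSums(bull) / pmax(rowSums(alleles), 1)
  dip_called <- called & !hap
  het <- rowSums(d == 1 & dip_called, na.rm = TRUE) /
    pmax(rowSums(dip_called), 1)
  n_called <- rowSums(called)
  cls <- rep("F2", nrow(d))
  cls[hi <= parental_hi & het <= parental_het] <- "parental_A"
  cls[hi >= 1 - parental_hi & het <= parental_het] <- "parental_B"
  cls[hi >= f1_hi[1] & hi <= f1_hi[2] & het >= f1_het] <- "F1"
  bc <- !(cls %in% c("parental_A", "parental_B", "F1"))
  cls[bc & hi < f1_hi[1]] <- "backcross_A"
  cls[bc & hi > f1_hi[2]] <- "backcross_B"
  cls[n_called < min_called] <- "unknown"
  data.frame(id = sample_ids(x), hybrid_index = hi, heterozygosity = het,
             n_called = n_called, class = cls, stringsAsFactors = FALSE)
}

#' Per-sample genotype classes at fixed diagnostic sites
#'
#' Polarizes against the supplied reference and returns, for each sample
#' and fixed site, `hom_ref` / `het` / `hom_alt` (the genotype-plot
#' encoding: Baltimore-like, heterozygote, Bullock's-like). Hemizygous
#' females on Z can only be `hom_ref` or `hom_alt`.
#'
#' @param x a [geno_matrix()].
#' @param fixed_sites integer site indices (per-site F_ST = 1).
#' @param reference polarization reference (a Baltimore individual), passed
#'   to [encode_polarized()].
#' @return list with `classes` (character matrix samples x sites) and
#'   `sites`.
#' @export
genotype_class_matrix <- function(x, fixed_sites, reference) {
  pol <- encode_polarized(x[, fixed_sites], reference)
  cls <- matrix(NA_character_, nrow(pol$dosage), ncol(pol$dosage),
                dimnames = list(rownames(pol$dosage), NULL))
  cls[!is.na(pol$dosage) & pol$dosage == 0L] <- "hom_ref"
  cls[!is.na(pol$dosage) & pol$dosage == 1L] <- "het"
  cls[!is.na(pol$dosage) & pol$dosage == 2L] <- "hom_alt"
  list(classes = cls, sites = pol$sites)
}
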