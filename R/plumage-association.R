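#' Genomic relationship (kinship) matrix
#'
#' Centered, allele-frequency-standardized GRM (VanRaden/GCTA form):
#' symmetric and positive semi-definite up to numerical tolerance; missing
#' dosages are mean-imputed. Used to control for population and family
#' structure in the mixed-model GWAS.
#'
#' @param x a [geno_matrix()] or dosage matrix.
#' @return numeric samples x samples matrix.
#' @export
kinship_grm <- function(x) {
  K <- grm_matrix(x)
  (K + t(K)) / 2
}

fit_null_lmm <- function(y, lambda, Uty, UtX0) {
  n <- length(y)
  nll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lambda + d)
    XtWX <- crossprod(UtX0, UtX0 * w)
    XtWy <- crossprod(UtX0, Uty * w)
    beta <- solve(XtWX, XtWy)
    r <- Uty - UtX0 %*% beta
    rss <- sum(w * r^2)
    sigma2 <- rss / n
    0.5 * (n * log(2 * pi * sigma2) + sum(log(lambda + d)) + n)
  }
  opt <- stats::optimize(nll, c(-12, 12))
  d <- exp(opt$minimum)
  w <- 1 / (lambda + d)
  beta <- solve(crossprod(UtX0, UtX0 * w), crossprod(UtX0, Uty * w))
  r <- Uty - UtX0 %*% beta
  sigma_g2 <- sum(w * r^2) / length(y)
  at_boundary <- opt$minimum < -11.5 || opt$minimum > 11.5
  list(delta = d, sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * d,
       nll = opt$objective, at_boundary = at_boundary)
}

#' Linear mixed model GWAS with kinship (EMMA-style)
#'
#' One univariate LMM per trait: y = mu + g beta + u + e with
#' u ~ N(0, sigma_g^2 K). The kinship matrix is eigendecomposed once per
#' trait; the variance ratio delta = sigma_e^2 / sigma_g^2 is estimated on
#' the rotated null model by 1-D likelihood optimization and held fixed
#' per SNP (the EMMAX approximation); each SNP's effect is then a
#' generalized-least-squares fit with Wald statistic (beta/se)^2 referred
#' to F(1, n-2), so with K = identity the test reduces exactly to the
#' ordinary least-squares Wald test. Ordinal scores are analyzed as
#' numeric. Missing dosages are mean-imputed per site. Traits whose null
#' optimization lands on the boundary of the delta search interval are
#' reported but flagged; traits that error are skipped.
#'
#' @param traits numeric matrix samples x traits (ordinal scores 0-4).
#' @param x a [geno_matrix()] or dosage matrix (sample order must match).
#' @param K kinship matrix from [kinship_grm()].
#' @param threshold significance threshold on -log10 p (default 7).
#' @return list of class `gwas_result`: per trait a data.frame (`chrom`,
#'   `pos`, `site`, `beta`, `se`, `wald`, `p`, `neglog10p`, `significant`)
#'   plus `varcomp` and `skipped`.
#' @export
lmm_gwas <- function(traits, x, K, threshold = 7) {
  g <- if (inherits(x, "geno_matrix")) x$dosage else as.matrix(x)
  s <- if (inherits(x, "geno_matrix")) x$sites
       else data.frame(chrom = "chr0", pos = seq_len(ncol(g)))
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  p <- colMeans(g, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- 2 * p[j]
  res <- list(); varcomp <- list(); skipped <- character(0)
  for (tn in colnames(traits)) {
    y_all <- traits[, tn]
    use <- !is.na(y_all)
    y <- y_all[use]
    n <- length(y)
    if (stats::sd(y) == 0) {
      # a constant trait carries no information: zero effects, p = 1
      res[[tn]] <- data.frame(chrom = s$chrom, pos = s$pos,
                              site = seq_len(ncol(g)), beta = 0, se = NA,
                              wald = 0, p = 1, neglog10p = 0,
                              significant = FALSE, stringsAsFactors = FALSE)
      varcomp[[tn]] <- c(sigma_g2 = 0, sigma_e2 = 0, delta = NA,
                         boundary = NA)
      next
    }
    Ku <- K[use, use]
    eg <- tryCatch(eigen(Ku, symmetric = TRUE), error = function(e) NULL)
    if (is.null(eg)) { skipped <- c(skipped, tn); next }
    lambda <- pmax(eg$values, 1e-10)
    U <- eg$vectors
    Uty <- crossprod(U, y)
    UtX0 <- crossprod(U, rep(1, n))
    null <- tryCatch(fit_null_lmm(y, lambda, Uty, UtX0),
                     error = function(e) NULL)
    if (is.null(null)) { skipped <- c(skipped, tn); next }
    w <- 1 / (lambda + null$delta)
    Utg <- crossprod(U, g[use, , drop = FALSE])
    # vectorized per-SNP GLS with X = [1, g] in the rotated basis
    x0 <- as.vector(UtX0)
    yv <- as.vector(Uty)
    s11 <- sum(w * x0^2)
    s1g <- colSums(w * x0 * Utg)
    sgg <- colSums(w * Utg^2)
    s1y <- sum(w * x0 * yv)
    sgy <- colSums(w * Utg * yv)
    syy <- sum(w * yv^2)
    det <- s11 * sgg - s1g^2
    beta <- (s11 * sgy - s1g * s1y) / det
    alpha <- (sgg * s1y - s1g * sgy) / det
    rss <- syy - alpha * s1y - beta * sgy
    sigma2 <- pmax(rss, 0) / (n - 2)
    se <- sqrt(sigma2 * s11 / det)
    bad <- !is.finite(det) | det <= 1e-12 | !is.finite(se) | se == 0
    tstat <- beta / se
    tstat[bad] <- 0; beta[bad] <- 0; se[bad] <- NA
    pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pval[bad] <- 1
    df <- data.frame(chrom = s$chrom, pos = s$pos, site = seq_len(ncol(g)),
                     beta = beta, se = se, wald = tstat^2, p = pval,
                     neglog10p = -log10(pmax(pval, .Machine$double.xmin)),
                     stringsAsFactors = FALSE)
    df$significant <- df$neglog10p >= threshold
    res[[tn]] <- df
    varcomp[[tn]] <- c(sigma_g2 = null$sigma_g2, sigma_e2 = null$sigma_e2,
                       delta = null$delta, boundary = null$at_boundary)
  }
  structure(list(traits = res, varcomp = varcomp, skipped = skipped,
                 threshold = threshold),
            class = "gwas_result")
}

#' Collate GWAS outliers across traits and map candidate genes
#'
#' Counts, per SNP, the number of traits for which it is significant;
#' reports the SNPs shared by two or more traits, genes whose interval
#' extended by `flank` bp (inclusive coordinates) contains a significant
#' SNP, and per-chromosome outlier fractions.
#'
#' @param gwas a [lmm_gwas()] result.
#' @param features optional feature intervals (genes).
#' @param flank flank in bp around gene intervals (default 40 kb).
#' @return list: `shared` (data.frame site, chrom, pos, n_traits),
#'   `genes` (gene -> SNPs), `per_chrom` fraction of significant SNPs per
#'   chromosome.
#' @export
collate_outliers <- function(gwas, features = NULL, flank = 40000) {
  tr <- gwas$traits
  if (!length(tr)) stop("empty GWAS result")
  sig <- sapply(tr, function(d) d$significant)
  n_traits <- rowSums(sig)
  base <- tr[[1]]
  shared <- data.frame(site = base$site, chrom = base$chrom, pos = base$pos,
                       n_traits = n_traits, stringsAsFactors = FALSE)
  any_sig <- n_traits > 0
  per_chrom <- tapply(any_sig, base$chrom, mean)
  genes <- NULL
  if (!is.null(features) && nrow(features)) {
    f <- if (any(features$type == "gene"))
      features[features$type == "gene", , drop = FALSE] else features
    gr_g <- GenomicRanges::GRanges(f$chrom,
      IRanges::IRanges(pmax(1, f$start - flank), f$end + flank))
    hits <- which(any_sig)
    if (length(hits)) {
      gr_s <- GenomicRanges::GRanges(base$chrom[hits],
        IRanges::IRanges(base$pos[hits], base$pos[hits]))
      ov <- GenomicRanges::findOverlaps(gr_g, gr_s)
      genes <- split(base$pos[hits][S4Vectors::subjectHits(ov)],
                     f$name[S4Vectors::queryHits(ov)])
    } else genes <- list()
  } else if (is.null(features)) {
    warning("no annotation supplied; gene collation omitted")
  }
  list(shared = shared[n_traits >= 2, , drop = FALSE],
       counts = shared, genes = genes, per_chrom = per_chrom)
}

#' Thin candidate SNPs to one per megabase by F_ST
#'
#' Within each 1-Mb bin per chromosome keeps the SNP with the highest
#' F_ST; ties broken by the lower coordinate. Deterministic regardless of
#' input order.
#'
#' @param snps data.frame with `chrom`, `pos`, `fst` (other columns kept).
#' @param bin_bp bin width (default 1e6).
#' @return the thinned data.frame, sorted by chrom, pos.
#' @export
thin_candidates <- function(snps, bin_bp = 1e6) {
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  bin <- (snps$pos - 1) %/% bin_bp
  key <- paste(snps$chrom, bin, sep = ":")
  pick <- unlist(lapply(split(seq_len(nrow(snps)), key), function(i) {
    i[which.max(snps$fst[i])]   # ties: first index = lower coordinate
  }), use.names = FALSE)
  out <- snps[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

collapse_factor <- function(g, min_n = 3) {
  f <- factor(g, levels = 0:2)
  tab <- table(f)
  collapsed <- FALSE
  while (any(tab > 0 & tab < min_n) && sum(tab > 0) > 1) {
    lv <- names(tab)[tab > 0 & tab < min_n][1]
    present <- as.integer(names(tab)[tab > 0])
    others <- present[present != as.integer(lv)]
    target <- others[which.min(abs(others - as.integer(lv)))]
    g[!is.na(g) & g == as.integer(lv)] <- target
    f <- factor(g)
    tab <- table(factor(g, levels = 0:2))
    collapsed <- TRUE
  }
  list(f = factor(g), collapsed = collapsed)
}

#' Additive-versus-epistatic model battery over candidate SNP pairs
#'
#' For each trait and each pair of candidate SNPs on different
#' chromosomes, fits linear models with the genotypes coded as 3-level
#' factors (Baltimore-like / heterozygote / Bullock's-like): an additive
#' model `score ~ g1 + g2` and an interactive model `score ~ g1 * g2`.
#' The interaction term is tested by the F-test comparing the two models;
#' each additive term by a marginal F-test in the additive model. Genotype
#' classes with fewer than 3 samples are collapsed into the nearest class
#' (flagged). Single-SNP models `score ~ g` are also fitted, and summary
#' counts are reported both over the full enumeration and excluding the
#' single-SNP models, at significance level `alpha` (with an additional
#' strong tier at `strong_alpha`).
#'
#' @param traits matrix samples x traits (ordinal scores).
#' @param x a polarized [geno_matrix()] restricted to the thinned
#'   candidates (dosage 0/1/2), or a dosage matrix.
#' @param alpha significance level for summary counts.
#' @param strong_alpha the strong-evidence tier.
#' @return list of class `epistasis_report`: `models` data.frame, `singles`
#'   data.frame, `summary` counts.
#' @export
epistasis_battery <- function(traits, x, alpha = 0.05, strong_alpha = 5e-4) {
  g <- if (inherits(x, "geno_matrix")) x$dosage else as.matrix(x)
  s <- if (inherits(x, "geno_matrix")) x$sites
       else data.frame(chrom = "chr0", pos = seq_len(ncol(g)),
                       sex_linked = FALSE)
  if (is.null(s$sex_linked)) s$sex_linked <- FALSE
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  m <- ncol(g)
  pairs <- which(outer(s$chrom, s$chrom, `!=`) & upper.tri(matrix(0, m, m)),
                 arr.ind = TRUE)
  rows <- list(); srows <- list()
  for (tn in colnames(traits)) {
    y <- traits[, tn]
    y_degenerate <- stats::sd(y, na.rm = TRUE) == 0
    for (j in seq_len(m)) {
      cf <- collapse_factor(g[, j])
      ok <- !is.na(y) & !is.na(g[, j])
      p1 <- NA_real_
      if (!y_degenerate && nlevels(droplevels(cf$f[ok])) > 1) {
        fit <- stats::lm(y[ok] ~ droplevels(cf$f[ok]))
        an <- stats::anova(fit)
        p1 <- an[["Pr(>F)"]][1]
      }
      srows[[length(srows) + 1]] <- data.frame(
        trait = tn, site = j, chrom = s$chrom[j], p = p1,
        collapsed = cf$collapsed, stringsAsFactors = FALSE)
    }
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
      j1 <- pairs[k, 1]; j2 <- pairs[k, 2]
      f1 <- collapse_factor(g[, j1]); f2 <- collapse_factor(g[, j2])
      ok <- !is.na(y) & !is.na(g[, j1]) & !is.na(g[, j2])
      y0 <- y[ok]
      ff1 <- droplevels(f1$f[ok]); ff2 <- droplevels(f2$f[ok])
      if (nlevels(ff1) < 2 || nlevels(ff2) < 2) next
      if (y_degenerate) {
        rows[[length(rows) + 1]] <- data.frame(
          trait = tn, site1 = j1, site2 = j2,
          chrom1 = s$chrom[j1], chrom2 = s$chrom[j2],
          p_g1 = NA_real_, p_g2 = NA_real_, p_interaction = NA_real_,
          involves_z = s$sex_linked[j1] || s$sex_linked[j2],
          collapsed = f1$collapsed || f2$collapsed,
          rank_deficient = FALSE, stringsAsFactors = FALSE)
        next
      }
      add <- stats::lm(y0 ~ ff1 + ff2)
      int <- stats::lm(y0 ~ ff1 * ff2)
      rank_def <- int$rank < length(stats::coef(int)) ||
        any(is.na(stats::coef(int)))
      p_int <- tryCatch(stats::anova(add, int)[["Pr(>F)"]][2],
                        error = function(e) NA_real_)
      dr <- tryCatch(stats::drop1(add, test = "F"),
                     error = function(e) NULL)
      p_g1 <- if (!is.null(dr)) dr[["Pr(>F)"]][rownames(dr) == "ff1"]
              else NA_real_
      p_g2 <- if (!is.null(dr)) dr[["Pr(>F)"]][rownames(dr) == "ff2"]
              else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        trait = tn, site1 = j1, site2 = j2,
        chrom1 = s$chrom[j1], chrom2 = s$chrom[j2],
        p_g1 = if (length(p_g1)) p_g1 else NA_real_,
        p_g2 = if (length(p_g2)) p_g2 else NA_real_,
        p_interaction = p_int,
        involves_z = s$sex_linked[j1] || s$sex_linked[j2],
        collapsed = f1$collapsed || f2$collapsed,
        rank_deficient = rank_def, stringsAsFactors = FALSE)
    }
  }
  models <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(0), p_interaction = numeric(0))
  singles <- do.call(rbind, srows)
  sig <- function(p, a) !is.na(p) & p < a
  add_sig <- sig(models$p_g1, alpha) | sig(models$p_g2, alpha)
  int_sig <- sig(models$p_interaction, alpha)
  summary <- list(
    n_pair_models = nrow(models),
    n_single_models = nrow(singles),
    n_models_total = nrow(models) + nrow(singles),
    n_additive_significant = sum(add_sig),
    n_interactive_significant = sum(int_sig),
    n_interactive_with_z = sum(int_sig & models$involves_z),
    n_strong = sum(sig(models$p_interaction, strong_alpha) |
                   sig(models$p_g1, strong_alpha) |
                   sig(models$p_g2, strong_alpha)),
    alpha = alpha)
  structure(list(models = models, singles = singles, summary = summary),
            class = "epistasis_report")
}

#' Regression of total plumage score on the melanin-genotype PC1
#'
#' Summarizes the melanin-candidate genotypes by their first principal
#' component and regresses the total plumage score (0-36) on it.
#'
#' @param x a [geno_matrix()] or dosage matrix restricted to melanin
#'   markers (>= 2 markers).
#' @param total_score numeric vector (>= 10 samples).
#' @return list: `slope`, `r_squared`, `p`, `pc1`.
#' @export
genotype_pc_regression <- function(x, total_score) {
  g <- if (inherits(x, "geno_matrix")) x$dosage else as.matrix(x)
  if (ncol(g) < 2) stop("need at least 2 melanin markers")
  if (length(total_score) < 10) stop("need at least 10 samples")
  if (all(apply(g, 2, function(v) stats::sd(v, na.rm = TRUE)) == 0))
    stop("zero genotype variance among melanin markers")
  pca <- genotype_pca(g, n_axes = 1, scale = FALSE)
  pc1 <- pca$scores[, 1]
  fit <- stats::lm(total_score ~ pc1)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), r_squared = sm$r.squared,
       p = sm$coefficients[2, 4], pc1 = pc1)
}
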