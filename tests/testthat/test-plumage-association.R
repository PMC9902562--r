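test_that("kinship matrix is symmetric with sensible relative values", {
  ds <- hz_small()
  K <- kinship_grm(ds$geno)
  expect_identical(max(abs(K - t(K))), 0)
  # PSD up to numerical tolerance
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # duplicated sample pair: off-diagonal close to the diagonal entries
  gm <- ds$geno[c(1:15, 1), ]
  K2 <- kinship_grm(gm)
  expect_lt(abs(K2[16, 1] - (K2[1, 1] + K2[16, 16]) / 2), 0.05)
})

test_that("with identity kinship the mixed model reduces to OLS", {
  set.seed(21)
  n <- 80
  g <- matrix(rbinom(n * 60, 2, 0.4), n, 60)
  y <- 0.4 * g[, 7] + rnorm(n)
  gw <- lmm_gwas(cbind(t1 = y), g, diag(n))
  d <- gw$traits$t1
  # oracle: per-SNP ordinary least squares
  for (j in c(1, 7, 30)) {
    fit <- summary(stats::lm(y ~ g[, j]))
    expect_equal(d$beta[j], fit$coefficients[2, 1], tolerance = 1e-6)
    expect_equal(d$p[j], fit$coefficients[2, 4], tolerance = 1e-6)
  }
  # Wald statistic is the squared t ratio
  expect_equal(d$wald, (d$beta / d$se)^2, tolerance = 1e-10)
})

test_that("a constant trait yields zero effects and no hits", {
  set.seed(3)
  g <- matrix(rbinom(40 * 30, 2, 0.3), 40, 30)
  gw <- lmm_gwas(cbind(flat = rep(2, 40)), g, kinship_grm(g))
  expect_true(all(gw$traits$flat$beta == 0))
  expect_true(all(!gw$traits$flat$significant))
  expect_true(all(gw$traits$flat$p >= 0 & gw$traits$flat$p <= 1))
})

test_that("LMM GWAS is calibrated under the null and powered at a causal SNP", {
  # family-structured cohort (30 sibships of 5) so the kinship correction
  # has work to do
  set.seed(77)
  n_fam <- 30; sibs <- 5; n <- n_fam * sibs; m <- 3000
  p <- runif(m, 0.1, 0.9)
  g <- matrix(0L, n, m)
  fam <- rep(seq_len(n_fam), each = sibs)
  for (f in seq_len(n_fam)) {
    mo <- rbind(rbinom(m, 1, p), rbinom(m, 1, p))
    fa <- rbind(rbinom(m, 1, p), rbinom(m, 1, p))
    for (s in seq_len(sibs)) {
      pick1 <- runif(m) < 0.5; pick2 <- runif(m) < 0.5
      g[(f - 1) * sibs + s, ] <- ifelse(pick1, mo[1, ], mo[2, ]) +
        ifelse(pick2, fa[1, ], fa[2, ])
    }
  }
  K <- kinship_grm(g)
  # family background + noise, no single causal SNP
  u <- rnorm(n_fam)[fam]
  y_null <- u + rnorm(n)
  gw0 <- lmm_gwas(cbind(null = y_null), g, K)
  pv <- gw0$traits$null$p
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  expect_lte(mean(gw0$traits$null$neglog10p >= 7), 2e-4)
  # planted causal SNP at 1.5 residual SD per allele copy
  y <- y_null + 1.5 * sd(y_null) * g[, 101]
  gw1 <- lmm_gwas(cbind(sig = y), g, K)
  expect_gte(gw1$traits$sig$neglog10p[101], 7)
  expect_lte(mean(gw1$traits$sig$neglog10p[-101] >= 7), 2e-4)
  # Wald and likelihood-ratio p agree within 2x on -log10 scale at a
  # moderate-effect SNP (where both references are in their asymptotic
  # regime)
  y_mod <- y_null + 0.45 * sd(y_null) * g[, 202]
  gw2 <- lmm_gwas(cbind(mod = y_mod), g, K)
  j <- 202
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors
  sw <- sqrt(1 / (pmax(eg$values, 1e-10) + gw2$varcomp$mod["delta"]))
  ys <- as.vector(sw * crossprod(U, y_mod))
  x0 <- as.vector(sw * crossprod(U, rep(1, n)))
  xj <- as.vector(sw * crossprod(U, g[, j]))
  ll0 <- stats::logLik(stats::lm(ys ~ x0 - 1))
  ll1 <- stats::logLik(stats::lm(ys ~ x0 + xj - 1))
  lrt_p <- stats::pchisq(2 * as.numeric(ll1 - ll0), 1, lower.tail = FALSE)
  ratio <- gw2$traits$mod$neglog10p[j] / (-log10(lrt_p))
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("outlier collation counts traits and maps genes at 40 kb", {
  # synthetic GWAS result exercising the boundary arithmetic exactly
  mk <- function(sig) data.frame(chrom = "chr1",
    pos = c(59999L, 70000L, 150000L), site = 1:3,
    beta = 0, se = 1, wald = 0,
    p = ifelse(sig, 1e-9, 0.5),
    neglog10p = ifelse(sig, 9, 0.3), significant = sig)
  gw <- structure(list(traits = list(
    t1 = mk(c(TRUE, TRUE, FALSE)),
    t2 = mk(c(FALSE, TRUE, FALSE)),
    t3 = mk(c(FALSE, TRUE, TRUE))), threshold = 7), class = "gwas_result")
  genes <- feature_intervals("chr1", 100000, 110000, "gene", "melgene")
  co <- collate_outliers(gw, genes)
  # SNP significant for one trait only is excluded from the shared set
  expect_equal(co$counts$n_traits, c(1L, 3L, 1L))
  expect_equal(co$shared$site, 2L)
  # 70 kb is within 40 kb of [100 kb, 110 kb]; 59,999 is not
  expect_true("melgene" %in% names(co$genes))
  expect_true(70000 %in% co$genes$melgene)
  expect_false(59999 %in% co$genes$melgene)
})

test_that("per-megabase thinning matches a brute-force argmax", {
  set.seed(12)
  snps <- data.frame(
    chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
    pos = sample.int(5e6, 200),
    fst = round(runif(200), 3))
  th <- thin_candidates(snps)
  # brute force per bin
  for (ch in unique(snps$chrom)) {
    sub <- snps[snps$chrom == ch, ]
    for (b in unique((sub$pos - 1) %/% 1e6)) {
      inbin <- sub[(sub$pos - 1) %/% 1e6 == b, ]
      best <- inbin[inbin$fst == max(inbin$fst), ]
      best <- best[which.min(best$pos), ]
      got <- th[th$chrom == ch & (th$pos - 1) %/% 1e6 == b, ]
      expect_equal(nrow(got), 1L)
      expect_equal(got$pos, best$pos)
    }
  }
  # determinism under input shuffling
  th2 <- thin_candidates(snps[sample(nrow(snps)), ])
  expect_equal(th, th2)
  # boundary: SNPs exactly 1 Mb apart fall in adjacent bins, both kept
  th3 <- thin_candidates(data.frame(chrom = "c", pos = c(1e6, 2e6),
                                    fst = c(0.5, 0.4)))
  expect_equal(nrow(th3), 2L)
  # two SNPs in one bin: higher FST wins
  th4 <- thin_candidates(data.frame(chrom = "c", pos = c(2e5, 7e5),
                                    fst = c(0.8, 0.9)))
  expect_equal(th4$pos, 7e5)
})

test_that("the epistasis battery separates additive from interactive signals", {
  set.seed(33)
  n <- 200
  g <- cbind(a = rbinom(n, 2, 0.5), b = rbinom(n, 2, 0.5),
             c = rbinom(n, 2, 0.5))
  gm <- geno_matrix(g, data.frame(chrom = c("chr1", "chr2", "Z"),
                                  pos = c(1L, 1L, 1L), ref = "A", alt = "T",
                                  sex_linked = c(FALSE, FALSE, TRUE)))
  # purely additive trait
  y_add <- g[, 1] + g[, 2] + rnorm(n, 0, 0.3)
  # XOR-like epistasis between a and c, no marginal effects
  y_xor <- as.numeric((g[, 1] > 0) != (g[, 3] > 0)) + rnorm(n, 0, 0.3)
  rep <- epistasis_battery(cbind(add = y_add, xor = y_xor), gm)
  m <- rep$models
  add_ab <- m[m$trait == "add" & m$site1 == 1 & m$site2 == 2, ]
  expect_lt(add_ab$p_g1, 0.001)
  expect_lt(add_ab$p_g2, 0.001)
  expect_gt(add_ab$p_interaction, 0.01)
  xor_ac <- m[m$trait == "xor" & m$site1 == 1 & m$site2 == 3, ]
  expect_lt(xor_ac$p_interaction, 1e-6)
  expect_true(xor_ac$involves_z)
  # constant trait: nothing significant anywhere
  rep0 <- epistasis_battery(cbind(flat = rep(1, n)), gm)
  expect_false(any(rep0$models$p_interaction < 0.05, na.rm = TRUE))
  expect_false(any(rep0$models$p_g1 < 0.05, na.rm = TRUE))
  # summaries enumerate singles and pairs separately
  expect_equal(rep$summary$n_pair_models, 2 * 3)
  expect_equal(rep$summary$n_single_models, 2 * 3)
  expect_equal(rep$summary$n_models_total, 12)
})

test_that("interaction false-positive rate sits near alpha for additive traits", {
  set.seed(44)
  n <- 120
  n_pairs_sig <- 0; n_models <- 0
  for (rep_i in 1:40) {
    g <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5))
    gm <- geno_matrix(g, data.frame(chrom = c("chr1", "chr2"), pos = 1L,
                                    ref = "A", alt = "T",
                                    sex_linked = FALSE))
    y <- g[, 1] + g[, 2] + rnorm(n)
    r <- epistasis_battery(cbind(t = y), gm)
    n_models <- n_models + nrow(r$models)
    n_pairs_sig <- n_pairs_sig + sum(r$models$p_interaction < 0.05,
                                     na.rm = TRUE)
  }
  rate <- n_pairs_sig / n_models
  # binomial error around alpha = 0.05 at 40 models
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_models) + 0.02)
})

test_that("rare genotype classes collapse and are flagged", {
  set.seed(55)
  n <- 60
  g1 <- c(rep(0L, 57), 1L, 2L, 2L)       # het class has 1 sample
  g2 <- rbinom(n, 2, 0.5)
  gm <- geno_matrix(cbind(g1, g2),
                    data.frame(chrom = c("chr1", "chr2"), pos = 1L,
                               ref = "A", alt = "T", sex_linked = FALSE))
  y <- rnorm(n)
  r <- epistasis_battery(cbind(t = y), gm)
  expect_true(all(r$models$collapsed))
})

test_that("melanin PC1 regression recovers the genotype-phenotype axis", {
  ds <- hz_small()
  mel <- which(ds$model$sites$class == "melanin")
  total <- rowSums(ds$phen)
  res <- genotype_pc_regression(ds$geno[, mel], total)
  expect_gte(res$r_squared, 0.8)
  expect_lt(res$p, 1e-6)
  # exactly linear scores give R^2 = 1
  pc1 <- res$pc1
  res_lin <- suppressWarnings(
    genotype_pc_regression(ds$geno[, mel], 3 * pc1 + 2))
  expect_equal(res_lin$r_squared, 1, tolerance = 1e-9)
  # permuted scores: R^2 collapses and p is non-extreme on average
  set.seed(66)
  r2s <- ps <- numeric(50)
  for (i in 1:50) {
    perm <- sample(total)
    rr <- genotype_pc_regression(ds$geno[, mel], perm)
    r2s[i] <- rr$r_squared; ps[i] <- rr$p
  }
  expect_lt(mean(r2s), 0.05)
  expect_gt(mean(ps > 0.05), 0.8)
  expect_error(genotype_pc_regression(ds$geno[, mel[1], drop = FALSE], total),
               "2 melanin")
  expect_error(genotype_pc_regression(matrix(1L, 20, 3), rnorm(20)),
               "variance")
})
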