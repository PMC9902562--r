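test_that("per-site Weir-Cockerham matches a direct transcription oracle", {
  cases <- list(
    list(a = c(0L, 0L, 1L), b = c(2L, 2L, 1L)),
    list(a = c(0L, 1L, 1L, 2L), b = c(2L, 2L, 1L, 0L)),
    list(a = c(0L, 0L, 0L, 1L), b = c(1L, 1L, 2L)),     # unequal sizes
    list(a = c(1L, 1L, 1L), b = c(1L, 1L, 1L)),          # all het
    list(a = c(0L, 2L, NA), b = c(2L, 0L, 2L))           # missing call
  )
  for (cs in cases) {
    na <- length(cs$a); nb <- length(cs$b)
    gm <- hz_tiny_matrix(matrix(c(cs$a, cs$b), ncol = 1))
    ids <- sample_ids(gm)
    got <- wc_fst(gm, ids[1:na], ids[na + 1:nb])
    want <- oracle_wc_fst_site(cs$a, cs$b)
    expect_equal(got$per_site, want$fst, tolerance = 1e-12)
    expect_equal(got$a, want$a, tolerance = 1e-12)
  }
})

test_that("FST estimator boundary behavior is exact", {
  # fixed difference with no missing data: exactly 1
  gm <- hz_tiny_matrix(matrix(c(0L, 0L, 0L, 2L, 2L, 2L), ncol = 1))
  ids <- sample_ids(gm)
  expect_identical(wc_fst(gm, ids[1:3], ids[4:6])$per_site, 1)
  # monomorphic across both groups: undefined
  gm2 <- hz_tiny_matrix(matrix(0L, 6, 1))
  expect_true(is.na(wc_fst(gm2, ids[1:3], ids[4:6])$per_site))
  # identical nonzero frequencies in both groups, large n: near zero
  set.seed(2)
  d <- matrix(rbinom(400 * 50, 2, 0.4), 400, 50)
  gm3 <- hz_tiny_matrix(d)
  ids3 <- sample_ids(gm3)
  f <- wc_fst(gm3, ids3[1:200], ids3[201:400])
  expect_lt(abs(mean(f$per_site, na.rm = TRUE)), 0.02)
  # estimates bounded in [-1, 1]
  expect_true(all(f$per_site >= -1 & f$per_site <= 1, na.rm = TRUE))
})

test_that("Tajima's D and pi match literal-formula oracles", {
  set.seed(9)
  # 10 haplotypes -> 5 diploids, 5 segregating sites in one window
  hap <- matrix(rbinom(10 * 5, 1, 0.4), 10, 5)
  while (!all(colSums(hap) > 0 & colSums(hap) < 10))
    hap <- matrix(rbinom(10 * 5, 1, 0.4), 10, 5)
  d <- hap[1:5, ] + hap[6:10, ]
  gm <- geno_matrix(d, data.frame(chrom = "c", pos = c(1L, 2L, 3L, 4L, 5L),
                                  ref = "A", alt = "T"))
  ws <- windowed_stats(gm, sample_ids(gm), sample_ids(gm)[0:0], # degenerate B
                       window = 50000L, min_snps = 1L)
  # compare group-A statistics against the oracle on the true haplotypes
  expect_equal(ws$tajd_a[1], oracle_tajima_d(hap), tolerance = 1e-10)
  pi_sum_oracle <- sum(apply(hap, 2, function(col) {
    k <- sum(col); 2 * k * (10 - k) / (10 * 9)
  }))
  expect_equal(ws$pi_a[1], pi_sum_oracle / 50000, tolerance = 1e-12)
})

test_that("windowed diversity handles degenerate windows exactly", {
  # n = 2 haplotypes (one diploid): D must be exactly 0 whenever S > 0
  d <- matrix(c(1L, 1L, 0L, 1L), 1, 4)
  gm <- hz_tiny_matrix(d)
  ws <- windowed_stats(gm, sample_ids(gm), character(0), min_snps = 1L)
  expect_identical(ws$tajd_a[1], 0)
  # invariant window: pi = 0, D missing
  gm0 <- hz_tiny_matrix(matrix(2L, 4, 6))
  ws0 <- windowed_stats(gm0, sample_ids(gm0), character(0), min_snps = 1L)
  expect_identical(ws0$pi_a[1], 0)
  expect_true(is.na(ws0$tajd_a[1]))
})

test_that("elevated-window rule needs all three criteria", {
  ds <- hz_small()
  pa <- hz_ids(ds, "PA"); pb <- hz_ids(ds, "PB")
  bca <- hz_ids(ds, "BCA"); bcb <- hz_ids(ds, "BCB")
  allo <- windowed_stats(ds$geno, pa, pb)
  back <- windowed_stats(ds$geno, bca, bcb)
  rep <- detect_elevated_windows(allo, back)
  ew <- ds$config$elevated_windows
  # planted window recovered, and every call satisfies the conjunction
  expect_true(any(rep$elevated$chrom == ew$chrom &
                  rep$elevated$start == ew$start))
  expect_true(all(rep$elevated$mean_fst > rep$threshold))
  expect_true(all(rep$elevated$contains_fixed))
  expect_true(all(!rep$elevated$sex_linked))
  # grid mismatch is an error
  expect_error(detect_elevated_windows(allo[-1, ], back), "grids")
  # a window above the percentile without a fixed SNP is not called:
  # strip the fixed flag and the call disappears
  allo2 <- allo
  allo2$contains_fixed <- FALSE
  rep2 <- detect_elevated_windows(allo2, back)
  expect_equal(nrow(rep2$elevated), 0L)
  # degenerate distribution: no window strictly exceeds the percentile
  allo3 <- allo
  allo3$mean_fst <- 0.3
  allo3$contains_fixed <- TRUE
  back3 <- back
  back3$mean_fst <- 0.3
  rep3 <- detect_elevated_windows(allo3, back3)
  expect_equal(nrow(rep3$elevated), 0L)
})

test_that("percentile thresholds flag about one percent of windows", {
  # homogeneous genome: fraction above the 99th percentile in (0, 2%]
  cfg <- sim_config(seed = 5,
    chromosomes = data.frame(name = "chr1", length_bp = 10e6,
                             sex_linked = FALSE, n_snps = 4000L),
    elevated_windows = NULL, inversion = NULL, n_melanin = 0L,
    n_inversion_aims = 0L,
    class_mix = c(PA = 0.5, PB = 0.5), n_cohort = 40L)
  mod <- build_parental_model(cfg)
  ds <- simulate_cohort(mod, cfg, "cohort")
  pa <- ds$samples$id[ds$samples$class == "PA"]
  pb <- ds$samples$id[ds$samples$class == "PB"]
  ws <- windowed_stats(ds$geno, pa, pb)
  pool <- ws$mean_fst[!ws$dropped & !ws$sex_linked]
  thr <- stats::quantile(pool, 0.99, names = FALSE)
  frac <- mean(pool > thr)
  expect_gt(frac, 0)
  expect_lte(frac, 0.02)
})

test_that("divergence increases monotonically with the simulator dial", {
  realized <- vapply(c(0.05, 0.19, 0.4), function(f) {
    cfg <- sim_config(seed = 13, baseline_divergence = f,
      chromosomes = data.frame(name = "chr1", length_bp = 10e6,
                               sex_linked = FALSE, n_snps = 4000L),
      elevated_windows = NULL, inversion = NULL, n_melanin = 0L,
      n_inversion_aims = 0L,
      class_mix = c(PA = 0.5, PB = 0.5), n_cohort = 40L)
    mod <- build_parental_model(cfg)
    ds <- simulate_cohort(mod, cfg, "cohort")
    wc_fst(ds$geno, ds$samples$id[ds$samples$class == "PA"],
           ds$samples$id[ds$samples$class == "PB"])$weighted
  }, 0)
  expect_true(all(diff(realized) > 0))
})

test_that("AIM panel selection obeys category rules", {
  ds <- hz_small()
  pa <- hz_ids(ds, "PA"); pb <- hz_ids(ds, "PB")
  fst <- wc_fst(ds$geno, pa, pb)
  ws <- windowed_stats(ds$geno, pa, pb, min_snps = 5L)
  # exons tiling part of chr1 so the 50-kb exclusion has teeth
  exons <- feature_intervals(chrom = rep("chr1", 20),
                             start = seq(1e6, 15e6, length.out = 20),
                             end = seq(1e6, 15e6, length.out = 20) + 2000,
                             type = "exon")
  panel <- suppressWarnings(select_aim_panel(
    ds$geno, fst$per_site, ws, exons,
    gwas_hits = which(ds$model$sites$class == "melanin"),
    inversion_snps = which(ds$model$sites$class == "inversion")[1:20],
    sizes = c(fixed = 10, background = 10, melanin = 8, inversion = 10),
    seed = 2))
  fx <- panel[panel$category == "fixed", ]
  expect_true(all(fx$stat == 1))
  bg <- panel[panel$category == "background", ]
  if (nrow(bg) >= 2) {
    # pairwise spacing >= 50 kb within chromosomes
    for (ch in unique(bg$chrom)) {
      pp <- sort(bg$pos[bg$chrom == ch])
      if (length(pp) > 1) expect_true(all(diff(pp) >= 50000))
    }
    # >= 50 kb from every exon, and inside the 55-65th percentile band,
    # verified by brute-force rescan
    for (i in seq_len(nrow(bg))) {
      same <- exons[exons$chrom == bg$chrom[i], ]
      if (nrow(same))
        expect_true(all(bg$pos[i] < same$start - 50000 |
                        bg$pos[i] > same$end + 50000))
      w <- ws[ws$chrom == bg$chrom[i] & ws$start <= bg$pos[i] &
              ws$end >= bg$pos[i], ]
      pool <- ws$mean_fst[!ws$dropped]
      expect_gte(w$mean_fst, stats::quantile(pool, 0.55, names = FALSE))
      expect_lte(w$mean_fst, stats::quantile(pool, 0.65, names = FALSE))
    }
  }
  # two eligible background sites 40 kb apart: only the first kept
  # (covered by the pairwise spacing assertion above); categories labeled
  expect_setequal(unique(panel$category),
                  c("fixed", "background", "melanin", "inversion"))
  # shortfall warning when a category cannot be filled
  expect_warning(select_aim_panel(
    ds$geno, fst$per_site, ws, exons,
    gwas_hits = integer(0), inversion_snps = integer(0),
    sizes = c(fixed = 5, background = 5, melanin = 5, inversion = 5),
    seed = 1), "partial AIM panel")
})
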