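test_that("genotype container enforces its invariants", {
  expect_error(hz_tiny_matrix(matrix(c(0L, 1L), 1, 2))$sites, NA)
  # positions must increase
  expect_error(geno_matrix(matrix(0L, 2, 2),
    data.frame(chrom = "c", pos = c(10, 10), ref = "A", alt = "T")),
    "increasing")
  # haploid entries can never be heterozygous
  expect_error(geno_matrix(matrix(1L, 1, 1),
    data.frame(chrom = "Z", pos = 1, ref = "A", alt = "T", sex_linked = TRUE),
    sex = "F"), "haploid")
  # allele counting: haploids contribute one allele
  gm <- geno_matrix(rbind(c(2L, 0L), c(2L, 1L)),
    data.frame(chrom = c("Z", "chr1"), pos = c(5L, 1L), ref = "A", alt = "T",
               sex_linked = c(TRUE, FALSE)), sex = c("F", "M"))
  ac <- allele_counts(gm)
  expect_equal(ac$n_alleles, c(3, 4))  # female Z haploid
  expect_equal(ac$alt_count, c(3, 1))
})

test_that("VCF tokens map to dosages and bad records are handled", {
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
           "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1|1",
           "chr1\t200\t.\tA\tTG\t.\tPASS\t.\tGT\t0/0\t0/0",  # indel: skipped
           "chr1\t300\t.\tC\tG,A\t.\tPASS\t.\tGT\t0/0\t0/0", # multiallelic
           "Z\t400\t.\tG\tC\t.\tPASS\t.\tGT\t1\t./.")
  path <- withr::local_tempfile(lines = vcf, fileext = ".vcf")
  suppressMessages(gm <- read_vcf(path))
  expect_equal(attr(gm, "skipped"), 2L)
  expect_equal(ncol(gm$dosage), 2L)
  expect_equal(unname(gm$dosage[, 1]), c(1L, 2L))
  expect_equal(unname(gm$dosage[, 2]), c(2L, NA))
  expect_true(gm$haploid["s1", 2])
  expect_true(gm$sites$sex_linked[2])
  bad <- sub("0/1", "0/x", vcf)
  path2 <- withr::local_tempfile(lines = bad, fileext = ".vcf")
  expect_error(suppressMessages(read_vcf(path2)), "malformed GT")
})

test_that("simulator VCF write -> read round-trips exactly", {
  ds <- hz_small()
  sub <- ds$geno[1:10, 1:100]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sub, path)
  g2 <- read_vcf(path, sex = stats::setNames(ds$samples$sex, ds$samples$id))
  expect_identical(unname(g2$dosage), unname(sub$dosage))
  expect_identical(g2$sites$pos, sub$sites$pos)
  expect_identical(g2$sites$ref, sub$sites$ref)
})

test_that("site filters apply the fixed rule order and exact thresholds", {
  # 10 samples; site 1: MAC 3, site 2: MAC 4, site 3: 30% missing,
  # site 4: 20% missing (retained under the <=20% rule), site 5: clean;
  # sites 3-4 stay polymorphic so only the missingness rule can drop them
  d <- matrix(0L, 10, 5)
  d[1:3, 1] <- 1L               # MAC 3
  d[1:4, 2] <- 1L               # MAC 4
  d[, 3] <- c(NA, NA, NA, 1L, 1L, 1L, 1L, 0L, 0L, 0L)  # 30% missing, MAC 4
  d[, 4] <- c(NA, NA, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)  # 20% missing, MAC 4
  d[1:5, 5] <- 2L
  gm <- hz_tiny_matrix(d)
  res <- suppressWarnings(filter_sites(gm, profile = "wgs"))
  expect_equal(res$report$minor_allele_count, 1L)
  expect_equal(res$report$missingness, 1L)
  expect_equal(res$kept, c(2L, 4L, 5L))
  # amplicon profile: only the >50% missing rule
  d2 <- matrix(0L, 10, 2)
  d2[1:6, 1] <- NA
  d2[1:5, 2] <- NA
  res2 <- filter_sites(hz_tiny_matrix(d2), profile = "amplicon")
  expect_equal(res2$kept, 2L)
  # filtering is idempotent
  res3 <- suppressWarnings(filter_sites(res$geno, profile = "wgs"))
  expect_equal(res3$report$retained, length(res$kept))
  expect_identical(res3$geno$dosage, res$geno$dosage)
  # retained genotype values are untouched
  expect_identical(res$geno$dosage, gm$dosage[, res$kept])
})

test_that("planted missingness is removed exactly by the site filter", {
  ds <- hz_small()
  gm <- ds$geno[, 1:1000]
  miss_sites <- 1:50
  set.seed(1)
  for (j in miss_sites)
    gm$dosage[sample(nrow(gm$dosage), 15), j] <- NA  # ~31% missing
  res <- filter_sites(gm, max_missing = 0.2)
  expect_equal(res$report$missingness, 50L)
  # brute-force recount agrees
  frac <- colMeans(is.na(gm$dosage))
  expect_equal(res$kept, which(frac <= 0.2))
})

test_that("sample filtering removes one member of each related pair", {
  ds <- hz_small()
  gm <- ds$geno[1:20, ]
  # duplicate sample 3 as sample 20 (r = 1), with extra missingness
  gm$dosage[20, ] <- gm$dosage[3, ]
  gm$haploid[20, ] <- gm$haploid[3, ]
  gm$sex[20] <- gm$sex[3]
  gm$dosage[20, 1:200] <- NA
  res <- filter_samples(gm, max_relatedness = 0.5)
  expect_identical(res$report$related, sample_ids(gm)[20])  # more missing
  expect_equal(nrow(res$geno$dosage), 19L)
  # an all-missing sample is removed with a report entry
  gm2 <- ds$geno[1:5, ]
  gm2$dosage[2, ] <- NA
  res2 <- filter_samples(gm2)
  expect_identical(res2$report$missing, sample_ids(gm2)[2])
  expect_error(filter_samples(gm, max_relatedness = 1.5), "0, 1")
})

test_that("relatedness ranks full sibs above unrelated pairs", {
  # sibs drawn from two shared parents (free recombination), embedded in a
  # panel of unrelated individuals from the same population
  ds <- hz_small()
  mod <- ds$model
  auto <- which(!mod$sites$sex_linked)
  p <- mod$p_a[auto]
  set.seed(31)
  m <- length(p)
  draw_ind <- function() rbind(rbinom(m, 1, p), rbinom(m, 1, p))
  parent1 <- draw_ind(); parent2 <- draw_ind()
  child <- function() {
    h1 <- ifelse(runif(m) < 0.5, parent1[1, ], parent1[2, ])
    h2 <- ifelse(runif(m) < 0.5, parent2[1, ], parent2[2, ])
    h1 + h2
  }
  panel <- t(replicate(20, colSums(draw_ind())))
  d <- rbind(sib1 = child(), sib2 = child(), panel)
  gm <- hz_tiny_matrix(d)
  r <- kinship_grm(gm)
  r_sib <- r["sib1", "sib2"]
  offdiag <- r[-(1:2), -(1:2)][upper.tri(r[-(1:2), -(1:2)])]
  expect_gt(r_sib, max(offdiag))
  expect_gt(r_sib, 0.35)          # pedigree expectation ~0.5
  expect_lt(mean(offdiag), 0.1)   # unrelated ~0
})

test_that("polarization maps the reference's alleles to zero", {
  d <- rbind(ref = c(2L, 0L, 1L, NA),
             s2 = c(2L, 1L, 0L, 2L),
             s3 = c(0L, 2L, 2L, 0L))
  gm <- hz_tiny_matrix(d)
  pol <- encode_polarized(gm, "ref")
  # site 1: reference 2/2 -> swapped; site 2 kept; sites 3,4 unpolarized
  expect_equal(attr(pol, "kept"), c(1L, 2L))
  expect_equal(attr(pol, "unpolarized"), c(3L, 4L))
  expect_equal(unname(pol$dosage["ref", ]), c(0L, 0L))
  expect_equal(unname(pol$dosage["s2", ]), c(0L, 1L))
  expect_equal(unname(pol$dosage["s3", ]), c(2L, 2L))
  # applying the recorded swap twice restores the original encoding
  sw <- attr(pol, "swapped")
  d2 <- pol$dosage
  d2[, sw] <- 2L - d2[, sw]
  expect_identical(unname(d2), unname(gm$dosage[, attr(pol, "kept")]))
  # re-polarizing an already-polarized matrix changes nothing
  pol2 <- encode_polarized(pol, "ref")
  expect_identical(pol2$dosage, pol$dosage[, attr(pol2, "kept")])
  expect_false(any(attr(pol2, "swapped")))
})

test_that("parental-A consensus polarization separates the species", {
  ds <- hz_small()
  mod <- ds$model
  pa <- hz_ids(ds, "PA"); pb <- hz_ids(ds, "PB")
  fixed <- which(abs(mod$p_a - mod$p_b) == 1)
  pol <- encode_polarized(ds$geno[, fixed], pa)
  mean_pa <- rowMeans(pol$dosage[pa, ], na.rm = TRUE)
  mean_pb <- rowMeans(pol$dosage[pb, ], na.rm = TRUE)
  expect_lt(max(mean_pa), min(mean_pb))
})

test_that("LD pruning removes tightly linked sites", {
  set.seed(5)
  base <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30)
  dup <- base[, rep(1:30, each = 2)]  # adjacent duplicated columns, r2 = 1
  gm <- hz_tiny_matrix(dup)
  pr <- ld_prune(gm, window = 10, step = 5, r2_max = 0.2)
  kept <- attr(pr, "kept")
  expect_lte(length(kept), 31)
  cc <- suppressWarnings(stats::cor(pr$dosage))^2
  diag(cc) <- 0
  # no surviving pair within a window exceeds the cutoff
  for (a in seq_along(kept)) for (b in seq_along(kept))
    if (a < b && abs(kept[a] - kept[b]) < 10)
      expect_lte(cc[a, b], 0.2 + 1e-9)
})

test_that("feature files read as 1-based inclusive intervals", {
  bed <- c("chr1\t999\t2000\tgeneA", "chr1\t4999\t6000\tgeneB")
  path <- withr::local_tempfile(lines = bed, fileext = ".bed")
  f <- read_features(path)
  expect_equal(f$start, c(1000, 5000))
  expect_equal(f$end, c(2000, 6000))
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=geneA;Name=geneA",
           "chr1\tsrc\texon\t1000\t1500\t.\t+\t.\tID=exonA1;Parent=geneA")
  path2 <- withr::local_tempfile(lines = gff, fileext = ".gff3")
  f2 <- read_features(path2)
  expect_setequal(f2$type, c("gene", "exon"))
  expect_equal(f2$start[f2$type == "gene"], 1000)
})
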