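# Shared desk-scale simulated datasets, built once per test run.

.hz_cache <- new.env(parent = emptyenv())

hz_memo <- function(key, expr) {
  if (!exists(key, envir = .hz_cache)) assign(key, expr, envir = .hz_cache)
  get(key, envir = .hz_cache)
}

# small cohort: 2 autosomes + Z, planted window, Z inversion, melanin loci
hz_small_config <- function(seed = 42) {
  sim_config(
    seed = seed,
    chromosomes = data.frame(
      name = c("chr1", "chr2", "Z"),
      length_bp = c(20e6, 10e6, 50e6),
      sex_linked = c(FALSE, FALSE, TRUE),
      n_snps = c(1500L, 800L, 700L)),
    elevated_windows = data.frame(chrom = "chr1", start = 5e6 + 1,
                                  end = 5e6 + 5e4, fst_target = 1),
    inversion = list(chrom = "Z", start = 10e6, end = 35e6, divergence = 0.5),
    n_cohort = 48L,
    n_melanin = 10L)
}

hz_small <- function() hz_memo("small", {
  cfg <- hz_small_config()
  mod <- build_parental_model(cfg)
  ds <- simulate_cohort(mod, cfg, "cohort")
  ds$phen <- simulate_phenotypes(ds, cfg)
  ds
})

hz_ids <- function(ds, cls) ds$samples$id[ds$samples$class %in% cls]

hz_transect <- function() hz_memo("transect", {
  cfg <- sim_config(
    seed = 7,
    chromosomes = data.frame(
      name = c("chr1", "Z"), length_bp = c(20e6, 50e6),
      sex_linked = c(FALSE, TRUE), n_snps = c(1200L, 600L)),
    elevated_windows = data.frame(chrom = "chr1", start = 5e6 + 1,
                                  end = 5e6 + 5e4, fst_target = 1),
    inversion = list(chrom = "Z", start = 10e6, end = 35e6, divergence = 0.5),
    localities = data.frame(name = sprintf("L%02d", 1:12),
                            distance_km = seq(0, 550, by = 50),
                            n_samples = 15L))
  mod <- build_parental_model(cfg)
  simulate_cohort(mod, cfg, "transect")
})

# tiny geno_matrix built by hand for exact-value tests
hz_tiny_matrix <- function(dosage, chrom = "chr1", sex = NULL,
                           sex_linked = FALSE) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  geno_matrix(dosage,
              data.frame(chrom = chrom, pos = seq_len(m) * 1000L,
                         ref = "A", alt = "T", sex_linked = sex_linked),
              sex = sex)
}
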