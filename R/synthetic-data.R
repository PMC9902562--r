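#' Simulation configuration for a synthetic hybrid zone
#'
#' Bundles every knob of the synthetic hybrid-zone generator. Defaults
#' describe a two-species avian contact zone at desk scale: two parental
#' populations differentiated at a genome-wide Weir-Cockerham FST of 0.19,
#' a handful of planted high-divergence autosomal windows, a large
#' recombination-suppressing inversion on the Z chromosome, five genotypic
#' classes (allopatric parentals, F1, and both backcrosses), a riverine
#' transect with sigmoid-clinal allele frequencies, and nine ordinal plumage
#' traits (scores 0-4) driven by additive and epistatic melanin loci.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param chromosomes data.frame with `name`, `length_bp`, `sex_linked`,
#'   `n_snps`.
#' @param baseline_divergence target genome-wide Weir-Cockerham FST between
#'   the two parental populations.
#' @param elevated_windows data.frame `chrom`, `start`, `end`, `fst_target`
#'   of planted high-divergence windows (per-site target near 1).
#' @param inversion list `chrom`, `start`, `end`, `divergence`; orientation
#'   is fixed for opposite arrangements in the two parental populations, and
#'   `divergence` controls allele-frequency differentiation of the SNPs it
#'   carries (Z divergence typically exceeds the autosomal baseline in
#'   ZW systems).
#' @param localities data.frame `name`, `distance_km`, `n_samples`;
#'   distances nonnegative, strictly increasing along the transect.
#' @param true_clines named list per marker class of `c(center, width)` in
#'   km, used as simulation truth in transect mode.
#' @param class_mix named proportions over genotypic classes
#'   (`PA`, `PB`, `F1`, `BCA`, `BCB`, `F2`) for cohort mode; must sum to 1.
#' @param n_cohort number of samples drawn in cohort mode.
#' @param trait_architecture NULL (a default architecture is built from the
#'   simulated melanin loci) or a list with `noise` and `traits`, the latter
#'   a list of 9 elements each holding data.frames `additive` (`site`,
#'   `effect`) and `epistatic` (`site1`, `site2`, `effect`); `site` values
#'   index the simulated variant table.
#' @param n_melanin number of melanin-candidate loci designated among
#'   strongly differentiated sites.
#' @param n_inversion_aims number of inversion-class sites made diagnostic
#'   (fixed between orientations), emulating amplicons strongly associated
#'   with the rearrangement.
#' @param missingness per-call missing probability, applied last.
#' @param xo_rate probability of one crossover per chromosome per meiosis
#'   (uniform position; suppressed inside the inversion when the
#'   transmitting parent is karyotype-heterozygous).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = data.frame(
                         name = c("chr1", "chr2", "Z"),
                         length_bp = c(50e6, 30e6, 75e6),
                         sex_linked = c(FALSE, FALSE, TRUE),
                         n_snps = c(45000L, 27000L, 2800L)),
                       baseline_divergence = 0.19,
                       elevated_windows = data.frame(
                         chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                         start = c(10e6, 24e6, 38e6, 8e6, 21e6) + 1,
                         end = c(10e6, 24e6, 38e6, 8e6, 21e6) + 50e3,
                         fst_target = 1),
                       inversion = list(chrom = "Z", start = 10e6, end = 40e6,
                                        divergence = 0.5),
                       localities = data.frame(
                         name = sprintf("L%02d", 1:12),
                         distance_km = seq(0, 550, by = 50),
                         n_samples = 15L),
                       true_clines = list(
                         fixed = c(center = 214, width = 362),
                         melanin = c(center = 175, width = 275),
                         inversion = c(center = 177, width = 244),
                         background = c(center = 175, width = 275)),
                       class_mix = c(PA = 0.2, PB = 0.2, F1 = 0.2,
                                     BCA = 0.2, BCB = 0.2),
                       n_cohort = 60L,
                       trait_architecture = NULL,
                       n_melanin = 12L,
                       n_inversion_aims = 8L,
                       missingness = 0,
                       xo_rate = 1) {
  cfg <- list(seed = as.integer(seed), chromosomes = chromosomes,
              baseline_divergence = baseline_divergence,
              elevated_windows = elevated_windows, inversion = inversion,
              localities = localities, true_clines = true_clines,
              class_mix = class_mix, n_cohort = as.integer(n_cohort),
              trait_architecture = trait_architecture,
              n_melanin = as.integer(n_melanin),
              n_inversion_aims = as.integer(n_inversion_aims),
              missingness = missingness, xo_rate = xo_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ch <- cfg$chromosomes
  stopifnot(all(c("name", "length_bp", "sex_linked", "n_snps") %in% names(ch)))
  if (!is.null(cfg$elevated_windows) && nrow(cfg$elevated_windows)) {
    ew <- cfg$elevated_windows
    for (k in seq_len(nrow(ew))) {
      i <- match(ew$chrom[k], ch$name)
      if (is.na(i) || ew$start[k] < 1 || ew$end[k] > ch$length_bp[i] ||
          ew$start[k] > ew$end[k])
        stop("elevated window ", ew$chrom[k], ":", ew$start[k], "-", ew$end[k],
             " lies outside the simulated chromosomes")
    }
  }
  if (!is.null(cfg$inversion)) {
    i <- match(cfg$inversion$chrom, ch$name)
    if (is.na(i) || cfg$inversion$start < 1 ||
        cfg$inversion$end > ch$length_bp[i])
      stop("inversion interval outside chromosome ", cfg$inversion$chrom)
  }
  if (!is.null(cfg$localities) && nrow(cfg$localities)) {
    d <- cfg$localities$distance_km
    if (any(d < 0) || any(diff(d) <= 0))
      stop("locality distances must be nonnegative and strictly increasing")
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1")
  invisible(cfg)
}

# Balding-Nichols draw of daughter-population frequencies around an ancestral
# frequency p with differentiation F: Beta(p(1-F)/F, (1-p)(1-F)/F).
# Checked once by simulation at 50k sites: the realized genome-wide
# Weir-Cockerham ratio-of-sums estimate between two drawn populations matches
# the nominal F within a few percent, so no calibration factor is applied.
bn_draw <- function(p, fst) {
  if (fst <= 0) return(p)
  f <- min(fst, 0.999)
  theta <- (1 - f) / f
  stats::rbeta(length(p), p * theta, (1 - p) * theta)
}

#' Build a two-population parental allele-frequency model
#'
#' Draws per-site allele frequencies for population A (Baltimore-like) and
#' population B (Bullock's-like) under a Balding-Nichols model whose
#' concentration is set by the target genome-wide FST, then plants the
#' configured high-divergence windows (per-site frequencies pushed to the
#' window's FST target; a target of 1 fixes opposite alleles), designates
#' melanin-candidate loci among fixed differences, and fixes opposite
#' inversion orientations in the two populations.
#'
#' @param config a [sim_config()].
#' @return A `parental_model`: list with `sites` (chrom, pos, ref, alt,
#'   sex_linked, class), `p_a`, `p_b` (per-site allele frequencies of the
#'   "1" allele), `inversion`, and the config.
#' @export
build_parental_model <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ch <- config$chromosomes
  sites <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    pos <- sort(sample.int(ch$length_bp[i], ch$n_snps[i]))
    data.frame(chrom = ch$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  # guarantee sites inside every planted window (>= 25, typical 50-kb density)
  ew <- config$elevated_windows
  if (!is.null(ew) && nrow(ew)) {
    add <- list()
    for (k in seq_len(nrow(ew))) {
      have <- sum(sites$chrom == ew$chrom[k] &
                  sites$pos >= ew$start[k] & sites$pos <= ew$end[k])
      if (have < 25) {
        newpos <- unique(round(stats::runif(25 - have, ew$start[k], ew$end[k])))
        add[[length(add) + 1]] <- data.frame(chrom = ew$chrom[k], pos = newpos,
                                             stringsAsFactors = FALSE)
      }
    }
    if (length(add)) {
      sites <- rbind(sites, do.call(rbind, add))
      sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
      sites <- sites[order(match(sites$chrom, ch$name), sites$pos), ]
    }
  }
  m <- nrow(sites)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  sites$sex_linked <- ch$sex_linked[match(sites$chrom, ch$name)]
  sites$class <- "background"
  rownames(sites) <- NULL

  p_anc <- stats::runif(m, 0.05, 0.95)
  p_a <- bn_draw(p_anc, config$baseline_divergence)
  p_b <- bn_draw(p_anc, config$baseline_divergence)

  inv <- config$inversion
  if (!is.null(inv)) {
    in_inv <- sites$chrom == inv$chrom & sites$pos >= inv$start &
      sites$pos <= inv$end
    sites$class[in_inv] <- "inversion"
    p_a[in_inv] <- bn_draw(p_anc[in_inv], inv$divergence)
    p_b[in_inv] <- bn_draw(p_anc[in_inv], inv$divergence)
    inv$freq_a <- 0; inv$freq_b <- 1   # orientation fixed in each parental pop
  }
  if (!is.null(ew) && nrow(ew)) {
    for (k in seq_len(nrow(ew))) {
      idx <- sites$chrom == ew$chrom[k] & sites$pos >= ew$start[k] &
        sites$pos <= ew$end[k]
      t <- ew$fst_target[k]
      p_a[idx] <- (1 - t) / 2
      p_b[idx] <- (1 + t) / 2
      sites$class[idx] <- "fixed"
    }
  }
  # melanin candidates: fixed-difference loci spread across chromosomes,
  # preferring the planted windows, with at least a third on the Z when a
  # Z inversion is configured (plumage loci concentrate on Z in such systems)
  n_inv_aims <- config$n_inversion_aims
  if (is.null(n_inv_aims)) n_inv_aims <- 0L
  if (!is.null(inv) && n_inv_aims > 0) {
    inv_idx <- which(sites$class == "inversion")
    pick <- sample(inv_idx, min(length(inv_idx), n_inv_aims))
    p_a[pick] <- 0; p_b[pick] <- 1   # diagnostic for the orientation
  }
  fixed_idx <- which(abs(p_a - p_b) == 1)
  if (config$n_melanin > 0) {
    pick <- integer(0)
    if (!is.null(inv)) {
      inv_idx <- which(sites$class == "inversion")
      n_z <- min(length(inv_idx), ceiling(config$n_melanin / 3))
      pick <- sample(inv_idx, n_z)
      p_a[pick] <- 0; p_b[pick] <- 1     # melanin loci are diagnostic
    }
    rest <- setdiff(fixed_idx, pick)
    pick <- c(pick, sample(rest, min(length(rest), config$n_melanin - length(pick))))
    sites$class[pick] <- "melanin"
  }
  structure(list(sites = sites, p_a = p_a, p_b = p_b, inversion = inv,
                 config = config),
            class = "parental_model")
}

unit_cline_q <- function(x, center, width) {
  (1 + tanh(2 * (x - center) / width)) / 2
}

# one meiosis: returns the transmitted haplotype (and Z orientation) from an
# individual with haplotypes h1/h2 (allele vectors), origins o1/o2, and
# inversion orientations ori (length-2, NA for absent Z copies).
make_gamete <- function(h1, h2, o1, o2, ori, sites, chrom_tab, inv, xo_rate) {
  g <- h1; og <- o1
  g_ori <- ori[1]
  for (i in seq_len(nrow(chrom_tab))) {
    cname <- chrom_tab$name[i]
    idx <- which(sites$chrom == cname)
    if (!length(idx)) next
    start_h <- sample.int(2L, 1L)
    xo <- NA_real_
    if (stats::runif(1) < xo_rate) xo <- stats::runif(1, 0, chrom_tab$length_bp[i])
    hetero_inv <- !is.null(inv) && cname == inv$chrom &&
      !any(is.na(ori)) && ori[1] != ori[2]
    if (hetero_inv && !is.na(xo) && xo >= inv$start && xo <= inv$end)
      xo <- NA_real_   # crossover suppressed inside the inversion
    take1 <- rep(start_h == 1L, length(idx))
    if (!is.na(xo)) {
      after <- sites$pos[idx] > xo
      take1[after] <- !take1[after]
    }
    g[idx] <- ifelse(take1, h1[idx], h2[idx])
    og[idx] <- ifelse(take1, o1[idx], o2[idx])
    if (!is.null(inv) && cname == inv$chrom) {
      # which haplotype supplies the inversion interval decides orientation;
      # the interval is never split when the parent is karyotype-heterozygous
      from_start <- if (is.na(xo)) TRUE
                    else if (xo < inv$start) FALSE    # interval lies after xo
                    else TRUE                          # xo inside (homokaryotype
                                                       # only) or beyond the end
      supplies_1 <- if (from_start) start_h == 1L else start_h != 1L
      g_ori <- if (supplies_1) ori[1] else ori[2]
    }
  }
  list(h = g, o = og, ori = g_ori)
}

draw_parental_hap <- function(model, pop) {
  p <- if (pop == "A") model$p_a else model$p_b
  ori <- if (is.null(model$inversion)) NA_integer_
         else if (pop == "A") model$inversion$freq_a else model$inversion$freq_b
  list(h = stats::rbinom(length(p), 1L, p),
       o = rep(if (pop == "A") 0L else 1L, length(p)),
       ori = as.integer(ori))
}

#' Simulate a hybrid-zone cohort or transect from a parental model
#'
#' Cohort mode draws samples from the configured genotypic-class mixture
#' (allopatric parentals, F1, backcrosses, F2) via explicit gamete
#' simulation: one crossover per chromosome per meiosis at a uniform
#' position, with zero recombination inside the inversion interval when the
#' transmitting parent is karyotype-heterozygous. Transect mode draws each
#' sample's alleles from the true cline frequency of its marker class at the
#' sample's locality distance; inversion-interval alleles are drawn
#' conditional on each Z haplotype's orientation, itself drawn from the
#' inversion-class cline. Sex is assigned 50:50 and females are hemizygous
#' on Z (dosage in \{0, 2\}, flagged haploid). Missingness is applied last.
#'
#' @param model a `parental_model` from [build_parental_model()].
#' @param config the [sim_config()] used to build the model.
#' @param mode `"cohort"` or `"transect"`.
#' @return A `sim_dataset`: list with `geno` ([geno_matrix()]), `samples`
#'   (id, sex, class, locality, distance_km, true_karyotype,
#'   true_ancestry), and `truth` (planted windows, inversion interval,
#'   causal loci once phenotypes are simulated, true clines).
#' @export
simulate_cohort <- function(model, config, mode = c("cohort", "transect")) {
  mode <- match.arg(mode)
  set.seed(config$seed + 1L)
  sites <- model$sites
  m <- nrow(sites)
  inv <- model$inversion
  ch <- config$chromosomes
  z_sites <- which(sites$sex_linked)

  if (mode == "cohort") {
    n <- config$n_cohort
    classes <- sample(names(config$class_mix), n, replace = TRUE,
                      prob = config$class_mix)
    locality <- rep(NA_character_, n); distance <- rep(NA_real_, n)
  } else {
    loc <- config$localities
    if (is.null(loc) || nrow(loc) == 0)
      stop("transect mode requires a non-empty locality list")
    n <- sum(loc$n_samples)
    classes <- rep("unknown", n)
    locality <- rep(loc$name, loc$n_samples)
    distance <- rep(loc$distance_km, loc$n_samples)
  }
  sex <- sample(c("M", "F"), n, replace = TRUE)
  hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
  org1 <- matrix(0L, n, m); org2 <- matrix(0L, n, m)
  ori <- matrix(NA_integer_, n, 2)

  if (mode == "cohort") {
    f1_pool <- replicate(4, {
      a <- draw_parental_hap(model, "A"); b <- draw_parental_hap(model, "B")
      list(h1 = a$h, h2 = b$h, o1 = a$o, o2 = b$o, ori = c(a$ori, b$ori))
    }, simplify = FALSE)
    for (i in seq_len(n)) {
      cl <- classes[i]
      if (cl %in% c("PA", "PB")) {
        pop <- if (cl == "PA") "A" else "B"
        g1 <- draw_parental_hap(model, pop); g2 <- draw_parental_hap(model, pop)
        g1 <- list(h = g1$h, o = g1$o, ori = g1$ori)
        g2 <- list(h = g2$h, o = g2$o, ori = g2$ori)
      } else if (cl == "F1") {
        pops <- sample(c("A", "B"))
        g1 <- draw_parental_hap(model, pops[1])   # paternal (carries Z)
        g2 <- draw_parental_hap(model, pops[2])   # maternal
      } else if (cl %in% c("BCA", "BCB")) {
        f1 <- f1_pool[[sample.int(length(f1_pool), 1)]]
        g1 <- make_gamete(f1$h1, f1$h2, f1$o1, f1$o2, f1$ori,
                          sites, ch, inv, config$xo_rate)
        g2 <- draw_parental_hap(model, if (cl == "BCA") "A" else "B")
      } else { # F2
        f1a <- f1_pool[[sample.int(length(f1_pool), 1)]]
        f1b <- f1_pool[[sample.int(length(f1_pool), 1)]]
        g1 <- make_gamete(f1a$h1, f1a$h2, f1a$o1, f1a$o2, f1a$ori,
                          sites, ch, inv, config$xo_rate)
        g2 <- make_gamete(f1b$h1, f1b$h2, f1b$o1, f1b$o2, f1b$ori,
                          sites, ch, inv, config$xo_rate)
      }
      hap1[i, ] <- g1$h; org1[i, ] <- g1$o
      hap2[i, ] <- g2$h; org2[i, ] <- g2$o
      ori[i, ] <- c(g1$ori, g2$ori)
    }
  } else {
    tc <- config$true_clines
    cls <- sites$class
    cls[!(cls %in% names(tc))] <- "background"
    for (i in seq_len(n)) {
      q <- vapply(cls, function(cl)
        unit_cline_q(distance[i], tc[[cl]]["center"], tc[[cl]]["width"]),
        0)
      p_site <- (1 - q) * model$p_a + q * model$p_b
      for (h in 1:2) {
        al <- stats::rbinom(m, 1L, p_site)
        o <- rep(NA_integer_, m)
        hori <- NA_integer_
        if (!is.null(inv)) {
          q_inv <- unit_cline_q(distance[i], tc[["inversion"]]["center"],
                                tc[["inversion"]]["width"])
          hori <- stats::rbinom(1, 1L, q_inv)
          in_inv <- sites$class %in% c("inversion", "melanin") &
            sites$chrom == inv$chrom &
            sites$pos >= inv$start & sites$pos <= inv$end
          p_cond <- if (hori == 1L) model$p_b[in_inv] else model$p_a[in_inv]
          al[in_inv] <- stats::rbinom(sum(in_inv), 1L, p_cond)
        }
        if (h == 1) { hap1[i, ] <- al; ori[i, 1] <- hori }
        else        { hap2[i, ] <- al; ori[i, 2] <- hori }
      }
    }
  }

  # females: single Z copy (the paternal/hap1 slot); hap2 Z is the W
  dosage <- hap1 + hap2
  hap2_valid <- matrix(TRUE, n, m)
  if (length(z_sites)) {
    fem <- which(sex == "F")
    if (length(fem)) {
      dosage[fem, z_sites] <- 2L * hap1[fem, z_sites]
      hap2_valid[fem, z_sites] <- FALSE
      ori[fem, 2] <- NA_integer_
    }
  }
  true_anc <- (rowSums(org1) +
               rowSums(org2 * hap2_valid)) /
    (m + rowSums(hap2_valid))
  if (mode == "transect") {
    tc <- config$true_clines
    true_anc <- unit_cline_q(distance, tc[["background"]]["center"],
                             tc[["background"]]["width"])
  }
  karyo <- rep(NA_character_, n)
  if (!is.null(inv)) {
    karyo <- ifelse(sex == "F",
                    ifelse(ori[, 1] == 1, "BB", "AA"),
                    c("AA", "AB", "BB")[ori[, 1] + ori[, 2] + 1L])
  }
  if (config$missingness > 0) {
    drop <- matrix(stats::runif(n * m) < config$missingness, n, m)
    dosage[drop] <- NA_integer_
  }
  ids <- sprintf("S%03d", seq_len(n))
  rownames(dosage) <- ids
  samples <- data.frame(id = ids, sex = sex, class = classes,
                        locality = locality, distance_km = distance,
                        true_karyotype = karyo, true_ancestry = true_anc,
                        stringsAsFactors = FALSE)
  geno <- geno_matrix(dosage, sites[, c("chrom", "pos", "ref", "alt",
                                        "sex_linked")], sex = sex)
  truth <- list(elevated_windows = config$elevated_windows,
                inversion = inv,
                site_class = sites$class,
                true_clines = config$true_clines,
                p_a = model$p_a, p_b = model$p_b)
  structure(list(geno = geno, samples = samples, truth = truth,
                 model = model, config = config),
            class = "sim_dataset")
}

#' Default plumage-trait architecture built from the simulated melanin loci
#'
#' Nine ordinal traits; each trait gets two additive melanin loci and, for
#' the first five traits, one epistatic pair (mirroring head traits being
#' the most interaction-driven in melanin-based plumage systems).
#'
#' @param model a `parental_model`.
#' @param noise Gaussian liability noise SD.
#' @param additive_effect,epistatic_effect per-locus effect sizes on the
#'   liability scale.
#' @return trait-architecture list suitable for `sim_config()`.
#' @export
default_trait_architecture <- function(model, noise = 0.5,
                                       additive_effect = 1,
                                       epistatic_effect = 1) {
  mel <- which(model$sites$class == "melanin")
  if (length(mel) < 4) stop("model has too few melanin loci")
  trait_names <- c("supercilium", "forehead", "ears", "neck", "throat",
                   "tail_tip", "tail_base", "greater_coverts",
                   "lesser_coverts")
  traits <- lapply(seq_along(trait_names), function(t) {
    loci <- mel[((2 * (t - 1)) %% length(mel)) + c(1, 2)]
    ep <- NULL
    if (t <= 5) {
      pr <- mel[((2 * t) %% length(mel)) + c(1, 2)]
      ep <- data.frame(site1 = pr[1], site2 = pr[2],
                       effect = epistatic_effect)
    }
    list(additive = data.frame(site = loci, effect = additive_effect),
         epistatic = ep)
  })
  names(traits) <- trait_names
  list(noise = noise, traits = traits)
}

#' Simulate ordinal plumage scores from a genetic architecture
#'
#' For each trait a latent liability is formed as the sum of additive
#' effects times alt-allele dosage, interaction effects times the centered
#' product coding (g1 - 1)(g2 - 1), and Gaussian noise; the liability is
#' mapped monotonically to integer scores 0-4 through fixed standardized
#' cut-points (-1.5, -0.5, 0.5, 1.5) shared across traits. The total score
#' over the nine traits lies in [0, 36].
#'
#' @param dataset a `sim_dataset` from [simulate_cohort()].
#' @param config its [sim_config()]; if `trait_architecture` is NULL,
#'   [default_trait_architecture()] is used.
#' @return Integer matrix samples x 9 traits with attribute `"liability"`
#'   (the noiseless-plus-noise latent values) and `"architecture"`.
#' @export
simulate_phenotypes <- function(dataset, config = dataset$config) {
  set.seed(config$seed + 2L)
  arch <- config$trait_architecture
  if (is.null(arch)) arch <- default_trait_architecture(dataset$model)
  g <- dataset$geno$dosage
  if (anyNA(g)) {
    af <- allele_counts(dataset$geno)$freq
    for (j in which(colSums(is.na(g)) > 0))
      g[is.na(g[, j]), j] <- 2 * af[j]
  }
  n <- nrow(g)
  scores <- matrix(0L, n, length(arch$traits),
                   dimnames = list(rownames(g), names(arch$traits)))
  liab <- matrix(0, n, length(arch$traits),
                 dimnames = dimnames(scores))
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  for (t in seq_along(arch$traits)) {
    tr <- arch$traits[[t]]
    L <- rep(0, n)
    if (!is.null(tr$additive) && nrow(tr$additive))
      for (k in seq_len(nrow(tr$additive)))
        L <- L + tr$additive$effect[k] * g[, tr$additive$site[k]]
    if (!is.null(tr$epistatic) && nrow(tr$epistatic))
      for (k in seq_len(nrow(tr$epistatic)))
        L <- L + tr$epistatic$effect[k] *
          (g[, tr$epistatic$site1[k]] - 1) * (g[, tr$epistatic$site2[k]] - 1)
    if (arch$noise > 0) L <- L + stats::rnorm(n, 0, arch$noise)
    liab[, t] <- L
    s <- stats::sd(L)
    z <- if (is.na(s) || s == 0) rep(0, n) else (L - mean(L)) / s
    scores[, t] <- findInterval(z, cuts)
  }
  attr(scores, "liability") <- liab
  attr(scores, "architecture") <- arch
  scores
}

#' Write a simulated dataset to disk
#'
#' Emits a plain-text GT-only VCF v4.2, a sample-metadata TSV, a trait TSV
#' (when phenotypes were simulated), and a truth-record JSON.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory, created if absent.
#' @param traits optional matrix from [simulate_phenotypes()].
#' @return Invisibly, the paths written.
#' @export
write_sim_dataset <- function(dataset, dir, traits = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(dataset$geno, paths["vcf"])
  utils::write.table(dataset$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(traits)) {
    paths["traits"] <- file.path(dir, "traits.tsv")
    df <- data.frame(id = rownames(traits), traits,
                     total = rowSums(traits), check.names = FALSE)
    utils::write.table(df, paths["traits"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tr <- dataset$truth
  tr$p_a <- NULL; tr$p_b <- NULL  # frequencies live in the model, not JSON
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}
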