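#' Geographic cline model
#'
#' Sigmoid allele-frequency cline along a one-dimensional transect with
#' optional exponential introgression tails. The central segment is
#' p(x) = pmin + (pmax - pmin) (1 + tanh(2 (x - c) / w)) / 2 with center c
#' (km) and width w (km, the inverse of the maximum slope). A tail takes
#' over at distance delta from the center on each side and decays
#' exponentially in x; tau in [0, 1] is the ratio of the tail's slope to
#' the central cline's slope at the junction, and continuity of p is
#' enforced at both junctions by construction. Tail modes: `none`,
#' `mirror` (right tail copies the left), `both` (independent tails).
#'
#' @param center,width cline center and width in km (width > 0).
#' @param pmin,pmax end allele frequencies (0 <= pmin < pmax <= 1).
#' @param tail tail mode.
#' @param delta_l,tau_l,delta_r,tau_r tail parameters (delta >= 0 km,
#'   tau in [0, 1]); in mirror mode the right side copies the left.
#' @return list of class `cline_model`.
#' @export
cline_model <- function(center, width, pmin = 0, pmax = 1,
                        tail = c("none", "mirror", "both"),
                        delta_l = NA, tau_l = NA, delta_r = NA, tau_r = NA) {
  tail <- match.arg(tail)
  stopifnot(width > 0, pmin >= 0, pmax <= 1, pmin < pmax)
  if (tail == "mirror") { delta_r <- delta_l; tau_r <- tau_l }
  if (tail != "none") {
    stopifnot(!is.na(delta_l), !is.na(tau_l), delta_l >= 0,
              tau_l >= 0, tau_l <= 1)
    if (tail == "both")
      stopifnot(!is.na(delta_r), !is.na(tau_r), delta_r >= 0,
                tau_r >= 0, tau_r <= 1)
  }
  structure(list(center = center, width = width, pmin = pmin, pmax = pmax,
                 tail = tail, delta_l = delta_l, tau_l = tau_l,
                 delta_r = delta_r, tau_r = tau_r),
            class = "cline_model")
}

#' Expected allele frequency under a cline model
#'
#' @param model a [cline_model()].
#' @param x transect distance(s) in km.
#' @return expected frequency, continuous and non-decreasing in x.
#' @export
cline_frequency <- function(model, x) {
  ctr <- model$center; w <- model$width
  q <- (1 + tanh(2 * (x - ctr) / w)) / 2
  if (model$tail != "none") {
    qslope <- function(z) (1 - tanh(2 * (z - ctr) / w)^2) / w
    xl <- ctr - model$delta_l
    ql <- (1 + tanh(2 * (xl - ctr) / w)) / 2
    if (ql > 0) {
      lam_l <- model$tau_l * qslope(xl) / ql
      left <- x < xl
      q[left] <- ql * exp(lam_l * (x[left] - xl))
    }
    xr <- ctr + model$delta_r
    qr <- (1 + tanh(2 * (xr - ctr) / w)) / 2
    if (qr < 1) {
      lam_r <- model$tau_r * qslope(xr) / (1 - qr)
      right <- x > xr
      q[right] <- 1 - (1 - qr) * exp(-lam_r * (x[right] - xr))
    }
  }
  model$pmin + (model$pmax - model$pmin) * q
}

cline_par_spec <- function(tail, fix_ends, dmin, dmax) {
  rng <- dmax - dmin
  spec <- data.frame(
    name = c("center", "width"),
    lo = c(dmin - rng, 1e-6),
    hi = c(dmax + rng, 3 * rng),
    init = c((dmin + dmax) / 2, rng / 2),
    stringsAsFactors = FALSE)
  if (!fix_ends)
    spec <- rbind(spec, data.frame(name = c("pmin", "pmax"),
                                   lo = c(0, 0), hi = c(1, 1),
                                   init = c(0.05, 0.95)))
  if (tail %in% c("mirror", "both"))
    spec <- rbind(spec, data.frame(name = c("delta_l", "tau_l"),
                                   lo = c(0, 0), hi = c(rng, 1),
                                   init = c(rng / 4, 0.5)))
  if (tail == "both")
    spec <- rbind(spec, data.frame(name = c("delta_r", "tau_r"),
                                   lo = c(0, 0), hi = c(rng, 1),
                                   init = c(rng / 4, 0.5)))
  spec
}

cline_from_par <- function(par, tail, fix_ends) {
  p <- as.list(par)
  cline_model(center = p$center, width = p$width,
              pmin = if (fix_ends) 0 else min(p$pmin, p$pmax - 1e-6),
              pmax = if (fix_ends) 1 else p$pmax,
              tail = tail,
              delta_l = if (!is.null(p$delta_l)) p$delta_l else NA,
              tau_l = if (!is.null(p$tau_l)) p$tau_l else NA,
              delta_r = if (!is.null(p$delta_r)) p$delta_r else NA,
              tau_r = if (!is.null(p$tau_r)) p$tau_r else NA)
}

cline_loglik <- function(par, data, tail, fix_ends) {
  if (!fix_ends && par["pmin"] >= par["pmax"]) return(-Inf)
  m <- cline_from_par(par, tail, fix_ends)
  p <- cline_frequency(m, data$distance_km)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  sum(data$count * log(p) + (data$n - data$count) * log(1 - p))
}

#' Fit a geographic cline by Metropolis-Hastings MCMC
#'
#' Binomial likelihood of per-locality allele counts under the cline
#' expectation (frequencies clamped to [1e-6, 1 - 1e-6]). Gaussian
#' random-walk proposals per parameter, with scales adapted during burn-in
#' to target 20-40% acceptance; uniform priors (center within the observed
#' distance range extended by one range-width, width in (0, 3 range],
#' delta in [0, range], tau in [0, 1]). `fix_ends` pins the end
#' frequencies to 0 (Baltimore side) and 1 (Bullock's side). Support
#' intervals are the two-log-likelihood rule applied to the posterior
#' sample; posterior quantile intervals are also reported.
#'
#' @param data data.frame with `distance_km`, `n` (called alleles:
#'   2 x diploids + 1 x hemizygotes), `count` (Bullock's-allele count);
#'   >= 4 localities.
#' @param tail tail mode (`none`, `mirror`, `both`).
#' @param fix_ends pin pmin = 0, pmax = 1.
#' @param chains number of MCMC chains.
#' @param iterations post-burn-in iterations per chain.
#' @param burn_in adaptation/burn-in iterations per chain.
#' @param seed RNG seed; identical settings give identical samples.
#' @param support `"profile"` (default) computes each parameter's
#'   two-log-likelihood support interval from the profile likelihood by
#'   constrained optimization; `"samples"` uses the faster but narrower
#'   range of posterior draws within two log-likelihood units of the
#'   maximum.
#' @return list of class `cline_fit`: `map` (MAP cline_model), `samples`
#'   (posterior draws + logL), `support` (two-log-likelihood intervals),
#'   `quantiles`, `loglik` (maximum), `aicc`, `n_par`, `acceptance`,
#'   `tail`, `seed`.
#' @export
fit_cline <- function(data, tail = c("none", "mirror", "both"),
                      fix_ends = TRUE, chains = 1, iterations = 4000,
                      burn_in = 1000, seed = 1,
                      support = c("profile", "samples")) {
  support <- match.arg(support)
  tail <- match.arg(tail)
  stopifnot(nrow(data) >= 4, length(unique(data$distance_km)) > 1,
            all(data$count >= 0), all(data$count <= data$n))
  if (all(data$count == 0) || all(data$count == data$n))
    warning("all-zero or all-n counts: degenerate flat cline")
  set.seed(seed)
  spec <- cline_par_spec(tail, fix_ends, min(data$distance_km),
                         max(data$distance_km))
  np <- nrow(spec)
  all_samples <- list(); acc_rates <- numeric(chains)
  for (chain in seq_len(chains)) {
    par <- stats::setNames(spec$init, spec$name)
    # jitter chain starts (deterministically, via the seeded stream)
    par <- par + 0.05 * (spec$hi - spec$lo) * stats::runif(np, -1, 1)
    par <- pmin(pmax(par, spec$lo), spec$hi)
    ll <- cline_loglik(par, data, tail, fix_ends)
    scale <- (spec$hi - spec$lo) / 20
    samples <- matrix(NA_real_, iterations, np + 1,
                      dimnames = list(NULL, c(spec$name, "logL")))
    acc <- integer(np); tries <- integer(np)
    for (it in seq_len(burn_in + iterations)) {
      for (k in seq_len(np)) {
        prop <- par
        prop[k] <- par[k] + stats::rnorm(1, 0, scale[k])
        if (prop[k] < spec$lo[k] || prop[k] > spec$hi[k]) next
        ll_p <- cline_loglik(prop, data, tail, fix_ends)
        tries[k] <- tries[k] + 1L
        if (is.finite(ll_p) && log(stats::runif(1)) < ll_p - ll) {
          par <- prop; ll <- ll_p; acc[k] <- acc[k] + 1L
        }
      }
      if (it <= burn_in && it %% 100 == 0) {
        rate <- ifelse(tries > 0, acc / tries, 0.3)
        scale[rate > 0.4] <- scale[rate > 0.4] * 1.3
        scale[rate < 0.2] <- scale[rate < 0.2] * 0.7
        acc[] <- 0L; tries[] <- 0L
      }
      if (it > burn_in) samples[it - burn_in, ] <- c(par, ll)
    }
    acc_rates[chain] <- mean(ifelse(tries > 0, acc / tries, NA), na.rm = TRUE)
    all_samples[[chain]] <- samples
  }
  samples <- do.call(rbind, all_samples)
  best <- which.max(samples[, "logL"])
  map_par <- samples[best, seq_len(np)]
  # polish the MAP by local optimization from the best draw
  if (np > 1) {
    opt <- tryCatch(stats::optim(map_par, function(p) {
      names(p) <- spec$name
      -cline_loglik(p, data, tail, fix_ends)
    }, method = "L-BFGS-B", lower = spec$lo + 1e-9, upper = spec$hi - 1e-9),
    error = function(e) NULL)
    if (!is.null(opt) && -opt$value > samples[best, "logL"]) {
      map_par <- stats::setNames(opt$par, spec$name)
    }
  }
  max_ll_map <- cline_loglik(map_par, data, tail, fix_ends)
  keep <- samples[, "logL"] >= max_ll_map - 2
  supp <- t(apply(samples[keep, seq_len(np), drop = FALSE], 2, range))
  colnames(supp) <- c("lo", "hi")
  if (support == "profile")
    supp <- profile_support(data, tail, fix_ends, spec, map_par, max_ll_map,
                            samples, supp)
  quantiles <- t(apply(samples[, seq_len(np), drop = FALSE], 2,
                       stats::quantile, c(0.025, 0.5, 0.975)))
  k_par <- np
  n_obs <- nrow(data)
  max_ll <- max_ll_map
  aicc <- if (n_obs - k_par - 1 > 0)
    -2 * max_ll + 2 * k_par + 2 * k_par * (k_par + 1) / (n_obs - k_par - 1)
    else Inf
  structure(list(map = cline_from_par(map_par, tail, fix_ends),
                 map_par = map_par, samples = samples, support = supp,
                 quantiles = quantiles, loglik = max_ll, aicc = aicc,
                 n_par = k_par, acceptance = acc_rates, tail = tail,
                 fix_ends = fix_ends, seed = seed),
            class = "cline_fit")
}

# Two-log-likelihood support interval per parameter from the profile
# likelihood: the interval of values whose profile (maximum over the other
# parameters, within the prior box) lies within 2 log-likelihood units of
# the maximum. Bounds found by root-finding; inner maximization initialized
# from the posterior draw nearest the probed value.
profile_support <- function(data, tail, fix_ends, spec, map_par, max_ll,
                            samples, fallback) {
  np <- nrow(spec)
  ll_of <- function(par) {
    names(par) <- spec$name
    v <- cline_loglik(par, data, tail, fix_ends)
    if (!is.finite(v)) -1e10 else v
  }
  prof <- function(k, v) {
    if (np == 1) {
      par <- map_par; par[k] <- v
      return(ll_of(par))
    }
    i0 <- which.min(abs(samples[, k] - v))
    init <- samples[i0, seq_len(np)]
    init[k] <- v
    init2 <- map_par; init2[k] <- v
    best <- -Inf
    for (ini in list(init, init2)) {
      opt <- tryCatch(stats::optim(ini[-k], function(o) {
        par <- ini; par[-k] <- o
        -ll_of(par)
      }, method = "L-BFGS-B", lower = spec$lo[-k] + 1e-9,
      upper = spec$hi[-k] - 1e-9),
      error = function(e) NULL)
      if (!is.null(opt)) best <- max(best, -opt$value)
    }
    best
  }
  out <- matrix(NA_real_, np, 2, dimnames = list(spec$name, c("lo", "hi")))
  for (k in seq_len(np)) {
    f <- function(v) max_ll - prof(k, v) - 2
    lo_b <- spec$lo[k]; hi_b <- spec$hi[k]
    out[k, 1] <- if (f(lo_b) <= 0) lo_b else
      tryCatch(stats::uniroot(f, c(lo_b, map_par[k]), tol = diff(range(
        c(lo_b, hi_b))) * 1e-4)$root, error = function(e) fallback[k, 1])
    out[k, 2] <- if (f(hi_b) <= 0) hi_b else
      tryCatch(stats::uniroot(f, c(map_par[k], hi_b), tol = diff(range(
        c(lo_b, hi_b))) * 1e-4)$root, error = function(e) fallback[k, 2])
  }
  out
}

#' Select among tail models by AICc
#'
#' @param fits list of [fit_cline()] results for the same data under
#'   different tail modes.
#' @return the chosen fit (lowest AICc; ties go to the fewest parameters),
#'   with attribute `"table"` summarizing all candidates.
#' @export
select_tail_model <- function(fits) {
  tab <- data.frame(tail = vapply(fits, `[[`, "", "tail"),
                    n_par = vapply(fits, `[[`, 0, "n_par"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aicc = vapply(fits, `[[`, 0, "aicc"),
                    stringsAsFactors = FALSE)
  ord <- order(tab$aicc, tab$n_par)
  chosen <- fits[[ord[1]]]
  attr(chosen, "table") <- tab[ord, ]
  chosen
}

interval_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Concordance and coincidence of clines across marker classes
#'
#' Clines are coincident when their center support intervals overlap and
#' concordant when their width support intervals overlap. Also reports
#' each class's center offset from a designated control class and the
#' direction of its longer introgression tail (the side whose exponential
#' decay is slower; NA for tail-free fits).
#'
#' @param fits named list of [fit_cline()] results (one per marker class).
#' @param control name of the control class (optional).
#' @return list of class `concordance_report`: `pairs` data.frame
#'   (`class_a`, `class_b`, `coincident`, `concordant`), `centers`,
#'   `widths`, `offsets`, `tail_direction`.
#' @export
concordance_report <- function(fits, control = NULL) {
  nm <- names(fits)
  ci <- lapply(fits, function(f) f$support["center", ])
  wi <- lapply(fits, function(f) f$support["width", ])
  pairs <- list()
  if (length(nm) >= 2) {
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (j <= i) next
      pairs[[length(pairs) + 1]] <- data.frame(
        class_a = nm[i], class_b = nm[j],
        coincident = interval_overlap(ci[[i]], ci[[j]]),
        concordant = interval_overlap(wi[[i]], wi[[j]]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  centers <- vapply(fits, function(f) unname(f$map_par["center"]), 0)
  widths <- vapply(fits, function(f) unname(f$map_par["width"]), 0)
  offsets <- if (!is.null(control) && control %in% nm)
    centers - centers[control] else NULL
  tail_dir <- vapply(fits, function(f) {
    m <- f$map
    if (m$tail == "none") return(NA_character_)
    qs <- function(z) (1 - tanh(2 * (z - m$center) / m$width)^2) / m$width
    ql <- cline_frequency(cline_model(m$center, m$width),
                          m$center - m$delta_l)
    qr <- cline_frequency(cline_model(m$center, m$width),
                          m$center + m$delta_r)
    lam_l <- m$tau_l * qs(m$center - m$delta_l) / max(ql, 1e-12)
    lam_r <- m$tau_r * qs(m$center + m$delta_r) / max(1 - qr, 1e-12)
    if (lam_l < lam_r) "west" else if (lam_r < lam_l) "east" else "equal"
  }, "")
  structure(list(pairs = pairs, centers = centers, widths = widths,
                 offsets = offsets, tail_direction = tail_dir),
            class = "concordance_report")
}

#' Per-locality allele frequencies for cline fitting
#'
#' Aggregates a transect-mode simulated dataset into locality allele
#' counts per marker class, using diagnostic sites (parental frequencies
#' 0 versus 1) so the Bullock's allele is unambiguous. Allele totals count
#' two per called diploid genotype and one per hemizygous call.
#'
#' @param dataset a transect-mode `sim_dataset`.
#' @param classes marker classes to aggregate (default: all present in the
#'   truth record).
#' @return data.frame: `marker_class`, `locality`, `distance_km`, `n`,
#'   `count`.
#' @export
locality_frequencies <- function(dataset, classes = NULL) {
  cls <- dataset$truth$site_class
  diag <- abs(dataset$truth$p_a - dataset$truth$p_b) == 1
  if (is.null(classes)) classes <- unique(cls[diag])
  g <- dataset$geno$dosage; hap <- dataset$geno$haploid
  rows <- list()
  for (mc in classes) {
    j <- which(cls == mc & diag)
    if (!length(j)) next
    bsign <- dataset$truth$p_b[j]  # 1 if alt allele is the Bullock's allele
    d <- g[, j, drop = FALSE]
    # orient so counting the Bullock's allele
    d[, bsign == 0] <- 2L - d[, bsign == 0, drop = FALSE]
    h <- hap[, j, drop = FALSE]
    called <- !is.na(d)
    alleles <- ifelse(h, 1, 2) * called
    bull <- ifelse(h, d / 2, d); bull[!called] <- 0
    for (loc in unique(dataset$samples$locality)) {
      i <- which(dataset$samples$locality == loc)
      rows[[length(rows) + 1]] <- data.frame(
        marker_class = mc, locality = loc,
        distance_km = dataset$samples$distance_km[i[1]],
        n = sum(alleles[i, ]), count = sum(bull[i, ]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
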