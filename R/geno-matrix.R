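#' Genotype matrix container
#'
#' Samples-by-sites container for biallelic SNP calls in alt-allele dosage
#' encoding \{0, 1, 2, NA\}. Sex-linked sites in hemizygous individuals
#' (females on Z under ZW sex determination) are encoded as diploid dosages
#' in \{0, 2\} and flagged haploid, so one matrix type serves all chromosomes.
#'
#' @param dosage integer matrix, rows = samples (rownames are sample ids),
#'   columns = sites; entries in \{0, 1, 2, NA\}.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and logical `sex_linked`; positions strictly increasing within
#'   each chromosome.
#' @param sex character vector per sample, "M"/"F"/NA.
#' @param haploid logical matrix, same shape as `dosage`; TRUE where the
#'   call carries a single allele. Defaults to `sex == "F"` at sex-linked
#'   sites.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, sites, sex = NULL, haploid = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(ncol(dosage) == nrow(sites))
  req <- c("chrom", "pos", "ref", "alt")
  stopifnot(all(req %in% names(sites)))
  if (is.null(sites$sex_linked)) sites$sex_linked <- FALSE
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  if (is.null(sex)) sex <- rep(NA_character_, nrow(dosage))
  if (is.null(haploid))
    haploid <- outer(!is.na(sex) & sex == "F", as.logical(sites$sex_linked), `&`)
  stopifnot(identical(dim(haploid), dim(dosage)))
  dimnames(haploid) <- dimnames(dosage)
  # positions strictly increasing within chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("site positions must be strictly increasing within chromosome ", ch)
  }
  bad <- haploid & !is.na(dosage) & dosage == 1L
  if (any(bad))
    stop("haploid calls cannot have dosage 1 (", sum(bad), " offending entries)")
  structure(
    list(dosage = dosage, sites = as.data.frame(sites, stringsAsFactors = FALSE),
         sex = sex, haploid = haploid),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "sites\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or sites
#'
#' @param x a `geno_matrix`.
#' @param i sample index (logical, integer, or sample ids).
#' @param j site index.
#' @param ... ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, rownames(x$dosage))
  geno_matrix(x$dosage[i, j, drop = FALSE], x$sites[j, , drop = FALSE],
              sex = x$sex[i], haploid = x$haploid[i, j, drop = FALSE])
}

#' Sample ids of a genotype matrix
#' @param x a `geno_matrix`.
#' @export
sample_ids <- function(x) rownames(x$dosage)

#' Per-site called allele counts and alternate-allele frequencies
#'
#' Haploid calls contribute one allele, diploid calls two.
#'
#' @param x a `geno_matrix`.
#' @return data.frame with `n_alleles`, `alt_count`, `freq` per site.
#' @export
allele_counts <- function(x) {
  called <- !is.na(x$dosage)
  ploidy <- matrix(2L, nrow(x$dosage), ncol(x$dosage))
  ploidy[x$haploid] <- 1L
  ploidy[!called] <- 0L
  contrib <- x$dosage
  contrib[x$haploid] <- contrib[x$haploid] %/% 2L  # haploid {0,2} -> {0,1}
  contrib[!called] <- 0L
  n_alleles <- colSums(ploidy)
  alt <- colSums(contrib)
  data.frame(n_alleles = n_alleles, alt_count = alt,
             freq = ifelse(n_alleles > 0, alt / n_alleles, NA_real_))
}
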