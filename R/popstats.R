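#' @title Locus- and SNP-level population-genetic statistics
#' @description Nucleotide diversity, segregating sites, Tajima's D, d_xy,
#'   Weir-Cockerham F_st and repeated random haplotype sampling (RRHS) for
#'   unphased genotypes.
#' @name popstats
NULL

.MISSING_CHARS <- c("N", "-", "?", ".")

# character vector of sequences -> haplotype matrix (rows = haplotypes)
.seq_matrix <- function(haps) {
  if (is.matrix(haps)) return(haps)
  if (length(unique(nchar(haps))) > 1L) stop("sequences differ in length")
  do.call(rbind, strsplit(toupper(haps), ""))
}

# per-site allele counts (sites x alleles), missing-aware
.allele_counts <- function(mat, chars = NULL) {
  if (is.null(chars))
    chars <- setdiff(unique(as.vector(mat)), .MISSING_CHARS)
  if (!length(chars))
    return(matrix(0, nrow = ncol(mat), ncol = 0))
  cnt <- vapply(chars, function(ch) colSums(mat == ch),
                numeric(ncol(mat)))
  if (ncol(mat) == 1L) cnt <- matrix(cnt, nrow = 1L, ncol = length(chars))
  colnames(cnt) <- chars
  cnt
}

# per-site mean pairwise difference fraction, missing-aware (vectorised)
.site_diff <- function(mat) {
  if (ncol(mat) == 0) return(numeric(0))
  cnt <- .allele_counts(mat)
  n <- rowSums(cnt)
  same <- rowSums(choose(cnt, 2))
  ifelse(n < 2, NA_real_, 1 - same / choose(n, 2))
}

#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise differences between haplotypes divided by the alignment
#' length.  Equals `n/(n-1) * sum(2 p (1-p)) / L` for biallelic sites.
#' Sites where fewer than two haplotypes have data are skipped.
#'
#' @param haplotypes character vector of equal-length sequences, or a
#'   character matrix (rows = haplotypes).
#' @param length alignment length in bp; defaults to the sequence length.
#'   Required when `haplotypes` holds only variable sites.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(haplotypes, length = NULL) {
  mat <- .seq_matrix(haplotypes)
  if (is.null(length)) length <- ncol(mat)
  if (length == 0) stop("alignment length must be >= 1")
  if (nrow(mat) < 2) stop("need >= 2 haplotypes")
  d <- .site_diff(mat)
  sum(d, na.rm = TRUE) / length
}

#' Number of segregating sites among haplotypes
#' @inheritParams nucleotide_diversity
#' @return Integer count of sites with more than one (non-missing) allele.
#' @export
segregating_sites <- function(haplotypes) {
  mat <- .seq_matrix(haplotypes)
  if (ncol(mat) == 0) return(0L)
  cnt <- .allele_counts(mat)
  if (ncol(cnt) == 0) return(0L)
  n <- rowSums(cnt)
  top <- do.call(pmax, as.data.frame(cnt))
  sum(n > 0 & top < n)
}

.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' The 1989 statistic contrasting mean pairwise differences with the
#' Watterson estimate from the number of segregating sites, with the
#' standard variance constants.  Undefined (NA) when there are no
#' segregating sites.
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D, or `NA` when S = 0.
#' @export
tajimas_d <- function(haplotypes) {
  mat <- .seq_matrix(haplotypes)
  n <- nrow(mat)
  if (n < 4) stop("Tajima's D needs at least 4 haplotypes")
  S <- segregating_sites(mat)
  if (S == 0) return(NA_real_)
  khat <- sum(.site_diff(mat), na.rm = TRUE)
  cst <- .tajima_constants(n)
  (khat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# vectorised Weir-Cockerham (1984) variance components for sites x pops
# p: pops x sites allele-frequency matrix; h: pops x sites observed-het
# proportions; nvec: diploids per pop.  Returns list of per-site a, b, c.
.wc_components <- function(p, h, nvec) {
  r <- length(nvec)
  nbar <- mean(nvec)
  nc <- (r * nbar - sum(nvec^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(p * nvec) / (r * nbar)
  s2 <- colSums(nvec * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(h * nvec) / (r * nbar)
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) *
    (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Weir-Cockerham F_st for one SNP
#'
#' The 1984 theta estimator from diploid dosages, with variance components
#' a (among populations), b (among individuals within populations) and
#' c (within individuals, from observed heterozygosity).  Negative values
#' are retained; a site monomorphic across all populations is undefined.
#'
#' @param genotypes_by_pop list of integer dosage vectors (0/1/2), one per
#'   population.
#' @return List with `fst`, `a`, `b`, `c` (`fst` is `NA` when undefined).
#' @export
snp_fst_wc <- function(genotypes_by_pop) {
  nvec <- vapply(genotypes_by_pop, length, integer(1))
  if (length(nvec) < 2) stop("need at least two populations")
  if (any(vapply(genotypes_by_pop, anyNA, logical(1))))
    stop("missing dosages: drop incomplete sites first")
  p <- matrix(vapply(genotypes_by_pop, function(g) sum(g) / (2 * length(g)),
                     numeric(1)), ncol = 1)
  h <- matrix(vapply(genotypes_by_pop, function(g) mean(g == 1L),
                     numeric(1)), ncol = 1)
  cc <- .wc_components(p, h, nvec)
  den <- cc$a + cc$b + cc$c
  list(fst = if (den == 0) NA_real_ else cc$a / den,
       a = cc$a, b = cc$b, c = cc$c)
}

#' Per-SNP Weir-Cockerham F_st table for a genotype matrix
#'
#' Computes per-site WC components between two groups of individuals
#' (typically the 13-year vs 17-year broods).  Sites with any missing
#' genotype among the used individuals are dropped (listwise deletion).
#'
#' @param geno a `genotype_matrix`.
#' @param pop1,pop2 character vectors of individual ids.
#' @return Data frame with `locus`, `pos`, `a`, `b`, `c`, `fst` (NA where
#'   undefined), one row per retained site, site order preserved.
#' @export
snp_fst_table <- function(geno, pop1, pop2) {
  g1 <- geno$calls[pop1, , drop = FALSE]
  g2 <- geno$calls[pop2, , drop = FALSE]
  ok <- colSums(is.na(g1)) == 0L & colSums(is.na(g2)) == 0L
  g1 <- g1[, ok, drop = FALSE]
  g2 <- g2[, ok, drop = FALSE]
  nvec <- c(length(pop1), length(pop2))
  p <- rbind(colSums(g1) / (2 * nvec[1]), colSums(g2) / (2 * nvec[2]))
  h <- rbind(colMeans(g1 == 1L), colMeans(g2 == 1L))
  cc <- .wc_components(p, h, nvec)
  den <- cc$a + cc$b + cc$c
  fst <- ifelse(den == 0, NA_real_, cc$a / den)
  data.frame(locus = geno$sites$locus[ok], pos = geno$sites$pos[ok],
             a = cc$a, b = cc$b, c = cc$c, fst = fst,
             stringsAsFactors = FALSE)
}

#' Locus-level F_st from per-SNP components
#'
#' The weighted locus estimator is the ratio of summed variance components,
#' `sum(a) / sum(a + b + c)` -- not the mean of per-SNP ratios.  The
#' maximum per-SNP F_st within the locus is returned as the alternative
#' divergence measure.
#'
#' @param snp_stats data frame with columns `a`, `b`, `c`, `fst` for the
#'   SNPs of one locus (as from [snp_fst_table()]).
#' @return List with `fst_weighted`, `fst_max` and `n_snps` (defined SNPs);
#'   both statistics are `NA` when every SNP is undefined.
#' @export
locus_fst <- function(snp_stats) {
  ok <- !is.na(snp_stats$fst)
  if (!any(ok))
    return(list(fst_weighted = NA_real_, fst_max = NA_real_, n_snps = 0L))
  den <- sum(snp_stats$a[ok] + snp_stats$b[ok] + snp_stats$c[ok])
  list(fst_weighted = sum(snp_stats$a[ok]) / den,
       fst_max = max(snp_stats$fst[ok]),
       n_snps = sum(ok))
}

#' Between-population nucleotide divergence d_xy per site
#'
#' Mean over all cross-population haplotype pairs of per-site differences.
#'
#' @param haplotypes_pop1,haplotypes_pop2 character vectors or matrices of
#'   equal-length haplotypes, one per population.
#' @param length alignment length in bp; defaults to the sequence length.
#' @return d_xy per site.
#' @export
dxy <- function(haplotypes_pop1, haplotypes_pop2, length = NULL) {
  m1 <- .seq_matrix(haplotypes_pop1)
  m2 <- .seq_matrix(haplotypes_pop2)
  if (ncol(m1) != ncol(m2)) stop("alignments differ in length")
  if (is.null(length)) length <- ncol(m1)
  if (length == 0) stop("alignment length must be >= 1")
  if (ncol(m1) == 0) return(0)
  chars <- setdiff(unique(c(as.vector(m1), as.vector(m2))), .MISSING_CHARS)
  c1 <- .allele_counts(m1, chars)
  c2 <- .allele_counts(m2, chars)
  n1 <- rowSums(c1)
  n2 <- rowSums(c2)
  ok <- n1 > 0 & n2 > 0
  shared <- rowSums((c1 / pmax(n1, 1)) * (c2 / pmax(n2, 1)))
  sum(1 - shared[ok]) / length
}

# resolve one replicate of unphased sequences into pseudo-haplotypes;
# heterozygous (IUPAC) sites are resolved independently at random
.rrhs_resolve <- function(mat, two_haplotypes = FALSE) {
  amb <- matrix(mat %in% names(.iupac_rev), nrow = nrow(mat))
  out <- mat
  out2 <- if (two_haplotypes) mat else NULL
  idx <- which(amb)
  if (length(idx)) {
    codes <- mat[idx]
    pick <- stats::runif(length(idx)) < 0.5
    first <- vapply(seq_along(idx), function(i)
      .iupac_rev[[codes[i]]][if (pick[i]) 1L else 2L], character(1))
    out[idx] <- first
    if (two_haplotypes) {
      second <- vapply(seq_along(idx), function(i)
        .iupac_rev[[codes[i]]][if (pick[i]) 2L else 1L], character(1))
      out2[idx] <- second
    }
  }
  if (two_haplotypes) rbind(out, out2) else out
}

#' Repeated random haplotype sampling (RRHS) estimate of a statistic
#'
#' For unphased data, each replicate resolves every individual's
#' heterozygous (IUPAC-coded) sites independently at random into one
#' pseudo-haplotype (optionally the complementary pair), computes the
#' statistic on the pseudo-haplotypes, and the estimate is the mean over
#' replicates.
#'
#' @param statistic `"pi"`, `"tajima_d"` or `"dxy"`.
#' @param alignment named character vector of unphased sequences (one per
#'   individual), ambiguity codes at heterozygous sites.
#' @param n_rep number of RRHS replicates (default 100).
#' @param seed optional integer seed.
#' @param pop1,pop2 individual names of the two populations (required for
#'   `"dxy"`; `pop1` defaults to all individuals for the one-population
#'   statistics).
#' @param two_haplotypes resolve each individual into a complementary pair
#'   of pseudo-haplotypes instead of a single one.
#' @return The RRHS mean; per-replicate values in
#'   `attr(, "replicates")`.
#' @export
rrhs_estimate <- function(statistic = c("pi", "tajima_d", "dxy"), alignment,
                          n_rep = 100, seed = NULL, pop1 = NULL, pop2 = NULL,
                          two_haplotypes = FALSE) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  mat <- .seq_matrix(alignment)
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  if (statistic == "dxy") {
    if (is.null(pop1) || is.null(pop2))
      stop("dxy needs pop1 and pop2 individual names")
  } else if (is.null(pop1)) {
    pop1 <- names(alignment)
  }
  vals <- vapply(seq_len(n_rep), function(r) {
    if (statistic == "dxy") {
      r1 <- .rrhs_resolve(mat[pop1, , drop = FALSE], two_haplotypes)
      r2 <- .rrhs_resolve(mat[pop2, , drop = FALSE], two_haplotypes)
      dxy(r1, r2, L)
    } else {
      res <- .rrhs_resolve(mat[pop1, , drop = FALSE], two_haplotypes)
      if (statistic == "pi") nucleotide_diversity(res, L) else tajimas_d(res)
    }
  }, numeric(1))
  structure(mean(vals), replicates = vals)
}

#' Per-locus statistics table for a synthetic or real dataset
#'
#' For each locus: RRHS nucleotide diversity over all individuals, number
#' of segregating sites, RRHS Tajima's D, RRHS d_xy between the 13- and
#' 17-year individuals, and weighted / maximum Weir-Cockerham F_st between
#' the two life cycles.
#'
#' @param loci a `locus_set`.
#' @param geno the matching `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param n_rrhs RRHS replicates per statistic (default 100).
#' @param seed optional integer seed.
#' @return Data frame, one row per locus.
#' @export
locus_stats <- function(loci, geno, popmap, n_rrhs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p13 <- individuals_of(popmap, cycle = 13)
  p17 <- individuals_of(popmap, cycle = 17)
  snp <- snp_fst_table(geno, p13, p17)
  out <- lapply(names(loci$alignments), function(loc) {
    aln <- loci$alignments[[loc]]
    L <- nchar(aln[[1]])
    pi <- rrhs_estimate("pi", aln, n_rep = n_rrhs)
    dj <- rrhs_estimate("dxy", aln, n_rep = n_rrhs, pop1 = p13, pop2 = p17)
    td <- rrhs_estimate("tajima_d", aln, n_rep = n_rrhs)
    sub <- snp[snp$locus == loc, , drop = FALSE]
    lf <- locus_fst(sub)
    in_locus <- geno$sites$locus == loc
    data.frame(locus = loc, length = L, pi = pi, S = sum(in_locus),
               tajima_d = td, dxy = dj,
               fst_weighted = lf$fst_weighted, fst_max = lf$fst_max,
               n_snps_fst = lf$n_snps, n_rrhs = n_rrhs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
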