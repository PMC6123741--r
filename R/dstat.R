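#' @title ABBA-BABA introgression test
#' @description Frequency-based D-statistic for a (((P1,P2),P3),O) quartet
#'   with locus bootstrap, Z score and two-sided normal P value.
#' @name dstat
NULL

#' Define an ABBA-BABA quartet
#'
#' @param P1,P2,P3,O character vectors of individual ids; the assumed
#'   relationship is (((P1, P2), P3), O), with P3 the candidate donor of
#'   introgression into P1 or P2.  Groups must be disjoint and non-empty;
#'   O may contain several individuals (e.g. both broods of another
#'   species group).
#' @return A `quartet_config`.
#' @export
quartet_config <- function(P1, P2, P3, O) {
  groups <- list(P1 = P1, P2 = P2, P3 = P3, O = O)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("all four groups must be non-empty")
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids))
    stop("quartet groups must be disjoint; duplicated: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(groups, class = "quartet_config")
}

# per-site ABBA/BABA terms; returns data.frame(locus, abba, baba)
.dstat_terms <- function(geno, quartet) {
  grp <- lapply(quartet, function(ids) geno$calls[ids, , drop = FALSE])
  ok <- Reduce(`&`, lapply(grp, function(g) colSums(is.na(g)) == 0L))
  if (!any(ok)) return(NULL)
  freq <- lapply(grp, function(g) {
    colSums(g[, ok, drop = FALSE]) / (2 * nrow(g))
  })
  fO <- freq$O
  # outgroup major allele is taken as ancestral; 50/50 ties are dropped
  keep <- fO != 0.5
  anc_is_alt <- fO > 0.5
  p1 <- ifelse(anc_is_alt, 1 - freq$P1, freq$P1)[keep]
  p2 <- ifelse(anc_is_alt, 1 - freq$P2, freq$P2)[keep]
  p3 <- ifelse(anc_is_alt, 1 - freq$P3, freq$P3)[keep]
  data.frame(locus = geno$sites$locus[ok][keep],
             abba = (1 - p1) * p2 * p3,
             baba = p1 * (1 - p2) * p3,
             stringsAsFactors = FALSE)
}

.dstat_from_terms <- function(terms) {
  used <- terms$abba > 0 | terms$baba > 0
  sa <- sum(terms$abba)
  sb <- sum(terms$baba)
  list(D = if (sa + sb == 0) NA_real_ else (sa - sb) / (sa + sb),
       abba = sa, baba = sb, n_sites = sum(used))
}

#' ABBA-BABA D-statistic for a quartet
#'
#' Per usable site, derived-allele frequencies are taken relative to the
#' outgroup major allele (sites where the outgroup is exactly 50/50 are
#' dropped; sites with missing genotypes in any group are dropped), and
#' `ABBA = (1-p1) p2 p3`, `BABA = p1 (1-p2) p3`.  Then
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`.  Sites contributing zero to
#' both terms do not count towards `n_sites`.
#'
#' @param geno a `genotype_matrix`.
#' @param quartet a `quartet_config`.
#' @return A `dstat_result` with `D`, `abba`, `baba`, `n_sites` (no
#'   bootstrap fields).
#' @export
d_statistic <- function(geno, quartet) {
  terms <- .dstat_terms(geno, quartet)
  if (is.null(terms) || nrow(terms) == 0)
    stop("no usable sites for this quartet")
  res <- .dstat_from_terms(terms)
  structure(c(res, list(sd = NA_real_, Z = NA_real_, P = NA_real_,
                        n_boot = 0L)),
            class = "dstat_result")
}

#' D-statistic with locus bootstrap, Z score and P value
#'
#' Loci are resampled with replacement `n_boot` times; the bootstrap
#' standard deviation of D gives `Z = |D| / SD` and the two-sided normal
#' P value `P = 2 (1 - Phi(Z))`.
#'
#' @inheritParams d_statistic
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return A `dstat_result` with `D`, `sd`, `Z`, `P`, `n_sites`, totals.
#' @export
d_bootstrap <- function(geno, quartet, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  terms <- .dstat_terms(geno, quartet)
  if (is.null(terms) || nrow(terms) == 0)
    stop("no usable sites for this quartet")
  loci <- unique(terms$locus)
  if (length(loci) < 2) stop("locus bootstrap needs >= 2 loci")
  by_locus <- rbind(
    abba = tapply(terms$abba, factor(terms$locus, loci), sum),
    baba = tapply(terms$baba, factor(terms$locus, loci), sum))
  res <- .dstat_from_terms(terms)
  nl <- length(loci)
  reps <- vapply(seq_len(n_boot), function(b) {
    pick <- sample.int(nl, nl, replace = TRUE)
    sa <- sum(by_locus["abba", pick])
    sb <- sum(by_locus["baba", pick])
    if (sa + sb == 0) NA_real_ else (sa - sb) / (sa + sb)
  }, numeric(1))
  sd_d <- stats::sd(reps, na.rm = TRUE)
  z <- if (is.na(sd_d) || sd_d == 0) NA_real_ else abs(res$D) / sd_d
  p <- if (is.na(z)) NA_real_ else 2 * (1 - stats::pnorm(z))
  structure(c(res, list(sd = sd_d, Z = z, P = p, n_boot = n_boot)),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat("D = ", format(x$D, digits = 4),
      if (!is.na(x$sd)) paste0(" (SD ", format(x$sd, digits = 4), ")"),
      "  sites = ", x$n_sites, sep = "")
  if (!is.na(x$Z))
    cat("  Z = ", format(x$Z, digits = 4),
        "  P = ", format(x$P, digits = 4), sep = "")
  cat("\n")
  invisible(x)
}
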