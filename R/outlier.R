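#' @title Simulation-calibrated F_st outlier detection
#' @description Neutral null distributions for per-SNP, weighted-locus and
#'   max-of-group F_st; outlier calling against 95% quantile thresholds;
#'   shared-outlier counts across species-pair comparisons and their
#'   permutation test.
#' @name outlier
NULL

#' Construct a null distribution object
#' @param kind one of `"snp_fst"`, `"locus_fst_weighted"`,
#'   `"locus_fst_max"` (or any label tying values to a statistic).
#' @param values simulated statistic values.
#' @param model_id identifier of the generating model.
#' @param quantile threshold quantile (default 0.95).
#' @return A `null_distribution` with `threshold` equal to the empirical
#'   `quantile` of `values`.
#' @export
null_distribution <- function(kind, values, model_id = NA_character_,
                              quantile = 0.95) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no defined values for the null distribution")
  structure(list(kind = kind, values = values,
                 threshold = stats::quantile(values, quantile, names = FALSE),
                 quantile = quantile,
                 model_id = model_id, n_sims = length(values)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution [", x$kind, "]: ", x$n_sims, " values, ",
      x$quantile * 100, "% threshold = ", format(x$threshold, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Neutral per-SNP F_st null distribution
#'
#' Simulates unlinked SNPs under the (fitted) demographic model, pools the
#' broods into the 13-year (XIX, XXIII) and 17-year (II, III) groups,
#' computes per-SNP Weir-Cockerham F_st, and stores the distribution with
#' its 95% quantile as the outlier threshold.
#'
#' @param model a `demographic_model`.
#' @param n number of simulated SNPs (default 10000).
#' @param seed optional integer seed.
#' @param quantile threshold quantile (default 0.95).
#' @return A `null_distribution` of kind `"snp_fst"`.
#' @export
snp_null <- function(model, n = 10000, seed = NULL, quantile = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_unlinked_snps(model, n)
  p13 <- grep("^(XIX|XXIII)_", geno$individuals, value = TRUE)
  p17 <- grep("^(II|III)_", geno$individuals, value = TRUE)
  tab <- snp_fst_table(geno, p13, p17)
  null_distribution("snp_fst", tab$fst,
                    model_id = paste(model$scenario, model$gene_flow,
                                     sep = "/"),
                    quantile = quantile)
}

#' Neutral weighted-locus F_st null distribution
#'
#' Per replicate, one linked locus (single genealogy, default 2500 bp) is
#' simulated and the weighted Weir-Cockerham F_st over its SNPs between
#' the 13- and 17-year groups computed; replicates with no defined SNP are
#' skipped (with a message).
#'
#' @param model a `demographic_model`.
#' @param length_bp locus length (default 2500 bp).
#' @param reps replicates (default 5000).
#' @param seed optional integer seed.
#' @param quantile threshold quantile (default 0.95).
#' @return A `null_distribution` of kind `"locus_fst_weighted"`.
#' @export
locus_null <- function(model, length_bp = 2500, reps = 5000, seed = NULL,
                       quantile = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  pk <- .pack_model(model)
  ti <- .tip_info(model)
  first <- which(ti$copy %% 2L == 1L)
  cyc13 <- ti$deme[first] %in% c("XIX", "XXIII")
  vals <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    sim <- cpp_sim_locus(pk$times, pk$events, pk$sizes, pk$mig, pk$samples,
                         as.integer(length_bp), model$mu)
    if (nrow(sim$geno) == 0) next
    dos <- t(sim$geno[, first, drop = FALSE] +
               sim$geno[, first + 1L, drop = FALSE])
    nvec <- c(sum(cyc13), sum(!cyc13))
    p <- rbind(colSums(dos[cyc13, , drop = FALSE]) / (2 * nvec[1]),
               colSums(dos[!cyc13, , drop = FALSE]) / (2 * nvec[2]))
    h <- rbind(colMeans(dos[cyc13, , drop = FALSE] == 1L),
               colMeans(dos[!cyc13, , drop = FALSE] == 1L))
    cc <- .wc_components(p, h, nvec)
    den <- cc$a + cc$b + cc$c
    ok <- den != 0
    if (any(ok)) vals[r] <- sum(cc$a[ok]) / sum(den[ok])
  }
  n_skip <- sum(is.na(vals))
  if (n_skip) message("locus_null: ", n_skip,
                      " replicate(s) without defined SNPs skipped")
  null_distribution("locus_fst_weighted", vals,
                    model_id = paste(model$scenario, model$gene_flow,
                                     sep = "/"),
                    quantile = quantile)
}

#' Max-of-group F_st null distribution
#'
#' Resamples `group_size` values from a per-SNP null and takes the
#' maximum, repeatedly, to calibrate the maximum-SNP-F_st locus statistic
#' (default group size 5, matching the original analysis choice).
#'
#' @param snp_null_dist a `null_distribution` of per-SNP values.
#' @param group_size values per maximum (default 5).
#' @param reps replicates (default 5000).
#' @param seed optional integer seed.
#' @param quantile threshold quantile (default 0.95).
#' @return A `null_distribution` of kind `"locus_fst_max"`.
#' @export
max_fst_null <- function(snp_null_dist, group_size = 5, reps = 5000,
                         seed = NULL, quantile = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  v <- snp_null_dist$values
  vals <- if (group_size == 1) v else vapply(seq_len(reps), function(r) {
    max(v[sample.int(length(v), group_size, replace = TRUE)])
  }, numeric(1))
  null_distribution("locus_fst_max", vals, model_id = snp_null_dist$model_id,
                    quantile = quantile)
}

#' Call outliers against a null threshold
#'
#' A value is flagged when strictly greater than the null threshold;
#' values exactly at the threshold and undefined (`NA`) values are never
#' flagged.
#'
#' @param values named numeric vector of observed statistics.
#' @param null a `null_distribution` of the same statistic kind.
#' @param kind optional statistic kind of `values`; must match the null's
#'   when given.
#' @return Named logical vector of flags.
#' @export
call_outliers <- function(values, null, kind = NULL) {
  if (!is.null(kind) && !identical(kind, null$kind))
    stop("statistic kind mismatch: values are '", kind, "', null is '",
         null$kind, "'")
  flags <- !is.na(values) & values > null$threshold
  names(flags) <- names(values)
  flags
}

#' Count outliers shared by two comparisons
#'
#' @param flags_A,flags_B logical vectors over a common item universe
#'   (same names/order): outlier flags from two species-pair comparisons.
#' @return A `shared_outlier_result` with `N_shared` (no P value).
#' @export
shared_outliers <- function(flags_A, flags_B) {
  if (length(flags_A) != length(flags_B))
    stop("flag vectors must cover the same item universe")
  if (length(flags_A) == 0) stop("empty item universe")
  structure(list(N_shared = sum(flags_A & flags_B, na.rm = TRUE),
                 n_A = sum(flags_A, na.rm = TRUE),
                 n_B = sum(flags_B, na.rm = TRUE),
                 N = length(flags_A),
                 P = NA_real_, n_perm = 0L,
                 flags_A = flags_A, flags_B = flags_B),
            class = "shared_outlier_result")
}

#' Permutation test for the number of shared outliers
#'
#' Holding the universe size and both outlier counts fixed, each
#' permutation redraws the two outlier sets uniformly at random and counts
#' their overlap.  `P = (1 + #\{perm >= observed\}) / (1 + n_perm)` (the
#' add-one rule avoids zero P at finite permutation counts).  With either
#' count zero, P = 1.
#'
#' @inheritParams shared_outliers
#' @param n_perm permutations (default 1000).
#' @param seed optional integer seed.
#' @return A `shared_outlier_result` with `N_shared`, `P`, `n_perm`.
#' @export
permutation_test_shared <- function(flags_A, flags_B, n_perm = 1000,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- shared_outliers(flags_A, flags_B)
  if (res$n_A == 0 || res$n_B == 0) {
    res$P <- 1
    res$n_perm <- n_perm
    return(res)
  }
  N <- res$N
  perm <- vapply(seq_len(n_perm), function(p) {
    a <- sample.int(N, res$n_A)
    b <- sample.int(N, res$n_B)
    length(intersect(a, b))
  }, integer(1))
  res$P <- (1 + sum(perm >= res$N_shared)) / (1 + n_perm)
  res$n_perm <- n_perm
  res
}

#' @export
print.shared_outlier_result <- function(x, ...) {
  cat("shared outliers: N_shared = ", x$N_shared, " (", x$n_A, " vs ",
      x$n_B, " outliers over ", x$N, " items)", sep = "")
  if (!is.na(x$P)) cat("  P = ", format(x$P, digits = 3),
                       " (", x$n_perm, " permutations)", sep = "")
  cat("\n")
  invisible(x)
}
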