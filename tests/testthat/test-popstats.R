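test_that("nucleotide diversity matches pairwise enumeration", {
  # 4 haplotypes, L = 10: site 1 A,A,T,T; site 2 C,C,C,G; rest invariant
  haps <- c("AGGGGGGGGC", "AGGGGGGGGC", "TGGGGGGGGC", "TGGGGGGGGG")
  haps <- c(paste0("A", "CCCCCCCC", "C"),
            paste0("A", "CCCCCCCC", "C"),
            paste0("T", "CCCCCCCC", "C"),
            paste0("T", "CCCCCCCC", "G"))
  expect_equal(nucleotide_diversity(haps), (7 / 6) / 10, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(rep("ACGT", 4)), 0)
  expect_equal(segregating_sites(haps), 2L)
})

test_that("pairwise and frequency definitions of pi agree", {
  set.seed(51)
  for (r in 1:5) {
    n <- 6; L <- 30
    mat <- matrix(sample(c("A", "T"), n * L, replace = TRUE,
                         prob = c(0.8, 0.2)), nrow = n)
    # frequency form: n/(n-1) * sum over sites of 2 p (1-p) / L
    p <- colMeans(mat == "T")
    freq_form <- n / (n - 1) * sum(2 * p * (1 - p)) / L
    expect_equal(nucleotide_diversity(mat), freq_form, tolerance = 1e-12)
  }
})

test_that("Tajima's D reproduces the worked example and the S = 0 rule", {
  haps <- c(paste0("A", "CCCCCCCC", "C"),
            paste0("A", "CCCCCCCC", "C"),
            paste0("T", "CCCCCCCC", "C"),
            paste0("T", "CCCCCCCC", "G"))
  expect_equal(tajimas_d(haps), 0.5916, tolerance = 1e-4)
  expect_true(is.na(tajimas_d(rep("ACGT", 4))))
  expect_error(tajimas_d(rep("ACGT", 3)), "at least 4")
})

test_that("neutral equilibrium simulations give slightly negative mean D", {
  set.seed(52)
  N <- 10000; mu <- 1.53e-8; L <- 5000; n <- 8
  m <- coal_model(c(A = n), c(A = N), mu = mu)
  pk <- cicadapop:::.pack_model(m)
  d <- vapply(seq_len(2000), function(r) {
    g <- cicadapop:::cpp_sim_locus(pk$times, pk$events, pk$sizes, pk$mig,
                                   pk$samples, L, mu)$geno
    if (nrow(g) == 0) return(NA_real_)
    tajimas_d(t(ifelse(g == 1L, "T", "A")))
  }, numeric(1))
  md <- mean(d, na.rm = TRUE)
  expect_gt(md, -0.15)
  expect_lt(md, 0.05)
})

test_that("Weir-Cockerham F_st matches hand-derived variance components", {
  # fixed difference
  expect_equal(snp_fst_wc(list(c(0L, 0L), c(2L, 2L)))$fst, 1)
  # worked example: pop1 (0,1), pop2 (1,2) -> a = 0.0625, b = 0, c = 0.25
  res <- snp_fst_wc(list(c(0L, 1L), c(1L, 2L)))
  expect_equal(res$a, 0.0625, tolerance = 1e-12)
  expect_equal(res$b, 0, tolerance = 1e-12)
  expect_equal(res$c, 0.25, tolerance = 1e-12)
  expect_equal(res$fst, 0.2, tolerance = 1e-12)
  # equal frequencies and sizes: estimator is non-positive
  expect_lte(snp_fst_wc(list(c(0L, 2L), c(1L, 1L)))$fst, 0)
  # monomorphic site undefined
  expect_true(is.na(snp_fst_wc(list(c(0L, 0L), c(0L, 0L)))$fst))
  # label swap leaves F_st unchanged
  g1 <- c(0L, 1L); g2 <- c(2L, 1L)
  expect_equal(snp_fst_wc(list(g1, g2))$fst, snp_fst_wc(list(g2, g1))$fst)
})

test_that("snp_fst_table agrees with the single-SNP path and drops missing", {
  set.seed(53)
  calls <- matrix(sample(0:2, 8 * 20, replace = TRUE), nrow = 8)
  calls[5, 3] <- NA
  geno <- toy_geno(calls)
  pm <- toy_popmap()
  p13 <- individuals_of(pm, cycle = 13)
  p17 <- individuals_of(pm, cycle = 17)
  tab <- snp_fst_table(geno, p13, p17)
  expect_equal(nrow(tab), 19L)
  for (i in c(1, 7, 19)) {
    site <- which(geno$sites$locus == tab$locus[i])
    single <- snp_fst_wc(list(calls[match(p13, geno$individuals), site],
                              calls[match(p17, geno$individuals), site]))
    expect_equal(tab$fst[i], single$fst, tolerance = 1e-12)
  }
})

test_that("weighted locus F_st is the ratio of sums, not the mean of ratios", {
  snp_stats <- data.frame(a = c(1, 0), b = c(0.5, 2), c = c(0.5, 2),
                          fst = c(0.5, 0))
  lf <- locus_fst(snp_stats)
  expect_equal(lf$fst_weighted, 1 / 6, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(lf$fst_weighted, mean(c(0.5, 0)))))
  expect_equal(lf$fst_max, 0.5)
  # single SNP: weighted = max = the SNP value
  one <- data.frame(a = 0.0625, b = 0, c = 0.25, fst = 0.2)
  expect_equal(locus_fst(one)$fst_weighted, 0.2, tolerance = 1e-12)
  expect_equal(locus_fst(one)$fst_max, 0.2, tolerance = 1e-12)
  # all-negative per-SNP values: max is the least negative
  neg <- data.frame(a = c(-0.2, -0.1), b = c(1, 1), c = c(1, 1),
                    fst = c(-0.2 / 1.8, -0.1 / 1.9))
  expect_equal(locus_fst(neg)$fst_max, -0.1 / 1.9)
  # all undefined -> undefined
  und <- data.frame(a = 0, b = 0, c = 0, fst = NA_real_)
  expect_true(is.na(locus_fst(und)$fst_weighted))
})

test_that("d_xy matches cross-pair enumeration", {
  expect_equal(dxy(c("AA", "AT"), c("TA", "TT")), 0.75)
  # identical populations: equals the cross-pair mean, not within-pop pi
  pop <- c("AC", "GC")
  expect_equal(dxy(pop, pop), 0.25)   # pairs: 0,1,1,0 -> 0.5/2
  # disjoint fixed alleles at every site
  expect_equal(dxy(c("AAAA"), c("TTTT")), 1)
})

test_that("RRHS reduces to the plain statistic without heterozygotes", {
  aln <- c(a = "ACGTAC", b = "ACGTAC", c = "ATGTAC", d = "ATGTAT")
  est <- rrhs_estimate("pi", aln, n_rep = 10, seed = 1)
  expect_equal(as.numeric(est), nucleotide_diversity(unname(aln)))
  expect_equal(length(unique(attr(est, "replicates"))), 1L)
})

test_that("RRHS mean pi matches the exhaustive expectation for an all-het site", {
  aln <- c(a = "R", b = "R", c = "R", d = "R")
  est <- rrhs_estimate("pi", aln, n_rep = 2000, seed = 2)
  # E[ n/(n-1) 2 p(1-p) ] over Binomial(4, 1/2) resolutions = 0.5
  expect_lt(abs(as.numeric(est) - 0.5), 0.02)
  est2 <- rrhs_estimate("pi", aln, n_rep = 200, seed = 9)
  est3 <- rrhs_estimate("pi", aln, n_rep = 200, seed = 9)
  expect_identical(est2, est3)
})

test_that("RRHS d_xy uses the two populations and both resolution variants run", {
  aln <- c(a = "AR", b = "AR", c = "TR", d = "TR")
  v1 <- rrhs_estimate("dxy", aln, n_rep = 50, seed = 3,
                      pop1 = c("a", "b"), pop2 = c("c", "d"))
  expect_gte(as.numeric(v1), 0.5)   # site 1 fixed different
  v2 <- rrhs_estimate("dxy", aln, n_rep = 50, seed = 3,
                      pop1 = c("a", "b"), pop2 = c("c", "d"),
                      two_haplotypes = TRUE)
  expect_true(is.finite(v2))
})

test_that("d_xy tracks diversity while F_st does not, on simulated loci", {
  ds <- simulate_dataset(small_model(), n_loci = 60, mean_locus_len = 1200,
                         seed = 55)
  tab <- locus_stats(ds$loci, ds$geno, ds$popmap, n_rrhs = 8, seed = 56)
  ok <- stats::complete.cases(tab[, c("pi", "dxy", "fst_weighted")])
  expect_gt(sum(ok), 30)
  c_dxy <- cor(tab$pi[ok], tab$dxy[ok])
  c_fst <- cor(tab$pi[ok], tab$fst_weighted[ok])
  expect_gt(c_dxy, 0.7)
  expect_gt(c_dxy, abs(c_fst) + 0.2)
})
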