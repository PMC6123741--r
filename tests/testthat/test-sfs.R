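# independent brute-force oracle: per-deme alternate counts, folded on the
# pooled minor allele with a lexicographic tie rule, written as plain loops
brute_sfs <- function(calls, deme_of, demes, maf_min = 0) {
  nvec <- 2L * vapply(demes, function(d) sum(deme_of == d), integer(1))
  counts <- array(0L, dim = nvec + 1L)
  for (s in seq_len(ncol(calls))) {
    if (any(is.na(calls[, s]))) next
    tup <- integer(length(demes))
    for (k in seq_along(demes))
      tup[k] <- sum(calls[deme_of == demes[k], s])
    tot <- sum(tup); ntot <- sum(nvec)
    if (tot == 0 || tot == ntot) next
    if (min(tot, ntot - tot) / ntot < maf_min) next
    flipped <- nvec - tup
    use <- if (tot > ntot / 2) flipped
           else if (tot < ntot / 2) tup
           else {  # tie: lexicographically smaller tuple
             pick <- tup
             for (k in seq_along(tup)) {
               if (tup[k] < flipped[k]) { pick <- tup; break }
               if (tup[k] > flipped[k]) { pick <- flipped; break }
             }
             pick
           }
    idx <- matrix(use + 1L, nrow = 1)
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

test_that("a hand-built 5-SNP matrix matches exhaustive counting", {
  calls <- cbind(c(0L,1L,0L,0L, 2L,2L,2L,2L),   # pooled count 9 -> folded
                 c(1L,1L,0L,0L, 0L,0L,0L,0L),   # pooled 2
                 c(2L,2L,2L,2L, 2L,2L,0L,0L),   # pooled 12 -> folded
                 c(1L,1L,1L,1L, 1L,1L,1L,1L),   # pooled 8 -> 50/50 tie
                 c(0L,0L,0L,0L, 0L,0L,0L,1L))   # singleton
  geno <- toy_geno(calls)
  pm <- toy_popmap()
  sfs <- joint_folded_sfs(geno, pm, maf_min = 0)
  deme_of <- sub("_[12]$", "", geno$individuals)
  oracle <- brute_sfs(calls, deme_of, c("II", "III", "XIX", "XXIII"))
  expect_equal(unname(as.integer(sfs$counts)), as.integer(oracle))
  expect_equal(sfs_total(sfs), 5L)
  expect_equal(unname(sfs$n), c(4L, 4L, 4L, 4L))
  expect_equal(unname(dim(sfs$counts)), c(5L, 5L, 5L, 5L))
})

test_that("random matrices match the brute-force oracle with MAF filtering", {
  set.seed(21)
  pm <- toy_popmap()
  demes <- c("II", "III", "XIX", "XXIII")
  for (rep in 1:5) {
    calls <- matrix(sample(0:2, 8 * 60, replace = TRUE,
                           prob = c(0.7, 0.2, 0.1)), nrow = 8)
    geno <- toy_geno(calls)
    deme_of <- sub("_[12]$", "", geno$individuals)
    for (maf in c(0, 0.05, 0.2)) {
      sfs <- joint_folded_sfs(geno, pm, maf_min = maf)
      oracle <- brute_sfs(calls, deme_of, demes, maf_min = maf)
      expect_equal(unname(as.integer(sfs$counts)), as.integer(oracle))
    }
  }
})

test_that("monomorphic data leave the SFS empty", {
  calls <- matrix(0L, nrow = 8, ncol = 10)
  calls[, 6:10] <- 2L
  sfs <- joint_folded_sfs(toy_geno(calls), toy_popmap())
  expect_equal(sfs_total(sfs), 0L)
})

test_that("folding is idempotent and individual order within demes is irrelevant", {
  set.seed(22)
  nvec <- c(4L, 4L, 4L, 4L)
  cnt <- matrix(sample(0:4, 200 * 4, replace = TRUE), ncol = 4)
  once <- cicadapop:::.fold_counts(cnt, nvec)
  twice <- cicadapop:::.fold_counts(once, nvec)
  expect_identical(once, twice)

  calls <- matrix(sample(0:2, 8 * 40, replace = TRUE), nrow = 8)
  geno <- toy_geno(calls)
  perm <- c(2, 1, 3, 4, 6, 5, 8, 7)   # swap individuals within each brood
  geno_p <- genotype_matrix(calls[perm, ], geno$sites,
                            geno$individuals[perm])
  s1 <- joint_folded_sfs(geno, toy_popmap(), maf_min = 0)
  s2 <- joint_folded_sfs(geno_p, toy_popmap(), maf_min = 0)
  expect_equal(s1$counts, s2$counts)
})

test_that("raising the MAF threshold never increases the SNP total", {
  set.seed(23)
  calls <- matrix(sample(0:2, 8 * 100, replace = TRUE,
                         prob = c(0.8, 0.15, 0.05)), nrow = 8)
  geno <- toy_geno(calls)
  totals <- vapply(c(0, 0.05, 0.1, 0.2, 0.3), function(maf) {
    sfs_total(joint_folded_sfs(geno, toy_popmap(), maf_min = maf))
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("sites with missing genotypes and non-synonymous SNPs are excluded", {
  calls <- matrix(1L, nrow = 8, ncol = 3)
  calls[3, 2] <- NA
  geno <- toy_geno(calls, synonymous = c(TRUE, TRUE, FALSE))
  sfs <- joint_folded_sfs(geno, toy_popmap(), maf_min = 0)
  expect_equal(sfs_total(sfs), 1L)
  sfs_all <- joint_folded_sfs(geno, toy_popmap(), maf_min = 0,
                              synonymous_only = FALSE)
  expect_equal(sfs_total(sfs_all), 2L)
})

test_that("Poisson bootstrap has the right moments and is reproducible", {
  calls <- matrix(0L, nrow = 8, ncol = 0)
  empty <- joint_folded_sfs(toy_geno(calls), toy_popmap())
  expect_equal(sfs_total(poisson_bootstrap_sfs(empty, seed = 1)), 0L)

  big <- empty
  big$counts[2, 1, 1, 1] <- 100L
  draws <- vapply(1:1000, function(i) {
    sum(poisson_bootstrap_sfs(big, seed = i)$counts)
  }, numeric(1))
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / 1000))
  expect_lt(abs(var(draws) - 100), 25)
  expect_identical(poisson_bootstrap_sfs(big, seed = 7)$counts,
                   poisson_bootstrap_sfs(big, seed = 7)$counts)
  expect_true(poisson_bootstrap_sfs(big, seed = 7)$provenance$bootstrap)
})

test_that("SFS files round-trip through the TSV dialect", {
  g <- simulate_unlinked_snps(small_model(), 300, seed = 31)
  pm <- toy_popmap()
  sfs <- joint_folded_sfs(g, pm, maf_min = 0.05)
  path <- file.path(withr::local_tempdir(), "sfs.tsv")
  write_sfs(sfs, path)
  back <- read_sfs(path)
  expect_equal(unname(back$counts), unname(sfs$counts))
  expect_equal(back$n, sfs$n)
  expect_equal(back$provenance$maf_min, sfs$provenance$maf_min)
})
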