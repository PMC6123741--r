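test_that("the nine model families have 9, 15 and 19 free parameters", {
  for (sc in c("S1", "S2", "S3")) {
    expect_equal(n_free_params(example_model("none", sc)), 9L)
    expect_equal(n_free_params(example_model("recent", sc)), 15L)
    expect_equal(n_free_params(example_model("past_and_recent", sc)), 19L)
  }
  # no-gene-flow models carry a zero migration matrix in every epoch
  m <- example_model("none")
  expect_true(all(vapply(m$mig, function(M) all(M == 0), logical(1))))
})

test_that("model construction rejects bad parameter sets and times", {
  p <- example_model("none")$params
  expect_error(build_model("S1", "recent", p), "missing")
  expect_error(build_model("S1", "none", c(p, bogus = 1)), "unexpected")
  p_bad <- p
  p_bad[["t3"]] <- p_bad[["t1"]] / 2      # root older than a cherry merge
  expect_error(build_model("S1", "none", p_bad), "t3")
  expect_error(build_model("S2", "none", p), "t1 < t2")   # t1 > t2 here
})

test_that("single-deme TMRCA matches the coalescent expectation E[T2] = 2N", {
  set.seed(101)
  m <- coal_model(c(A = 2), c(A = 1000))
  tm <- replicate(5000, attr(simulate_genealogy(m), "tmrca"))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("no inter-deme coalescence predates the divergence time", {
  set.seed(102)
  m <- coal_model(c(A = 1, B = 1, anc = 0), c(A = 500, B = 500, anc = 500),
                  events = data.frame(time = 4000, a = "A", b = "B",
                                      dest = "anc"))
  tm <- replicate(300, attr(simulate_genealogy(m), "tmrca"))
  expect_true(all(tm >= 4000))
})

test_that("simulation is deterministic under a fixed seed", {
  m <- small_model()
  g1 <- simulate_genealogy(m, seed = 5)
  g2 <- simulate_genealogy(m, seed = 5)
  expect_identical(g1, g2)
  s1 <- simulate_unlinked_snps(m, 200, seed = 9)
  s2 <- simulate_unlinked_snps(m, 200, seed = 9)
  expect_identical(s1$calls, s2$calls)
  l1 <- simulate_linked_locus(m, 2000, seed = 13)
  l2 <- simulate_linked_locus(m, 2000, seed = 13)
  expect_identical(l1$alignment, l2$alignment)
})

test_that("unlinked SNPs are biallelic and polymorphic in the pooled sample", {
  g <- simulate_unlinked_snps(small_model(), 500, seed = 3)
  expect_equal(nrow(g$sites), 500L)
  tot <- colSums(g$calls)
  expect_true(all(tot > 0 & tot < 2 * length(g$individuals)))
})

test_that("single-deme folded SFS follows 1/i + 1/(n-i)", {
  set.seed(103)
  m8 <- coal_model(c(A = 8), c(A = 1000))
  cnt <- cicadapop:::.sim_snp_counts(m8, 60000)
  f <- pmin(cnt[, 1], 8 - cnt[, 1])
  obs <- as.numeric(table(factor(f, 1:4)))
  obs <- obs / sum(obs)
  expected <- vapply(1:4, function(i) (1 / i + 1 / (8 - i)) / (1 + (i == 4)),
                     numeric(1))
  expected <- expected / sum(expected)
  expect_lt(0.5 * sum(abs(obs - expected)), 0.02)
})

test_that("linked loci match the Watterson expectation and pi = 4 N mu", {
  set.seed(104)
  N <- 10000; mu <- 1.53e-8; L <- 2000; n <- 8
  m <- coal_model(c(A = n), c(A = N), mu = mu)
  pk <- cicadapop:::.pack_model(m)
  reps <- 2500
  S <- numeric(reps); pi <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- cicadapop:::cpp_sim_locus(pk$times, pk$events, pk$sizes, pk$mig,
                                   pk$samples, L, mu)$geno
    S[r] <- nrow(g)
    pi[r] <- if (nrow(g) == 0) 0 else {
      d <- rowMeans(g)
      sum(2 * d * (1 - d)) * n / (n - 1) / L
    }
  }
  theta_L <- 4 * N * mu * L
  exp_S <- theta_L * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - exp_S), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(pi) - 4 * N * mu), 3 * sd(pi) / sqrt(reps))
})

test_that("mu = 0 yields no segregating sites; saturation errors", {
  m0 <- coal_model(c(A = 4), c(A = 1000), mu = 0)
  l0 <- simulate_linked_locus(m0, 500, seed = 1)
  expect_equal(length(l0$positions), 0L)
  expect_equal(ncol(l0$geno$calls), 0L)
  msat <- coal_model(c(A = 4), c(A = 1000), mu = 10)
  expect_error(simulate_linked_locus(msat, 2, seed = 1), "saturated")
})

test_that("demes with equal parameters are exchangeable", {
  set.seed(105)
  mk <- coal_model(c(A = 6, B = 6, anc = 0),
                   c(A = 2000, B = 2000, anc = 2000),
                   events = data.frame(time = 3000, a = "A", b = "B",
                                       dest = "anc"),
                   migration = {
                     M <- matrix(0, 3, 3)
                     M[1, 2] <- M[2, 1] <- 1e-4
                     M
                   })
  cnt <- cicadapop:::.sim_snp_counts(mk, 30000)
  # fold each deme's marginal spectrum and compare the two distributions
  marg <- function(j) {
    f <- pmin(cnt[, j], 6 - cnt[, j])
    tab <- table(factor(f, 0:3))
    as.numeric(tab) / sum(tab)
  }
  expect_lt(0.5 * sum(abs(marg(1) - marg(2))), 0.02)
})

test_that("inter-deme F_st increases with divergence time", {
  fst_at <- function(T, seed) {
    set.seed(seed)
    m <- coal_model(c(A = 8, B = 8, anc = 0),
                    c(A = 5000, B = 5000, anc = 5000),
                    events = data.frame(time = T, a = "A", b = "B",
                                        dest = "anc"))
    cnt <- cicadapop:::.sim_snp_counts(m, 4000)
    # haplotype-level F_st proxy: among-pop variance of allele frequency
    p1 <- cnt[, 1] / 8; p2 <- cnt[, 2] / 8
    pbar <- (p1 + p2) / 2
    mean((p1 - pbar)^2 + (p2 - pbar)^2) / mean(pbar * (1 - pbar))
  }
  shallow <- fst_at(500, 106)
  deep <- fst_at(20000, 107)
  expect_gt(deep, shallow)
})

test_that("simulate_dataset builds a coherent synthetic study", {
  ds <- simulate_dataset(small_model(), n_loci = 25, mean_locus_len = 900,
                         seed = 42)
  expect_s3_class(ds$geno, "genotype_matrix")
  expect_s3_class(ds$popmap, "population_map")
  expect_equal(length(ds$geno$individuals), 8L)
  expect_equal(length(ds$loci), 25L)
  expect_true(all(locus_lengths(ds$loci) >= 300))
  # genotype sites all reference existing loci
  expect_true(all(ds$geno$sites$locus %in% names(ds$loci$alignments)))
  # heterozygous dosage matches an ambiguity code in the alignment
  het <- which(ds$geno$calls == 1L, arr.ind = TRUE)[1, ]
  site <- ds$geno$sites[het["col"], ]
  aln <- ds$loci$alignments[[site$locus]]
  chr <- substr(aln[[ds$geno$individuals[het["row"]]]], site$pos, site$pos)
  expect_true(chr %in% c("M", "R", "W", "S", "Y", "K"))
})

test_that("the synonymous flag frequency matches its default rate", {
  ds <- simulate_dataset(example_model(t3 = 40000, gene_flow = "none"),
                         n_loci = 120, mean_locus_len = 1200, seed = 77)
  syn <- ds$geno$sites$synonymous
  expect_gt(length(syn), 300)
  expect_lt(abs(mean(syn) - 0.68), 3 * sqrt(0.68 * 0.32 / length(syn)))
})

test_that("deep-divergence datasets show higher inter-cycle F_st than panmictic-like ones", {
  deep <- simulate_dataset(example_model(gene_flow = "none", t3 = 60000,
                                         t1 = 500, t2 = 490),
                           n_loci = 40, mean_locus_len = 800, seed = 8)
  near <- simulate_dataset(example_model(gene_flow = "recent", t3 = 700,
                                         t1 = 500, t2 = 490),
                           n_loci = 40, mean_locus_len = 800, seed = 9)
  fst_of <- function(ds) {
    tab <- snp_fst_table(ds$geno,
                         individuals_of(ds$popmap, cycle = 13),
                         individuals_of(ds$popmap, cycle = 17))
    mean(tab$fst, na.rm = TRUE)
  }
  expect_gt(fst_of(deep), fst_of(near))
})

test_that("model YAML files round-trip", {
  m <- example_model("past_and_recent")
  path <- file.path(withr::local_tempdir(), "model.yaml")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$params, m$params)
  expect_equal(back$scenario, m$scenario)
  expect_equal(back$mig, m$mig)
})
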