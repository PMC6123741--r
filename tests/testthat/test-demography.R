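fake_sfs <- function(counts) {
  # minimal joint_sfs stand-in for likelihood arithmetic tests
  structure(list(counts = array(counts), demes = "x",
                 n = length(counts) - 1L,
                 provenance = list(maf_min = 0)),
            class = "joint_sfs")
}

test_that("composite log-likelihood matches hand evaluation", {
  obs <- fake_sfs(c(3, 1))
  expected <- list(probs = c(0.75, 0.25))
  expect_equal(composite_loglik(obs, expected),
               3 * log(0.75) + log(0.25), tolerance = 1e-12)
  expect_equal(round(composite_loglik(obs, expected), 4), -2.2493)
  # empty SFS
  expect_equal(composite_loglik(fake_sfs(c(0, 0)), expected), 0)
})

test_that("the likelihood is maximal at proportional probabilities (Gibbs)", {
  obs <- fake_sfs(c(60, 30, 10))
  p0 <- c(0.6, 0.3, 0.1)
  l0 <- composite_loglik(obs, list(probs = p0))
  set.seed(81)
  for (i in 1:20) {
    p <- p0 + runif(3, -0.05, 0.05)
    p <- abs(p) / sum(abs(p))
    expect_lte(composite_loglik(obs, list(probs = p)), l0 + 1e-12)
  }
})

test_that("expected SFS is a proper distribution over canonical cells", {
  ex <- expected_sfs(small_model(), 4000, seed = 1)
  expect_equal(sum(ex$probs), 1, tolerance = 1e-12)
  expect_true(all(ex$probs[ex$cells] > 0))        # epsilon floor applied
  expect_true(all(ex$probs[-ex$cells] == 0))
  # deterministic under the common-random-number seed
  ex2 <- expected_sfs(small_model(), 4000, seed = 1)
  expect_identical(ex$probs, ex2$probs)
})

test_that("expected SFS is symmetric for exchangeable demes", {
  m <- coal_model(c(A = 4, B = 4, anc = 0),
                  c(A = 3000, B = 3000, anc = 3000),
                  events = data.frame(time = 5000, a = "A", b = "B",
                                      dest = "anc"))
  set.seed(82)
  cnt <- cicadapop:::.sim_snp_counts(m, 30000)
  nvec <- c(4L, 4L)
  f <- cicadapop:::.fold_counts(cnt, nvec)
  fs <- cicadapop:::.fold_counts(cnt[, 2:1], nvec)
  tab <- tabulate(cicadapop:::.cell_index(f, nvec), 25)
  swapped <- tabulate(cicadapop:::.cell_index(fs, nvec), 25)
  expect_lt(0.5 * sum(abs(tab / sum(tab) - swapped / sum(swapped))), 0.02)
})

test_that("Akaike weights are normalised, shift-invariant and split ties", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102, 110))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, akaike_weights(c(0, 2, 10)), tolerance = 1e-12)
  cmp <- compare_models(data.frame(AIC = c(12, 10, 14)))
  expect_equal(min(cmp$dAIC), 0)
  expect_equal(cmp$dAIC, c(2, 0, 4))
})

test_that("zero-free-parameter fits return the likelihood at fixed values", {
  m <- small_model()
  g <- simulate_unlinked_snps(m, 2000, seed = 83)
  sfs <- joint_folded_sfs(g, toy_popmap())
  f <- fit_model(sfs, "S1", "recent",
                 start = setNames(numeric(0), character(0)),
                 fixed = m$params,
                 settings = fit_settings(n_sim = 1500), seed = 4)
  expect_equal(f$k, 0L)
  expect_equal(f$AIC, -2 * f$lnL, tolerance = 1e-12)
  expect_true(f$converged)
  # identical settings and seed reproduce the fit exactly
  f2 <- fit_model(sfs, "S1", "recent",
                  start = setNames(numeric(0), character(0)),
                  fixed = m$params,
                  settings = fit_settings(n_sim = 1500), seed = 4)
  expect_identical(f$lnL, f2$lnL)
})

test_that("one-parameter fits are deterministic and satisfy the AIC identity", {
  m <- small_model()
  g <- simulate_unlinked_snps(m, 3000, seed = 84)
  sfs <- joint_folded_sfs(g, toy_popmap())
  fixed <- m$params[setdiff(names(m$params), "t3")]
  f <- fit_model(sfs, "S1", "recent", start = c(t3 = 9000),
                 lower = c(t3 = 5200), upper = c(t3 = 40000),
                 fixed = fixed, settings = fit_settings(n_sim = 1500),
                 seed = 6)
  expect_equal(f$k, 1L)
  expect_equal(f$AIC, 2 - 2 * f$lnL, tolerance = 1e-12)
  expect_true(f$estimates[["t3"]] >= 5200 && f$estimates[["t3"]] <= 40000)
  f2 <- fit_model(sfs, "S1", "recent", start = c(t3 = 9000),
                  lower = c(t3 = 5200), upper = c(t3 = 40000),
                  fixed = fixed, settings = fit_settings(n_sim = 1500),
                  seed = 6)
  expect_identical(f$estimates, f2$estimates)
})

test_that("bootstrap model selection returns proportions over candidates", {
  m <- small_model()
  g <- simulate_unlinked_snps(m, 2500, seed = 85)
  sfs <- joint_folded_sfs(g, toy_popmap())
  # single candidate: proportion 1
  spec1 <- list(list(scenario = "S1", gene_flow = "recent",
                     start = setNames(numeric(0), character(0)),
                     fixed = m$params))
  p1 <- bootstrap_model_selection(sfs, spec1, n_boot = 3, seed = 2,
                                  settings = fit_settings(n_sim = 800))
  expect_equal(unname(p1), 1)
  # two candidates: proportions sum to 1
  params_s3 <- m$params
  params_s3[["t1"]] <- 4900; params_s3[["t2"]] <- 5000
  spec2 <- c(spec1, list(list(scenario = "S3", gene_flow = "recent",
                              start = setNames(numeric(0), character(0)),
                              fixed = params_s3)))
  p2 <- bootstrap_model_selection(sfs, spec2, n_boot = 4, seed = 3,
                                  settings = fit_settings(n_sim = 800))
  expect_equal(sum(p2), 1)
  expect_length(p2, 2)
})

test_that("N_e from pi follows pi = 4 N_e mu", {
  expect_equal(ne_from_pi(4e-8, 1e-8), 1)
  expect_equal(ne_from_pi(0, 1e-8), 0)
  expect_equal(ne_from_pi(0.0019, 1.53e-8), 31045.75, tolerance = 1e-4)
  expect_error(ne_from_pi(0.1, 0), "mu")
})

test_that("gene-flow estimates are N times m with sane bounds", {
  m <- example_model(N_II = 1e5, m_II_III = 1e-5)
  gf <- gene_flow_estimates(m)
  expect_equal(nrow(gf), 6L)
  expect_equal(gf$NeM[gf$pair == "II-III"], 1.0)
  expect_true(all(gf$NeM >= 0))
  m0 <- example_model("none")
  expect_equal(nrow(gene_flow_estimates(m0)), 0L)
})
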