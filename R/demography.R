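#' @title Composite-likelihood demographic inference
#' @description Fitting the nine brood-divergence models to a folded joint
#'   SFS by simulated composite likelihood, AIC-based model comparison,
#'   Poisson-bootstrap model-selection proportions and derived quantities.
#' @name demography
NULL

# enumerate the canonical (folded, polymorphic, MAF-passing) cells of a
# joint SFS with gene-copy counts nvec; returns linear cell indices
.canonical_cells <- function(nvec, maf_min) {
  grids <- lapply(nvec, function(n) 0:n)
  tup <- as.matrix(expand.grid(grids))
  ntot <- sum(nvec)
  pooled <- rowSums(tup)
  keep <- pooled > 0 & pooled < ntot &
    pmin(pooled, ntot - pooled) / ntot >= maf_min
  tup <- tup[keep, , drop = FALSE]
  folded <- .fold_counts(tup, nvec)
  canonical <- rowSums(abs(tup - folded)) == 0
  sort(.cell_index(tup[canonical, , drop = FALSE], nvec))
}

#' Expected folded joint SFS of a model, by simulation
#'
#' Simulates `n_sim_snps` unlinked SNPs under the model, builds the folded
#' joint SFS with the same filters as the observed one, excludes the
#' monomorphic cell and renormalises.  Canonical cells left unobserved are
#' floored at `eps = 0.1 / n_sim_snps` and the table renormalised, so the
#' composite likelihood is always finite.
#'
#' @param model a `demographic_model` (or `coal_model` with the four brood
#'   demes sampled).
#' @param n_sim_snps number of simulated SNPs (>= 1e4 recommended for
#'   production fits).
#' @param seed optional integer seed; fixing it makes the expected SFS (and
#'   hence the likelihood surface) deterministic.
#' @param maf_min pooled minor-allele-frequency threshold, matching the
#'   observed SFS's provenance.
#' @return List with `probs` (vector over all cells, zero off-support),
#'   `cells` (canonical cell indices), `n`, `eps`.
#' @export
expected_sfs <- function(model, n_sim_snps, seed = NULL, maf_min = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- .sim_snp_counts(model, n_sim_snps)
  nvec <- model$sample_config[model$sample_config > 0]
  ntot <- sum(nvec)
  pooled <- rowSums(cnt)
  ok <- pooled > 0 & pooled < ntot &
    pmin(pooled, ntot - pooled) / ntot >= maf_min
  folded <- .fold_counts(cnt[ok, , drop = FALSE], nvec)
  ncell <- prod(nvec + 1L)
  tab <- tabulate(.cell_index(folded, nvec), nbins = ncell)
  cells <- .canonical_cells(nvec, maf_min)
  eps <- 0.1 / n_sim_snps
  p <- numeric(ncell)
  p[cells] <- pmax(tab[cells], 0)
  p[cells][p[cells] == 0] <- eps * sum(tab)
  p <- p / sum(p)
  list(probs = p, cells = cells, n = nvec, eps = eps)
}

#' Composite log-likelihood of an observed SFS
#'
#' `lnL = sum_i m_i log p_i` over polymorphic entries, treating SNPs as
#' independent (composite likelihood).  Natural logarithm.
#'
#' @param obs_sfs a `joint_sfs`.
#' @param expected_probs output of [expected_sfs()] (axes must match).
#' @return The composite log-likelihood (0 for an empty SFS).
#' @export
composite_loglik <- function(obs_sfs, expected_probs) {
  m <- as.numeric(obs_sfs$counts)
  p <- expected_probs$probs
  if (length(m) != length(p)) stop("SFS axes do not match expected table")
  nz <- m > 0
  if (!any(nz)) return(0)
  if (any(p[nz] <= 0))
    stop("observed entry with zero expected probability; increase ",
         "n_sim_snps or check axes")   # impossible after flooring
  sum(m[nz] * log(p[nz]))
}

#' Fitting settings for [fit_model()]
#' @param n_sim simulated SNPs per likelihood evaluation.
#' @param n_starts number of optimiser starts (>= 1; first start is the
#'   supplied one, the rest are drawn log-uniformly within the bounds).
#' @param maxit iteration cap per start.
#' @param reltol relative convergence tolerance.
#' @return A settings list.
#' @export
fit_settings <- function(n_sim = 10000, n_starts = 5, maxit = 200,
                         reltol = 1e-6) {
  list(n_sim = n_sim, n_starts = n_starts, maxit = maxit, reltol = reltol)
}

#' Fit a demographic model to an observed folded joint SFS
#'
#' Maximises the simulated composite likelihood over the chosen free
#' parameters.  Optimisation is multi-start Nelder-Mead (Brent for a single
#' parameter) on log10-transformed parameters; common random numbers (a
#' fixed simulation seed per evaluation) make the likelihood surface
#' deterministic given the settings.
#'
#' @param obs_sfs a `joint_sfs`.
#' @param scenario,gene_flow model family (see [build_model()]).
#' @param start named vector of initial values for the parameters to
#'   optimise (a subset of the model's parameters).
#' @param lower,upper named bounds on the free parameters (natural scale).
#' @param fixed named vector of the remaining parameters, held fixed.
#' @param settings see [fit_settings()].
#' @param seed integer; seeds both the common-random-number stream and the
#'   start draws.
#' @param mu,generation_time,fixed_deme,sample_config passed to
#'   [build_model()].
#' @return A `fit_result` with fields `estimates`, `lnL`, `k`, `AIC`,
#'   `model`, `converged`.
#' @export
fit_model <- function(obs_sfs, scenario, gene_flow, start, lower = NULL,
                      upper = NULL, fixed = NULL, settings = fit_settings(),
                      seed = 1, mu = 1.53e-8, generation_time = 15,
                      fixed_deme = "XIX",
                      sample_config = c(II = 2, III = 2, XIX = 2, XXIII = 2)) {
  start <- unlist(start)
  fixed <- unlist(fixed)
  k <- length(start)
  maf_min <- if (!is.null(obs_sfs$provenance$maf_min))
    obs_sfs$provenance$maf_min else 0.05
  sim_seed <- as.integer(seed %% .Machine$integer.max)
  mk <- function(free) {
    build_model(scenario, gene_flow, c(free, fixed),
                sample_config = sample_config, mu = mu,
                generation_time = generation_time, fixed_deme = fixed_deme)
  }
  obj <- function(logp) {
    free <- stats::setNames(10^logp, names(start))
    model <- tryCatch(mk(free), error = function(e) NULL)
    if (is.null(model)) return(1e10)  # infeasible (e.g. unordered times)
    ex <- expected_sfs(model, settings$n_sim, seed = sim_seed,
                       maf_min = maf_min)
    -composite_loglik(obs_sfs, ex)
  }
  if (k == 0) {
    model <- mk(stats::setNames(numeric(0), character(0)))
    ex <- expected_sfs(model, settings$n_sim, seed = sim_seed,
                       maf_min = maf_min)
    lnL <- composite_loglik(obs_sfs, ex)
    return(structure(list(scenario = scenario, gene_flow = gene_flow,
                          estimates = fixed, free = character(0),
                          lnL = lnL, k = 0L, AIC = -2 * lnL,
                          model = model, converged = TRUE),
                     class = "fit_result"))
  }
  if (is.null(lower)) lower <- start / 100
  if (is.null(upper)) upper <- start * 100
  lower <- unlist(lower)[names(start)]
  upper <- unlist(upper)[names(start)]
  set.seed(sim_seed)
  starts <- matrix(log10(start), nrow = 1)
  if (settings$n_starts > 1) {
    extra <- vapply(seq_len(settings$n_starts - 1), function(i) {
      stats::runif(k, log10(lower), log10(upper))
    }, numeric(k))
    starts <- rbind(starts, t(matrix(extra, nrow = k)))
  }
  best <- NULL
  conv <- FALSE
  if (k == 1) {
    # deterministic surface (common random numbers): golden-section search
    res <- stats::optimize(obj, lower = log10(lower), upper = log10(upper),
                           tol = 0.005)
    best <- list(par = res$minimum, value = res$objective)
    conv <- TRUE
  } else {
    for (s in seq_len(nrow(starts))) {
      res <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                          control = list(maxit = settings$maxit,
                                         reltol = settings$reltol))
      if (is.null(best) || res$value < best$value) {
        best <- res
        conv <- res$convergence == 0
      }
    }
  }
  est <- stats::setNames(10^best$par, names(start))
  est <- pmin(pmax(est, lower), upper)
  lnL <- -best$value
  structure(list(scenario = scenario, gene_flow = gene_flow,
                 estimates = c(est, fixed), free = names(start),
                 lnL = lnL, k = k, AIC = 2 * k - 2 * lnL,
                 model = mk(est), converged = conv),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: ", x$scenario, "/", x$gene_flow, "  lnL = ",
      format(x$lnL), "  k = ", x$k, "  AIC = ", format(x$AIC),
      if (!x$converged) "  [not converged]", "\n", sep = "")
  if (length(x$free)) {
    cat("  free parameter estimates:\n")
    print(x$estimates[x$free])
  }
  invisible(x)
}

#' Akaike weights from AIC values
#'
#' `w_i = exp(-dAIC_i / 2) / sum_j exp(-dAIC_j / 2)` with
#' `dAIC_i = AIC_i - min(AIC)`.  Invariant to adding a constant to all
#' AIC values.
#'
#' @param aic numeric vector of AIC values.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Compare fitted demographic models by AIC
#'
#' @param fits a list of `fit_result` objects, or a data frame with columns
#'   `AIC` and (optionally) `scenario`, `gene_flow`, `k`, `lnL`.
#' @return A `model_comparison` data frame ordered as supplied, with
#'   `dAIC` and Akaike `weight` columns appended.
#' @export
compare_models <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits
  } else {
    tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(scenario = f$scenario, gene_flow = f$gene_flow,
                 k = f$k, lnL = f$lnL, AIC = f$AIC,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(tab$AIC)) stop("an AIC column is required")
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$weight <- akaike_weights(tab$AIC)
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Bootstrap model-selection proportions
#'
#' Poisson-bootstraps the observed SFS `n_boot` times; each replicate is
#' refitted under every candidate model and the AIC-best model recorded.
#' The proportion of replicates in which each model wins estimates the
#' stability of the selection.
#'
#' @param obs_sfs a `joint_sfs`.
#' @param model_specs list of specs, each a list of arguments for
#'   [fit_model()] (at least `scenario`, `gene_flow`, `start` and/or
#'   `fixed`).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param settings see [fit_settings()].
#' @return Named numeric vector of proportions (summing to 1 over the
#'   replicates that fitted successfully).
#' @export
bootstrap_model_selection <- function(obs_sfs, model_specs, n_boot = 100,
                                      seed = 1, settings = fit_settings()) {
  labels <- vapply(model_specs, function(s)
    paste(s$scenario, s$gene_flow, sep = "/"), character(1))
  wins <- stats::setNames(numeric(length(labels)), labels)
  n_ok <- 0L
  for (b in seq_len(n_boot)) {
    rep_sfs <- poisson_bootstrap_sfs(obs_sfs, seed = seed * 1000 + b)
    aics <- rep(NA_real_, length(model_specs))
    for (i in seq_along(model_specs)) {
      sp <- model_specs[[i]]
      f <- tryCatch(
        do.call(fit_model, c(list(obs_sfs = rep_sfs), sp,
                             list(settings = settings,
                                  seed = seed * 1000 + b))),
        error = function(e) NULL)
      if (!is.null(f)) aics[i] <- f$AIC
    }
    if (all(is.na(aics))) {
      message("bootstrap replicate ", b, " skipped: all fits failed")
      next
    }
    wins[which.min(aics)] <- wins[which.min(aics)] + 1
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0) stop("no bootstrap replicate fitted successfully")
  wins / n_ok
}

#' Effective population size from nucleotide diversity
#'
#' Uses the neutral equilibrium relationship `pi = 4 N_e mu`.
#'
#' @param pi nucleotide diversity per site (>= 0).
#' @param mu mutation rate per site per generation (> 0).
#' @return `N_e = pi / (4 mu)` (diploid).
#' @export
ne_from_pi <- function(pi, mu) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(pi < 0)) stop("pi must be >= 0")
  pi / (4 * mu)
}

#' Gene-flow estimates (N_e M) from a fitted model
#'
#' For each deme pair with a migration parameter, the effective number of
#' migrants per generation is `N_e M = N x m`, using the receiving deme's
#' diploid size.  Rates are symmetric, so each pair is reported once per
#' direction-defining deme; here the receiving deme is taken as each pair
#' member in turn and the maximum-N convention would double-count, so the
#' first deme of the canonical pair ordering is reported.
#'
#' @param fit a `fit_result` or `demographic_model`.
#' @return Data frame with columns `pair`, `deme`, `m`, `NeM`.
#' @export
gene_flow_estimates <- function(fit) {
  model <- if (inherits(fit, "fit_result")) fit$model else fit
  if (!inherits(model, "demographic_model"))
    stop("need a fitted demographic model")
  params <- model$params
  mn <- intersect(.recent_names, names(params))
  if (!length(mn)) {
    return(data.frame(pair = character(0), deme = character(0),
                      m = numeric(0), NeM = numeric(0)))
  }
  out <- do.call(rbind, lapply(mn, function(nm) {
    pr <- strsplit(sub("^m_", "", nm), "_")[[1]]
    recv <- pr[1]
    data.frame(pair = paste(pr, collapse = "-"), deme = recv,
               m = unname(params[[nm]]),
               NeM = unname(params[[paste0("N_", recv)]] * params[[nm]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
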