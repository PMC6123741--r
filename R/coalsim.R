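#' Low-level structured-coalescent model
#'
#' Generic container consumed by the simulation engine.  Demes coalesce
#' internally at rate k(k-1)/(4N) per generation (diploid effective sizes),
#' lineages migrate backward in time at per-generation rates given by an
#' epoch-specific matrix, and divergence events merge demes (backward) at
#' fixed times.  [build_model()] constructs the four-brood divergence
#' models on top of this.
#'
#' @param sample_config named integer vector: gene copies sampled per deme
#'   (0 for unsampled/ancestral demes).
#' @param deme_sizes named numeric vector of diploid effective sizes, one
#'   per deme; names define deme order.
#' @param events data frame with columns `time` (generations, ascending),
#'   `a`, `b`, `dest` (deme names): at `time`, lineages in `a` and `b` move
#'   to `dest`.
#' @param migration either a single demes-x-demes matrix applied to every
#'   epoch, or a list of `nrow(events) + 1` matrices (epoch 0 first).
#'   Entry (i, j) is the backward per-generation rate at which a lineage in
#'   deme i moves to deme j.  Rates involving demes that do not exist in an
#'   epoch are zeroed.
#' @param mu mutation rate per site per generation.
#' @param generation_time generation time in years (reporting only).
#' @return An object of class `coal_model`.
#' @export
coal_model <- function(sample_config, deme_sizes, events = NULL,
                       migration = NULL, mu = 1.53e-8, generation_time = 15) {
  demes <- names(deme_sizes)
  if (is.null(demes) || anyDuplicated(demes))
    stop("deme_sizes must have unique names")
  nd <- length(demes)
  if (any(deme_sizes <= 0)) stop("all deme sizes must be > 0")
  if (is.null(events))
    events <- data.frame(time = numeric(0), a = character(0),
                         b = character(0), dest = character(0))
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) {
    if (is.unsorted(events$time)) stop("event times must be non-decreasing")
    if (!all(c(events$a, events$b, events$dest) %in% demes))
      stop("event demes must be named in deme_sizes")
  }
  ne <- nrow(events)
  if (is.null(migration)) migration <- matrix(0, nd, nd)
  if (is.matrix(migration)) migration <- rep(list(migration), ne + 1L)
  if (length(migration) != ne + 1L)
    stop("migration must be one matrix or a list of n_events + 1 matrices")
  sc <- integer(nd)
  names(sc) <- demes
  sc[names(sample_config)] <- as.integer(sample_config)
  if (sum(sc) < 2) stop("need at least two sampled gene copies")
  # deme existence per epoch: initial demes until merged; dest demes from
  # their event until merged later
  first_merge <- rep(ne + 1L, nd)
  names(first_merge) <- demes
  created <- rep(0L, nd)
  names(created) <- demes
  if (ne) {
    for (e in seq_len(ne)) {
      for (d in c(events$a[e], events$b[e]))
        if (first_merge[d] > ne) first_merge[d] <- e
      if (created[events$dest[e]] == 0L) created[events$dest[e]] <- e
    }
  }
  mig <- vector("list", ne + 1L)
  for (ep in seq_len(ne + 1L)) {
    M <- as.matrix(migration[[ep]])
    if (!all(dim(M) == c(nd, nd))) stop("migration matrices must be demes x demes")
    if (any(M < 0) || any(M >= 1)) stop("migration rates must satisfy 0 <= m < 1")
    alive <- created <= (ep - 1L) & first_merge > (ep - 1L)
    M[!alive, ] <- 0
    M[, !alive] <- 0
    diag(M) <- 0
    mig[[ep]] <- M
  }
  structure(list(demes = demes, sample_config = sc, sizes = deme_sizes,
                 events = events, mig = mig, mu = mu,
                 generation_time = generation_time),
            class = "coal_model")
}

# canonical ordered pairs of the four brood demes
.brood_demes <- c("II", "III", "XIX", "XXIII")
.brood_pairs <- t(utils::combn(.brood_demes, 2))
.recent_names <- apply(.brood_pairs, 1, function(p) paste("m", p[1], p[2], sep = "_"))

.scenario_events <- function(scenario, t1, t2, t3) {
  switch(scenario,
    S1 = data.frame(time = c(t1, t2, t3),
                    a = c("II", "XIX", "anc1"),
                    b = c("III", "XXIII", "anc2"),
                    dest = c("anc1", "anc2", "root"),
                    stringsAsFactors = FALSE),
    S2 = data.frame(time = c(t1, t2, t3),
                    a = c("III", "anc1", "anc2"),
                    b = c("XIX", "XXIII", "II"),
                    dest = c("anc1", "anc2", "root"),
                    stringsAsFactors = FALSE),
    S3 = data.frame(time = c(t1, t2, t3),
                    a = c("XIX", "anc1", "anc2"),
                    b = c("XXIII", "III", "II"),
                    dest = c("anc1", "anc2", "root"),
                    stringsAsFactors = FALSE),
    stop("scenario must be one of S1, S2, S3"))
}

#' Build one of the nine brood-divergence demographic models
#'
#' Three divergence scenarios for the four sampled broods (II, III
#' 17-year; XIX, XXIII 13-year) crossed with three gene-flow patterns give
#' the nine models compared in the demographic analysis:
#' \describe{
#'   \item{S1}{life cycles monophyletic: ((II, III), (XIX, XXIII))}
#'   \item{S2}{geography over life cycle: (II, (XXIII, (III, XIX)))}
#'   \item{S3}{13-year monophyletic, nested: (II, (III, (XIX, XXIII)))}
#' }
#' Gene-flow patterns: `none`; `recent` (symmetric migration between each
#' of the 6 pairs of current demes, active until either member merges);
#' `past_and_recent` (additionally, migration between coexisting demes in
#' the two ancestral epochs: 3 pair rates after the first merge, 1 after
#' the second, supplied positionally as `pm1`..`pm4`).  One current deme's
#' effective size is pinned (from pi = 4 N_e mu), so the free-parameter
#' counts are 9, 15 and 19.
#'
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param gene_flow `"none"`, `"recent"` or `"past_and_recent"`.
#' @param params named numeric vector/list with divergence times `t1`,
#'   `t2`, `t3` (generations, backward; `t1 < t2 < t3` for S2/S3,
#'   `t3 > max(t1, t2)` for S1), current sizes `N_II`, `N_III`, `N_XIX`,
#'   `N_XXIII`, ancestral sizes `N_anc1`, `N_anc2`, `N_root`, plus
#'   `m_<pair>` rates for `recent`, plus `pm1`..`pm4` for
#'   `past_and_recent`.
#' @param sample_config diploid individuals sampled per brood (default 2).
#' @param mu mutation rate per site per generation.
#' @param generation_time generation time in years (default 15, the 13/17
#'   average).
#' @param fixed_deme the brood whose N_e is pinned rather than free
#'   (brood XIX for Decim, II for Cassini and Decula in the original
#'   design).
#' @return A `demographic_model` (extends `coal_model`).
#' @export
build_model <- function(scenario, gene_flow, params,
                        sample_config = c(II = 2, III = 2, XIX = 2, XXIII = 2),
                        mu = 1.53e-8, generation_time = 15,
                        fixed_deme = "XIX") {
  gene_flow <- match.arg(gene_flow, c("none", "recent", "past_and_recent"))
  scenario <- match.arg(scenario, c("S1", "S2", "S3"))
  params <- unlist(params)
  req <- c("t1", "t2", "t3", paste0("N_", .brood_demes),
           "N_anc1", "N_anc2", "N_root")
  if (gene_flow != "none") req <- c(req, .recent_names)
  if (gene_flow == "past_and_recent") req <- c(req, paste0("pm", 1:4))
  missing_p <- setdiff(req, names(params))
  extra_p <- setdiff(names(params), req)
  if (length(missing_p) || length(extra_p))
    stop("wrong parameter set for ", scenario, "/", gene_flow,
         if (length(missing_p)) paste0("; missing: ",
                                       paste(missing_p, collapse = ", ")),
         if (length(extra_p)) paste0("; unexpected: ",
                                     paste(extra_p, collapse = ", ")))
  t1 <- params[["t1"]]; t2 <- params[["t2"]]; t3 <- params[["t3"]]
  if (scenario == "S1") {
    if (!(t1 > 0 && t2 > 0 && t3 > max(t1, t2)))
      stop("S1 requires t1, t2 > 0 and t3 > max(t1, t2)")
  } else if (!(t1 > 0 && t1 < t2 && t2 < t3)) {
    stop(scenario, " requires 0 < t1 < t2 < t3")
  }
  if (!fixed_deme %in% .brood_demes) stop("fixed_deme must be a brood")
  sizes <- c(params[paste0("N_", .brood_demes)],
             params[c("N_anc1", "N_anc2", "N_root")])
  names(sizes) <- c(.brood_demes, "anc1", "anc2", "root")
  ev <- .scenario_events(scenario, t1, t2, t3)
  ord <- order(ev$time)
  ev <- ev[ord, , drop = FALSE]
  demes <- names(sizes)
  nd <- length(demes)
  # per-epoch migration matrices
  zero <- matrix(0, nd, nd, dimnames = list(demes, demes))
  mig <- rep(list(zero), 4L)
  set_rate <- function(M, a, b, r) { M[a, b] <- r; M[b, a] <- r; M }
  if (gene_flow != "none") {
    M0 <- zero
    for (i in seq_len(nrow(.brood_pairs)))
      M0 <- set_rate(M0, .brood_pairs[i, 1], .brood_pairs[i, 2],
                     params[[.recent_names[i]]])
    mig[[1]] <- M0
  }
  alive_in <- function(ep) {  # epoch index 0..3
    merged <- unique(unlist(ev[seq_len(ep), c("a", "b")]))
    born <- ev$dest[seq_len(ep)]
    setdiff(c(setdiff(.brood_demes, merged), born), merged)
  }
  if (gene_flow == "recent") {
    # a pair's recent rate persists while both members are still current
    for (ep in 1:2) {
      M <- zero
      al <- alive_in(ep)
      for (i in seq_len(nrow(.brood_pairs))) {
        p <- .brood_pairs[i, ]
        if (all(p %in% al))
          M <- set_rate(M, p[1], p[2], params[[.recent_names[i]]])
      }
      mig[[ep + 1L]] <- M
    }
  } else if (gene_flow == "past_and_recent") {
    pm <- params[paste0("pm", 1:4)]
    pi_ <- 1L
    for (ep in 1:2) {
      M <- zero
      al <- sort(match(alive_in(ep), demes))
      if (length(al) >= 2) {
        prs <- utils::combn(al, 2)
        for (cc in seq_len(ncol(prs))) {
          M <- set_rate(M, demes[prs[1, cc]], demes[prs[2, cc]], pm[[pi_]])
          pi_ <- pi_ + 1L
        }
      }
      mig[[ep + 1L]] <- M
    }
  }
  sc <- c(stats::setNames(as.integer(sample_config[.brood_demes]) * 2L,
                          .brood_demes),
          anc1 = 0L, anc2 = 0L, root = 0L)
  m <- coal_model(sc, sizes, ev, mig, mu = mu,
                  generation_time = generation_time)
  m$scenario <- scenario
  m$gene_flow <- gene_flow
  m$params <- params
  m$fixed_deme <- fixed_deme
  m$free_params <- setdiff(req, paste0("N_", fixed_deme))
  class(m) <- c("demographic_model", "coal_model")
  m
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model: ", x$scenario, "/", x$gene_flow, ", ",
      length(x$free_params), " free parameters (N_", x$fixed_deme,
      " fixed)\n", sep = "")
  invisible(x)
}

#' Number of free parameters of a demographic model
#' @param model a `demographic_model`.
#' @return Integer: 9 (`none`), 15 (`recent`) or 19 (`past_and_recent`).
#' @export
n_free_params <- function(model) length(model$free_params)

# pack a coal_model for the C++ engine
.pack_model <- function(model) {
  demes <- model$demes
  nd <- length(demes)
  ev <- model$events
  emat <- matrix(0L, nrow(ev), 3L)
  if (nrow(ev)) {
    emat[, 1] <- match(ev$a, demes) - 1L
    emat[, 2] <- match(ev$b, demes) - 1L
    emat[, 3] <- match(ev$dest, demes) - 1L
  }
  migflat <- unlist(lapply(model$mig, function(M) as.vector(t(M))))
  if (is.null(migflat)) migflat <- numeric(0)
  list(times = as.numeric(ev$time), events = emat,
       sizes = as.numeric(model$sizes), mig = as.numeric(migflat),
       samples = as.integer(model$sample_config))
}

# tip labels "<deme>.<copy>"; diploids pair consecutive copies
.tip_info <- function(model) {
  sc <- model$sample_config
  demes <- rep(model$demes, sc)
  copy <- unlist(lapply(sc, seq_len), use.names = FALSE)
  if (length(copy) == 0) copy <- integer(0)
  data.frame(deme = demes, copy = copy, stringsAsFactors = FALSE)
}

#' Simulate one genealogy under a structured-coalescent model
#'
#' Returns a single coalescent tree over all sampled gene copies, as an
#' `ape` phylo object with branch lengths in generations.  Tip labels are
#' `<deme>.<copy>`; the deme of each tip is in `attr(tree, "tip_deme")`
#' and the sample TMRCA (in generations) in `attr(tree, "tmrca")`.
#'
#' @param model a `coal_model` or `demographic_model`.
#' @param seed optional integer seed.
#' @return An `ape::phylo`.
#' @export
simulate_genealogy <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pk <- .pack_model(model)
  g <- cpp_sim_genealogy(pk$times, pk$events, pk$sizes, pk$mig, pk$samples)
  ntip <- g$n_tip
  m <- length(g$node_time) - ntip      # number of internal nodes
  remap <- function(id) ifelse(id < ntip, id + 1L, ntip + (m - (id - ntip)))
  edge <- cbind(remap(g$parent), remap(g$child))
  elen <- g$parent_time - g$node_time[g$child + 1L]
  ti <- .tip_info(model)
  labels <- paste(model$demes[g$tip_deme + 1L],
                  ti$copy, sep = ".")
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = labels, Nnode = m),
                  class = "phylo", order = "postorder")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "tip_deme") <- model$demes[g$tip_deme + 1L]
  attr(tr, "tmrca") <- max(g$node_time)
  tr
}

# internal: n_snps x n_tips 0/1 derived-allele matrix (one tree per SNP,
# one mutation placed uniformly by branch length -> always segregating)
.sim_snp_tips <- function(model, n_snps) {
  pk <- .pack_model(model)
  cpp_sim_unlinked(pk$times, pk$events, pk$sizes, pk$mig, pk$samples,
                   as.integer(n_snps))
}

# internal: derived gene-copy counts per deme, n_snps x n_sampled_demes
.sim_snp_counts <- function(model, n_snps) {
  tips <- .sim_snp_tips(model, n_snps)
  ti <- .tip_info(model)
  demes <- model$demes[model$sample_config > 0]
  ind <- outer(ti$deme, demes, "==") + 0
  cnt <- tips %*% ind
  colnames(cnt) <- demes
  cnt
}

# tips matrix -> genotype_matrix (pair consecutive copies into diploids)
.tips_to_geno <- function(tips, model, loci, pos, synonymous = TRUE) {
  ti <- .tip_info(model)
  stopifnot(all(model$sample_config %% 2 == 0))
  first <- which(ti$copy %% 2L == 1L)
  calls <- t(tips[, first, drop = FALSE] + tips[, first + 1L, drop = FALSE])
  inds <- paste(ti$deme[first], (ti$copy[first] + 1L) %/% 2L, sep = "_")
  sites <- data.frame(locus = loci, pos = pos, ref = "A", alt = "T",
                      synonymous = synonymous, stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, inds)
}

#' Simulate unlinked SNPs
#'
#' Each SNP comes from an independent genealogy; one mutation is placed
#' uniformly by branch length, so every returned site is polymorphic in the
#' pooled sample.  Consecutive gene copies within a deme are paired into
#' diploid individuals.
#'
#' @param model a `coal_model`/`demographic_model` with even gene-copy
#'   counts per sampled deme.
#' @param n_snps number of SNPs (>= 1).
#' @param seed optional integer seed.
#' @return A `genotype_matrix` with one single-SNP locus per site.
#' @export
simulate_unlinked_snps <- function(model, n_snps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_snps >= 1)
  tips <- .sim_snp_tips(model, n_snps)
  .tips_to_geno(tips, model, sprintf("snp%06d", seq_len(n_snps)),
                rep(1L, n_snps))
}

.BASES <- c("A", "C", "G", "T")

# resolve two haplotype characters into one unphased character
.unphase <- function(h1, h2) {
  out <- h1
  het <- h1 != h2
  if (any(het)) {
    key <- paste0(pmin(h1[het], h2[het]), pmax(h1[het], h2[het]))
    out[het] <- .iupac[key]
  }
  out
}

#' Simulate one linked locus (no intra-locus recombination)
#'
#' A single genealogy underlies the whole locus; the mutation count is
#' Poisson(total branch length x mu x length) with infinite-sites placement
#' on distinct positions.
#'
#' @param model a `coal_model`/`demographic_model`.
#' @param length_bp alignment length in bp (>= 1).
#' @param seed optional integer seed.
#' @param locus_id locus name used in the outputs.
#' @return List with `alignment` (named character vector of unphased
#'   per-individual sequences, heterozygous sites IUPAC-coded),
#'   `geno` (a `genotype_matrix` slice over the segregating sites) and
#'   `positions`.
#' @export
simulate_linked_locus <- function(model, length_bp, seed = NULL,
                                  locus_id = "locus1") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length_bp >= 1)
  pk <- .pack_model(model)
  sim <- cpp_sim_locus(pk$times, pk$events, pk$sizes, pk$mig, pk$samples,
                       as.integer(length_bp), model$mu)
  anc <- sample(.BASES, length_bp, replace = TRUE)
  S <- nrow(sim$geno)
  ti <- .tip_info(model)
  hap <- matrix(rep(anc, each = nrow(ti)), nrow = nrow(ti))
  ref <- character(S); alt <- character(S)
  if (S > 0) {
    for (s in seq_len(S)) {
      p <- sim$positions[s]
      ref[s] <- anc[p]
      alt[s] <- sample(setdiff(.BASES, anc[p]), 1)
      hap[sim$geno[s, ] == 1L, p] <- alt[s]
    }
  }
  first <- which(ti$copy %% 2L == 1L)
  inds <- paste(ti$deme[first], (ti$copy[first] + 1L) %/% 2L, sep = "_")
  aln <- vapply(seq_along(first), function(i) {
    paste(.unphase(hap[first[i], ], hap[first[i] + 1L, ]), collapse = "")
  }, character(1))
  names(aln) <- inds
  geno <- if (S > 0) {
    sites <- data.frame(locus = locus_id, pos = sim$positions,
                        ref = ref, alt = alt, synonymous = TRUE,
                        stringsAsFactors = FALSE)
    calls <- t(sim$geno[, first, drop = FALSE] +
                 sim$geno[, first + 1L, drop = FALSE])
    genotype_matrix(calls, sites, inds)
  } else {
    genotype_matrix(matrix(integer(0), nrow = length(inds), ncol = 0,
                           dimnames = list(inds, NULL)),
                    data.frame(locus = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               synonymous = logical(0)), inds)
  }
  list(alignment = aln, geno = geno, positions = sim$positions,
       locus_id = locus_id)
}

#' Simulate a full synthetic study dataset
#'
#' Emulates the sampling design of the brood study at one-species-group
#' scale: four brood demes with two diploid individuals each, loci with
#' lengths drawn around a mean of 1627 bp, unphased genotypes
#' (heterozygotes IUPAC-coded in the alignments) and a synonymous flag
#' drawn per SNP with probability `p_synonymous`.
#'
#' @param model a `demographic_model` (see [build_model()],
#'   [example_model()]).
#' @param n_loci number of loci (>= 1).
#' @param mean_locus_len mean alignment length in bp.
#' @param seed optional integer seed.
#' @param p_synonymous probability that a SNP is flagged synonymous
#'   (default 0.68, the genome-wide synonymous proportion).
#' @param group,species_13,species_17 labels used in the population map.
#' @return List with `geno` (`genotype_matrix`), `loci` (`locus_set`) and
#'   `popmap` (`population_map`).
#' @export
simulate_dataset <- function(model, n_loci, mean_locus_len = 1627,
                             seed = NULL, p_synonymous = 0.68,
                             group = "Decim", species_13 = "neotredecim",
                             species_17 = "septendecim") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_loci >= 1)
  lens <- pmax(300L, as.integer(round(stats::rnorm(n_loci, mean_locus_len,
                                                   0.25 * mean_locus_len))))
  alns <- list()
  genos <- list()
  for (i in seq_len(n_loci)) {
    id <- sprintf("locus%05d", i)
    sim <- simulate_linked_locus(model, lens[i], locus_id = id)
    alns[[id]] <- sim$alignment
    if (ncol(sim$geno$calls) > 0) genos[[id]] <- sim$geno
  }
  if (length(genos)) {
    calls <- do.call(cbind, lapply(genos, function(g) g$calls))
    sites <- do.call(rbind, lapply(genos, function(g) g$sites))
    rownames(sites) <- NULL
    sites$synonymous <- stats::runif(nrow(sites)) < p_synonymous
    geno <- genotype_matrix(calls, sites, genos[[1]]$individuals)
  } else {
    inds <- names(alns[[1]])
    geno <- genotype_matrix(matrix(integer(0), nrow = length(inds), ncol = 0,
                                   dimnames = list(inds, NULL)),
                            data.frame(locus = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0),
                                       synonymous = logical(0)), inds)
  }
  pm <- do.call(rbind, lapply(seq_along(geno$individuals), function(j) {
    id <- geno$individuals[j]
    brood <- sub("_[0-9]+$", "", id)
    cyc <- if (brood %in% c("XIX", "XXIII")) 13L else 17L
    data.frame(individual = id, brood = brood,
               species = if (cyc == 13L) species_13 else species_17,
               group = group, cycle = cyc, stringsAsFactors = FALSE)
  }))
  list(geno = geno, loci = locus_set(alns), popmap = population_map(pm))
}

#' Reference four-brood model with realistic defaults
#'
#' A ready-made S1 (life cycles monophyletic) model at the study's scale:
#' life-cycle split about 197 kya (13,133 generations at 15 y per
#' generation), within-cycle brood splits during the last glacial period,
#' current brood sizes of 20,000-25,000 diploids (within-deme diversity
#' pi = 4 N_e mu of about 1.2e-3 to 1.5e-3 at mu = 1.53e-8), and symmetric
#' recent migration strongest between the adjacent 13-year broods
#' (N_e M of about 5) and weak elsewhere.
#'
#' @param gene_flow gene-flow pattern (default `"recent"`).
#' @param scenario divergence scenario (default `"S1"`).
#' @param ... overrides passed to [build_model()] parameters by name.
#' @return A `demographic_model`.
#' @export
example_model <- function(gene_flow = "recent", scenario = "S1", ...) {
  params <- c(t1 = 5000, t2 = 4900, t3 = 13133,
              N_II = 25000, N_III = 25000, N_XIX = 20000, N_XXIII = 20000,
              N_anc1 = 10000, N_anc2 = 10000, N_root = 15000)
  if (gene_flow != "none")
    params <- c(params,
                m_II_III = 2.5e-5, m_II_XIX = 2.5e-5, m_II_XXIII = 2.5e-5,
                m_III_XIX = 1e-4, m_III_XXIII = 2.5e-5,
                m_XIX_XXIII = 2.5e-4)
  if (gene_flow == "past_and_recent")
    params <- c(params, pm1 = 1e-5, pm2 = 1e-5, pm3 = 1e-5, pm4 = 1e-5)
  if (scenario != "S1") {  # S2/S3 need strictly ordered times
    params[["t1"]] <- 4900
    params[["t2"]] <- 5000
  }
  over <- list(...)
  for (nm in names(over)) params[[nm]] <- over[[nm]]
  build_model(scenario, gene_flow, params)
}

#' Write a demographic model to a YAML file
#' @param model a `demographic_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(list(scenario = model$scenario,
                        gene_flow = model$gene_flow,
                        params = as.list(model$params),
                        sample_config =
                          as.list(model$sample_config[.brood_demes] / 2L),
                        mu = model$mu,
                        generation_time = model$generation_time,
                        fixed_deme = model$fixed_deme), path)
  invisible(path)
}

#' Read a demographic model from a YAML file
#' @param path YAML file written by [write_model()] (or hand-authored with
#'   the same keys).
#' @return A `demographic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  y <- yaml::read_yaml(path)
  build_model(y$scenario, y$gene_flow, unlist(y$params),
              sample_config = unlist(y$sample_config),
              mu = y$mu, generation_time = y$generation_time,
              fixed_deme = y$fixed_deme)
}
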