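#' @title End-to-end analysis pipeline
#' @description Runs the full synthetic-study workflow -- simulate a
#'   dataset, build the folded joint SFS, evaluate and compare demographic
#'   models, compute per-locus statistics, the ABBA-BABA test and the F_st
#'   outlier scan -- writing versioned outputs and a provenance log.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]; every
#' block can be overridden (partially) via `...` or a YAML file with the
#' same structure.  Each stochastic stage receives a sub-seed derived from
#' the root seed by a fixed offset, which is recorded in the provenance
#' log.
#'
#' @param seed root seed.
#' @param ... named blocks overriding the defaults (`model`, `simulate`,
#'   `sfs`, `fit`, `stats`, `dstat`, `outliers`).
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    model = list(scenario = "S1", gene_flow = "recent"),
    simulate = list(n_loci = 40, mean_locus_len = 800),
    sfs = list(maf_min = 0.05, synonymous_only = TRUE),
    fit = list(enabled = TRUE, n_sim = 2000,
               scenarios = c("S1", "S2", "S3")),
    stats = list(n_rrhs = 20),
    dstat = list(n_boot = 200),
    outliers = list(n_snp_null = 2000, locus_reps = 300, locus_len = 2500,
                    max_group = 5)
  )
  over <- list(...)
  for (nm in names(over))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [default_config()] structure (missing
#'   blocks take defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cfg <- default_config(seed = if (!is.null(y$seed)) y$seed else 1)
  for (nm in setdiff(names(y), "seed"))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], y[[nm]])
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> sfs -> fit/compare -> stats -> dstat -> outliers
#' in order, writing result tables into `out_dir` together with a
#' provenance log (seeds, parameters, package version).  A stage failure
#' aborts with the stage name; outputs of earlier stages are preserved.
#'
#' @param config a `run_config` (see [default_config()]) or the path to a
#'   YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  seeds <- list(simulate = seed + 1L, sfs = seed + 2L, fit = seed + 3L,
                stats = seed + 4L, dstat = seed + 5L, outliers = seed + 6L)

  model <- .stage("model", {
    if (!is.null(config$model$path)) read_model(config$model$path)
    else if (!is.null(config$model$params))
      build_model(config$model$scenario, config$model$gene_flow,
                  unlist(config$model$params))
    else example_model(gene_flow = config$model$gene_flow,
                       scenario = config$model$scenario)
  })

  ds <- .stage("simulate", {
    out <- simulate_dataset(model, n_loci = config$simulate$n_loci,
                            mean_locus_len = config$simulate$mean_locus_len,
                            seed = seeds$simulate)
    write_popmap(out$popmap, file.path(out_dir, "popmap.tsv"))
    write_vcf(out$geno, file.path(out_dir, "genotypes.vcf"))
    write_locus_fasta(out$loci, file.path(out_dir, "loci"))
    out
  })

  sfs <- .stage("sfs", {
    s <- joint_folded_sfs(ds$geno, ds$popmap,
                          maf_min = config$sfs$maf_min,
                          synonymous_only = config$sfs$synonymous_only)
    write_sfs(s, file.path(out_dir, "joint_sfs.tsv"))
    s
  })

  comparison <- .stage("fit", {
    if (!isTRUE(config$fit$enabled)) NULL else {
      # evaluate each candidate scenario at the generating parameter values
      # (k = 0 composite-likelihood comparison; full optimisation is run
      # separately via fit_model when parameters are to be estimated)
      fits <- lapply(config$fit$scenarios, function(sc) {
        params <- model$params
        if (sc != "S1" && params[["t1"]] > params[["t2"]]) {
          tt <- params[["t1"]]
          params[["t1"]] <- params[["t2"]]
          params[["t2"]] <- tt
        }
        fit_model(sfs, sc, model$gene_flow,
                  start = stats::setNames(numeric(0), character(0)),
                  fixed = params,
                  settings = fit_settings(n_sim = config$fit$n_sim),
                  seed = seeds$fit)
      })
      cmp <- compare_models(fits)
      utils::write.table(as.data.frame(cmp),
                         file.path(out_dir, "model_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cmp
    }
  })

  stats_tab <- .stage("stats", {
    tab <- locus_stats(ds$loci, ds$geno, ds$popmap,
                       n_rrhs = config$stats$n_rrhs, seed = seeds$stats)
    utils::write.table(tab, file.path(out_dir, "locus_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  dres <- .stage("dstat", {
    q <- if (!is.null(config$dstat$quartet)) {
      quartet_config(config$dstat$quartet$P1, config$dstat$quartet$P2,
                     config$dstat$quartet$P3, config$dstat$quartet$O)
    } else {
      quartet_config(individuals_of(ds$popmap, brood = "II"),
                     individuals_of(ds$popmap, brood = "III"),
                     individuals_of(ds$popmap, brood = "XIX"),
                     individuals_of(ds$popmap, brood = "XXIII"))
    }
    d <- d_bootstrap(ds$geno, q, n_boot = config$dstat$n_boot,
                     seed = seeds$dstat)
    utils::write.table(
      data.frame(n_sites = d$n_sites, D = d$D, SD = d$sd, Z = d$Z, P = d$P),
      file.path(out_dir, "dstat.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    d
  })

  outl <- .stage("outliers", {
    nsnp <- snp_null(model, n = config$outliers$n_snp_null,
                     seed = seeds$outliers)
    nloc <- locus_null(model, length_bp = config$outliers$locus_len,
                       reps = config$outliers$locus_reps,
                       seed = seeds$outliers + 1L)
    nmax <- max_fst_null(nsnp, group_size = config$outliers$max_group,
                         reps = config$outliers$locus_reps,
                         seed = seeds$outliers + 2L)
    p13 <- individuals_of(ds$popmap, cycle = 13)
    p17 <- individuals_of(ds$popmap, cycle = 17)
    snp_tab <- snp_fst_table(ds$geno, p13, p17)
    snp_flags <- call_outliers(
      stats::setNames(snp_tab$fst, paste(snp_tab$locus, snp_tab$pos,
                                         sep = ":")), nsnp)
    loc_w <- stats::setNames(stats_tab$fst_weighted, stats_tab$locus)
    loc_m <- stats::setNames(stats_tab$fst_max, stats_tab$locus)
    out <- list(
      thresholds = c(snp = nsnp$threshold, locus_weighted = nloc$threshold,
                     locus_max = nmax$threshold),
      snp_flags = snp_flags,
      locus_weighted_flags = call_outliers(loc_w, nloc),
      locus_max_flags = call_outliers(loc_m, nmax))
    utils::write.table(
      data.frame(item = names(snp_flags), fst = snp_tab$fst,
                 threshold = nsnp$threshold, flagged = snp_flags),
      file.path(out_dir, "snp_outliers.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(locus = names(loc_w), fst_weighted = loc_w,
                 fst_max = loc_m,
                 threshold_weighted = nloc$threshold,
                 threshold_max = nmax$threshold,
                 flagged_weighted = out$locus_weighted_flags,
                 flagged_max = out$locus_max_flags),
      file.path(out_dir, "locus_outliers.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out
  })

  prov <- list(package = "cicadapop",
               version = as.character(utils::packageVersion("cicadapop")),
               seed = seed, stage_seeds = seeds,
               model = list(scenario = model$scenario,
                            gene_flow = model$gene_flow,
                            params = as.list(model$params)),
               config = config[setdiff(names(config), "model")])
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, dataset = ds, sfs = sfs,
                 comparison = comparison, locus_stats = stats_tab,
                 dstat = dres, outliers = outl, out_dir = out_dir))
}
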