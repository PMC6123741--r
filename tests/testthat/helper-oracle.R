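# Independent coalescent oracle: joint derived-allele counts simulated with
# msprime through the system python.  Used only to cross-validate the
# package's own simulator.

msprime_available <- function() {
  py <- Sys.which("python")
  if (py == "") return(FALSE)
  ok <- try(system2(py, c("-c", shQuote("import msprime")),
                    stdout = FALSE, stderr = FALSE), silent = TRUE)
  !inherits(ok, "try-error") && identical(ok, 0L)
}

.msprime_script <- '
import sys, json
import msprime
import numpy as np

cfg = json.load(open(sys.argv[1]))
dem = msprime.Demography()
for name, size in cfg["sizes"].items():
    dem.add_population(name=name, initial_size=size)
for a, b, r in cfg["migration"]:
    dem.set_symmetric_migration_rate([a, b], r)
for t, a, b, dest in cfg["events"]:
    dem.add_population_split(time=t, derived=[a, b], ancestral=dest)
dem.sort_events()
counts = []
reps = msprime.sim_ancestry(samples=cfg["samples"], demography=dem,
                            ploidy=2, sequence_length=cfg["seq_len"],
                            num_replicates=cfg["n_reps"],
                            random_seed=cfg["seed"])
pops = list(cfg["samples"].keys())
for ts in reps:
    mts = msprime.sim_mutations(ts, rate=cfg["mu"],
                                model=msprime.BinaryMutationModel())
    if mts.num_sites == 0:
        continue
    sample_pop = np.array([mts.node(u).population for u in mts.samples()])
    pop_idx = [np.where(sample_pop == dem[p].id)[0] for p in pops]
    for var in mts.variants():
        g = var.genotypes
        counts.append([int(g[idx].sum()) for idx in pop_idx])
np.savetxt(sys.argv[2], np.array(counts, dtype=int), fmt="%d",
           delimiter="\\t")
'

# simulate joint derived counts for a demographic_model under msprime
msprime_joint_counts <- function(model, n_reps, seq_len, mu, seed) {
  stopifnot(inherits(model, "demographic_model"))
  demes <- model$demes
  mig <- model$mig[[1]]
  pairs <- which(upper.tri(mig) & mig > 0, arr.ind = TRUE)
  mig_list <- lapply(seq_len(nrow(pairs)), function(i) {
    list(demes[pairs[i, 1]], demes[pairs[i, 2]],
         mig[pairs[i, 1], pairs[i, 2]])
  })
  ev <- model$events
  events <- lapply(seq_len(nrow(ev)), function(e) {
    list(ev$time[e], ev$a[e], ev$b[e], ev$dest[e])
  })
  samples <- lapply(model$sample_config[model$sample_config > 0],
                    function(x) as.integer(x / 2))
  cfg <- list(sizes = as.list(model$sizes), migration = mig_list,
              events = events, samples = samples, seq_len = seq_len,
              mu = mu, n_reps = n_reps, seed = seed)
  dir <- tempfile("msp_"); dir.create(dir)
  cfg_path <- file.path(dir, "cfg.json")
  py_path <- file.path(dir, "oracle.py")
  out_path <- file.path(dir, "counts.tsv")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  writeLines(.msprime_script, py_path)
  status <- system2(Sys.which("python"), c(py_path, cfg_path, out_path),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("msprime oracle run failed")
  as.matrix(utils::read.table(out_path, sep = "\t"))
}

# total-variation distance between two folded joint SFS count matrices
folded_tv <- function(cnt_a, cnt_b, nvec) {
  ncell <- prod(nvec + 1L)
  tab <- function(cnt) {
    keep <- rowSums(cnt) > 0 & rowSums(cnt) < sum(nvec)
    f <- cicadapop:::.fold_counts(cnt[keep, , drop = FALSE], nvec)
    tabulate(cicadapop:::.cell_index(f, nvec), ncell)
  }
  ta <- tab(cnt_a); tb <- tab(cnt_b)
  0.5 * sum(abs(ta / sum(ta) - tb / sum(tb)))
}
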