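# Shared fixtures, all built in code.

# toy genotype matrix: 8 individuals (2 per brood), hand-set dosages
toy_geno <- function(calls, loci = NULL, pos = NULL, synonymous = TRUE) {
  inds <- c("II_1", "II_2", "III_1", "III_2",
            "XIX_1", "XIX_2", "XXIII_1", "XXIII_2")
  n_sites <- ncol(calls)
  if (is.null(loci)) loci <- sprintf("L%03d", seq_len(n_sites))
  if (is.null(pos)) pos <- rep(1L, n_sites)
  rownames(calls) <- inds
  genotype_matrix(calls,
                  data.frame(locus = loci, pos = pos,
                             ref = rep("A", n_sites),
                             alt = rep("T", n_sites),
                             synonymous = rep(synonymous,
                                              length.out = n_sites)),
                  inds)
}

toy_popmap <- function() {
  population_map(data.frame(
    individual = c("II_1", "II_2", "III_1", "III_2",
                   "XIX_1", "XIX_2", "XXIII_1", "XXIII_2"),
    brood = c("II", "II", "III", "III", "XIX", "XIX", "XXIII", "XXIII"),
    species = c(rep("septendecim", 4), rep("neotredecim", 4)),
    group = "Decim",
    cycle = c(17, 17, 17, 17, 13, 13, 13, 13)))
}

# the full 28-individual sampling design: 2 individuals per brood per
# species; 13-year species in broods XIX/XXIII, 17-year in II/III
study_popmap <- function() {
  sp <- list(
    list(species = "tredecim", group = "Decim", cycle = 13),
    list(species = "neotredecim", group = "Decim", cycle = 13),
    list(species = "septendecim", group = "Decim", cycle = 17),
    list(species = "tredecassini", group = "Cassini", cycle = 13),
    list(species = "cassini", group = "Cassini", cycle = 17),
    list(species = "tredecula", group = "Decula", cycle = 13),
    list(species = "septendecula", group = "Decula", cycle = 17))
  rows <- do.call(rbind, lapply(sp, function(s) {
    broods <- if (s$cycle == 13) c("XIX", "XXIII") else c("II", "III")
    do.call(rbind, lapply(broods, function(b) {
      data.frame(individual = paste(s$species, b, 1:2, sep = "_"),
                 brood = b, species = s$species, group = s$group,
                 cycle = s$cycle)
    }))
  }))
  population_map(rows)
}

# a small, fast demographic model (shallow histories, cheap trees)
small_model <- function(gene_flow = "recent", ...) {
  example_model(gene_flow = gene_flow, ...)
}

# write a minimal VCF fixture and return its path
write_vcf_fixture <- function(lines, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("vcf_fixture_")
    dir.create(dir)
  }
  path <- file.path(dir, "fixture.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
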