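#' Construct a genotype matrix
#'
#' Core container for diploid biallelic genotypes: individuals by sites, with
#' per-site metadata (locus, 1-based position within the locus, ref/alt
#' alleles, synonymous flag).  Calls are alternate-allele dosages in
#' \{0, 1, 2\} with `NA` for missing.
#'
#' @param calls integer matrix, individuals x sites, values 0/1/2/NA.
#' @param sites data frame with columns `locus`, `pos`, `ref`, `alt` and
#'   optionally `synonymous` (logical; defaults to `TRUE`).
#' @param individuals character vector of unique individual ids; defaults to
#'   `rownames(calls)`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, individuals = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individuals)) stop("individual ids are required")
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) stop("individual ids must be unique")
  if (nrow(calls) != length(individuals))
    stop("calls must have one row per individual")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("locus", "pos", "ref", "alt")
  if (!all(req %in% names(sites)))
    stop("sites needs columns: ", paste(req, collapse = ", "))
  if (is.null(sites$synonymous)) sites$synonymous <- TRUE
  if (ncol(calls) != nrow(sites)) stop("calls must have one column per site")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(calls) <- individuals
  colnames(calls) <- paste(sites$locus, sites$pos, sep = ":")
  structure(list(individuals = individuals, sites = sites, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      nrow(x$sites), "biallelic sites (",
      length(unique(x$sites$locus)), "loci )\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by site index
#' @param geno a `genotype_matrix`.
#' @param idx integer or logical site index.
#' @return A `genotype_matrix` over the selected sites, order preserved.
#' @export
subset_sites <- function(geno, idx) {
  genotype_matrix(geno$calls[, idx, drop = FALSE],
                  geno$sites[idx, , drop = FALSE], geno$individuals)
}

#' Read a population map
#'
#' A population map assigns each individual to a brood (II, III, XIX,
#' XXIII), a species, a species group (Decim, Cassini, Decula) and a life
#' cycle (13 or 17 years).  Brood and life cycle must be consistent: broods
#' XIX and XXIII are 13-year, II and III are 17-year.
#'
#' @param path TSV file with header columns
#'   `individual`, `brood`, `species`, `group`, `cycle`.
#' @return A data frame of class `population_map`.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  population_map(tab)
}

#' Construct and validate a population map from a data frame
#' @param tab data frame with columns `individual`, `brood`, `species`,
#'   `group`, `cycle`.
#' @return A validated `population_map`.
#' @export
population_map <- function(tab) {
  req <- c("individual", "brood", "species", "group", "cycle")
  if (!all(req %in% names(tab)))
    stop("popmap needs columns: ", paste(req, collapse = ", "))
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab$brood <- as.character(tab$brood)
  tab$cycle <- as.integer(tab$cycle)
  if (anyDuplicated(tab$individual))
    stop("duplicate individual id(s): ",
         paste(unique(tab$individual[duplicated(tab$individual)]),
               collapse = ", "))
  known <- c(II = 17L, III = 17L, XIX = 13L, XXIII = 13L)
  bad <- setdiff(tab$brood, names(known))
  if (length(bad)) stop("unknown brood label(s): ", paste(bad, collapse = ", "))
  mism <- tab$cycle != known[tab$brood]
  if (any(mism))
    stop("brood/life-cycle mismatch for: ",
         paste(tab$individual[mism], collapse = ", "),
         " (XIX, XXIII are 13-year; II, III are 17-year)")
  class(tab) <- c("population_map", "data.frame")
  tab
}

#' Write a population map to TSV
#' @param popmap a `population_map`.
#' @param path output path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(as.data.frame(popmap), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Individuals belonging to given broods / cycles / groups
#' @param popmap a `population_map`.
#' @param brood,cycle,group,species optional filters; `NULL` means no filter.
#' @return Character vector of individual ids.
#' @export
individuals_of <- function(popmap, brood = NULL, cycle = NULL, group = NULL,
                           species = NULL) {
  keep <- rep(TRUE, nrow(popmap))
  if (!is.null(brood)) keep <- keep & popmap$brood %in% brood
  if (!is.null(cycle)) keep <- keep & popmap$cycle %in% cycle
  if (!is.null(group)) keep <- keep & popmap$group %in% group
  if (!is.null(species)) keep <- keep & popmap$species %in% species
  popmap$individual[keep]
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads GT fields from a VCF (via vcfR), keeps biallelic SNP records only
#' (multiallelic sites and indels are dropped with a message), and converts
#' genotypes to alternate-allele dosages.  The CHROM field is taken as the
#' locus id and POS as the 1-based position within the locus.
#'
#' @param path VCF file (plain or gzipped).
#' @param popmap a `population_map`; every sample in the VCF must appear.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, popmap) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop,
            " non-biallelic-SNP record(s), kept ", sum(snp))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ids <- colnames(gt)
  missing_ids <- setdiff(ids, popmap$individual)
  if (length(missing_ids))
    stop("VCF sample(s) absent from popmap: ",
         paste(missing_ids, collapse = ", "))
  dos <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- t(apply(gt, 2, dos))
  if (nrow(gt) == 1L) calls <- matrix(calls, ncol = 1L)
  sites <- data.frame(locus = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, ids)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits plain-text VCF with GT-only genotypes, suitable for round-tripping
#' through [read_vcf()].
#'
#' @param geno a `genotype_matrix`.
#' @param path output path.
#' @export
write_vcf <- function(geno, path) {
  gtxt <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(geno$sites), ncol = length(geno$individuals))
  for (j in seq_along(geno$individuals)) {
    d <- geno$calls[j, ]
    ok <- !is.na(d)
    gt[ok, j] <- gtxt[d[ok] + 1L]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cicadapop",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$individuals), collapse = "\t"))
  body <- paste(geno$sites$locus, geno$sites$pos, ".", geno$sites$ref,
                geno$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# IUPAC ambiguity codes for heterozygous base pairs
.iupac <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
.iupac_rev <- {
  m <- strsplit(names(.iupac), "")
  stats::setNames(m, unname(.iupac))
}

#' Build a locus set from per-locus alignments
#'
#' A `locus_set` stores, per locus, an equal-length alignment of unphased
#' per-individual sequences in which heterozygous sites carry IUPAC
#' ambiguity codes (M, R, W, S, Y, K).
#'
#' @param alignments named list (one entry per locus) of named character
#'   vectors of equal-length sequences.
#' @return An object of class `locus_set`.
#' @export
locus_set <- function(alignments) {
  for (loc in names(alignments)) {
    lens <- nchar(alignments[[loc]])
    if (length(unique(lens)) > 1L)
      stop("ragged alignment in locus ", loc)
    if (length(lens) && lens[1] < 1L) stop("zero-length locus ", loc)
  }
  structure(list(alignments = alignments), class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  n <- length(x$alignments)
  cat("locus_set:", n, "loci")
  if (n) cat(", mean length", round(mean(locus_lengths(x))), "bp")
  cat("\n")
  invisible(x)
}

#' @export
length.locus_set <- function(x) length(x$alignments)

#' Alignment lengths of a locus set
#' @param ls a `locus_set`.
#' @return Named integer vector of per-locus alignment lengths.
#' @export
locus_lengths <- function(ls) {
  vapply(ls$alignments, function(a) {
    if (length(a) == 0L) 0L else nchar(a[[1]])
  }, integer(1))
}

#' Heterozygous (ambiguity-coded) positions of one locus
#' @param ls a `locus_set`.
#' @param locus locus id.
#' @return Sorted integer vector of 1-based positions where any sequence
#'   carries an IUPAC ambiguity code.
#' @export
het_positions <- function(ls, locus) {
  aln <- ls$alignments[[locus]]
  if (is.null(aln)) stop("unknown locus: ", locus)
  hits <- lapply(aln, function(s) {
    which(strsplit(s, "")[[1]] %in% names(.iupac_rev))
  })
  sort(unique(unlist(hits)))
}

#' Read per-locus FASTA alignments into a locus set
#'
#' @param paths character vector of FASTA files, one per locus; the locus id
#'   is the file base name without extension.  IUPAC ambiguity codes mark
#'   unphased heterozygous sites.
#' @return A `locus_set`.
#' @export
read_locus_fasta <- function(paths) {
  alns <- list()
  for (p in paths) {
    seqs <- Biostrings::readBStringSet(p)
    v <- toupper(as.character(seqs))
    loc <- sub("\\.[^.]*$", "", basename(p))
    if (length(unique(nchar(v))) > 1L)
      stop("ragged alignment in locus ", loc)
    alns[[loc]] <- v
  }
  locus_set(alns)
}

#' Write a locus set as per-locus FASTA files
#' @param ls a `locus_set`.
#' @param dir output directory; one `<locus>.fasta` per locus.
#' @return Character vector of written paths.
#' @export
write_locus_fasta <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (loc in names(ls$alignments)) {
    p <- file.path(dir, paste0(loc, ".fasta"))
    s <- Biostrings::BStringSet(ls$alignments[[loc]])
    Biostrings::writeXStringSet(s, p)
    paths <- c(paths, p)
  }
  paths
}

#' Drop sites with any missing genotype
#'
#' SFS and F_st computations use listwise (per-site) deletion: a site with
#' any missing call is removed entirely.
#'
#' @param geno a `genotype_matrix`.
#' @param quiet suppress the message about dropped sites.
#' @return A `genotype_matrix` over complete sites, order preserved.
#' @export
drop_missing_sites <- function(geno, quiet = FALSE) {
  keep <- colSums(is.na(geno$calls)) == 0L
  if (!quiet && any(!keep))
    message("dropped ", sum(!keep), " site(s) with missing genotypes")
  subset_sites(geno, keep)
}
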