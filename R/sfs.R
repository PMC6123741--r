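#' @title Folded joint site-frequency spectra
#' @description Construction, resampling and serialisation of the folded
#'   joint 4-population SFS used by the demographic inference.
#' @name sfs
NULL

# Fold derived/alternate copy counts on the globally minor allele.
# cnt: n_sites x n_demes integer matrix; nvec: gene copies per deme.
# Rows with pooled count > n/2 are flipped; exact 50/50 ties take the
# lexicographically smaller of the tuple and its complement.
.fold_counts <- function(cnt, nvec) {
  if (nrow(cnt) == 0) return(cnt)
  pooled <- rowSums(cnt)
  ntot <- sum(nvec)
  flip <- pooled > ntot / 2
  tie <- pooled == ntot / 2
  if (any(tie)) {
    for (r in which(tie)) {
      a <- cnt[r, ]
      b <- nvec - a
      cmp <- a - b
      nz <- which(cmp != 0)
      if (length(nz) && cmp[nz[1]] > 0) flip[r] <- TRUE
    }
  }
  if (any(flip))
    cnt[flip, ] <- rep(nvec, each = sum(flip)) - cnt[flip, , drop = FALSE]
  cnt
}

# linear cell index (1-based, first axis fastest, matching R arrays)
.cell_index <- function(cnt, nvec) {
  mult <- cumprod(c(1, nvec[-length(nvec)] + 1))
  as.integer(1 + cnt %*% mult)
}

#' Construct the folded joint SFS of four populations
#'
#' Per retained SNP, alternate-allele copy counts are taken per deme and
#' folded on the globally (pooled) minor allele; exact 50/50 ties take the
#' lexicographically smaller of the entry and its complement.  Sites are
#' excluded if monomorphic in the pooled sample, if their pooled
#' minor-allele frequency is below `maf_min`, if any genotype is missing
#' (listwise deletion), or -- when `synonymous_only` -- if not flagged
#' synonymous.
#'
#' @param geno a `genotype_matrix`.
#' @param popmap a `population_map` covering all used individuals.
#' @param demes brood labels defining the four axes (default the four
#'   sampled broods).
#' @param maf_min pooled minor-allele-frequency threshold (default 0.05);
#'   sites strictly below it are excluded.
#' @param synonymous_only keep synonymous-flagged SNPs only (default TRUE).
#' @return A `joint_sfs`: counts array with axes `demes`, gene-copy counts
#'   `n`, and filter provenance.
#' @export
joint_folded_sfs <- function(geno, popmap, demes = c("II", "III", "XIX", "XXIII"),
                             maf_min = 0.05, synonymous_only = TRUE) {
  inds <- lapply(demes, function(d) individuals_of(popmap, brood = d))
  nper <- vapply(inds, length, integer(1))
  if (any(nper == 0))
    stop("deme(s) with zero sampled individuals: ",
         paste(demes[nper == 0], collapse = ", "))
  used <- unlist(inds)
  keep <- rep(TRUE, nrow(geno$sites))
  if (synonymous_only) keep <- keep & geno$sites$synonymous
  sub <- geno$calls[used, , drop = FALSE]
  keep <- keep & colSums(is.na(sub)) == 0L
  sub <- sub[, keep, drop = FALSE]
  nvec <- 2L * nper
  names(nvec) <- demes
  cnt <- matrix(0, nrow = ncol(sub), ncol = length(demes))
  for (k in seq_along(demes))
    cnt[, k] <- colSums(sub[inds[[k]], , drop = FALSE])
  ntot <- sum(nvec)
  pooled <- rowSums(cnt)
  poly <- pooled > 0 & pooled < ntot
  maf_ok <- pmin(pooled, ntot - pooled) / ntot >= maf_min
  cnt <- cnt[poly & maf_ok, , drop = FALSE]
  folded <- .fold_counts(cnt, nvec)
  counts <- array(0L, dim = nvec + 1L,
                  dimnames = lapply(nvec, function(n) as.character(0:n)))
  if (nrow(folded)) {
    tab <- tabulate(.cell_index(folded, nvec), nbins = prod(nvec + 1L))
    counts[] <- tab
  }
  structure(list(counts = counts, demes = demes, n = nvec,
                 provenance = list(maf_min = maf_min,
                                   maf_scope = "pooled",
                                   synonymous_only = synonymous_only,
                                   monomorphic_excluded = TRUE,
                                   bootstrap = FALSE)),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("joint_sfs over (", paste(x$demes, collapse = ", "), "), axes (",
      paste(x$n + 1L, collapse = ","), "), ", sum(x$counts),
      " SNPs retained\n", sep = "")
  invisible(x)
}

#' Total number of retained SNPs in an SFS
#' @param sfs a `joint_sfs`.
#' @return Integer sum of entries.
#' @export
sfs_total <- function(sfs) sum(sfs$counts)

#' Poisson bootstrap replicate of a joint SFS
#'
#' Each entry is replaced by an independent Poisson draw with mean equal to
#' the observed entry (the Poisson approximation to multinomial
#' resampling).
#'
#' @param sfs a `joint_sfs`.
#' @param seed optional integer seed.
#' @return A `joint_sfs` with provenance marked as bootstrap.
#' @export
poisson_bootstrap_sfs <- function(sfs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- sfs
  out$counts[] <- stats::rpois(length(sfs$counts), as.numeric(sfs$counts))
  out$provenance$bootstrap <- TRUE
  out
}

#' Write a joint SFS as TSV with a JSON provenance header
#' @param sfs a `joint_sfs`.
#' @param path output path.
#' @export
write_sfs <- function(sfs, path) {
  hdr <- paste0("#cicadapop_sfs ", jsonlite::toJSON(
    c(list(demes = sfs$demes, n = unname(sfs$n)), sfs$provenance),
    auto_unbox = TRUE))
  nz <- which(sfs$counts != 0L, arr.ind = TRUE)
  rows <- data.frame(nz - 1L, count = sfs$counts[sfs$counts != 0L])
  names(rows) <- c(paste0("i", seq_along(sfs$demes)), "count")
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(rows, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  invisible(path)
}

#' Read a joint SFS written by [write_sfs()]
#' @param path TSV path.
#' @return A `joint_sfs`.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#cicadapop_sfs "))
    stop("not a cicadapop SFS file: ", path)
  meta <- jsonlite::fromJSON(sub("^#cicadapop_sfs ", "", lines[1]))
  tab <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  nvec <- as.integer(meta$n)
  names(nvec) <- meta$demes
  counts <- array(0L, dim = nvec + 1L,
                  dimnames = lapply(nvec, function(n) as.character(0:n)))
  if (nrow(tab)) {
    idx <- as.matrix(tab[, seq_along(nvec), drop = FALSE])
    counts[.cell_index(idx, nvec)] <- tab$count
  }
  prov <- meta[setdiff(names(meta), c("demes", "n"))]
  structure(list(counts = counts, demes = meta$demes, n = nvec,
                 provenance = prov),
            class = "joint_sfs")
}
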