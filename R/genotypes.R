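#' Phased bi-allelic genotypes
#'
#' Container for fully phased genotypes of `q` individuals at `m` bi-allelic
#' SNPs: two haplotype matrices (0/1 allele codes, individuals in rows), the
#' sample identifiers and the marker map. All downstream haplotype machinery
#' (block enumeration, coding, relationship matrices) operates on this
#' container; phasing itself is an upstream task.
#'
#' @param hap1,hap2 Integer `q x m` matrices of 0/1 allele codes, the two
#'   phased haplotypes of each individual.
#' @param samples Character vector of `q` sample identifiers.
#' @param chrom,pos Marker map (defaults: one chromosome, positions `1..m`).
#' @param id Marker identifiers.
#' @param ref,alt Reference and alternate marker alleles (defaults "A"/"B").
#' @return An object of class `phased_geno`.
#' @export
phased_genotypes <- function(hap1, hap2, samples = NULL,
                             chrom = NULL, pos = NULL, id = NULL,
                             ref = NULL, alt = NULL) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  if (!all(dim(hap1) == dim(hap2))) abort("`hap1` and `hap2` must have identical dimensions")
  if (!all(hap1 %in% c(0L, 1L)) || !all(hap2 %in% c(0L, 1L))) {
    abort("haplotype matrices must contain 0/1 allele codes only")
  }
  q <- nrow(hap1); m <- ncol(hap1)
  samples <- samples %||% paste0("ind", seq_len(q))
  if (length(samples) != q) abort("`samples` must name every individual")
  structure(list(
    hap1 = matrix(as.integer(hap1), q, m),
    hap2 = matrix(as.integer(hap2), q, m),
    samples = as.character(samples),
    chrom = as.character(chrom %||% rep("1", m)),
    pos = as.integer(pos %||% seq_len(m)),
    id = as.character(id %||% paste0("snp", seq_len(m))),
    ref = as.character(ref %||% rep("A", m)),
    alt = as.character(alt %||% rep("B", m))
  ), class = "phased_geno")
}

#' @export
print.phased_geno <- function(x, ...) {
  cat(sprintf("<phased_geno> %d individuals x %d phased bi-allelic SNPs\n",
              nrow(x$hap1), ncol(x$hap1)))
  invisible(x)
}

#' @export
dim.phased_geno <- function(x) dim(x$hap1)

#' Subset individuals of a phased genotype set
#'
#' @param geno A [phased_genotypes()] object.
#' @param i Row (individual) index or sample names.
#' @return A `phased_geno` with the selected individuals.
#' @export
subset_individuals <- function(geno, i) {
  stopifnot(inherits(geno, "phased_geno"))
  if (is.character(i)) i <- match(i, geno$samples)
  phased_genotypes(geno$hap1[i, , drop = FALSE], geno$hap2[i, , drop = FALSE],
                   samples = geno$samples[i], chrom = geno$chrom,
                   pos = geno$pos, id = geno$id, ref = geno$ref, alt = geno$alt)
}
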