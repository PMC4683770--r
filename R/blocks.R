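#' Define haplotype blocks over the marker map
#'
#' Builds the block plan that groups SNPs into haplotype blocks, by exactly
#' one of three rules: a fixed number of SNPs per block (`n_snps`), a fixed
#' physical block length in base pairs (`block_length`), or explicit
#' intervals from a BED file (`bed`; 0-based half-open intervals, converted
#' to the 1-based marker coordinates). Blocks never span chromosomes;
#' intervals containing no SNP are dropped with a warning.
#'
#' @param geno A [phased_genotypes()] object.
#' @param n_snps Number of SNPs per block (last block of a chromosome may be
#'   shorter).
#' @param block_length Block length in base pairs; SNPs are binned by
#'   position from the first SNP of each chromosome.
#' @param bed Path to a BED file of block intervals.
#' @param allow_overlap Permit overlapping blocks (BED rule only).
#' @return Object of class `block_plan`: list of integer SNP-index vectors,
#'   one per block, with block names.
#' @export
plan_blocks <- function(geno, n_snps = NULL, block_length = NULL, bed = NULL,
                        allow_overlap = FALSE) {
  stopifnot(inherits(geno, "phased_geno"))
  rules <- c(!is.null(n_snps), !is.null(block_length), !is.null(bed))
  if (sum(rules) != 1L) {
    abort("specify exactly one of `n_snps`, `block_length`, `bed`")
  }
  m <- ncol(geno$hap1)
  ord <- order(geno$chrom, geno$pos)
  blocks <- list()
  if (!is.null(n_snps)) {
    n_snps <- as.integer(n_snps)
    if (n_snps < 1L) abort("`n_snps` must be at least 1")
    for (ch in unique(geno$chrom[ord])) {
      idx <- ord[geno$chrom[ord] == ch]
      grp <- ceiling(seq_along(idx) / n_snps)
      blocks <- c(blocks, unname(split(idx, grp)))
    }
  } else if (!is.null(block_length)) {
    block_length <- as.numeric(block_length)
    if (block_length <= 0) abort("`block_length` must be positive")
    for (ch in unique(geno$chrom[ord])) {
      idx <- ord[geno$chrom[ord] == ch]
      bin <- floor((geno$pos[idx] - min(geno$pos[idx])) / block_length)
      blocks <- c(blocks, unname(split(idx, bin)))
    }
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE) ||
        !requireNamespace("GenomicRanges", quietly = TRUE)) {
      abort("reading BED block definitions requires rtracklayer and GenomicRanges")
    }
    gr <- rtracklayer::import(bed, format = "BED")  # 1-based closed after import
    for (t in seq_along(gr)) {
      ch <- as.character(GenomicRanges::seqnames(gr)[t])
      lo <- GenomicRanges::start(gr)[t]
      hi <- GenomicRanges::end(gr)[t]
      idx <- which(geno$chrom == ch & geno$pos >= lo & geno$pos <= hi)
      if (length(idx) == 0L) {
        warn(sprintf("BED interval %s:%d-%d contains no SNP; dropped", ch, lo - 1L, hi))
        next
      }
      blocks <- c(blocks, list(idx[order(geno$pos[idx])]))
    }
    if (!allow_overlap && length(blocks) > 1L) {
      all_idx <- unlist(blocks)
      if (anyDuplicated(all_idx)) {
        abort("BED blocks overlap; pass `allow_overlap = TRUE` to permit this")
      }
    }
  }
  if (length(blocks) == 0L) abort("block plan is empty")
  names(blocks) <- paste0("block", seq_along(blocks))
  structure(blocks, class = "block_plan", m = m)
}

#' @export
print.block_plan <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("<block_plan> %d block(s), %d SNPs (sizes %s)\n",
              length(x), sum(sizes),
              paste(head(sizes, 8), collapse = ",")))
  invisible(x)
}
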