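#' Read a two-sample genotype table from a VCF
#'
#' Reads biallelic SNP genotypes for two named samples via the vcfR
#' parser. Indel records and records with more than one ALT allele are
#' dropped and counted in the `"dropped"` attribute; downstream counting
#' ([count_site_classes()]) additionally drops missing calls. Positions
#' are converted from VCF 1-based to the package's 0-based convention,
#' with the CHROM field carried as `cds_id`.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_a,sample_b Sample names; default the first two samples.
#' @return Tibble `cds_id`, `pos` (0-based), `gt_a`, `gt_b`.
#' @export
read_genotype_vcf <- function(path, sample_a = NULL, sample_b = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  sample_a <- sample_a %||% samples[1]
  sample_b <- sample_b %||% samples[2]
  stopifnot(all(c(sample_a, sample_b) %in% samples))
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE)
  out <- tibble::tibble(
    cds_id = fix[snp, "CHROM"],
    pos = as.integer(fix[snp, "POS"]) - 1L,
    gt_a = unname(gt[snp, sample_a]),
    gt_b = unname(gt[snp, sample_b])
  )
  attr(out, "dropped") <- c(non_snp_or_multiallelic = sum(!snp))
  out
}

#' Write a two-sample genotype table as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with GT-only genotypes for samples
#' `A` and `B`; REF/ALT are placeholders (`A`/`T`) unless columns `ref`
#' and `alt` are present. Positions are written 1-based.
#'
#' @param geno Tibble with `cds_id` (or a single `chrom` value), `pos`
#'   (0-based), `gt_a`, `gt_b`.
#' @param path Output path.
#' @export
write_genotype_vcf <- function(geno, path) {
  chrom <- if ("cds_id" %in% names(geno)) geno$cds_id else "chr1"
  ref <- if ("ref" %in% names(geno)) geno$ref else "A"
  alt <- if ("alt" %in% names(geno)) geno$alt else "T"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "A", "B",
      sep = "\t"
    )
  )
  body <- if (nrow(geno) == 0) {
    character(0)
  } else {
    paste(chrom, geno$pos + 1L, ".", ref, alt, ".", "PASS", ".",
      "GT", geno$gt_a, geno$gt_b,
      sep = "\t"
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write coding sequences as FASTA
#'
#' @param cds Named character vector of sequences (e.g. from
#'   [sim_pair_genotypes()]).
#' @param path Output path.
#' @export
write_cds_fasta <- function(cds, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(cds),
    filepath = path
  )
  invisible(path)
}
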