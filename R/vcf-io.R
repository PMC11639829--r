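#' Read genotypes from a VCF file
#'
#' Reads diploid GT calls from a VCF 4.x file via the Bioconductor
#' VariantAnnotation parser. Only biallelic SNV/indel records are kept;
#' multiallelic records are skipped with a warning giving the count. Phasing
#' is ignored: `0/1`, `1/0` and `0|1` all become dosage 1; `./.` (or any GT
#' containing `.`) becomes missing.
#'
#' @param vcf_path path to a VCF (.vcf or .vcf.gz).
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(vcf_path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf() requires the VariantAnnotation package")
  if (!file.exists(vcf_path)) stop("file not found: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  if (!"GT" %in% rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf))))
    stop("VCF has no GT FORMAT field: ", vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  keep <- n_alt == 1L
  if (any(!keep))
    warning("skipped ", sum(!keep), " multiallelic record(s) in ", vcf_path)
  if (!any(keep)) stop("no biallelic records in ", vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  rr <- rr[keep]
  dosage <- function(g) {
    if (grepl("\\.", g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
  }
  G <- t(apply(gt, c(1, 2), dosage))
  vid <- names(rr)
  if (is.null(vid) || anyDuplicated(vid))
    vid <- paste0(GenomicRanges::seqnames(rr), ":",
                  GenomicRanges::start(rr))
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    vid = vid,
    ref_allele = as.character(VariantAnnotation::ref(vcf))[keep],
    alt_allele = as.character(unlist(alt[keep])),
    stringsAsFactors = FALSE)
  genotype_dataset(G, variants, data.frame(sid = colnames(gt)))
}
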