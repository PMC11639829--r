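# PLINK 1 binary (.bed/.bim/.fam) reader/writer.
#
# Allele convention: .bim column 5 (A1) is the counted alt allele, column 6
# (A2) the ref allele, so the 2-bit code 0b00 (hom A1) is dosage 2 and 0b11
# (hom A2) is dosage 0; 0b01 is missing, 0b10 heterozygous. Both
# variant-major (third magic byte 0x01) and sample-major (0x00) payloads are
# accepted on read; files are always written variant-major.

.bed_magic <- as.raw(c(0x6c, 0x1b))

# 256 x 4 lookup: byte value -> 4 dosages (NA = missing), lowest bits first
.bed_decode_table <- local({
  codes <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  m <- matrix(NA_integer_, 256, 4)
  for (b in 0:255)
    for (j in 0:3)
      m[b + 1, j + 1] <- codes[bitwAnd(bitwShiftR(b, 2 * j), 3L) + 1L]
  m
})

#' Read a PLINK 1 binary fileset
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are read. Alternatively
#'   give the three paths explicitly.
#' @param bed_path,bim_path,fam_path explicit file paths (override `prefix`).
#' @return A [genotype_dataset()]. Breed labels are taken from the fam family
#'   id column when it is not `"0"`.
#' @details The .bim A1 allele (column 5) is interpreted as the counted alt
#'   allele. Payload size is checked against the .bim/.fam line counts before
#'   decoding; a mismatch is a consistency error.
#' @export
read_plink <- function(prefix = NULL, bed_path = NULL, bim_path = NULL,
                       fam_path = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed_path)) bed_path <- paste0(prefix, ".bed")
    if (is.null(bim_path)) bim_path <- paste0(prefix, ".bim")
    if (is.null(fam_path)) fam_path <- paste0(prefix, ".fam")
  }
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)

  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "vid", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic))
    stop("not a PLINK .bed file (bad magic bytes at offset 0): ", bed_path)
  mode <- as.integer(raw[3])
  if (!mode %in% c(0L, 1L))
    stop("unknown .bed storage mode byte at offset 2: ", mode)
  variant_major <- mode == 1L
  per_rec <- if (variant_major) ceiling(n / 4) else ceiling(m / 4)
  n_rec <- if (variant_major) m else n
  expect <- 3 + per_rec * n_rec
  if (length(raw) != expect)
    stop(".bed payload is ", length(raw) - 3, " bytes but .bim/.fam imply ",
         expect - 3, " (", m, " variants x ", n,
         " samples); inconsistent fileset")

  body <- as.integer(raw[-(1:3)])
  # decode all bytes at once, then reshape and trim the padding genotypes
  geno <- .bed_decode_table[body + 1L, , drop = FALSE]  # n_bytes x 4
  geno <- matrix(t(geno), nrow = 4 * per_rec)           # (4*per_rec) x n_rec
  if (variant_major) {
    G <- geno[seq_len(n), , drop = FALSE]               # samples x variants
  } else {
    G <- t(geno[seq_len(m), , drop = FALSE])            # records are samples
  }
  variants <- data.frame(chrom = bim$chrom, pos = bim$pos, vid = bim$vid,
                         ref_allele = bim$a2, alt_allele = bim$a1,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sid = fam[[2]],
                        breed = ifelse(fam[[1]] == "0", NA_character_,
                                       fam[[1]]),
                        stringsAsFactors = FALSE)
  genotype_dataset(G, variants, samples)
}

#' Write a genotype dataset as a PLINK 1 binary fileset
#'
#' Writes `<prefix>.bed` (variant-major), `<prefix>.bim` and `<prefix>.fam`.
#' The alt allele is written as A1 (bim column 5). Breed labels, when
#' present, become the fam family id (otherwise `"0"`).
#'
#' @param ds genotype_dataset.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$G); m <- ncol(ds$G)
  if (n == 0 || m == 0) stop("cannot write an empty dataset")
  bim <- data.frame(ds$variants$chrom, ds$variants$vid, 0,
                    ds$variants$pos, ds$variants$alt_allele,
                    ds$variants$ref_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(ifelse(is.na(ds$samples$breed), "0", ds$samples$breed),
                    ds$samples$sid, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  per_rec <- ceiling(n / 4)
  # dosage -> 2-bit code: 2->00, NA->01, 1->10, 0->11; padding uses 00
  code <- matrix(0L, nrow = 4 * per_rec, ncol = m)
  d <- ds$G
  cd <- matrix(3L, n, m)
  cd[d == 1L] <- 2L
  cd[d == 2L] <- 0L
  cd[is.na(d)] <- 1L
  code[seq_len(n), ] <- cd
  shift <- rep(c(1L, 4L, 16L, 64L), per_rec)
  byte_of <- rowsum(code * shift, rep(seq_len(per_rec), each = 4))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.bed_magic, as.raw(0x01)), con)
  writeBin(as.raw(byte_of), con)
  invisible(prefix)
}
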