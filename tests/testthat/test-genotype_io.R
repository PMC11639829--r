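test_that("hand-encoded .bed fileset decodes to the expected dosage matrix", {
  # 2 samples x 3 variants: [[0,1,2],[2,NA,0]]
  # variant-major, codes per (sample within variant): 2->00, 1->10, 0->11,
  # NA->01; byte = bits lowest-first
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  bytes <- as.raw(c(0x6c, 0x1b, 0x01,
                    0x03,   # v1: s1=0 (11), s2=2 (00) -> 0b0011
                    0x0e,   # v2: s1=1 (10), s2=NA (01) -> 0b0110 = 0x06? see below
                    0x0c))  # v3: s1=2 (00), s2=0 (11) -> 0b1100
  # recompute v2 carefully: s1 code 10 in bits (b1 b0) = (1,0) -> bits0,1 = 0,1
  # s2 code 01 -> bits2,3 = 1,0 ; byte = 0b0110 = 0x06
  bytes[5] <- as.raw(0x06)
  writeBin(bytes, paste0(prefix, ".bed"))
  writeLines(c("1\tv1\t0\t100\tG\tA", "1\tv2\t0\t200\tG\tA",
               "2\tv3\t0\t300\tG\tA"), paste0(prefix, ".bim"))
  writeLines(c("0\ts1\t0\t0\t0\t-9", "0\ts2\t0\t0\t0\t-9"),
             paste0(prefix, ".fam"))
  ds <- read_plink(prefix)
  expect_identical(unname(ds$G), rbind(c(0L, 1L, 2L), c(2L, NA, 0L)))
  expect_identical(ds$variants$vid, c("v1", "v2", "v3"))
  expect_identical(ds$samples$sid, c("s1", "s2"))
})

test_that("write_plink / read_plink round-trips a simulated dataset", {
  sim <- two_pop_sim(n_variants = 120, n = 8, seed = 11,
                     missing_rate = 0.05)
  ds <- sim$dataset
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "rt")
  write_plink(ds, prefix)
  back <- read_plink(prefix)
  expect_identical(back$G, ds$G)
  expect_identical(back$variants[c("chrom", "pos", "vid", "ref_allele",
                                   "alt_allele")],
                   ds$variants[c("chrom", "pos", "vid", "ref_allele",
                                 "alt_allele")])
  expect_identical(back$samples$sid, ds$samples$sid)
  expect_identical(back$samples$breed, ds$samples$breed)
  # byte-identical on re-write
  write_plink(back, paste0(prefix, "2"))
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 1e6),
                   readBin(paste0(prefix, "2.bed"), "raw", 1e6))
})

test_that("bed/fam inconsistencies and bad magic are format errors", {
  sim <- two_pop_sim(n_variants = 10, n = 4, seed = 3)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  write_plink(sim$dataset, prefix)
  # fam with an extra (5th) line while bed is sized for 4 samples
  fam <- readLines(paste0(prefix, ".fam"))
  writeLines(c(fam, "0\textra\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "inconsistent")
  writeLines(fam, paste0(prefix, ".fam"))
  bed <- readBin(paste0(prefix, ".bed"), "raw", 1e6)
  bed[1] <- as.raw(0x00)
  writeBin(bed, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
})

test_that("writing an empty dataset is rejected, a 1x1 dataset is valid", {
  dir <- withr::local_tempdir()
  one <- tiny_dataset(matrix(2L, 1, 1))
  ds0 <- one
  ds0$G <- one$G[, 0, drop = FALSE]
  ds0$variants <- one$variants[0, ]
  expect_error(write_plink(ds0, file.path(dir, "empty")), "empty")
  write_plink(one, file.path(dir, "one"))
  back <- read_plink(file.path(dir, "one"))
  expect_identical(unname(back$G), matrix(2L, 1, 1))
})

test_that("VCF genotypes map to dosages with phasing ignored", {
  skip_if_not_installed("VariantAnnotation")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tiny.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tA\tG\t.\t.\t.\tGT\t0|1\t1/0\t./.",
    "1\t300\trs3\tA\tG,T\t.\t.\t.\tGT\t0/0\t0/1\t0/2",
    "1\t400\trs4\tC\tT\t.\t.\t.\tGT\t1|1\t0|0\t0/1"), path)
  expect_warning(ds <- read_vcf(path), "multiallelic")
  expect_identical(ds$variants$vid, c("rs1", "rs2", "rs4"))
  expect_identical(unname(ds$G[, "rs1"]), c(0L, 1L, 2L))
  expect_identical(unname(ds$G[, "rs2"]), c(1L, 1L, NA))
  expect_identical(unname(ds$G[, "rs4"]), c(2L, 0L, 1L))
})

test_that("merge matches by vid, flips swapped alleles, drops ambiguous", {
  a <- tiny_dataset(rbind(c(0L, 1L, 2L, 0L)))
  b <- tiny_dataset(rbind(c(0L, 2L, 1L, 2L)))
  # v2 in b has ref/alt swapped -> dosage flipped; v3 ambiguous A/T pair
  b$variants$ref_allele <- c("A", "G", "A", "A")
  b$variants$alt_allele <- c("G", "A", "T", "G")
  a$variants$ref_allele[3] <- "T"; a$variants$alt_allele[3] <- "A"
  b$samples$sid <- "other"
  expect_warning(m <- merge_on_shared_variants(a, b), "ambiguous")
  expect_identical(m$variants$vid, c("v001", "v002", "v004"))
  expect_identical(unname(m$G[2, ]), c(0L, 0L, 2L))  # flipped at v002
  expect_identical(m$samples$sid, c("s001", "other"))

  # disjoint variant sets are a merge error
  c_ds <- tiny_dataset(rbind(c(0L, 1L)))
  c_ds$variants$vid <- c("x1", "x2")
  expect_error(merge_on_shared_variants(a, c_ds), "no shared variants")

  # self-merge doubles samples, keeps variants
  a2 <- a; a2$samples$sid <- "dup"
  m2 <- merge_on_shared_variants(a, a2)
  expect_identical(dim(m2$G), c(2L, 4L))
  expect_identical(m2$G[1, ], m2$G[2, ])
})

test_that("merge is associative on the shared variant set", {
  sim <- two_pop_sim(n_variants = 60, n = 3, seed = 5)
  mk <- function(vids, tag) {
    d <- subset_dataset(sim$dataset, samples = 1:2, variants = vids)
    d$samples$sid <- paste0(tag, d$samples$sid)
    d
  }
  a <- mk(1:40, "a"); b <- mk(15:55, "b"); c_ <- mk(25:60, "c")
  ab_c <- merge_on_shared_variants(merge_on_shared_variants(a, b), c_)
  a_bc <- merge_on_shared_variants(a, merge_on_shared_variants(b, c_))
  expect_setequal(ab_c$variants$vid, a_bc$variants$vid)
})
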