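#' Construct a genotype dataset
#'
#' The universal currency of the pipeline: a samples x variants matrix of
#' alt-allele dosages together with variant and sample metadata.
#'
#' @param G integer/numeric matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA` (missing).
#' @param variants data.frame with columns `chrom`, `pos`, `vid`,
#'   `ref_allele`, `alt_allele`; one row per column of `G`. `vid` must be
#'   unique and `ref_allele != alt_allele` at every variant.
#' @param samples data.frame with columns `sid` (unique), `breed`, `tier`
#'   (one of `"commercial"`, `"indigenous"`, `"candidate"`, `"unknown"`)
#'   and `group` (`"EUD"`, `"ASD"` or `NA`); one row per row of `G`.
#'   Missing columns are filled with `NA`/`"unknown"`.
#' @return An object of class `genotype_dataset` with elements `G`
#'   (samples x variants, dimnames set to sid/vid), `variants` and `samples`.
#' @examples
#' G <- rbind(a = c(0, 1, 2), b = c(2, NA, 0))
#' ds <- genotype_dataset(G,
#'   variants = data.frame(chrom = "1", pos = 1:3, vid = paste0("v", 1:3),
#'                         ref_allele = "A", alt_allele = "C"),
#'   samples  = data.frame(sid = c("a", "b")))
#' dim(ds$G)
#' @export
genotype_dataset <- function(G, variants, samples) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"breed" %in% names(samples)) samples$breed <- NA_character_
  if (!"tier" %in% names(samples)) samples$tier <- "unknown"
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  req_v <- c("chrom", "pos", "vid", "ref_allele", "alt_allele")
  if (!all(req_v %in% names(variants)))
    stop("variants must have columns: ", paste(req_v, collapse = ", "))
  if (nrow(variants) != ncol(G))
    stop("variant table has ", nrow(variants), " rows but G has ",
         ncol(G), " columns")
  if (nrow(samples) != nrow(G))
    stop("sample table has ", nrow(samples), " rows but G has ",
         nrow(G), " rows")
  if (anyDuplicated(variants$vid))
    stop("duplicated variant ids: ",
         paste(head(unique(variants$vid[duplicated(variants$vid)]), 5),
               collapse = ", "))
  if (anyDuplicated(samples$sid))
    stop("duplicated sample ids: ",
         paste(head(unique(samples$sid[duplicated(samples$sid)]), 5),
               collapse = ", "))
  if (any(variants$ref_allele == variants$alt_allele))
    stop("ref_allele equals alt_allele at ",
         sum(variants$ref_allele == variants$alt_allele), " variants")
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(head(unique(G[bad]), 3), collapse = ", "))
  rownames(samples) <- NULL
  rownames(variants) <- NULL
  dimnames(G) <- list(samples$sid, variants$vid)
  structure(list(G = G, variants = variants, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset: ", nrow(x$G), " samples x ", ncol(x$G),
      " variants\n", sep = "")
  miss <- mean(is.na(x$G))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  tiers <- table(x$samples$tier)
  cat("  tiers: ", paste(names(tiers), tiers, sep = "=", collapse = ", "),
      "\n", sep = "")
  br <- x$samples$breed
  if (any(!is.na(br)))
    cat("  breeds: ", length(unique(br[!is.na(br)])), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$G)

#' Subset a genotype dataset by samples and/or variants
#'
#' @param ds genotype_dataset.
#' @param samples,variants index vectors (integer, logical, or character
#'   matching `sid`/`vid`); `NULL` keeps everything.
#' @return genotype_dataset restricted to the selection, order preserved as
#'   given by the indices.
#' @export
subset_dataset <- function(ds, samples = NULL, variants = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(ds$G)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(ds$G)) else variants
  if (is.character(si)) si <- match(si, ds$samples$sid)
  if (is.character(vi)) vi <- match(vi, ds$variants$vid)
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(vi)) stop("unknown variant id in subset")
  genotype_dataset(ds$G[si, vi, drop = FALSE],
                   ds$variants[vi, , drop = FALSE],
                   ds$samples[si, , drop = FALSE])
}

#' Stack two datasets sharing an identical variant table
#'
#' Row-binds samples; both datasets must have the same variants in the same
#' order (use [merge_on_shared_variants()] otherwise).
#'
#' @param a,b genotype_dataset.
#' @return genotype_dataset with `a`'s samples followed by `b`'s.
#' @export
bind_samples <- function(a, b) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  if (!identical(a$variants$vid, b$variants$vid))
    stop("variant tables differ; use merge_on_shared_variants()")
  genotype_dataset(rbind(a$G, b$G), a$variants,
                   rbind(a$samples, b$samples))
}
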