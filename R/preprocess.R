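#' Per-variant alt-allele frequency
#'
#' @param ds genotype_dataset.
#' @return Numeric vector (length = variants) of alt-allele frequencies,
#'   `sum(dosage) / (2 * n_nonmissing)`. Variants with no non-missing call
#'   get `NA` with a warning.
#' @export
allele_frequency <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n_ok <- colSums(!is.na(ds$G))
  f <- colSums(ds$G, na.rm = TRUE) / (2 * n_ok)
  if (any(n_ok == 0)) {
    warning(sum(n_ok == 0), " variant(s) with all calls missing; ",
            "frequency set to NA")
    f[n_ok == 0] <- NA_real_
  }
  unname(f)
}

#' Pairwise genotypic LD (r-squared) between two dosage vectors
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples
#' (composite genotypic LD, the behaviour class of PLINK's
#' `--indep-pairwise`). Zero variance in either vector gives r² = 0.
#'
#' @param x,y dosage vectors of equal length (0/1/2/NA).
#' @return r² in `[0, 1]`.
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("need at least 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Windowed LD pruning
#'
#' Reproduces the `--indep-pairwise <window> <step> <r2>` variant filter:
#' within each sliding window of `window_size` variants (advanced by `step`,
#' never spanning chromosomes), pairs of retained variants with r² above
#' `r2_threshold` are broken up until none remain in any window position.
#'
#' The pair-removal dialect is deterministic: pairs within a window are
#' visited in index order and the member with the lower minor-allele
#' frequency is removed (tie: the higher variant index). This matches
#' PLINK's filter in spirit but need not reproduce its kept set
#' variant-for-variant.
#'
#' @param ds genotype_dataset with variants in genomic order within each
#'   chromosome.
#' @param window_size window width in variants (>= 2).
#' @param step window increment in variants (>= 1).
#' @param r2_threshold prune pairs with r² strictly above this value.
#' @return A list of class `prune_result`: `kept` and `removed` (integer
#'   column indices into `ds`), `kept_vid`, `removed_vid`, and `params`.
#' @export
ld_prune <- function(ds, window_size = 50, step = 10, r2_threshold = 0.5) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (step <= 0) stop("step must be positive")
  if (window_size < 2) stop("window_size must be at least 2")
  m <- ncol(ds$G)
  keep <- rep(TRUE, m)
  f <- suppressWarnings(allele_frequency(ds))
  maf <- pmin(f, 1 - f)
  maf[is.na(maf)] <- -1  # all-missing variants lose every tie

  for (chr in unique(ds$variants$chrom)) {
    idx <- which(ds$variants$chrom == chr)
    mc <- length(idx)
    if (mc < 2) next
    starts <- seq(1L, mc, by = step)
    starts <- starts[starts <= max(1L, mc - 1L)]
    for (s in starts) {
      w <- idx[s:min(s + window_size - 1L, mc)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      cw <- suppressWarnings(
        stats::cor(ds$G[, w, drop = FALSE],
                   use = "pairwise.complete.obs"))
      cw[!is.finite(cw)] <- 0
      r2 <- cw^2
      alive <- rep(TRUE, length(w))
      for (i in seq_len(length(w) - 1L)) {
        if (!alive[i]) next
        for (j in seq.int(i + 1L, length(w))) {
          if (!alive[j]) next
          if (r2[i, j] > r2_threshold) {
            drop_local <- if (maf[w[i]] < maf[w[j]]) i
                          else if (maf[w[j]] < maf[w[i]]) j
                          else j  # tie: higher variant index
            alive[drop_local] <- FALSE
            if (drop_local == i) break
          }
        }
      }
      keep[w[!alive]] <- FALSE
    }
  }
  structure(list(kept = which(keep), removed = which(!keep),
                 kept_vid = ds$variants$vid[keep],
                 removed_vid = ds$variants$vid[!keep],
                 params = list(window_size = window_size, step = step,
                               r2_threshold = r2_threshold)),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat("prune_result: kept ", length(x$kept), ", removed ",
      length(x$removed), " (window ", x$params$window_size, ", step ",
      x$params$step, ", r2 > ", x$params$r2_threshold, ")\n", sep = "")
  invisible(x)
}

#' Write PLINK-style prune lists
#'
#' Emits `<prefix>.prune.in` and `<prefix>.prune.out`, one variant id per
#' line, as produced by `--indep-pairwise`.
#'
#' @param pr prune_result from [ld_prune()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_prune_lists <- function(pr, prefix) {
  stopifnot(inherits(pr, "prune_result"))
  writeLines(pr$kept_vid, paste0(prefix, ".prune.in"))
  writeLines(pr$removed_vid, paste0(prefix, ".prune.out"))
  invisible(prefix)
}
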