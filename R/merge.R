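#' Merge two datasets on their shared variants
#'
#' Variants are matched by id (`vid`) by default, or by `(chrom, pos)` when
#' `by = "position"`. At shared variants the allele pairs are reconciled:
#'
#' * same ref/alt: dosages taken as-is;
#' * ref and alt swapped in `b`: `b`'s dosages are flipped (`d -> 2 - d`);
#' * strand-ambiguous pairs (A/T, C/G) that do not match exactly, and any
#'   other incompatible pair, are dropped (counted in the warning).
#'
#' The merged sample order is all of `a` then all of `b`.
#'
#' @param a,b genotype_dataset objects (non-empty).
#' @param by `"vid"` (default, chip-style data) or `"position"`.
#' @return genotype_dataset over the reconciled shared variants.
#' @export
merge_on_shared_variants <- function(a, b, by = c("vid", "position")) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  by <- match.arg(by)
  if (nrow(a$G) == 0 || nrow(b$G) == 0 || ncol(a$G) == 0 || ncol(b$G) == 0)
    stop("cannot merge an empty dataset")
  key <- function(v) {
    if (by == "vid") v$vid else paste(v$chrom, v$pos, sep = ":")
  }
  ib <- match(key(a$variants), key(b$variants))
  ia <- which(!is.na(ib))
  ib <- ib[ia]
  if (length(ia) == 0) stop("no shared variants between the two datasets")

  ra <- a$variants$ref_allele[ia]; aa <- a$variants$alt_allele[ia]
  rb <- b$variants$ref_allele[ib]; ab <- b$variants$alt_allele[ib]
  same <- ra == rb & aa == ab
  swapped <- ra == ab & aa == rb
  ambiguous <- paste(pmin(ra, aa), pmax(ra, aa)) %in% c("A T", "C G")
  usable <- same | (swapped & !ambiguous)
  n_drop <- sum(!usable)
  if (n_drop > 0)
    warning(n_drop, " shared variant(s) dropped for incompatible or ",
            "strand-ambiguous allele pairs")
  if (!any(usable)) stop("no shared variants with compatible alleles")

  ia <- ia[usable]; ib <- ib[usable]
  flip <- swapped[usable]
  Gb <- b$G[, ib, drop = FALSE]
  if (any(flip)) Gb[, flip] <- 2L - Gb[, flip]
  genotype_dataset(rbind(a$G[, ia, drop = FALSE], Gb),
                   a$variants[ia, , drop = FALSE],
                   rbind(a$samples, b$samples))
}
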