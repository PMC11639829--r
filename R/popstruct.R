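#' Principal component analysis of genotypes
#'
#' Standardises dosages as `(d - 2f) / sqrt(2 f (1 - f))` (the
#' PLINK/Patterson convention; plain centering with `scale = FALSE`),
#' imputes missing entries to 0 after centering, and eigendecomposes the
#' sample x sample covariance. Monomorphic (and all-missing) variants carry
#' no information and are dropped with a message.
#'
#' @param ds genotype_dataset.
#' @param n_components number of PCs to return (<= min(samples, variants)).
#' @param scale standardise by `sqrt(2 f (1 - f))` (default) or centre only.
#' @return Object of class `pca_result`: `coords` (samples x n_components,
#'   eigenvector scaled by the square root of its eigenvalue, rownames =
#'   sid), `explained` (share of total variance per component), `values`
#'   (eigenvalues).
#' @export
pca_genotypes <- function(ds, n_components = 10, scale = TRUE) {
  stopifnot(inherits(ds, "genotype_dataset"))
  f <- suppressWarnings(allele_frequency(ds))
  poly <- !is.na(f) & f > 0 & f < 1
  if (!any(poly)) stop("no polymorphic variants usable for PCA")
  if (any(!poly))
    message(sum(!poly), " monomorphic/all-missing variant(s) dropped from PCA")
  X <- ds$G[, poly, drop = FALSE]
  f <- f[poly]
  X <- sweep(X, 2, 2 * f)
  if (scale) X <- sweep(X, 2, sqrt(2 * f * (1 - f)), "/")
  X[is.na(X)] <- 0
  n <- nrow(X)
  n_components <- min(n_components, n, ncol(X))
  C <- tcrossprod(X) / ncol(X)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_components)]), n_components)
  rownames(coords) <- ds$samples$sid
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(list(coords = coords,
                 explained = vals / sum(vals),
                 values = vals),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: ", nrow(x$coords), " samples, ", ncol(x$coords),
      " components\n  explained: ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained,
                                                ncol(x$coords))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise identity-by-state distance matrix
#'
#' `D[i,j] = 1 - mean_m(IBS(d_i, d_j) / 2)` over pairwise non-missing
#' variants, with `IBS = 2 - |d_i - d_j|` — the `1 - DST` distance that
#' PLINK's `--genome` reports and that distance-tree builders conventionally
#' consume.
#'
#' @param ds genotype_dataset.
#' @return Object of class `dist_matrix`: `D` (symmetric, zero diagonal,
#'   dimnames = sid) and `labels`. Pairs with no shared non-missing variant
#'   get `NA` with a warning.
#' @export
ibs_distance <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  G <- ds$G
  ok <- !is.na(G)
  # sum_m |d_i - d_j| via dosage-class indicator cross-products
  I0 <- (G == 0L) & ok; I1 <- (G == 1L) & ok; I2 <- (G == 2L) & ok
  c01 <- tcrossprod(I0 * 1, I1 * 1)
  c02 <- tcrossprod(I0 * 1, I2 * 1)
  c12 <- tcrossprod(I1 * 1, I2 * 1)
  absdiff <- c01 + t(c01) + c12 + t(c12) + 2 * (c02 + t(c02))
  M_ij <- tcrossprod(ok * 1)
  if (any(M_ij == 0 & upper.tri(M_ij)))
    warning(sum(M_ij == 0 & upper.tri(M_ij)),
            " sample pair(s) share no non-missing variant; distance NA")
  D <- absdiff / (2 * M_ij)
  D[M_ij == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(ds$samples$sid, ds$samples$sid)
  structure(list(D = D, labels = ds$samples$sid), class = "dist_matrix")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape), with negative branch lengths clamped
#' to zero by default as distance-tree viewers expect.
#'
#' @param dm dist_matrix from [ibs_distance()], a `dist`, or a square
#'   symmetric matrix with dimnames.
#' @param clamp_negative set negative branch lengths to 0 (default TRUE).
#' @return An [ape::nj()] `phylo` tree.
#' @export
nj_tree <- function(dm, clamp_negative = TRUE) {
  D <- if (inherits(dm, "dist_matrix")) dm$D else as.matrix(dm)
  if (nrow(D) < 3) stop("neighbour joining needs at least 3 samples")
  if (anyNA(D)) stop("distance matrix contains NA")
  tree <- ape::nj(stats::as.dist(D))
  if (clamp_negative) tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Write a tree in Newick format
#'
#' @param tree `phylo` object.
#' @param path output file (.nwk).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as a square TSV
#'
#' @param dm dist_matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  df <- data.frame(sid = dm$labels, dm$D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
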