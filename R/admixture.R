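#' Log-likelihood of the binomial admixture model
#'
#' For ancestry proportions `Q` (samples x K) and component alt-allele
#' frequencies `F` (K x variants), each non-missing dosage `d` contributes
#' `d * log(p) + (2 - d) * log(1 - p)` with `p = sum_k Q[i,k] F[k,m]`
#' clamped to `[1e-9, 1 - 1e-9]`; the binomial coefficient is a constant
#' and omitted.
#'
#' @param ds genotype_dataset.
#' @param Q samples x K matrix, rows on the probability simplex.
#' @param F K x variants matrix of frequencies in `[0, 1]`.
#' @return Scalar log-likelihood (natural log).
#' @export
admixture_loglik <- function(ds, Q, F) {
  stopifnot(inherits(ds, "genotype_dataset"))
  Q <- as.matrix(Q); F <- as.matrix(F)
  if (nrow(Q) != nrow(ds$G) || ncol(F) != ncol(ds$G) || ncol(Q) != nrow(F))
    stop("dimension mismatch: G is ", nrow(ds$G), "x", ncol(ds$G),
         ", Q is ", nrow(Q), "x", ncol(Q), ", F is ", nrow(F), "x", ncol(F))
  admixture_loglik_cpp(.dosage_for_em(ds), Q, F)
}

# samples x variants double matrix with missing encoded as -9 for the C++ core
.dosage_for_em <- function(ds) {
  D <- ds$G
  storage.mode(D) <- "double"
  D[is.na(D)] <- -9
  D
}

#' Fit the admixture model by expectation-maximisation
#'
#' Unsupervised maximum-likelihood estimation of per-sample ancestry
#' proportions `Q` and per-component allele frequencies `F` for a given
#' number of ancestral components `K`, by multiplicative EM updates on the
#' binomial admixture likelihood (see [admixture_loglik()]). This is the
#' computation usually delegated to the ADMIXTURE program; the EM engine
#' shares its stationary points with ADMIXTURE's accelerated optimiser.
#'
#' Initialisation is fully seeded: `Q` rows are drawn from a symmetric
#' Dirichlet(1) and `F` rows are the observed allele frequencies perturbed
#' by Uniform(-0.05, 0.05), clamped to `[1e-6, 1 - 1e-6]`. With
#' `n_restarts > 1` the restart with the best final log-likelihood wins.
#'
#' @param ds genotype_dataset.
#' @param K number of ancestral components (>= 1, <= number of samples).
#' @param seed integer seed; restart `r` uses `seed + r - 1`.
#' @param tol stop when the relative log-likelihood increase drops below
#'   this value.
#' @param max_iter iteration cap per restart.
#' @param n_restarts independent EM restarts.
#' @return An object of class `admixture_fit`: `Q` (samples x K, rownames =
#'   sid), `F` (K x variants, colnames = vid), `loglik_trace`,
#'   `converged`, `seed`, `K`.
#' @examples
#' ds <- simulate_panel(sim_config(n_variants = 200,
#'   breeds = list(list(name = "A", group = "EUD", fst = 0.3, n = 15),
#'                 list(name = "B", group = "ASD", fst = 0.3, n = 15)),
#'   seed = 7))$dataset
#' fit <- fit_admixture(ds, K = 2, seed = 1)
#' head(round(fit$Q, 2))
#' @export
fit_admixture <- function(ds, K, seed = 1L, tol = 1e-6, max_iter = 2000L,
                          n_restarts = 1L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (K < 1) stop("K must be at least 1")
  if (nrow(ds$G) < K) stop("need at least K samples (", K, ")")
  D <- .dosage_for_em(ds)
  f <- suppressWarnings(allele_frequency(ds))
  f[is.na(f)] <- 0.5

  best <- NULL
  for (r in seq_len(n_restarts)) {
    run_seed <- as.integer(seed) + r - 1L
    init <- withr_seed(run_seed, {
      Q0 <- matrix(stats::rexp(nrow(D) * K), ncol = K)
      Q0 <- Q0 / rowSums(Q0)  # Dirichlet(1) rows
      F0 <- matrix(rep(f, each = K), nrow = K) +
        matrix(stats::runif(K * ncol(D), -0.05, 0.05), nrow = K)
      list(Q0 = Q0, F0 = pmin(pmax(F0, 1e-6), 1 - 1e-6))
    })
    em <- admixture_em_cpp(D, init$Q0, init$F0, tol, as.integer(max_iter))
    ll <- em$loglik_trace[length(em$loglik_trace)]
    if (is.null(best) || ll > best$ll)
      best <- list(em = em, ll = ll, seed = run_seed)
  }
  Q <- best$em$Q
  F <- best$em$F
  dimnames(Q) <- list(ds$samples$sid, NULL)
  dimnames(F) <- list(NULL, ds$variants$vid)
  structure(list(Q = Q, F = F, loglik_trace = best$em$loglik_trace,
                 converged = best$em$converged, seed = best$seed, K = K),
            class = "admixture_fit")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.admixture_fit <- function(x, ...) {
  ll <- x$loglik_trace[length(x$loglik_trace)]
  cat("admixture_fit: K = ", x$K, ", ", nrow(x$Q), " samples, ",
      ncol(x$F), " variants\n  loglik = ", format(ll), " after ",
      length(x$loglik_trace) - 1, " EM iterations (",
      if (x$converged) "converged" else "iteration cap", ")\n", sep = "")
  invisible(x)
}

#' Write ADMIXTURE-compatible Q and P files
#'
#' `<prefix>.<K>.Q` holds the samples x K ancestry proportions and
#' `<prefix>.<K>.P` the variants x K component allele frequencies, both
#' space-separated without headers, matching the ADMIXTURE output layout.
#'
#' @param fit admixture_fit.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_admixture_files <- function(fit, prefix) {
  stopifnot(inherits(fit, "admixture_fit"))
  qf <- paste0(prefix, ".", fit$K, ".Q")
  pf <- paste0(prefix, ".", fit$K, ".P")
  utils::write.table(format(fit$Q, digits = 6, trim = TRUE), qf,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(format(t(fit$F), digits = 6, trim = TRUE), pf,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
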