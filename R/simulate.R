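#' Simulation configuration for a multi-breed genotype panel
#'
#' Describes the stated world the simulator generates: ancestral allele
#' frequencies, a two-level Balding-Nichols drift hierarchy (continental
#' group, then breed within group), purebred sample sizes, crossbreeding
#' schemes, planted contaminants, genotype missingness and a seed.
#'
#' @param n_variants number of variants, spread uniformly over
#'   `n_chromosomes` pseudo-chromosomes.
#' @param ancestral_freq_range interval the ancestral frequency is drawn
#'   from, uniformly.
#' @param group_fst drift of each continental group (EUD, ASD) away from the
#'   shared ancestral pool. `0` collapses the hierarchy so breed frequencies
#'   are drawn directly around the ancestral frequency.
#' @param breeds list of `list(name, group, fst, n)` entries: breed label,
#'   group ("EUD"/"ASD"), Balding-Nichols drift of the breed away from its
#'   group pool, and purebred sample count. Commercial tier is inferred from
#'   the group (EUD -> commercial, ASD -> indigenous) unless a `tier` entry
#'   is given.
#' @param crosses list of `list(name, proportions, n, scheme)` entries;
#'   `proportions` is a named breed->fraction vector summing to 1; `scheme`
#'   is `"f1_haploid"` (pedigree draw, one allele per parental side) or
#'   `"binomial_admixed"` (dosage ~ Binomial(2, sum_b q_b p_bm)).
#' @param contaminants list of `list(name, labelled_as, proportions, n)`
#'   entries: samples generated as `binomial_admixed` crosses of
#'   `proportions` but *labelled* with breed `labelled_as` (planted
#'   mislabelled/admixed individuals for testing panel curation). An
#'   optional `concentration` entry makes the admixture heterogeneous:
#'   individual proportions are drawn from
#'   Dirichlet(`concentration * proportions`), mimicking real introgressed
#'   breeds whose members vary in commercial ancestry (smaller values =
#'   more variable individuals).
#' @param missing_rate fraction of calls masked at random.
#' @param n_chromosomes pseudo-chromosome count (pig autosomes: 18).
#' @param seed integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_variants = 3000,
                       ancestral_freq_range = c(0.05, 0.95),
                       group_fst = 0.2,
                       breeds = default_breeds(),
                       crosses = list(),
                       contaminants = list(),
                       missing_rate = 0.01,
                       n_chromosomes = 18,
                       seed = 1L) {
  stopifnot(n_variants >= 1,
            length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            group_fst >= 0, group_fst < 1,
            missing_rate >= 0, missing_rate < 1)
  for (b in breeds) {
    stopifnot(!is.null(b$name), b$group %in% c("EUD", "ASD"),
              b$fst > 0, b$fst < 1, b$n >= 0)
  }
  for (cr in crosses) {
    stopifnot(!is.null(cr$name), cr$n >= 0)
    if (abs(sum(cr$proportions) - 1) > 1e-8)
      stop("cross '", cr$name, "': proportions must sum to 1")
    if (!all(names(cr$proportions) %in% vapply(breeds, `[[`, "", "name")))
      stop("cross '", cr$name, "' references an unknown breed")
  }
  structure(list(n_variants = as.integer(n_variants),
                 ancestral_freq_range = ancestral_freq_range,
                 group_fst = group_fst, breeds = breeds, crosses = crosses,
                 contaminants = contaminants, missing_rate = missing_rate,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulated panel composition
#'
#' Three commercial-style European breeds (Duroc/Landrace/Yorkshire stand-ins,
#' 30 samples each, strong line drift) and five indigenous-style Asian breeds
#' (40 samples each, milder drift), all with breed-level drift inside the
#' 0.1-0.25 band typical of differentiated pig breeds.
#'
#' @return list of breed definitions for [sim_config()].
#' @export
default_breeds <- function() {
  list(
    list(name = "D", group = "EUD", fst = 0.25, n = 30),
    list(name = "L", group = "EUD", fst = 0.22, n = 30),
    list(name = "Y", group = "EUD", fst = 0.20, n = 30),
    list(name = "IB1", group = "ASD", fst = 0.10, n = 40),
    list(name = "IB2", group = "ASD", fst = 0.12, n = 40),
    list(name = "IB3", group = "ASD", fst = 0.15, n = 40),
    list(name = "IB4", group = "ASD", fst = 0.18, n = 40),
    list(name = "IB5", group = "ASD", fst = 0.13, n = 40))
}

# Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F) around pool frequency p
.bn_draw <- function(p, fst) {
  stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Draw per-breed allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are Uniform over `ancestral_freq_range`; each
#' group pool drifts from the ancestral pool with `group_fst` (skipped when
#' 0); each breed drifts from its group pool with its own `fst`. Frequencies
#' are clipped away from 0/1 by 1e-6 so downstream binomial draws stay
#' non-degenerate.
#'
#' @param cfg sim_config. The draw consumes the current RNG stream; seed it
#'   (or use [simulate_panel()], which seeds from `cfg$seed`).
#' @return list: `breed_freqs` (breed x variant matrix, rownames = breed),
#'   `ancestral` (vector), `group_freqs` (group x variant matrix).
#' @export
simulate_breed_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$n_variants
  anc <- stats::runif(m, cfg$ancestral_freq_range[1],
                      cfg$ancestral_freq_range[2])
  groups <- unique(vapply(cfg$breeds, `[[`, "", "group"))
  gf <- matrix(rep(anc, each = length(groups)), nrow = length(groups),
               dimnames = list(groups, NULL))
  if (cfg$group_fst > 0)
    for (g in groups) gf[g, ] <- .bn_draw(anc, cfg$group_fst)
  bf <- matrix(NA_real_, length(cfg$breeds), m,
               dimnames = list(vapply(cfg$breeds, `[[`, "", "name"), NULL))
  for (b in cfg$breeds)
    bf[b$name, ] <- .bn_draw(gf[b$group, ], b$fst)
  bf <- pmin(pmax(bf, 1e-6), 1 - 1e-6)
  list(breed_freqs = bf, ancestral = anc, group_freqs = gf)
}

#' Draw purebred genotypes
#'
#' Dosages are Binomial(2, p) at each breed frequency (Hardy-Weinberg within
#' breed, linkage-free).
#'
#' @param breed_freqs breed x variant frequency matrix.
#' @param breed breed name (row of `breed_freqs`).
#' @param n number of individuals.
#' @return n x variants integer dosage matrix.
#' @export
sample_purebred <- function(breed_freqs, breed, n) {
  p <- breed_freqs[breed, ]
  matrix(stats::rbinom(n * length(p), 2, rep(p, each = n)), nrow = n)
}

#' Draw crossbred genotypes with known breed composition
#'
#' `f1_haploid` draws each allele from one parental side of a pedigree:
#' a 50/50 cross takes one allele from each parent breed; a
#' `c(A = .5, B = .25, C = .25)` terminal cross takes one allele from A and
#' the other from B or C by a per-locus fair coin (the classic
#' D x (L x Y) scheme). Other proportion vectors are not expressible as a
#' two-sided pedigree and are rejected with a pointer to
#' `binomial_admixed`, which draws dosage ~ Binomial(2, sum_b q_b p_bm) for
#' arbitrary proportions.
#'
#' @param breed_freqs breed x variant frequency matrix.
#' @param proportions named breed->fraction vector summing to 1.
#' @param n number of individuals.
#' @param scheme `"f1_haploid"` or `"binomial_admixed"`.
#' @return list: `G` (n x variants integer matrix), `truth` (the
#'   proportions, normalised named vector).
#' @export
sample_crossbred <- function(breed_freqs, proportions, n,
                             scheme = c("f1_haploid", "binomial_admixed")) {
  scheme <- match.arg(scheme)
  q <- proportions / sum(proportions)
  if (!all(names(q) %in% rownames(breed_freqs)))
    stop("unknown breed in proportions")
  m <- ncol(breed_freqs)
  if (scheme == "binomial_admixed") {
    p_mix <- as.vector(q %*% breed_freqs[names(q), , drop = FALSE])
    G <- matrix(stats::rbinom(n * m, 2, rep(p_mix, each = n)), nrow = n)
  } else {
    sides <- .pedigree_sides(q)
    draw_side <- function(side) {
      # side: named vector of within-side breed weights summing to 1
      if (length(side) == 1) {
        p <- breed_freqs[names(side), ]
        matrix(stats::rbinom(n * m, 1, rep(p, each = n)), nrow = n)
      } else {
        # per-locus, per-individual choice of the contributing breed
        pick <- matrix(sample(names(side), n * m, replace = TRUE,
                              prob = side), nrow = n)
        p <- matrix(breed_freqs[cbind(match(pick, rownames(breed_freqs)),
                                      rep(seq_len(m), each = n))], nrow = n)
        matrix(stats::rbinom(n * m, 1, as.vector(p)), nrow = n)
      }
    }
    G <- draw_side(sides[[1]]) + draw_side(sides[[2]])
  }
  list(G = G, truth = q)
}

# split cross proportions into two parental haploid sides, or fail
.pedigree_sides <- function(q) {
  q <- q[q > 0]
  if (length(q) == 2 && all(abs(q - 0.5) < 1e-8)) {
    sides <- list(q[1] * 2, q[2] * 2)
  } else if (length(q) == 3 && sum(abs(q - 0.5) < 1e-8) == 1 &&
             sum(abs(q - 0.25) < 1e-8) == 2) {
    a <- names(q)[abs(q - 0.5) < 1e-8]
    bc <- names(q)[abs(q - 0.25) < 1e-8]
    sides <- list(stats::setNames(1, a),
                  stats::setNames(c(0.5, 0.5), bc))
  } else {
    stop("proportions not expressible as a two-sided pedigree; ",
         "use scheme = 'binomial_admixed'")
  }
  lapply(sides, function(s) stats::setNames(as.numeric(s), names(s)))
}

#' Simulate a complete labelled panel with known truth
#'
#' Assembles purebreds, crossbreds and planted contaminants from one
#' Balding-Nichols frequency draw, applies the missingness mask, and
#' attaches truth (per-sample breed composition). Deterministic given
#' `cfg$seed`.
#'
#' @param cfg sim_config.
#' @return Object of class `simulated_panel`: `dataset`
#'   (genotype_dataset with breed/tier/group labels; contaminants carry
#'   their *claimed* label), `truth` (samples x breeds matrix of true
#'   proportions, rows summing to 1), `breed_freqs`, `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr_seed(cfg$seed, {
    fr <- simulate_breed_freqs(cfg)
    bf <- fr$breed_freqs
    m <- cfg$n_variants
    breed_names <- rownames(bf)

    Gs <- list(); meta <- list(); truth <- list()
    one_hot <- function(b) {
      v <- stats::setNames(numeric(length(breed_names)), breed_names)
      v[b] <- 1
      v
    }
    add <- function(G, sid, breed, tier, group, tr) {
      i <- length(Gs) + 1L
      Gs[[i]] <<- G
      meta[[i]] <<- data.frame(sid = sid, breed = breed, tier = tier,
                               group = group, stringsAsFactors = FALSE)
      truth[[i]] <<- matrix(rep(tr, each = nrow(G)), nrow = nrow(G),
                            dimnames = list(sid, names(tr)))
    }
    for (b in cfg$breeds) {
      if (b$n == 0) next
      tier <- if (!is.null(b$tier)) b$tier
              else if (b$group == "EUD") "commercial" else "indigenous"
      add(sample_purebred(bf, b$name, b$n),
          sprintf("%s_%03d", b$name, seq_len(b$n)),
          b$name, tier, b$group, one_hot(b$name))
    }
    for (cr in cfg$crosses) {
      if (cr$n == 0) next
      scheme <- if (is.null(cr$scheme)) "f1_haploid" else cr$scheme
      sc <- sample_crossbred(bf, cr$proportions, cr$n, scheme)
      tr <- stats::setNames(numeric(length(breed_names)), breed_names)
      tr[names(sc$truth)] <- sc$truth
      add(sc$G, sprintf("%s_%03d", cr$name, seq_len(cr$n)),
          cr$name, "candidate", NA_character_, tr)
    }
    for (ct in cfg$contaminants) {
      if (ct$n == 0) next
      lab <- ct$labelled_as
      grp <- vapply(cfg$breeds, function(b) b$group, "")[
        match(lab, breed_names)]
      tier <- if (grp == "EUD") "commercial" else "indigenous"
      sids <- sprintf("%s_%03d", ct$name, seq_len(ct$n))
      if (is.null(ct$concentration)) {
        # homogeneous admixture: every individual shares the proportions
        sc <- sample_crossbred(bf, ct$proportions, ct$n,
                               "binomial_admixed")
        tr <- stats::setNames(numeric(length(breed_names)), breed_names)
        tr[names(sc$truth)] <- sc$truth
        add(sc$G, sids, lab, tier, grp, tr)
      } else {
        # heterogeneous admixture, as in real introgressed breeds:
        # individual proportions ~ Dirichlet(concentration * base)
        base <- ct$proportions / sum(ct$proportions)
        qs <- sapply(ct$concentration * base, function(a)
          stats::rgamma(ct$n, shape = a))
        qs <- matrix(qs, nrow = ct$n)
        qs <- qs / rowSums(qs)
        G <- matrix(0L, ct$n, m)
        tr <- matrix(0, ct$n, length(breed_names),
                     dimnames = list(sids, breed_names))
        for (ii in seq_len(ct$n)) {
          qi <- stats::setNames(qs[ii, ], names(base))
          sc <- sample_crossbred(bf, qi, 1, "binomial_admixed")
          G[ii, ] <- sc$G
          tr[ii, names(qi)] <- qi
        }
        i <- length(Gs) + 1L
        Gs[[i]] <- G
        meta[[i]] <- data.frame(sid = sids, breed = lab, tier = tier,
                                group = grp, stringsAsFactors = FALSE)
        truth[[i]] <- tr
      }
    }
    if (length(Gs) == 0) stop("configuration generates no samples")

    G <- do.call(rbind, Gs)
    samples <- do.call(rbind, meta)
    truth <- do.call(rbind, truth)
    if (cfg$missing_rate > 0)
      G[matrix(stats::runif(length(G)) < cfg$missing_rate,
               nrow = nrow(G))] <- NA_integer_

    chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
    pos <- stats::ave(chrom, chrom, FUN = seq_along) * 1000L
    variants <- data.frame(chrom = as.character(chrom), pos = pos,
                           vid = sprintf("snp%05d", seq_len(m)),
                           ref_allele = "A", alt_allele = "G",
                           stringsAsFactors = FALSE)
    structure(list(dataset = genotype_dataset(G, variants, samples),
                   truth = truth, breed_freqs = bf, config = cfg),
              class = "simulated_panel")
  })
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat("simulated_panel (seed ", x$config$seed, "):\n", sep = "")
  print(x$dataset)
  invisible(x)
}

#' Write the simulation truth table as TSV
#'
#' @param sim simulated_panel.
#' @param path output file; columns sid, breed, tier, then one true
#'   proportion column per breed.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_panel"))
  df <- cbind(sim$dataset$samples[c("sid", "breed", "tier")],
              as.data.frame(sim$truth))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
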