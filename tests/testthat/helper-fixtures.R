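# Small in-code fixtures shared across test files.

# hand-built dataset: n samples x m variants, dosages supplied row-wise
tiny_dataset <- function(G, chrom = NULL, breed = NULL, tier = NULL,
                         group = NULL) {
  G <- as.matrix(G)
  n <- nrow(G); m <- ncol(G)
  variants <- data.frame(
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    pos = seq_len(m) * 100L,
    vid = sprintf("v%03d", seq_len(m)),
    ref_allele = "A", alt_allele = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sid = sprintf("s%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (!is.null(breed)) samples$breed <- breed
  if (!is.null(tier)) samples$tier <- tier
  if (!is.null(group)) samples$group <- group
  genotype_dataset(G, variants, samples)
}

# small two-population panel used by several admixture tests
two_pop_sim <- function(n_variants = 300, n = 15, fst = 0.3, seed = 42,
                        missing_rate = 0) {
  simulate_panel(sim_config(
    n_variants = n_variants, group_fst = 0,
    breeds = list(list(name = "A", group = "EUD", fst = fst, n = n),
                  list(name = "B", group = "ASD", fst = fst, n = n)),
    missing_rate = missing_rate, seed = seed))
}

# align columns of estimated Q to truth columns by best mean match
align_Q <- function(Q, truth) {
  K <- ncol(Q)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_err <- Inf
  for (p in perms(seq_len(K))) {
    err <- mean(abs(Q[, p, drop = FALSE] - truth))
    if (err < best_err) { best_err <- err; best <- p }
  }
  Q[, best, drop = FALSE]
}

# Hudson Fst estimator between two frequency vectors given haploid
# sample sizes (here: frequencies are known, use the parametric form)
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# shared simulated panel: 3 clean commercial breeds, 2 clean indigenous
# breeds, 1 "indigenous" breed that is really a heterogeneous mixture with
# mostly Duroc genomes (the Meishan/AQSW-style mixed breed the mean-P_IB
# rule exists for), plus planted 30%-commercial-admixed individuals inside
# a clean breed
panel_sim_with_contamination <- function(seed = 101) {
  cfg <- sim_config(
    n_variants = 1200,
    breeds = list(
      list(name = "D", group = "EUD", fst = 0.25, n = 40),
      list(name = "L", group = "EUD", fst = 0.22, n = 40),
      list(name = "Y", group = "EUD", fst = 0.20, n = 40),
      list(name = "IB1", group = "ASD", fst = 0.12, n = 30),
      list(name = "IB2", group = "ASD", fst = 0.15, n = 30),
      # zero-sample pool anchoring the mixed breed's indigenous side
      list(name = "MIX", group = "ASD", fst = 0.12, n = 0)),
    contaminants = list(
      # mixed "indigenous" breed: commercial ancestry from all three
      # commercial lines dominates on average, no single origin reaching
      # half, and individuals vary in their admixture fractions
      list(name = "fake", labelled_as = "MIX",
           proportions = c(D = 0.3, L = 0.25, Y = 0.15, MIX = 0.3),
           n = 25, concentration = 8),
      # 30%-admixed individuals planted inside clean breed IB1
      list(name = "adm", labelled_as = "IB1",
           proportions = c(D = 0.3, IB1 = 0.7), n = 10)),
    missing_rate = 0, seed = seed)
  simulate_panel(cfg)
}

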