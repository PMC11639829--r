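# exhaustive assignment oracle: over all injective component assignments,
# maximise the total of assigned group means (ties resolved like the
# greedy: preferred group order, then lower component index)
assign_oracle <- function(gm) {
  glev <- rownames(gm); K <- ncol(gm)
  perms <- function(v, r) {
    if (r == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i], r - 1)) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_total <- -Inf
  for (p in perms(seq_len(K), length(glev))) {
    total <- sum(gm[cbind(seq_along(glev), p)])
    if (total > best_total + 1e-12) { best_total <- total; best <- p }
  }
  labels <- rep("Unknown", K)
  labels[best] <- glev
  labels
}

test_that("component labelling follows group means, leftovers -> Unknown", {
  Q <- rbind(e1 = c(0.95, 0.05), e2 = c(0.96, 0.04),
             a1 = c(0.03, 0.97), a2 = c(0.02, 0.98))
  lm <- label_components(Q, c(e1 = "EUD", e2 = "EUD",
                              a1 = "ASD", a2 = "ASD"))
  expect_identical(lm$labels, c("EUD", "ASD"))
  expect_equal(lm$margins, c(0.955, 0.975))

  # K=5 with 4 groups leaves exactly one Unknown component
  set.seed(4)
  Q5 <- matrix(rexp(8 * 5), ncol = 5); Q5 <- Q5 / rowSums(Q5)
  Q5[1:2, 1] <- Q5[1:2, 1] + 2; Q5[3:4, 2] <- Q5[3:4, 2] + 2
  Q5[5:6, 3] <- Q5[5:6, 3] + 2; Q5[7:8, 4] <- Q5[7:8, 4] + 2
  Q5 <- Q5 / rowSums(Q5)
  rownames(Q5) <- paste0("s", 1:8)
  grp <- setNames(rep(c("D", "L", "Y", "Indigenous"), each = 2),
                  rownames(Q5))
  lm5 <- label_components(Q5, grp)
  expect_equal(sum(lm5$labels == "Unknown"), 1)
  expect_setequal(lm5$labels, c("D", "L", "Y", "Indigenous", "Unknown"))
  expect_error(label_components(Q, setNames(c("A", "B", "C"),
                                            c("e1", "e2", "a1"))),
               "components")
})

test_that("conflicting group maxima resolve like the exhaustive oracle", {
  # both groups maximal on component 1; the larger mean wins it
  Q <- rbind(g1a = c(0.70, 0.20, 0.10), g1b = c(0.72, 0.18, 0.10),
             g2a = c(0.60, 0.35, 0.05), g2b = c(0.58, 0.37, 0.05))
  grp <- setNames(c("D", "D", "L", "L"), rownames(Q))
  lm <- label_components(Q, grp)
  gm <- lm$group_means
  expect_identical(lm$labels, assign_oracle(gm))
  expect_identical(lm$labels, c("D", "L", "Unknown"))

  # group-dominant mean matrices (each group clearly owns one distinct
  # component, the realistic panel regime): greedy agrees with the
  # total-maximising exhaustive oracle
  set.seed(12)
  for (rep in 1:20) {
    n_g <- sample(2:4, 1); K <- n_g + sample(0:2, 1)
    gm <- matrix(runif(n_g * K, 0, 0.25), n_g,
                 dimnames = list(paste0("G", seq_len(n_g)), NULL))
    own <- sample(seq_len(K), n_g)
    gm[cbind(seq_len(n_g), own)] <- runif(n_g, 0.6, 0.95)
    Qr <- gm[rep(seq_len(n_g), each = 3), , drop = FALSE]
    rownames(Qr) <- paste0("s", seq_len(n_g * 3))
    grp_r <- setNames(rep(rownames(gm), each = 3), rownames(Qr))
    got <- label_components(Qr, grp_r)$labels
    expect_identical(got, assign_oracle(gm), info = paste("rep", rep))
    expect_identical(got[own], rownames(gm))
  }
})

test_that("ensemble aggregation reproduces hand-computed mean/SE and the
           strict reliability rule", {
  run <- function(breed, props, seed = 1)
    list(indigenous_breed = breed, labelled_proportions = props,
         seed = seed)
  labs <- c(D = 0.4, L = 0.2, Y = 0.2, Indigenous = 0.15, Unknown = 0.05)
  r1 <- run("b1", labs); r2 <- run("b2", labs + c(0.2, 0, 0, -0.2, 0))
  agg <- aggregate_ensemble(list(r1, r2))
  # D proportions {0.4, 0.6}: mean 0.5, SE = sample SD = 0.1414
  expect_equal(unname(agg$per_label_mean["D"]), 0.5)
  expect_equal(unname(agg$per_label_se["D"]), sd(c(0.4, 0.6)))
  expect_equal(unname(agg$per_label_se["D"]), 0.1414214, tolerance = 1e-6)
  expect_equal(unname(agg$per_label_se["L"]), 0)
  expect_identical(names(agg$indigenous_ranking)[1], "b1")
  expect_equal(unname(agg$indigenous_ranking), c(0.15, -0.05))

  # all-identical ensemble: SE 0 everywhere, reliable
  agg_id <- aggregate_ensemble(replicate(5, run("b", labs),
                                         simplify = FALSE))
  expect_true(all(agg_id$per_label_se == 0))
  expect_true(agg_id$reliable)

  # 38 runs, exactly 2 labels with SE > 0.2 -> still reliable (strict >2)
  mk_ens <- function(n_noisy) {
    runs <- list()
    for (b in 1:38) {
      props <- labs
      noisy <- c("D", "L", "Y")[seq_len(n_noisy)]
      props[noisy] <- props[noisy] + ifelse(b %% 2 == 0, 0.3, -0.3)
      runs[[b]] <- run(paste0("b", b), props)
    }
    runs
  }
  expect_true(aggregate_ensemble(mk_ens(2))$reliable)
  expect_false(aggregate_ensemble(mk_ens(3))$reliable)
  expect_equal(aggregate_ensemble(mk_ens(3))$n_high_se_labels, 3)

  # label missing from one run: excluded pairwise from that label's stats
  r3 <- run("b3", labs[c("D", "L", "Y", "Indigenous")])
  agg3 <- aggregate_ensemble(list(r1, r2, r3))
  expect_equal(unname(agg3$per_label_mean["Unknown"]), 0.05)
  expect_error(aggregate_ensemble(list(r1)), "at least 2")
})

test_that("EUD/ASD identification recovers purebred and F1 candidates", {
  cfg <- sim_config(
    n_variants = 1500, seed = 303, missing_rate = 0,
    breeds = list(
      list(name = "D", group = "EUD", fst = 0.25, n = 25),
      list(name = "L", group = "EUD", fst = 0.22, n = 25),
      list(name = "IB1", group = "ASD", fst = 0.12, n = 25),
      list(name = "IB2", group = "ASD", fst = 0.15, n = 25)),
    crosses = list(
      list(name = "DxIB1", proportions = c(D = 0.5, IB1 = 0.5), n = 2,
           scheme = "f1_haploid")))
  sim <- simulate_panel(cfg)
  ds <- sim$dataset
  cand_idx <- which(ds$samples$tier == "candidate")
  panel <- panel_from_labels(subset_dataset(
    ds, samples = setdiff(seq_len(nrow(ds$G)), cand_idx)))

  # purebred EUD candidate: a fresh Duroc draw
  set.seed(9)
  pure <- tiny_dataset(sample_purebred(sim$breed_freqs, "D", 1))
  pure$variants <- ds$variants
  pure$samples$sid <- "cand_pure"
  res_p <- identify_eud_asd(panel, pure, seed = 5)
  expect_gt(res_p$EUD, 0.95)
  expect_equal(res_p$EUD + res_p$ASD, 1, tolerance = 1e-6)

  # F1 EUD x ASD: half-and-half ancestry
  f1 <- subset_dataset(ds, samples = cand_idx)
  res_f1 <- identify_eud_asd(panel, f1, seed = 6)
  expect_true(all(res_f1$EUD > 0.45 & res_f1$EUD < 0.55))

  # candidate copied from a panel member matches that member's own labels
  dup <- subset_dataset(ds, samples = which(ds$samples$breed == "D")[1])
  dup$samples$sid <- "copy_of_D1"
  dup$samples$tier <- "candidate"
  res_dup <- identify_eud_asd(panel, dup, seed = 7)
  expect_gt(res_dup$EUD, 0.98)
})
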