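test_that("PC sign gates mark the published example point ineligible", {
  rule <- commercial_rule("D", pc1_sign = "<", pc1_threshold = 0,
                          pc2_sign = "<", pc2_threshold = -0.05)
  expect_false(pigdeconv:::.rule_eligible(rule, 0.1, -0.2))
  expect_true(pigdeconv:::.rule_eligible(rule, -0.1, -0.2))
  expect_false(pigdeconv:::.rule_eligible(rule, -0.1, -0.01))
})

test_that("centroid-proximity selection matches an exhaustive oracle", {
  sim <- panel_sim_with_contamination(7)
  ds <- subset_dataset(sim$dataset,
                       samples = which(sim$dataset$samples$breed == "D"))
  rule <- commercial_rule("D", pc1_sign = "<", pc1_threshold = Inf,
                          pc2_sign = "<", pc2_threshold = Inf,
                          n_select = 30)
  sel <- select_commercial(ds, list(rule))
  expect_length(sel$D, 30)
  # oracle: recompute the PCA, rank all (eligible = all) samples by
  # distance to the centroid, take the bottom 30
  pc <- pca_genotypes(ds, n_components = 2)
  ctr <- colMeans(pc$coords)
  d2 <- (pc$coords[, 1] - ctr[1])^2 + (pc$coords[, 2] - ctr[2])^2
  oracle <- ds$samples$sid[order(d2)[1:30]]
  expect_setequal(sel$D, oracle)

  # when eligible count equals n_select, centroid rank is irrelevant
  sel_all <- select_commercial(ds, list(commercial_rule(
    "D", pc1_sign = "<", pc1_threshold = Inf, pc2_sign = "<",
    pc2_threshold = Inf, n_select = nrow(ds$G))))
  expect_setequal(sel_all$D, ds$samples$sid)
  # shortfall is an error naming the gap
  expect_error(select_commercial(ds, list(commercial_rule(
    "D", pc1_sign = "<", pc1_threshold = -Inf, n_select = 5))),
    "only 0 eligible")
})

test_that("P_IB component choice takes the max mean, ties to lower index", {
  Q <- rbind(c(0.5, 0.5, 0.0, 0.0),
             c(0.5, 0.5, 0.0, 0.0))
  p <- pigdeconv:::.pib_from_Q(Q, 1:2)
  expect_equal(p$component_index, 1L)
  expect_equal(p$mean_pib, 0.5)
  Q2 <- rbind(c(0.1, 0.2, 0.6, 0.1), c(0.0, 0.1, 0.8, 0.1))
  p2 <- pigdeconv:::.pib_from_Q(Q2, 1:2)
  expect_equal(p2$component_index, 3L)
  expect_equal(p2$pib, c(0.6, 0.8))
})

test_that("P_IB flags commercial-admixed breeds and keeps drifted ones", {
  sim <- panel_sim_with_contamination(11)
  ds <- sim$dataset
  dly <- subset_dataset(ds, samples = which(
    ds$samples$breed %in% c("D", "L", "Y")))
  fake <- subset_dataset(ds, samples = grep("^fake_", ds$samples$sid))
  pib_fake <- compute_pib(dly, fake, K = 4, seed = 5)
  expect_lt(pib_fake$mean_pib, 0.50)
  expect_false(pib_fake$retained)

  clean <- subset_dataset(ds, samples = which(ds$samples$breed == "IB2"))
  pib_clean <- compute_pib(dly, clean, K = 4, seed = 5)
  expect_gt(pib_clean$mean_pib, 0.9)
  expect_true(pib_clean$retained)
  expect_true(all(pib_clean$per_individual_pib >= 0 &
                    pib_clean$per_individual_pib <= 1))
})

test_that("threshold boundaries follow the strict published inequalities", {
  mk_report <- function(breed, pibs) {
    structure(list(breed = breed,
                   per_individual_pib = setNames(
                     pibs, paste0(breed, seq_along(pibs))),
                   mean_pib = mean(pibs), component_index = 1L,
                   retained = mean(pibs) >= 0.5), class = "pib_report")
  }
  reports <- list(
    exact_mean = mk_report("exact_mean", c(0.5, 0.5)),     # mean == 0.50
    below_mean = mk_report("below_mean", c(0.4, 0.55)),    # mean < 0.50
    boundary_ind = mk_report("boundary_ind", c(0.80, 0.95, 0.81)))
  filt <- pigdeconv:::.apply_pib_filters(reports)
  # breed with mean P_IB exactly 0.50 is retained (strict < drops)
  expect_true(filt$exact_mean$breed_kept)
  expect_false(filt$below_mean$breed_kept)
  expect_length(filt$below_mean$kept_sids, 0)
  # individual with P_IB exactly 0.80 is excluded (strict > keeps)
  expect_setequal(filt$boundary_ind$kept_sids,
                  c("boundary_ind2", "boundary_ind3"))
})

test_that("build_panel drops the mixed breed and planted admixed individuals", {
  sim <- panel_sim_with_contamination(13)
  rules <- lapply(c("D", "L", "Y"), function(b)
    commercial_rule(b, pc1_sign = "<", pc1_threshold = Inf,
                    pc2_sign = "<", pc2_threshold = Inf, n_select = 30))
  panel <- build_panel(sim$dataset, rules, seed = 20)
  kept_breeds <- unique(panel$dataset$samples$breed[
    panel$dataset$samples$tier == "indigenous"])
  expect_false("MIX" %in% kept_breeds)
  expect_setequal(kept_breeds, c("IB1", "IB2"))
  expect_equal(sum(panel$dataset$samples$tier == "commercial"), 90)

  # planted 30%-admixed IB1 individuals excluded with sensitivity >= 0.9
  adm_sids <- grep("^adm_", sim$dataset$samples$sid, value = TRUE)
  excluded <- setdiff(adm_sids, panel$dataset$samples$sid)
  expect_gte(length(excluded) / length(adm_sids), 0.9)
  # group map: commercial -> EUD, indigenous -> ASD
  expect_true(all(panel$dataset$samples$group[
    panel$dataset$samples$tier == "commercial"] == "EUD"))
  expect_true(all(panel$dataset$samples$group[
    panel$dataset$samples$tier == "indigenous"] == "ASD"))
  # provenance totals are coherent
  prov <- panel$provenance
  expect_equal(sum(prov$n_after[prov$tier == "indigenous"]),
               sum(panel$dataset$samples$tier == "indigenous"))

  # panel size is monotone in the individual threshold
  panel_strict <- build_panel(sim$dataset, rules, pib_ind_min = 0.95,
                              seed = 20)
  expect_lte(nrow(panel_strict$dataset$G), nrow(panel$dataset$G))
})
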