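#' Commercial selection rule
#'
#' A sign/threshold gate on the first two principal components of a
#' within-breed PCA, plus the number of reliable individuals to keep. The
#' canonical gates for the three commercial breeds are
#' Duroc `PC1 < 0 & PC2 < -0.05`, Landrace `PC1 < 0 & PC2 < 0`,
#' Yorkshire `PC1 > 0 & PC2 < 0`; PC signs are dataset-specific, so gates
#' are always user-supplied configuration.
#'
#' @param breed breed label the rule applies to.
#' @param pc1_sign,pc2_sign `"<"` or `">"`: which side of the threshold is
#'   eligible.
#' @param pc1_threshold,pc2_threshold thresholds in PC units.
#' @param n_select number of individuals to keep (>= 1).
#' @return Object of class `commercial_rule`.
#' @export
commercial_rule <- function(breed, pc1_sign = "<", pc1_threshold = 0,
                            pc2_sign = "<", pc2_threshold = 0,
                            n_select = 30) {
  stopifnot(pc1_sign %in% c("<", ">"), pc2_sign %in% c("<", ">"),
            n_select >= 1)
  structure(list(breed = breed, pc1_sign = pc1_sign,
                 pc1_threshold = pc1_threshold, pc2_sign = pc2_sign,
                 pc2_threshold = pc2_threshold,
                 n_select = as.integer(n_select)),
            class = "commercial_rule")
}

.rule_eligible <- function(rule, pc1, pc2) {
  e1 <- if (rule$pc1_sign == "<") pc1 < rule$pc1_threshold
        else pc1 > rule$pc1_threshold
  e2 <- if (rule$pc2_sign == "<") pc2 < rule$pc2_threshold
        else pc2 > rule$pc2_threshold
  e1 & e2
}

#' Select reliable commercial individuals by PCA gating
#'
#' For each rule, a PCA is run on that breed's samples alone; samples
#' passing the PC1/PC2 sign gates are eligible, and the `n_select` eligible
#' samples closest (Euclidean, PC1-PC2 plane) to the eligible-set centroid
#' are kept — a deterministic, outlier-robust refinement of "pick n
#' credible individuals".
#'
#' @param ds genotype_dataset containing the commercial samples (breed
#'   labels set).
#' @param rules list of [commercial_rule()] objects.
#' @return Named list (by breed) of selected sample id vectors.
#' @export
select_commercial <- function(ds, rules) {
  stopifnot(inherits(ds, "genotype_dataset"))
  out <- list()
  for (rule in rules) {
    idx <- which(ds$samples$breed == rule$breed)
    if (length(idx) == 0)
      stop("no samples labelled '", rule$breed, "'")
    sub <- subset_dataset(ds, samples = idx)
    pc <- pca_genotypes(sub, n_components = 2)
    pc1 <- pc$coords[, 1]; pc2 <- pc$coords[, 2]
    elig <- which(.rule_eligible(rule, pc1, pc2))
    if (length(elig) < rule$n_select)
      stop("breed '", rule$breed, "': only ", length(elig),
           " eligible individuals for n_select = ", rule$n_select,
           " (short by ", rule$n_select - length(elig), ")")
    ctr <- c(mean(pc1[elig]), mean(pc2[elig]))
    d2 <- (pc1[elig] - ctr[1])^2 + (pc2[elig] - ctr[2])^2
    pickn <- elig[order(d2, elig)[seq_len(rule$n_select)]]
    out[[rule$breed]] <- sub$samples$sid[pickn]
  }
  out
}

#' Indigenous breed-specific ancestry proportion (P_IB)
#'
#' Merges the selected Duroc/Landrace/Yorkshire individuals with one
#' indigenous breed, fits the admixture model at `K` (default 4), and takes
#' the component with the maximum mean ancestry proportion over the
#' indigenous individuals as the breed-specific component. Each indigenous
#' individual's loading on that component is its P_IB; the breed is retained
#' when the mean P_IB is at least 0.50 (a mean strictly below 0.50 marks a
#' mixed/commercial-admixed breed).
#'
#' @param dly_selected genotype_dataset of the selected commercial
#'   individuals (D/L/Y).
#' @param breed_ds genotype_dataset of one indigenous breed.
#' @param K number of components (one per commercial breed + one
#'   indigenous).
#' @param seed seed for the admixture fit.
#' @return Object of class `pib_report`: `breed`, `per_individual_pib`
#'   (named vector over the breed's samples), `mean_pib`,
#'   `component_index`, `retained` (`mean_pib >= 0.50`), `fit`.
#' @export
compute_pib <- function(dly_selected, breed_ds, K = 4, seed = 1L) {
  breeds <- unique(breed_ds$samples$breed)
  if (length(breeds) != 1)
    stop("breed_ds must contain a single breed, found: ",
         paste(breeds, collapse = ", "))
  merged <- merge_on_shared_variants(dly_selected, breed_ds)
  fit <- fit_admixture(merged, K = K, seed = seed)
  ind <- seq_len(nrow(breed_ds$G)) + nrow(dly_selected$G)
  p <- .pib_from_Q(fit$Q, ind)
  names(p$pib) <- breed_ds$samples$sid
  structure(list(breed = breeds, per_individual_pib = p$pib,
                 mean_pib = p$mean_pib,
                 component_index = p$component_index,
                 retained = p$mean_pib >= 0.50, fit = fit),
            class = "pib_report")
}

#' @export
print.pib_report <- function(x, ...) {
  cat("pib_report '", x$breed, "': mean P_IB = ",
      sprintf("%.3f", x$mean_pib), " (component ", x$component_index,
      "), ", if (x$retained) "retained" else "dropped (mixed breed)",
      "\n", sep = "")
  invisible(x)
}

# breed-specific component of a Q matrix: the component with the maximum
# mean over the breed's individuals (rows `ind`); exact ties go to the
# lower component index
.pib_from_Q <- function(Q, ind) {
  comp_means <- colMeans(Q[ind, , drop = FALSE])
  component_index <- which.max(comp_means)
  pib <- Q[ind, component_index]
  list(component_index = component_index, pib = pib, mean_pib = mean(pib))
}

# apply the two curation thresholds to a list of pib_reports;
# breed dropped when mean P_IB < breed_min, individual kept when
# P_IB > ind_min (both strict, matching the published rules)
.apply_pib_filters <- function(reports, pib_breed_min = 0.50,
                               pib_ind_min = 0.80) {
  lapply(reports, function(r) {
    breed_kept <- !(r$mean_pib < pib_breed_min)
    kept <- if (breed_kept)
      names(r$per_individual_pib)[r$per_individual_pib > pib_ind_min]
    else character(0)
    list(breed = r$breed, breed_kept = breed_kept, kept_sids = kept,
         mean_pib = r$mean_pib,
         n_before = length(r$per_individual_pib),
         n_after = length(kept))
  })
}

#' Build the ancestry reference panel
#'
#' Two-tier curation of a labelled multi-breed dataset:
#'
#' 1. *Commercial tier*: per-breed PCA gating via [select_commercial()]
#'    keeps `n_select` reliable individuals per commercial breed.
#' 2. *Indigenous tier*: each indigenous breed is merged with the selected
#'    commercial individuals and scored by [compute_pib()]. Breeds with
#'    mean P_IB < `pib_breed_min` are dropped entirely (mixed breeds);
#'    within retained breeds only individuals with P_IB > `pib_ind_min`
#'    are kept. A retained breed losing every individual is dropped with a
#'    warning.
#'
#' Panel groups default to tier (commercial -> EUD, indigenous -> ASD) but
#' honour an explicit `group` column in `ds_all$samples`.
#'
#' @param ds_all genotype_dataset with breed labels and a `tier` column
#'   distinguishing `"commercial"` from `"indigenous"` samples.
#' @param rules list of [commercial_rule()] (one per commercial breed).
#' @param pib_breed_min mean-P_IB threshold below which a breed is dropped.
#' @param pib_ind_min per-individual P_IB threshold (strictly greater
#'   keeps).
#' @param K components for the P_IB fits.
#' @param seed base seed; indigenous breed `b` (in label order) uses
#'   `seed + b`.
#' @return Object of class `reference_panel`: `dataset` (curated
#'   genotype_dataset with breed/tier/group), `provenance` (data.frame:
#'   breed, tier, mean_pib, n_before, n_after), `pib_reports`,
#'   `commercial_selection`.
#' @export
build_panel <- function(ds_all, rules, pib_breed_min = 0.50,
                        pib_ind_min = 0.80, K = 4, seed = 1L) {
  stopifnot(inherits(ds_all, "genotype_dataset"))
  com_sel <- select_commercial(
    subset_dataset(ds_all, samples = which(ds_all$samples$tier ==
                                             "commercial")),
    rules)
  dly_sids <- unlist(com_sel, use.names = FALSE)
  dly <- subset_dataset(ds_all, samples = dly_sids)

  ind_breeds <- sort(unique(ds_all$samples$breed[
    ds_all$samples$tier == "indigenous"]))
  reports <- list()
  for (i in seq_along(ind_breeds)) {
    b <- ind_breeds[i]
    breed_ds <- subset_dataset(
      ds_all, samples = which(ds_all$samples$breed == b &
                                ds_all$samples$tier == "indigenous"))
    reports[[b]] <- compute_pib(dly, breed_ds, K = K,
                                seed = as.integer(seed) + i)
  }
  filt <- .apply_pib_filters(reports, pib_breed_min, pib_ind_min)
  kept_ind <- character(0)
  prov <- list()
  for (f in filt) {
    if (f$breed_kept && f$n_after == 0)
      warning("breed '", f$breed,
              "' retained by mean P_IB but no individual passed P_IB > ",
              pib_ind_min, "; breed dropped")
    kept_ind <- c(kept_ind, f$kept_sids)
    prov[[f$breed]] <- data.frame(
      breed = f$breed, tier = "indigenous", mean_pib = f$mean_pib,
      n_before = f$n_before, n_after = f$n_after,
      stringsAsFactors = FALSE)
  }
  prov_com <- do.call(rbind, lapply(names(com_sel), function(b)
    data.frame(breed = b, tier = "commercial", mean_pib = NA_real_,
               n_before = sum(ds_all$samples$breed == b &
                                ds_all$samples$tier == "commercial"),
               n_after = length(com_sel[[b]]), stringsAsFactors = FALSE)))
  provenance <- rbind(prov_com, do.call(rbind, prov))
  rownames(provenance) <- NULL

  panel_ds <- subset_dataset(ds_all, samples = c(dly_sids, kept_ind))
  grp <- ifelse(panel_ds$samples$tier == "commercial", "EUD", "ASD")
  explicit <- !is.na(panel_ds$samples$group)
  grp[explicit] <- panel_ds$samples$group[explicit]
  panel_ds$samples$group <- grp
  structure(list(dataset = panel_ds, provenance = provenance,
                 pib_reports = reports, commercial_selection = com_sel),
            class = "reference_panel")
}

#' Assemble a reference panel directly from labelled samples
#'
#' Skips curation: every sample with a breed label and a
#' commercial/indigenous tier goes straight into the panel. Useful when the
#' input is already curated (e.g. simulated purebreds with known truth).
#'
#' @param ds genotype_dataset with breed and tier labels.
#' @return reference_panel with empty curation provenance.
#' @export
panel_from_labels <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  keep <- which(ds$samples$tier %in% c("commercial", "indigenous") &
                  !is.na(ds$samples$breed))
  if (length(keep) == 0) stop("no labelled commercial/indigenous samples")
  panel_ds <- subset_dataset(ds, samples = keep)
  grp <- ifelse(panel_ds$samples$tier == "commercial", "EUD", "ASD")
  explicit <- !is.na(panel_ds$samples$group)
  grp[explicit] <- panel_ds$samples$group[explicit]
  panel_ds$samples$group <- grp
  structure(list(dataset = panel_ds,
                 provenance = data.frame(), pib_reports = list(),
                 commercial_selection = list()),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  s <- x$dataset$samples
  cat("reference_panel: ", nrow(s), " individuals, ",
      length(unique(s$breed)), " breeds (",
      sum(s$tier == "commercial"), " commercial / ",
      sum(s$tier == "indigenous"), " indigenous)\n", sep = "")
  invisible(x)
}

#' Write panel provenance as TSV
#'
#' @param panel reference_panel.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_provenance <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  utils::write.table(panel$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
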