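#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow with its published
#' default: pruning window 50 variants / step 10 / r² 0.5, mean-P_IB breed
#' threshold 0.50, per-individual P_IB threshold 0.80, K = 2 for group
#' identification, K = 5 for breed identification, SE threshold 0.2 with at
#' most 2 high-SE labels tolerated.
#'
#' @param input either a path prefix of a PLINK fileset holding the
#'   labelled reference data, or a `sim_config` to generate it (the
#'   default), or a genotype_dataset.
#' @param candidates optional: PLINK prefix or genotype_dataset of
#'   candidates. When `input` is a `sim_config`, samples with tier
#'   `"candidate"` are split off automatically.
#' @param rules list of [commercial_rule()]; `NULL` derives default
#'   sign-free rules (every sample eligible) for each commercial breed —
#'   appropriate for simulated data without PCA outliers.
#' @param prune_window,prune_step,prune_r2 LD pruning parameters.
#' @param pib_breed_min,pib_ind_min P_IB curation thresholds.
#' @param k_group,k_breed admixture K for group/breed identification.
#' @param se_threshold,max_high_se ensemble reliability rule.
#' @param curate run the full P_IB curation (`TRUE`) or take labels at face
#'   value via [panel_from_labels()] (`FALSE`).
#' @param mode identification mode(s) to run: subset of
#'   `c("group", "breed")`.
#' @param seed master seed.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(input = sim_config(), candidates = NULL,
                            rules = NULL, prune_window = 50,
                            prune_step = 10, prune_r2 = 0.5,
                            pib_breed_min = 0.50, pib_ind_min = 0.80,
                            k_group = 2, k_breed = 5, se_threshold = 0.2,
                            max_high_se = 2, curate = TRUE,
                            mode = c("group", "breed"), seed = 1L) {
  stopifnot(prune_r2 >= 0, prune_r2 <= 1,
            pib_breed_min >= 0, pib_breed_min <= 1,
            pib_ind_min >= 0, pib_ind_min <= 1,
            se_threshold >= 0, se_threshold <= 1,
            k_group >= 2, k_breed >= 2)
  structure(list(input = input, candidates = candidates, rules = rules,
                 prune_window = prune_window, prune_step = prune_step,
                 prune_r2 = prune_r2, pib_breed_min = pib_breed_min,
                 pib_ind_min = pib_ind_min, k_group = k_group,
                 k_breed = k_breed, se_threshold = se_threshold,
                 max_high_se = max_high_se, curate = curate,
                 mode = match.arg(mode, several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.load_input <- function(x) {
  if (inherits(x, "genotype_dataset")) return(list(ds = x, sim = NULL))
  if (inherits(x, "sim_config")) {
    sim <- simulate_panel(x)
    return(list(ds = sim$dataset, sim = sim))
  }
  if (is.character(x)) return(list(ds = read_plink(x), sim = NULL))
  stop("unsupported input of class ", paste(class(x), collapse = "/"))
}

#' Run the end-to-end breed-composition pipeline
#'
#' Stages, in order, each logged with its filter tallies and cached as
#' files under `out_dir`:
#'
#' 1. *load/simulate* the labelled dataset (and candidates);
#' 2. *prune* variants by windowed LD;
#' 3. *build-panel* (PCA gating + P_IB curation, or label passthrough);
#' 4. *characterize* the panel (PCA coordinates, IBS distances,
#'    neighbour-joining tree, K = 2 structure);
#' 5. *identify* candidate EUD/ASD and/or breed composition.
#'
#' A `manifest.json` records package version, seed, parameters and
#' per-stage counts; rerunning with the same config and seed reproduces
#' every output file.
#'
#' @param config pipeline_config.
#' @param out_dir results directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results: `pruned`
#'   dataset, `panel`, `pca`, `tree`, `structure_k2`, `group_results`,
#'   `breed_results`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  manifest <- list(package = "pigdeconv",
                   version = as.character(utils::packageVersion("pigdeconv")),
                   seed = config$seed,
                   params = config[setdiff(names(config),
                                           c("input", "candidates",
                                             "rules"))],
                   stages = list())

  # -- load / simulate ------------------------------------------------
  inp <- .load_input(config$input)
  ds <- inp$ds
  cand <- NULL
  if (!is.null(config$candidates)) {
    cand <- .load_input(config$candidates)$ds
  } else if (any(ds$samples$tier == "candidate")) {
    ci <- which(ds$samples$tier == "candidate")
    cand <- subset_dataset(ds, samples = ci)
    ds <- subset_dataset(ds, samples = setdiff(seq_len(nrow(ds$G)), ci))
  }
  say("input: ", nrow(ds$G), " reference samples, ",
      if (is.null(cand)) 0 else nrow(cand$G), " candidates, ",
      ncol(ds$G), " variants")
  if (!is.null(inp$sim)) write_truth_tsv(inp$sim,
                                         file.path(out_dir, "truth.tsv"))
  manifest$stages$input <- list(n_reference = nrow(ds$G),
                                n_candidates = if (is.null(cand)) 0
                                               else nrow(cand$G),
                                n_variants = ncol(ds$G))

  # -- prune ----------------------------------------------------------
  pr <- ld_prune(ds, config$prune_window, config$prune_step,
                 config$prune_r2)
  write_prune_lists(pr, file.path(out_dir, "reference"))
  ds <- subset_dataset(ds, variants = pr$kept)
  if (!is.null(cand)) {
    shared <- intersect(ds$variants$vid, cand$variants$vid)
    cand <- subset_dataset(cand, variants = shared)
  }
  say("prune: removed ", length(pr$removed), " variants, kept ",
      length(pr$kept))
  manifest$stages$prune <- list(removed = length(pr$removed),
                                kept = length(pr$kept))

  # -- build panel ----------------------------------------------------
  if (config$curate) {
    rules <- config$rules
    if (is.null(rules)) {
      com_breeds <- unique(ds$samples$breed[ds$samples$tier ==
                                              "commercial"])
      rules <- lapply(com_breeds, function(b)
        commercial_rule(b, pc1_sign = "<", pc1_threshold = Inf,
                        pc2_sign = "<", pc2_threshold = Inf,
                        n_select = min(30, sum(ds$samples$breed == b))))
      say("build-panel: no PCA gates supplied; using all-eligible rules ",
          "(non-default fallback, gates are dataset-specific)")
    }
    panel <- build_panel(ds, rules, pib_breed_min = config$pib_breed_min,
                         pib_ind_min = config$pib_ind_min,
                         seed = config$seed)
  } else {
    panel <- panel_from_labels(ds)
  }
  write_panel_provenance(panel, file.path(out_dir, "panel_provenance.tsv"))
  write_plink(panel$dataset, file.path(out_dir, "panel"))
  say("build-panel: ", nrow(panel$dataset$G), " individuals, ",
      length(unique(panel$dataset$samples$breed)), " breeds")
  manifest$stages$panel <- list(n_individuals = nrow(panel$dataset$G),
                                n_breeds = length(unique(
                                  panel$dataset$samples$breed)))

  # -- characterize ---------------------------------------------------
  pca <- pca_genotypes(panel$dataset, n_components = 10)
  utils::write.table(
    data.frame(sid = rownames(pca$coords), pca$coords),
    file.path(out_dir, "panel_pca.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  dm <- ibs_distance(panel$dataset)
  write_dist_tsv(dm, file.path(out_dir, "panel_dist.tsv"))
  tree <- nj_tree(dm)
  write_newick(tree, file.path(out_dir, "panel_nj.nwk"))
  k2 <- fit_admixture(panel$dataset, K = 2, seed = config$seed)
  write_admixture_files(k2, file.path(out_dir, "panel"))
  say("characterize: PCA (PC1 ", sprintf("%.1f%%", 100 * pca$explained[1]),
      "), NJ tree, K=2 structure written")
  manifest$stages$characterize <- list(pc1_explained = pca$explained[1])

  # -- identify -------------------------------------------------------
  group_results <- NULL
  breed_results <- NULL
  if (!is.null(cand) && nrow(cand$G) > 0) {
    if ("group" %in% config$mode) {
      group_results <- identify_eud_asd(panel, cand,
                                        seed = config$seed + 1000L)
      utils::write.table(group_results,
                         file.path(out_dir, "group_composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      say("identify(group): ", nrow(group_results), " candidates")
    }
    if ("breed" %in% config$mode) {
      breed_results <- identify_candidates(
        panel, cand, mode = "breed", seed = config$seed + 2000L,
        K = config$k_breed, se_threshold = config$se_threshold,
        max_high_se = config$max_high_se)
      utils::write.table(breed_results,
                         file.path(out_dir, "breed_composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      say("identify(breed): ", length(unique(breed_results$sid)),
          " candidates x ", length(unique(breed_results$label)),
          " labels")
    }
  }
  manifest$stages$identify <- list(
    n_group = if (is.null(group_results)) 0 else nrow(group_results),
    n_breed = if (is.null(breed_results)) 0
              else length(unique(breed_results$sid)))

  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(pruned = ds, panel = panel, pca = pca, tree = tree,
                 structure_k2 = k2, group_results = group_results,
                 breed_results = breed_results, manifest = manifest))
}
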