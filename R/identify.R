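#' Label admixture components by reference group means
#'
#' Components of an unsupervised admixture fit carry no names; they are
#' labelled post hoc by the reference groups that dominate them. For every
#' group the mean ancestry proportion per component is computed over that
#' group's panel samples (candidates excluded); assignment is greedy on
#' those means — repeatedly take the largest mean among still-unassigned
#' (group, component) pairs — so each group claims the component it
#' dominates most and conflicts resolve in favour of the stronger group.
#' Ties are broken by a fixed group order (D, L, Y, Indigenous, EUD, ASD,
#' then alphabetical) and then by the lower component index. Leftover
#' components are labelled `"Unknown"`.
#'
#' @param fit admixture_fit (or a bare Q matrix).
#' @param groups named character vector: sample id -> group label, covering
#'   the panel samples (ids absent from `rownames(Q)` are ignored; panel
#'   samples only — do not include candidates).
#' @return Object of class `group_label_map`: `labels` (length-K character
#'   vector, component -> label), `margins` (mean proportion behind each
#'   assignment, NA for Unknown), `group_means` (group x K matrix).
#' @export
label_components <- function(fit, groups) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  groups <- groups[names(groups) %in% rownames(Q)]
  if (length(groups) == 0) stop("no group members found among Q rows")
  glev <- unique(groups)
  K <- ncol(Q)
  if (length(glev) > K)
    stop(length(glev), " groups but only ", K, " components")
  gm <- t(vapply(glev, function(g)
    colMeans(Q[names(groups)[groups == g], , drop = FALSE]),
    numeric(K)))
  rownames(gm) <- glev

  pref <- c("D", "L", "Y", "Indigenous", "EUD", "ASD")
  grank <- match(glev, pref)
  grank[is.na(grank)] <- length(pref) + rank(glev[is.na(grank)])

  labels <- rep("Unknown", K)
  margins <- rep(NA_real_, K)
  free_g <- rep(TRUE, length(glev))
  free_k <- rep(TRUE, K)
  for (step in seq_along(glev)) {
    cand <- which(outer(free_g, free_k, "&"), arr.ind = TRUE)
    vals <- gm[cand]
    best <- max(vals)
    at <- cand[vals == best, , drop = FALSE]
    # deterministic tie-break: preferred group order, then lower component
    at <- at[order(grank[at[, 1]], at[, 2]), , drop = FALSE]
    g <- at[1, 1]; k <- at[1, 2]
    labels[k] <- glev[g]
    margins[k] <- gm[g, k]
    free_g[g] <- FALSE
    free_k[k] <- FALSE
  }
  structure(list(labels = labels, margins = margins, group_means = gm),
            class = "group_label_map")
}

#' @export
print.group_label_map <- function(x, ...) {
  cat("group_label_map: ",
      paste0("c", seq_along(x$labels), "=", x$labels, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# collapse a candidate's Q row into named labelled proportions;
# duplicate labels (several Unknown components) are summed
.labelled_proportions <- function(q_row, labels) {
  out <- tapply(q_row, labels, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' European/Asian (EUD/ASD) ancestry proportions of candidates
#'
#' Each candidate is merged with the reference panel one at a time (so
#' candidates never influence one another's fits), the admixture model is
#' fitted at K = 2, the two components are labelled EUD/ASD from the panel
#' group means, and the candidate's labelled proportions are returned.
#'
#' @param panel reference_panel.
#' @param candidate_ds genotype_dataset of one or more candidates.
#' @param seed base seed; candidate `i` uses `seed + i - 1`.
#' @return data.frame: sid, EUD, ASD (one row per candidate).
#' @export
identify_eud_asd <- function(panel, candidate_ds, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(candidate_ds, "genotype_dataset"))
  groups <- stats::setNames(panel$dataset$samples$group,
                            panel$dataset$samples$sid)
  res <- vector("list", nrow(candidate_ds$G))
  for (i in seq_len(nrow(candidate_ds$G))) {
    cand <- subset_dataset(candidate_ds, samples = i)
    merged <- merge_on_shared_variants(panel$dataset, cand)
    fit <- fit_admixture(merged, K = 2, seed = as.integer(seed) + i - 1L)
    lm <- label_components(fit, groups)
    props <- .labelled_proportions(fit$Q[nrow(merged$G), ], lm$labels)
    res[[i]] <- data.frame(sid = cand$samples$sid,
                           EUD = unname(props["EUD"]),
                           ASD = unname(props["ASD"]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Aggregate an ensemble of labelled admixture runs
#'
#' The breed-identification ensemble produces one labelled proportion
#' vector per indigenous breed in the panel. Aggregation reports, per
#' label, the mean and the dispersion across runs — the run-to-run sample
#' standard deviation, written SE in the reliability rule — plus the
#' reliability verdict: a candidate is reliable when at most
#' `max_high_se` labels exceed `se_threshold` (the published rule removes
#' candidates with *more than 2* labels of SE > 0.2). Labels absent from a
#' run (a failed fit) are excluded pairwise from that label's statistics.
#'
#' @param runs list of ensemble runs: each a list with
#'   `indigenous_breed`, `labelled_proportions` (named numeric) and `seed`.
#' @param se_threshold dispersion threshold per label.
#' @param max_high_se maximum number of high-dispersion labels tolerated.
#' @return Object of class `breed_composition`: `per_label_mean`,
#'   `per_label_se` (named vectors over D, L, Y, Indigenous, Unknown),
#'   `n_high_se_labels`, `reliable`, `indigenous_ranking` (named vector,
#'   per-run Indigenous proportion by breed, descending), `runs`.
#' @export
aggregate_ensemble <- function(runs, se_threshold = 0.2, max_high_se = 2) {
  if (length(runs) < 2)
    stop("ensemble aggregation needs at least 2 runs")
  labs <- unique(unlist(lapply(runs, function(r)
    names(r$labelled_proportions))))
  mat <- sapply(labs, function(l)
    vapply(runs, function(r) {
      v <- r$labelled_proportions[l]
      if (is.null(v) || is.na(names(v))) NA_real_ else unname(v)
    }, numeric(1)))
  mat <- matrix(mat, nrow = length(runs), dimnames = list(NULL, labs))
  per_label_mean <- apply(mat, 2, mean, na.rm = TRUE)
  per_label_se <- apply(mat, 2, stats::sd, na.rm = TRUE)
  n_high <- sum(per_label_se > se_threshold, na.rm = TRUE)
  ranking <- sort(stats::setNames(
    vapply(runs, function(r) {
      v <- r$labelled_proportions["Indigenous"]
      if (is.null(v) || is.na(names(v))) NA_real_ else unname(v)
    }, numeric(1)),
    vapply(runs, `[[`, "", "indigenous_breed")), decreasing = TRUE)
  structure(list(per_label_mean = per_label_mean,
                 per_label_se = per_label_se,
                 n_high_se_labels = n_high,
                 reliable = n_high <= max_high_se,
                 indigenous_ranking = ranking,
                 runs = runs),
            class = "breed_composition")
}

#' @export
print.breed_composition <- function(x, ...) {
  cat("breed_composition (", length(x$runs), " ensemble runs, ",
      if (x$reliable) "reliable" else "unreliable", "):\n", sep = "")
  for (l in names(x$per_label_mean))
    cat(sprintf("  %-10s %.3f (SE %.3f)\n", l, x$per_label_mean[l],
                x$per_label_se[l]))
  top <- names(x$indigenous_ranking)[1]
  cat("  best-matching indigenous breed: ", top, "\n", sep = "")
  invisible(x)
}

#' Breed composition of a candidate via the per-indigenous-breed ensemble
#'
#' For every indigenous breed `b` in the panel, the candidate is merged
#' with the selected commercial individuals (D, L, Y) plus breed `b` and
#' the admixture model is fitted at K = 5. Components are labelled for the
#' groups D, L, Y and Indigenous from the panel means; the leftover
#' component is Unknown. One labelled proportion vector per breed results;
#' [aggregate_ensemble()] turns the ensemble into per-label mean/SE, the
#' reliability verdict, and the ranked indigenous best match. A failing
#' run is skipped with a warning; if fewer than half the runs survive the
#' result is an error.
#'
#' @param panel reference_panel with >= 1 indigenous breed.
#' @param candidate_ds genotype_dataset holding exactly one candidate (use
#'   a loop or [identify_candidates()] for batches).
#' @param K components per run (4 reference groups + 1 free).
#' @param seed base seed; run `b` uses `seed + b`.
#' @param se_threshold,max_high_se reliability rule, see
#'   [aggregate_ensemble()].
#' @return breed_composition (see [aggregate_ensemble()]) with `candidate`
#'   set to the sample id.
#' @export
identify_breed <- function(panel, candidate_ds, K = 5, seed = 1L,
                           se_threshold = 0.2, max_high_se = 2) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(candidate_ds, "genotype_dataset"))
  if (nrow(candidate_ds$G) != 1)
    stop("identify_breed() takes one candidate at a time")
  ps <- panel$dataset$samples
  com <- which(ps$tier == "commercial")
  if (length(com) == 0) stop("panel has no commercial individuals")
  ind_breeds <- sort(unique(ps$breed[ps$tier == "indigenous"]))
  if (length(ind_breeds) == 0) stop("panel has no indigenous breeds")

  runs <- list()
  for (b in seq_along(ind_breeds)) {
    breed <- ind_breeds[b]
    idx <- c(com, which(ps$breed == breed & ps$tier == "indigenous"))
    ref <- subset_dataset(panel$dataset, samples = idx)
    run <- tryCatch({
      merged <- merge_on_shared_variants(ref, candidate_ds)
      fit <- fit_admixture(merged, K = K, seed = as.integer(seed) + b)
      groups <- stats::setNames(
        ifelse(ref$samples$tier == "indigenous", "Indigenous",
               ref$samples$breed),
        ref$samples$sid)
      lm <- label_components(fit, groups)
      props <- .labelled_proportions(fit$Q[nrow(merged$G), ], lm$labels)
      list(indigenous_breed = breed, labelled_proportions = props,
           seed = as.integer(seed) + b)
    }, error = function(e) {
      warning("ensemble run for breed '", breed, "' failed: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(run)) runs[[length(runs) + 1]] <- run
  }
  if (length(runs) < length(ind_breeds) / 2)
    stop("fewer than half the ensemble runs survived (",
         length(runs), "/", length(ind_breeds), ")")
  res <- aggregate_ensemble(runs, se_threshold = se_threshold,
                            max_high_se = max_high_se)
  res$candidate <- candidate_ds$samples$sid
  res
}

#' Identify a batch of candidates
#'
#' Runs [identify_eud_asd()] (`mode = "group"`) or [identify_breed()]
#' (`mode = "breed"`) for each candidate independently and returns a tidy
#' table.
#'
#' @param panel reference_panel.
#' @param candidate_ds genotype_dataset of candidates.
#' @param mode `"group"` or `"breed"`.
#' @param seed base seed; candidate `i` offsets by `100 * (i - 1)` so
#'   ensemble runs of different candidates never share a seed.
#' @param ... passed to the per-candidate function.
#' @return `mode = "group"`: data.frame sid/EUD/ASD. `mode = "breed"`:
#'   data.frame sid, label, mean, se, reliable, top_indigenous (long
#'   format, one row per label).
#' @export
identify_candidates <- function(panel, candidate_ds,
                                mode = c("group", "breed"), seed = 1L,
                                ...) {
  mode <- match.arg(mode)
  if (mode == "group")
    return(identify_eud_asd(panel, candidate_ds, seed = seed, ...))
  out <- list()
  for (i in seq_len(nrow(candidate_ds$G))) {
    cand <- subset_dataset(candidate_ds, samples = i)
    r <- identify_breed(panel, cand, seed = as.integer(seed) +
                          100L * (i - 1L), ...)
    out[[i]] <- data.frame(sid = cand$samples$sid,
                           label = names(r$per_label_mean),
                           mean = unname(r$per_label_mean),
                           se = unname(r$per_label_se),
                           reliable = r$reliable,
                           top_indigenous = names(r$indigenous_ranking)[1],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
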