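#' Score differential abundance calls against ground truth
#'
#' Exact confusion counts over a universe of evaluated taxa and the three
#' benchmark ratios: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' and false discovery rate `FP/(FP+TP)`.  By convention the FDR is 0 when
#' nothing is called, and sensitivity is `NA` when the truth set is empty.
#'
#' @param called Character vector of taxa called significant.
#' @param truth Character vector of truly spiked taxa (or a truth
#'   data.frame with a `taxon` column).
#' @param universe All evaluated taxa.
#' @return A one-row data.frame with TP, FP, TN, FN, sensitivity,
#'   specificity, fdr.
#' @export
score_calls <- function(called, truth, universe) {
  if (is.data.frame(truth)) truth <- truth$taxon
  if (!length(universe)) stop("empty evaluation universe")
  called <- intersect(unique(called), universe)
  truth <- intersect(unique(truth), universe)
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  tn <- length(universe) - tp - fp - fn
  data.frame(
    TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fdr = if (tp + fp > 0) fp / (tp + fp) else 0
  )
}

#' Subset-coherence evaluation on real data
#'
#' The real-data benchmark design: the caller's significant taxa on the
#' complete dataset define the "verified truth"; the caller is then run on
#' each of three random sample splits (stratified by group, and by subject
#' for repeated measures) and scored against that truth.  Metrics are
#' averaged over the three splits.
#'
#' @param counts Count matrix.
#' @param meta Sample frame.
#' @param caller Function `(counts, meta) -> character vector` of
#'   significant taxa.
#' @param n_splits Number of splits (default 3).
#' @param seed Integer seed for the split assignment.
#' @return A list with `truth` (full-data calls), `per_split` (metrics per
#'   split) and `mean` (averaged metrics).
#' @export
subset_coherence_eval <- function(counts, meta, caller, n_splits = 3L,
                                  seed = 1L) {
  truth <- caller(counts, meta)
  universe <- rownames(counts)
  multi_occ <- length(unique(meta$occasion)) > 1L
  unit_ids <- if (multi_occ) unique(meta$subject_id) else meta$sample_id
  unit_group <- if (multi_occ) {
    meta$group[match(unit_ids, meta$subject_id)]
  } else meta$group
  split_of <- with_seed(seed, {
    for (attempt in 1:10) {
      assign_v <- integer(length(unit_ids))
      for (g in levels(droplevels(factor(unit_group)))) {
        i <- which(unit_group == g)
        assign_v[i] <- (sample(seq_along(i)) %% n_splits) + 1L
      }
      ok <- all(vapply(seq_len(n_splits), function(s) {
        length(unique(unit_group[assign_v == s])) ==
          length(unique(unit_group))
      }, logical(1L)))
      if (ok) break
      message("split left an empty group; resplitting (attempt ",
              attempt, ")")
    }
    assign_v
  })
  per_split <- lapply(seq_len(n_splits), function(s) {
    units <- unit_ids[split_of == s]
    keep <- if (multi_occ) meta$subject_id %in% units else
      meta$sample_id %in% units
    m_s <- meta[keep, , drop = FALSE]
    c_s <- counts[, m_s$sample_id, drop = FALSE]
    score_calls(caller(c_s, m_s), truth, universe)
  })
  per_split <- do.call(rbind, per_split)
  list(truth = truth, per_split = per_split,
       mean = colMeans(per_split, na.rm = TRUE))
}

#' Compare per-method benchmark metrics
#'
#' Omnibus Kruskal-Wallis test across methods followed by post hoc
#' pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment.
#' With ties, mid-ranks are used and the normal approximation replaces the
#' exact rank-sum distribution (flagged in the result).
#'
#' @param metric_samples Named list (one numeric vector of replicate
#'   metrics per method), at least 2 methods with >= 2 replicates each.
#' @return A list with `kruskal_p`, `pairwise_p` (raw lower-triangular
#'   matrix), `pairwise_p_adj` (BH-adjusted), and `ties_approximated`.
#' @export
compare_performance <- function(metric_samples) {
  stopifnot(is.list(metric_samples), length(metric_samples) >= 2L,
            all(lengths(metric_samples) >= 2L))
  if (is.null(names(metric_samples))) {
    names(metric_samples) <- paste0("method", seq_along(metric_samples))
  }
  values <- unlist(metric_samples, use.names = FALSE)
  groups <- factor(rep(names(metric_samples), lengths(metric_samples)),
                   levels = names(metric_samples))
  kw <- kruskal.test(values, groups)
  ties <- anyDuplicated(values) > 0L
  pw <- suppressWarnings(
    pairwise.wilcox.test(values, groups, p.adjust.method = "none",
                         exact = !ties)
  )$p.value
  adj <- pw
  adj[] <- NA_real_
  flat <- as.numeric(pw)
  flat_adj <- adjust_bh(flat)
  adj[] <- flat_adj
  list(kruskal_p = kw$p.value, pairwise_p = pw, pairwise_p_adj = adj,
       ties_approximated = ties)
}

#' Run the end-to-end benchmark
#'
#' For each replicate: simulate a dataset from the scenario (with seed
#' `seed + replicate`), run the DA caller (by default the full
#' [microgee()] pipeline with global-test calls), and score the calls
#' against the spiked truth over the universe of all simulated taxa
#' (spiked taxa lost to filtering count as false negatives).
#'
#' @param scn A [sim_scenario()]; its `n_occasions` selects the
#'   cross-sectional or longitudinal simulator.
#' @param replicates Number of replicate sub-datasets.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param control [microgee_control()] for the default caller.
#' @param caller Optional `(counts, meta) -> character` override scoring
#'   any other method's output.
#' @return A data.frame of class `"microgee_benchmark"` with one row per
#'   replicate: replicate, TP, FP, TN, FN, sensitivity, specificity, fdr,
#'   failed.
#' @export
run_benchmark <- function(scn, replicates = 50L, seed = 1L,
                          control = microgee_control(),
                          caller = NULL) {
  if (is.null(caller)) {
    caller <- function(counts, meta) {
      significant_taxa(microgee(counts, meta, control))
    }
  }
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    scn_r <- scn
    scn_r$seed <- (seed + r) %% .Machine$integer.max
    sim <- if (scn$n_occasions == 2L) simulate_longitudinal(scn_r) else
      simulate_cross_sectional(scn_r)
    res <- tryCatch({
      called <- caller(sim$counts, sim$meta)
      cbind(score_calls(called, sim$truth, rownames(sim$counts)),
            failed = FALSE)
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      data.frame(TP = NA_integer_, FP = NA_integer_, TN = NA_integer_,
                 FN = NA_integer_, sensitivity = NA_real_,
                 specificity = NA_real_, fdr = NA_real_, failed = TRUE)
    })
    rows[[r]] <- cbind(replicate = r, res)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("microgee_benchmark", class(out))
  out
}

#' @export
summary.microgee_benchmark <- function(object, ...) {
  ok <- !object$failed
  c(replicates = sum(ok),
    failed = sum(!ok),
    sensitivity = mean(object$sensitivity[ok], na.rm = TRUE),
    specificity = mean(object$specificity[ok], na.rm = TRUE),
    fdr = mean(object$fdr[ok], na.rm = TRUE))
}
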