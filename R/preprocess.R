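#' Remove low-prevalence taxa
#'
#' Drops taxa that are non-zero in fewer than `prevalence_min` of the
#' samples (boundary inclusive: a taxon exactly at the floor is retained).
#' Masked (`NA`) cells count as neither zero nor non-zero; the denominator
#' is the number of samples.
#'
#' @param counts Count matrix (taxa x samples), possibly with `NA` masks.
#' @param prevalence_min Fraction in `[0, 1)`.
#' @return A list with `counts` (the filtered matrix) and `report`
#'   (a filter report, see [apply_preprocessing()]).
#' @export
filter_low_prevalence <- function(counts, prevalence_min = 0.10) {
  stopifnot(prevalence_min >= 0, prevalence_min < 1)
  prev <- rowSums(counts > 0, na.rm = TRUE) / ncol(counts)
  keep <- prev >= prevalence_min
  if (!any(keep)) {
    stop("all taxa removed by the prevalence filter; lower prevalence_min")
  }
  removed <- rownames(counts)[!keep]
  list(
    counts = counts[keep, , drop = FALSE],
    report = new_filter_report(
      removed_taxa = if (length(removed))
        data.frame(taxon = removed, reason = "low_prevalence") else NULL
    )
  )
}

#' Remove low-depth samples
#'
#' Drops samples whose library size (column sum over unmasked cells) is
#' below `min_library_size`.
#'
#' @inheritParams filter_low_prevalence
#' @param min_library_size Non-negative integer read floor.
#' @return A list with `counts` and `report` as in
#'   [filter_low_prevalence()].
#' @export
filter_low_depth_samples <- function(counts, min_library_size = 1000L) {
  stopifnot(min_library_size >= 0)
  depth <- colSums(counts, na.rm = TRUE)
  keep <- depth >= min_library_size
  if (!any(keep)) {
    stop("all samples removed by the library-size filter; lower ",
         "min_library_size")
  }
  removed <- colnames(counts)[!keep]
  list(
    counts = counts[, keep, drop = FALSE],
    report = new_filter_report(
      removed_samples = if (length(removed))
        data.frame(sample = removed, reason = "low_library_size") else NULL
    )
  )
}

#' Classify zero cells
#'
#' Labels every cell of the count matrix as `observed` (non-zero),
#' `structural_zero` (the taxon is zero in at least `structural_fraction`
#' of the group's samples — biological absence), `sampling_zero`
#' (a zero explainable by sequencing depth), or `outlier_zero` (a zero in a
#' group where the taxon is almost always present and the sample's depth
#' cannot explain the absence).  Structural and sampling zeros are retained
#' downstream; outlier zeros are masked.
#'
#' @inheritParams filter_low_prevalence
#' @param meta Sample frame (see [as_sample_frame()]).
#' @param structural_fraction Within-group zero fraction declaring
#'   structural zeros (default 1).
#' @param outlier_zero_prevalence Within-group non-zero prevalence at or
#'   above which an unexplained zero is an outlier zero (default 0.9).
#' @return A character matrix of labels, same dimensions as `counts`, class
#'   `"zero_classification"`.
#' @export
classify_zeros <- function(counts, meta, structural_fraction = 1,
                           outlier_zero_prevalence = 0.90) {
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  lab <- matrix("observed", nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  lab[is.na(counts)] <- NA_character_
  depth <- colSums(counts, na.rm = TRUE)
  for (g in levels(droplevels(meta$group))) {
    in_g <- which(meta$group == g)
    n_g <- length(in_g)
    if (n_g < 2L) {
      warning("group '", g, "' has a single sample; structural-zero ",
              "classification skipped for it")
      zero_here <- which(counts[, in_g, drop = FALSE] == 0, arr.ind = TRUE)
      lab[cbind(zero_here[, 1L], in_g[zero_here[, 2L]])] <- "sampling_zero"
      next
    }
    sub <- counts[, in_g, drop = FALSE]
    nz <- rowSums(sub > 0, na.rm = TRUE)
    n_obs <- rowSums(!is.na(sub))
    zero_frac <- ifelse(n_obs > 0, (n_obs - nz) / n_obs, 0)
    nz_prev <- ifelse(n_obs > 0, nz / n_obs, 0)
    med_depth <- median(depth[in_g])
    for (k in seq_len(nrow(counts))) {
      zc <- in_g[which(sub[k, ] == 0)]
      if (!length(zc)) next
      if (zero_frac[k] >= structural_fraction) {
        lab[k, zc] <- "structural_zero"
      } else {
        out <- zc[nz_prev[k] >= outlier_zero_prevalence &
                    depth[zc] > med_depth]
        lab[k, zc] <- "sampling_zero"
        if (length(out)) lab[k, out] <- "outlier_zero"
      }
    }
  }
  structure(lab, class = c("zero_classification", class(lab)))
}

#' Detect outlier non-zero counts
#'
#' Within each group x taxon, non-zero counts whose `log(count + 1)` lies
#' outside `median +/- k * 1.4826 * MAD` of the group's non-zero logged
#' values are flagged.  Degenerate vectors (MAD zero) and groups with fewer
#' than three non-zero values yield no flags; flagged cells are masked
#' (treated as missing completely at random) downstream.
#'
#' @inheritParams classify_zeros
#' @param k Robust-z cutoff (default 3).
#' @return A logical matrix, `TRUE` where a non-zero cell is an outlier.
#' @export
detect_outlier_values <- function(counts, meta, k = 3) {
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  flag <- matrix(FALSE, nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  for (g in levels(droplevels(meta$group))) {
    in_g <- which(meta$group == g)
    if (length(in_g) < 3L) {
      warning("group '", g, "' has fewer than 3 samples; no outlier ",
              "flagging performed in it")
      next
    }
    sub <- counts[, in_g, drop = FALSE]
    for (t in seq_len(nrow(sub))) {
      y <- sub[t, ]
      nz <- which(!is.na(y) & y > 0)
      if (length(nz) < 3L) next
      v <- log(y[nz] + 1)
      m <- median(v)
      s <- mad(v)          # 1.4826 * median absolute deviation
      if (s == 0) next
      out <- nz[abs(v - m) > k * s]
      if (length(out)) flag[t, in_g[out]] <- TRUE
    }
  }
  flag
}

#' Full preprocessing pass
#'
#' Composition of the four preprocessing operations in order: prevalence
#' filter, library-size filter, zero classification, and outlier masking
#' (outlier zeros and outlier non-zero values become `NA`).  The
#' composition is iterated to a fixed point so that re-applying the whole
#' pass changes nothing (masking can alter robust statistics and
#' prevalences, so a single pass is not idempotent in general).
#'
#' @inheritParams classify_zeros
#' @param control A [microgee_control()] list.
#' @return A list with elements `counts` (filtered matrix with `NA` masks),
#'   `zero_labels` (the final [classify_zeros()] matrix), and `report`
#'   (removed taxa/samples with reasons plus the masked-cell count).
#' @export
apply_preprocessing <- function(counts, meta, control = microgee_control()) {
  counts <- validate_counts(counts)
  meta <- validate_metadata(meta, counts)
  report <- new_filter_report()
  cur <- counts
  storage.mode(cur) <- "double"
  labels <- NULL
  for (pass in 1:10) {
    p1 <- filter_low_prevalence(cur, control$prevalence_min)
    p2 <- filter_low_depth_samples(p1$counts, control$min_library_size)
    report <- merge_filter_reports(report, p1$report, p2$report)
    m <- meta[meta$sample_id %in% colnames(p2$counts), , drop = FALSE]
    labels <- classify_zeros(p2$counts, m, control$structural_fraction,
                             control$outlier_zero_prevalence)
    vflag <- detect_outlier_values(p2$counts, m, control$outlier_k)
    nxt <- p2$counts
    mask <- (!is.na(labels) & labels == "outlier_zero") | vflag
    nxt[mask] <- NA_real_
    if (identical(dim(nxt), dim(cur)) && identical(is.na(nxt), is.na(cur))) {
      cur <- nxt
      break
    }
    cur <- nxt
  }
  report$cells_masked <- sum(is.na(cur))
  list(counts = cur, zero_labels = labels, report = report)
}

new_filter_report <- function(removed_taxa = NULL, removed_samples = NULL) {
  empty_t <- data.frame(taxon = character(), reason = character())
  empty_s <- data.frame(sample = character(), reason = character())
  structure(list(
    removed_taxa = if (is.null(removed_taxa)) empty_t else removed_taxa,
    removed_samples = if (is.null(removed_samples)) empty_s else
      removed_samples,
    cells_masked = 0L
  ), class = "filter_report")
}

merge_filter_reports <- function(...) {
  reps <- list(...)
  out <- new_filter_report()
  for (r in reps) {
    out$removed_taxa <- unique(rbind(out$removed_taxa, r$removed_taxa))
    out$removed_samples <- unique(rbind(out$removed_samples,
                                        r$removed_samples))
  }
  out
}

#' Serialize preprocessing outputs
#'
#' Writes `filter_report.json` and `zero_labels.tsv` (taxon, sample, label)
#' to a directory.
#'
#' @param prep Result of [apply_preprocessing()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_preprocessing <- function(prep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(removed_taxa = prep$report$removed_taxa,
         removed_samples = prep$report$removed_samples,
         cells_masked = prep$report$cells_masked),
    file.path(dir, "filter_report.json"), auto_unbox = TRUE, digits = NA
  )
  lab <- prep$zero_labels
  idx <- which(!is.na(lab) & lab != "observed", arr.ind = TRUE)
  df <- data.frame(taxon = rownames(lab)[idx[, 1L]],
                   sample = colnames(lab)[idx[, 2L]],
                   label = lab[idx])
  write_result_table(df, file.path(dir, "zero_labels.tsv"))
  invisible(dir)
}
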