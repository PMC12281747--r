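#' Differential abundance analysis with GEE-CLR-CTF
#'
#' The main fitting function.  Runs, in fixed order: preprocessing
#' (prevalence and library-size filters, zero classification, outlier
#' masking), CTF normalization (counts adjusted with trimmed-mean-of-
#' M-values factors), pseudocount addition, centered log-ratio transform,
#' a joint Gaussian identity-link GEE across all retained taxa with
#' subject clusters, and local/global Wald inference with
#' Benjamini-Hochberg adjustment.  The model for the CLR value of taxon
#' `k` in subject `i` (group `g`, occasion `j`) is
#' `E(Y_ijg^k) = b0^k + b1g^k + b2j^k + b3jg^k`
#' with reference-level coefficients fixed at zero, so the group, time and
#' group x time interaction effects are taxon-specific while all `K x J`
#' measurements of a subject are treated as equicorrelated
#' (exchangeable working correlation) and inference uses the robust
#' sandwich covariance.
#'
#' @param counts Count matrix (taxa x samples) or a path accepted by
#'   [read_count_table()].
#' @param meta Sample frame (see [as_sample_frame()]) or a path accepted
#'   by [read_metadata()].
#' @param control A [microgee_control()] list; individual fields may also
#'   be passed through `...`.
#' @param ... Overrides forwarded to [microgee_control()].
#' @return An object of class `"microgee"` with components `global` and
#'   `local` (the DA tables), `fit` (the [fit_gee()] object), `prep`
#'   (preprocessing result), `norm` (normalization factors), `clr`
#'   (transformed matrix), `control`, and `provenance`.
#' @examples
#' sim <- simulate_cross_sectional(sim_scenario(
#'   n_taxa = 30, n_samples = 20, seed = 7,
#'   template = synthetic_template(seed = 7)))
#' fit <- microgee(sim$counts, sim$meta, min_library_size = 0)
#' fit
#' @export
microgee <- function(counts, meta, control = microgee_control(), ...) {
  dots <- list(...)
  if (length(dots)) {
    control <- do.call(microgee_control,
                       modifyList(unclass(control), dots))
  }
  if (is.character(counts)) counts <- read_count_table(counts)
  if (is.character(meta)) {
    meta <- read_metadata(meta, counts, group_ref = control$group_ref,
                          occasion_ref = control$occasion_ref)
  } else if (!is.null(control$group_ref) || !is.null(control$occasion_ref)) {
    meta <- as_sample_frame(meta, counts, group_ref = control$group_ref,
                            occasion_ref = control$occasion_ref)
  }
  counts <- validate_counts(counts)
  meta <- validate_metadata(meta, counts)
  counts <- counts[, meta$sample_id[meta$sample_id %in% colnames(counts)],
                   drop = FALSE]
  if (nlevels(droplevels(meta$group)) < 2L) {
    stop("at least 2 groups are required for differential abundance")
  }
  set.seed(control$seed)

  prep <- apply_preprocessing(counts, meta, control)
  meta_f <- meta[meta$sample_id %in% colnames(prep$counts), , drop = FALSE]
  norm <- ctf_normalize(prep$counts, control$trim_M, control$trim_A)
  clr <- clr_transform(add_pseudocount(norm$adjusted, control$pseudocount))

  if (control$joint) {
    des <- build_design(clr, meta_f)
    fit <- fit_gee(des$Y, des$X, des$cluster,
                   corstr = control$working_correlation,
                   tol = control$tol, max_iter = control$max_iter)
    if (!fit$converged) {
      stop("GEE did not converge in ", fit$n_iter, " iterations (last ",
           "alpha = ", signif(fit$alpha, 4), ", scale = ",
           signif(fit$scale, 4), "); consider working_correlation = ",
           "'independence' or raising max_iter")
    }
    tabs <- build_da_tables(fit, control$alpha_level)
  } else {
    fits <- lapply(rownames(clr), function(tx) {
      des <- build_design(clr[tx, , drop = FALSE], meta_f)
      fit_gee(des$Y, des$X, des$cluster,
              corstr = control$working_correlation,
              tol = control$tol, max_iter = control$max_iter)
    })
    names(fits) <- rownames(clr)
    bad <- names(fits)[!vapply(fits, `[[`, logical(1L), "converged")]
    if (length(bad)) {
      stop("per-taxon GEE did not converge for: ",
           paste(bad, collapse = ", "))
    }
    locs <- do.call(rbind, lapply(fits, local_tests))
    glos <- do.call(rbind, lapply(fits, global_tests))
    locs$p_adj <- NA_real_
    for (tm in unique(locs$term)) {
      i <- locs$term == tm
      locs$p_adj[i] <- adjust_bh(locs$p[i])
    }
    glos$p_adj <- adjust_bh(glos$p)
    tabs <- list(local = call_significance(locs, control$alpha_level),
                 global = call_significance(glos, control$alpha_level))
    tabs$local <- tabs$local[order(tabs$local$term, tabs$local$p,
                                   tabs$local$taxon), ]
    tabs$global <- tabs$global[order(tabs$global$p, tabs$global$taxon), ]
    rownames(tabs$local) <- rownames(tabs$global) <- NULL
    fit <- fits
  }

  structure(list(
    global = tabs$global,
    local = tabs$local,
    fit = fit,
    prep = prep,
    norm = norm,
    clr = clr,
    control = control,
    provenance = list(
      package_version = as.character(utils::packageVersion("microgee")),
      r_version = R.version.string,
      seed = control$seed,
      stages = c("preprocess", "ctf_normalize", "pseudocount", "clr",
                 "gee_fit", "wald_tests", "bh_adjust"),
      n_taxa_input = nrow(counts), n_samples_input = ncol(counts),
      n_taxa_retained = nrow(prep$counts),
      n_samples_retained = ncol(prep$counts)
    )
  ), class = "microgee")
}

#' @export
print.microgee <- function(x, ...) {
  pv <- x$provenance
  cat("GEE-CLR-CTF differential abundance fit\n")
  cat(sprintf("  taxa: %d retained of %d;  samples: %d retained of %d\n",
              pv$n_taxa_retained, pv$n_taxa_input,
              pv$n_samples_retained, pv$n_samples_input))
  if (inherits(x$fit, "gee_fit")) {
    cat(sprintf("  working correlation: %s (alpha = %.4f), scale = %.4f\n",
                x$fit$corstr, x$fit$alpha, x$fit$scale))
  }
  cat(sprintf("  globally significant taxa (BH-adjusted p < %.3g): %d\n",
              x$control$alpha_level, sum(x$global$significant)))
  invisible(x)
}

#' @export
summary.microgee <- function(object, ...) {
  structure(list(
    global = object$global,
    local = object$local,
    n_significant = sum(object$global$significant),
    alpha_level = object$control$alpha_level,
    provenance = object$provenance
  ), class = "summary.microgee")
}

#' @export
print.summary.microgee <- function(x, ...) {
  cat("Global per-taxon Wald tests (top rows):\n")
  print(utils::head(x$global, 10L))
  cat("\nLocal per-coefficient tests (top rows):\n")
  print(utils::head(x$local, 10L))
  cat(sprintf("\n%d taxa significant at adjusted p < %.3g\n",
              x$n_significant, x$alpha_level))
  invisible(x)
}

#' @export
coef.microgee <- function(object, ...) {
  if (inherits(object$fit, "gee_fit")) object$fit$beta
  else unlist(lapply(object$fit, `[[`, "beta"))
}

#' @export
vcov.microgee <- function(object, ...) {
  if (inherits(object$fit, "gee_fit")) object$fit$robust_cov
  else lapply(object$fit, `[[`, "robust_cov")
}

#' Volcano-style plot of a DA fit
#'
#' Plots per-taxon maximum absolute local effect against the global
#' `-log10` adjusted p-value, highlighting significant taxa.
#'
#' @param x A [microgee()] object.
#' @param ... Passed to [plot()].
#' @importFrom graphics abline
#' @export
plot.microgee <- function(x, ...) {
  eff <- tapply(abs(x$local$estimate), x$local$taxon, max)
  ord <- match(x$global$taxon, names(eff))
  px <- as.numeric(eff[ord])
  py <- -log10(pmax(x$global$p_adj, 1e-300))
  plot(px, py, pch = 19,
       col = ifelse(x$global$significant, "firebrick", "grey50"),
       xlab = "max |CLR effect|", ylab = "-log10 adjusted p", ...)
  abline(h = -log10(x$control$alpha_level), lty = 2)
  invisible(x)
}

#' Taxa called differentially abundant
#'
#' @param x A [microgee()] object.
#' @param table Which table drives the call: `"global"` (default) or
#'   `"local"` (any significant local term).
#' @return Character vector of significant taxon ids.
#' @export
significant_taxa <- function(x, table = c("global", "local")) {
  table <- match.arg(table)
  tab <- x[[table]]
  sort(unique(tab$taxon[tab$significant]))
}

#' Write all pipeline outputs
#'
#' Writes `global.tsv`, `local.tsv`, `provenance.json`,
#' `filter_report.json`, `zero_labels.tsv`, `factors.tsv` and
#' `gee_fit.json` into a directory.
#'
#' @param x A [microgee()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_microgee <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_result_table(x$global, file.path(dir, "global.tsv"))
  write_result_table(x$local, file.path(dir, "local.tsv"))
  write_preprocessing(x$prep, dir)
  write_factors(x$norm, file.path(dir, "factors.tsv"))
  if (inherits(x$fit, "gee_fit")) {
    write_gee_fit(x$fit, file.path(dir, "gee_fit.json"))
  }
  prov <- x$provenance
  prov$control <- unclass(x$control)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
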