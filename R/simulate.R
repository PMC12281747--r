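#' Benchmark simulation scenario
#'
#' Collects the knobs of the negative-binomial benchmark simulator.  The
#' defaults are the framework's standard operating point: 100 taxa, 50
#' samples (40 for two-occasion designs), a threefold spike-in for 10% of
#' taxa split between up- and down-regulation (compensation), a Pearson-
#' residual outlier cap of 5, structural zeros for the down-regulated
#' taxa, copula-induced inter-taxa correlation, and unit coverage.
#'
#' @param template Taxa x samples count table of one stable group (or a
#'   pre-fitted [fit_template()] object).
#' @param n_taxa Number of taxa per simulated dataset.
#' @param n_samples Number of samples (default 50 cross-sectional, 40
#'   longitudinal; must be even for two occasions).
#' @param n_occasions 1 (cross-sectional) or 2 (longitudinal).
#' @param fold_change Spike-in fold change (>= 1; 1 disables spiking).
#' @param direction `"up"` or `"up_and_down"` (compensation; spiked taxa
#'   split evenly).
#' @param spike_fraction Fraction of taxa spiked.
#' @param residual_cap Pearson-residual cap for outlier injection (3, 4,
#'   5, or `Inf` to disable); lower caps induce more outliers.
#' @param outlier_fraction Fraction of cells regenerated at the residual
#'   cap boundary.
#' @param depth_scale Coverage multiplier (0.5 = half depth, 2 = double).
#' @param structural_zeros Introduce hard zeros for down-regulated spiked
#'   taxa in the affected group (compensation scenarios).
#' @param correlation Induce inter-taxa correlation through a Gaussian
#'   copula with a sparse random correlation graph.
#' @param correlation_edge_prob,correlation_rho_range Copula graph edge
#'   probability and absolute-correlation range.
#' @param subject_sigma Standard deviation of the subject-level lognormal
#'   factor inducing within-subject dependence (two-occasion designs).
#' @param template_prevalence Prevalence floor applied when fitting the
#'   template (taxa present in at least this fraction of samples).
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(template,
                         n_taxa = 100L,
                         n_samples = NULL,
                         n_occasions = 1L,
                         fold_change = 3,
                         direction = c("up_and_down", "up"),
                         spike_fraction = 0.10,
                         residual_cap = 5,
                         outlier_fraction = 0.02,
                         depth_scale = 1,
                         structural_zeros = TRUE,
                         correlation = TRUE,
                         correlation_edge_prob = 0.05,
                         correlation_rho_range = c(0.3, 0.7),
                         subject_sigma = 0.3,
                         template_prevalence = 0.05,
                         seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(n_occasions %in% c(1L, 2L), fold_change >= 1,
            spike_fraction >= 0, spike_fraction <= 1,
            residual_cap > 0, depth_scale > 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  if (is.null(n_samples)) n_samples <- if (n_occasions == 2L) 40L else 50L
  structure(list(
    template = template, n_taxa = as.integer(n_taxa),
    n_samples = as.integer(n_samples), n_occasions = as.integer(n_occasions),
    fold_change = fold_change, direction = direction,
    spike_fraction = spike_fraction, residual_cap = residual_cap,
    outlier_fraction = outlier_fraction, depth_scale = depth_scale,
    structural_zeros = structural_zeros, correlation = correlation,
    correlation_edge_prob = correlation_edge_prob,
    correlation_rho_range = correlation_rho_range,
    subject_sigma = subject_sigma,
    template_prevalence = template_prevalence,
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

#' Synthetic stable-group template
#'
#' Generates a synthetic taxa x samples count table emulating a stable
#' (non-differential) healthy cohort profiled by pyrosequencing-era 16S
#' amplicon sequencing, in which samples from several distinct body-site
#' communities are pooled into a single group.  Each community is a
#' long-tailed (log-normal) relative-abundance profile over the same taxon
#' set; every sample is drawn from one community at random, with strong
#' per-taxon negative-binomial overdispersion (sizes mostly 0.1-1) and
#' log-normal library sizes around a few thousand reads.  Pooling
#' heterogeneous communities is what makes real multi-site reference
#' cohorts so variable: taxa abundant in one community and rare in
#' another appear bimodal in the pooled group, which inflates the
#' apparent dispersion of the method-of-moments fit in [fit_template()]
#' and produces the high sparsity (roughly two thirds of cells zero)
#' typical of such tables.  It stands in for a real stable-group table
#' wherever one is not supplied.
#'
#' @param n_taxa,n_samples Template dimensions.
#' @param mean_depth Median library size.
#' @param n_communities Number of pooled body-site communities.
#' @param seed Integer seed.
#' @return An integer count matrix with taxon/sample names.
#' @export
synthetic_template <- function(n_taxa = 300L, n_samples = 60L,
                               mean_depth = 5000, n_communities = 3L,
                               seed = 1L) {
  stopifnot(n_communities >= 1L)
  with_seed(seed, {
    profiles <- vapply(seq_len(n_communities), function(j) {
      la <- rnorm(n_taxa, 0, 2.5)
      exp(la) / sum(exp(la))
    }, numeric(n_taxa))
    size_k <- rlnorm(n_taxa, log(0.3), 0.6)
    L <- round(rlnorm(n_samples, log(mean_depth), 0.3))
    community <- sample.int(n_communities, n_samples, replace = TRUE)
    m <- matrix(0L, n_taxa, n_samples)
    for (s in seq_len(n_samples)) {
      m[, s] <- rnbinom(n_taxa, mu = profiles[, community[s]] * L[s],
                        size = size_k)
    }
    dimnames(m) <- list(sprintf("taxon_%03d", seq_len(n_taxa)),
                        sprintf("tmpl_%03d", seq_len(n_samples)))
    m
  })
}

#' Fit negative-binomial template parameters
#'
#' Method-of-moments per-taxon negative-binomial fit on a stable-group
#' count table: mean relative abundance `pi` (converted downstream to
#' per-sample means `theta = pi * library size`), NB size
#' `mean^2 / (var - mean)` with the dispersion (1/size) floored at 1e-8
#' when the variance does not exceed the mean, and the empirical
#' library-size distribution.  All-zero taxa are excluded with a warning;
#' taxa below the prevalence floor are dropped.
#'
#' @param template Count matrix (taxa x samples), >= 10 samples.
#' @param prevalence_min Prevalence floor (default 0.05).
#' @return A list of class `"nb_template"`: `taxa`, `pi`, `size`,
#'   `lib_sizes`.
#' @export
fit_template <- function(template, prevalence_min = 0.05) {
  if (inherits(template, "nb_template")) return(template)
  stopifnot(ncol(template) >= 10L)
  allzero <- rowSums(template) == 0
  if (any(allzero)) {
    warning(sum(allzero), " all-zero taxa excluded from the template")
    template <- template[!allzero, , drop = FALSE]
  }
  prev <- rowMeans(template > 0)
  template <- template[prev >= prevalence_min, , drop = FALSE]
  L <- colSums(template)
  pi_k <- rowMeans(sweep(template, 2L, L, `/`))
  m <- rowMeans(template)
  v <- apply(template, 1L, var)
  size_k <- ifelse(v > m, m^2 / (v - m), 1e8)
  size_k <- pmin(size_k, 1e8)    # dispersion floor 1e-8
  structure(list(taxa = rownames(template), pi = pi_k, size = size_k,
                 lib_sizes = L), class = "nb_template")
}

#' Correlated negative-binomial sampler
#'
#' Builds a Gaussian copula over a sparse random correlation graph
#' (Erdos-Renyi edges with probability `edge_prob`, correlations drawn
#' uniformly in `+/- rho_range`) and returns a sampler mapping correlated
#' normals to NB quantiles, preserving the marginal NB parameters.
#' Non-positive-definite targets are repaired to the nearest correlation
#' matrix.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param edge_prob Edge probability of the correlation graph.
#' @param rho_range Length-2 range for absolute correlations.
#' @return A list with `sample(mu, size)` (mu a taxa x samples matrix,
#'   size a per-taxon vector) and `corr` (the target correlation matrix).
#' @export
induce_correlation <- function(n_taxa, edge_prob = 0.05,
                               rho_range = c(0.3, 0.7)) {
  stopifnot(n_taxa >= 2L)
  C <- diag(n_taxa)
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  on_edge <- runif(nrow(pairs)) < edge_prob
  if (any(on_edge)) {
    rho <- runif(sum(on_edge), rho_range[1L], rho_range[2L]) *
      sample(c(-1, 1), sum(on_edge), replace = TRUE)
    C[pairs[on_edge, , drop = FALSE]] <- rho
    C[pairs[on_edge, 2:1, drop = FALSE]] <- rho
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
    message("correlation target repaired to nearest positive-definite")
  }
  U_chol <- chol(C)
  sampler <- function(mu, size) {
    ns <- ncol(mu)
    Z <- matrix(rnorm(ns * n_taxa), ns, n_taxa) %*% U_chol
    U <- pnorm(Z)
    y <- qnbinom(t(U), mu = mu, size = rep(size, ns))
    dimnames(y) <- dimnames(mu)
    y
  }
  list(sample = sampler, corr = C)
}

#' Inject boundary outliers
#'
#' Perturbs the count matrix so that the maximum allowed Pearson residual
#' under the generating NB model equals `residual_cap`: cells exceeding
#' the cap are pulled to the boundary value
#' `floor(mu + cap * sqrt(mu + mu^2/size))`, and a random fraction of
#' cells is regenerated at the boundary, becoming outliers relative to the
#' model.  Lower caps put the boundary closer to the mean and therefore
#' induce more boundary cells.
#'
#' @param counts Count matrix.
#' @param mu,size Generating NB mean matrix and per-taxon size vector.
#' @param residual_cap Positive cap (use `Inf` for the identity).
#' @param outlier_fraction Fraction of cells regenerated at the boundary.
#' @return The perturbed non-negative integer matrix.
#' @export
inject_outliers <- function(counts, mu, size, residual_cap = 5,
                            outlier_fraction = 0.02) {
  stopifnot(residual_cap > 0)
  if (!is.finite(residual_cap)) return(counts)
  sd_mat <- sqrt(mu + mu^2 / size)
  boundary <- pmax(floor(mu + residual_cap * sd_mat), 0)
  out <- pmin(counts, boundary)
  n_inject <- round(outlier_fraction * length(counts))
  if (n_inject > 0) {
    cells <- sample(length(counts), n_inject)
    out[cells] <- boundary[cells]
  }
  storage.mode(out) <- "integer"
  out
}

#' Inject structural zeros
#'
#' Sets the counts of down-regulated spiked taxa to hard zero in the
#' affected samples (the spiked group, restricted to the spiked occasion
#' in longitudinal designs): their abundance is reduced below one count
#' ("log-negative") and floored to zero.  The truth set is unchanged.
#'
#' @param counts Count matrix.
#' @param truth Truth data.frame with columns `taxon` and `direction`.
#' @param affected_samples Character vector of sample ids to zero.
#' @return The modified matrix.
#' @export
inject_structural_zeros <- function(counts, truth, affected_samples) {
  down <- truth$taxon[truth$direction == "down"]
  if (length(down)) {
    counts[down, affected_samples] <- 0L
  }
  counts
}

#' Scale sequencing coverage
#'
#' Halved coverage (`depth_scale < 1`) is produced by binomial thinning,
#' which preserves zero cells; increased coverage (`depth_scale > 1`) is
#' produced by redrawing from the NB model with scaled means (requires
#' `mu` and `size`).
#'
#' @param counts Count matrix.
#' @param depth_scale Positive coverage multiplier.
#' @param mu,size NB parameters, required when `depth_scale > 1`.
#' @return The rescaled count matrix.
#' @export
scale_coverage <- function(counts, depth_scale, mu = NULL, size = NULL) {
  stopifnot(depth_scale > 0)
  if (depth_scale == 1) return(counts)
  if (depth_scale < 1) {
    out <- counts
    out[] <- rbinom(length(counts), size = as.integer(counts),
                    prob = depth_scale)
    return(out)
  }
  if (is.null(mu) || is.null(size)) {
    stop("depth_scale > 1 requires the NB parameters (mu, size)")
  }
  out <- counts
  out[] <- rnbinom(length(counts), mu = as.numeric(mu) * depth_scale,
                   size = rep(size, ncol(counts)))
  out
}

#' Stratify taxa by relative abundance
#'
#' Assigns each taxon to a stratum by its quantile rank of mean relative
#' abundance across taxa: low (`< 10%`), intermediate (`10%-90%`), or high
#' (`> 90%`).
#'
#' @param counts Count matrix.
#' @return Named factor with levels low/intermediate/high.
#' @export
stratify_abundance <- function(counts) {
  rel <- rowMeans(sweep(counts, 2L, pmax(colSums(counts), 1), `/`))
  pr <- rank(rel, ties.method = "average") / length(rel)
  out <- ifelse(pr < 0.10, "low", ifelse(pr > 0.90, "high", "intermediate"))
  factor(setNames(out, rownames(counts)),
         levels = c("low", "intermediate", "high"))
}

# shared spike-set construction
pick_spikes <- function(taxa, spike_fraction, fold_change, direction) {
  n_spike <- round(length(taxa) * spike_fraction)
  if (fold_change == 1 || n_spike < 1) {
    if (fold_change > 1 && spike_fraction > 0 && n_spike < 1) {
      warning("spike_fraction too small for any spiked taxon; empty truth")
    }
    return(data.frame(taxon = character(), direction = character()))
  }
  spiked <- sample(taxa, n_spike)
  dirs <- if (direction == "up") rep("up", n_spike) else
    rep(c("up", "down"), length.out = n_spike)
  data.frame(taxon = spiked, direction = dirs, stringsAsFactors = FALSE)
}

# shared NB drawing step (independent or copula-correlated)
draw_counts <- function(mu, size, scn) {
  if (scn$correlation && nrow(mu) >= 2L) {
    cop <- induce_correlation(nrow(mu), scn$correlation_edge_prob,
                              scn$correlation_rho_range)
    cop$sample(mu, size)
  } else {
    y <- mu
    y[] <- rnbinom(length(mu), mu = as.numeric(mu),
                   size = rep(size, ncol(mu)))
    y
  }
}

#' Simulate a cross-sectional benchmark dataset
#'
#' Draws a two-group dataset from the NB template: `n_taxa` randomly
#' selected taxa, `n_samples` samples with resampled library sizes and
#' shuffled group assignment, fold-change spike-ins in group 2 (up and/or
#' down), followed by the scenario's outlier injection, structural zeros,
#' and coverage scaling.  Deterministic given the scenario seed.
#'
#' @param scn A [sim_scenario()].
#' @return A list with `counts` (integer matrix), `meta` (sample frame;
#'   subjects coincide with samples), `truth` (data.frame taxon,
#'   direction), and `params` (the per-cell NB means and per-taxon sizes
#'   used).
#' @export
simulate_cross_sectional <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  with_seed(scn$seed, {
    tpl <- fit_template(scn$template, scn$template_prevalence)
    if (length(tpl$taxa) < scn$n_taxa) {
      stop("template provides ", length(tpl$taxa), " taxa; scenario needs ",
           scn$n_taxa)
    }
    sel <- sample(seq_along(tpl$taxa), scn$n_taxa)
    taxa <- tpl$taxa[sel]
    pi_k <- tpl$pi[sel]
    size_k <- tpl$size[sel]
    n <- scn$n_samples
    L <- sample(tpl$lib_sizes, n, replace = TRUE)
    grp <- rep("group2", n)
    grp[sample(n, floor(n / 2))] <- "group1"
    sample_ids <- sprintf("S%03d", seq_len(n))
    truth <- pick_spikes(taxa, scn$spike_fraction, scn$fold_change,
                         scn$direction)
    mu <- outer(pi_k, L)
    dimnames(mu) <- list(taxa, sample_ids)
    g2 <- which(grp == "group2")
    up <- truth$taxon[truth$direction == "up"]
    dn <- truth$taxon[truth$direction == "down"]
    mu[up, g2] <- mu[up, g2] * scn$fold_change
    mu[dn, g2] <- mu[dn, g2] / scn$fold_change
    if (scn$depth_scale > 1) mu <- mu * scn$depth_scale
    y <- draw_counts(mu, size_k, scn)
    y <- inject_outliers(y, mu, size_k, scn$residual_cap,
                         scn$outlier_fraction)
    if (scn$structural_zeros) {
      y <- inject_structural_zeros(y, truth, sample_ids[g2])
    }
    if (scn$depth_scale < 1) y <- scale_coverage(y, scn$depth_scale)
    storage.mode(y) <- "integer"
    meta <- data.frame(sample_id = sample_ids, subject_id = sample_ids,
                       group = factor(grp, levels = c("group1", "group2")),
                       occasion = factor(rep("1", n)),
                       stringsAsFactors = FALSE)
    list(counts = y, meta = meta, truth = truth,
         params = list(mu = mu, size = size_k))
  })
}

#' Simulate a longitudinal benchmark dataset
#'
#' Two-group, two-occasion repeated-measures design: each subject is
#' observed at both occasions, spiked taxa receive the fold change in
#' group 2 at occasion 2 only (a pure group x time interaction signal),
#' and within-subject dependence is induced by a shared subject-level
#' lognormal factor multiplying all taxon means.
#'
#' @param scn A [sim_scenario()] with `n_occasions = 2` and an even
#'   `n_samples`.
#' @return As [simulate_cross_sectional()], with subjects spanning two
#'   samples each.
#' @export
simulate_longitudinal <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (scn$n_occasions != 2L) stop("scenario must have n_occasions = 2")
  if (scn$n_samples %% 2L != 0L) {
    stop("n_samples must be even: each subject is observed at both occasions")
  }
  with_seed(scn$seed, {
    tpl <- fit_template(scn$template, scn$template_prevalence)
    if (length(tpl$taxa) < scn$n_taxa) {
      stop("template provides ", length(tpl$taxa), " taxa; scenario needs ",
           scn$n_taxa)
    }
    sel <- sample(seq_along(tpl$taxa), scn$n_taxa)
    taxa <- tpl$taxa[sel]
    pi_k <- tpl$pi[sel]
    size_k <- tpl$size[sel]
    n_sub <- scn$n_samples %/% 2L
    subj <- sprintf("subj%03d", seq_len(n_sub))
    grp_s <- rep("group2", n_sub)
    grp_s[sample(n_sub, floor(n_sub / 2))] <- "group1"
    u <- exp(rnorm(n_sub, 0, scn$subject_sigma))
    meta <- data.frame(
      sample_id = paste0(rep(subj, each = 2L), "_t", rep(1:2, n_sub)),
      subject_id = rep(subj, each = 2L),
      group = factor(rep(grp_s, each = 2L),
                     levels = c("group1", "group2")),
      occasion = factor(rep(c("1", "2"), n_sub)),
      stringsAsFactors = FALSE
    )
    n <- nrow(meta)
    L <- sample(tpl$lib_sizes, n, replace = TRUE)
    mu <- outer(pi_k, L * rep(u, each = 2L))
    dimnames(mu) <- list(taxa, meta$sample_id)
    truth <- pick_spikes(taxa, scn$spike_fraction, scn$fold_change,
                         scn$direction)
    hit <- which(meta$group == "group2" & meta$occasion == "2")
    up <- truth$taxon[truth$direction == "up"]
    dn <- truth$taxon[truth$direction == "down"]
    mu[up, hit] <- mu[up, hit] * scn$fold_change
    mu[dn, hit] <- mu[dn, hit] / scn$fold_change
    if (scn$depth_scale > 1) mu <- mu * scn$depth_scale
    y <- draw_counts(mu, size_k, scn)
    y <- inject_outliers(y, mu, size_k, scn$residual_cap,
                         scn$outlier_fraction)
    if (scn$structural_zeros) {
      y <- inject_structural_zeros(y, truth, meta$sample_id[hit])
    }
    if (scn$depth_scale < 1) y <- scale_coverage(y, scn$depth_scale)
    storage.mode(y) <- "integer"
    list(counts = y, meta = meta, truth = truth,
         params = list(mu = mu, size = size_k))
  })
}

#' Write a simulated dataset
#'
#' Writes `counts.tsv`, `meta.tsv` and `truth.tsv` to a directory.
#'
#' @param sim Result of [simulate_cross_sectional()] or
#'   [simulate_longitudinal()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_result_table(sim$meta, file.path(dir, "meta.tsv"))
  write_result_table(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
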