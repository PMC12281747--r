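test_that("template fitting matches the method-of-moments definition", {
  m <- rbind(t1 = c(4L, 8L, 12L, 16L),
             t2 = c(10L, 10L, 10L, 10L),
             t3 = c(0L, 0L, 0L, 0L))
  m <- cbind(m, m, m)  # 12 samples to satisfy the size floor
  colnames(m) <- sprintf("s%02d", 1:12)
  tpl <- suppressWarnings(fit_template(m, prevalence_min = 0))
  expect_setequal(tpl$taxa, c("t1", "t2"))  # all-zero taxon excluded
  expect_warning(fit_template(m, prevalence_min = 0), "all-zero")
  L <- colSums(m[1:2, ])
  expect_equal(unname(tpl$pi["t1"]), mean(m["t1", ] / L), tolerance = 1e-12)
  mu1 <- mean(m["t1", ]); v1 <- var(m["t1", ])
  expect_equal(unname(tpl$size["t1"]), mu1^2 / (v1 - mu1), tolerance = 1e-12)
  # variance <= mean -> dispersion floored at 1e-8 (size capped at 1e8)
  expect_equal(unname(tpl$size["t2"]), 1e8)
  expect_identical(tpl$lib_sizes, colSums(m))
})

test_that("simulation is bit-exact in the seed and leaves the RNG alone", {
  scn <- sim_scenario(template = bench_template(), n_taxa = 40,
                      n_samples = 20, seed = 99)
  set.seed(1); before <- runif(1)
  s1 <- suppressMessages(simulate_cross_sectional(scn))
  s2 <- suppressMessages(simulate_cross_sectional(scn))
  expect_identical(s1, s2)
  scn$seed <- 100L
  s3 <- suppressMessages(simulate_cross_sectional(scn))
  expect_false(identical(s1$counts, s3$counts))
  # with_seed restores the global RNG state
  set.seed(1)
  invisible(suppressMessages(simulate_cross_sectional(scn)))
  expect_identical(runif(1), before)
})

test_that("spike-ins multiply the NB means by the fold change", {
  scn <- sim_scenario(template = bench_template(), n_taxa = 50,
                      n_samples = 30, fold_change = 3, correlation = FALSE,
                      structural_zeros = FALSE, residual_cap = Inf, seed = 55)
  sim <- simulate_cross_sectional(scn)
  mu <- sim$params$mu
  g1 <- sim$meta$sample_id[sim$meta$group == "group1"]
  g2 <- sim$meta$sample_id[sim$meta$group == "group2"]
  up <- sim$truth$taxon[sim$truth$direction == "up"]
  dn <- sim$truth$taxon[sim$truth$direction == "down"]
  base <- setdiff(rownames(mu), sim$truth$taxon)[1]
  # mu is pi * L with the fold applied in group 2 only, so the ratio of
  # taxon-to-baseline mean ratios between any group2 and group1 sample is
  # exactly the fold (up), its inverse (down), or 1 (null)
  rr <- function(tx) (mu[tx, g2[1]] / mu[base, g2[1]]) /
    (mu[tx, g1[1]] / mu[base, g1[1]])
  expect_equal(unname(vapply(up, rr, numeric(1))),
               rep(3, length(up)), tolerance = 1e-12)
  expect_equal(unname(vapply(dn, rr, numeric(1))),
               rep(1 / 3, length(dn)), tolerance = 1e-12)
  # Monte-Carlo: realized counts track the spiked means within 5%
  big <- sim_scenario(template = bench_template(), n_taxa = 30,
                      n_samples = 2000, fold_change = 3,
                      correlation = FALSE, structural_zeros = FALSE,
                      residual_cap = Inf, spike_fraction = 0.2, seed = 7)
  bs <- simulate_cross_sectional(big)
  mu_bar <- rowMeans(bs$params$mu)
  v_bar <- rowMeans(bs$params$mu +
                      sweep(bs$params$mu^2, 1, bs$params$size, `/`))
  z <- (rowMeans(bs$counts) - mu_bar) / sqrt(v_bar / ncol(bs$counts))
  expect_lt(max(abs(z)), 5)
})

test_that("up/down split is even and fold 1 disables spiking", {
  tr <- with_seed(3, pick_spikes(paste0("t", 1:40), 0.25, 3, "up_and_down"))
  expect_equal(nrow(tr), 10)
  expect_equal(sum(tr$direction == "up"), 5)
  expect_equal(sum(tr$direction == "down"), 5)
  expect_equal(nrow(with_seed(3, pick_spikes(paste0("t", 1:40), 0.25, 1,
                                             "up_and_down"))), 0)
  tr_up <- with_seed(3, pick_spikes(paste0("t", 1:40), 0.1, 2, "up"))
  expect_true(all(tr_up$direction == "up"))
})

test_that("lower residual caps induce more boundary cells", {
  with_seed(31, {
    mu <- matrix(runif(600, 5, 60), 30, 20)
    size <- runif(30, 0.3, 2)
    y <- matrix(rnbinom(600, mu = mu, size = size), 30, 20)
    y3 <- inject_outliers(y, mu, size, residual_cap = 3,
                          outlier_fraction = 0)
    y5 <- inject_outliers(y, mu, size, residual_cap = 5,
                          outlier_fraction = 0)
    expect_gte(sum(y3 != y), sum(y5 != y))
    # after injection no Pearson residual exceeds the cap
    sd3 <- sqrt(mu + mu^2 / size)
    expect_true(all((y3 - mu) / sd3 <= 3))
    expect_identical(inject_outliers(y, mu, size, Inf, 0.5), y)
    # regeneration places cells exactly at the boundary
    yb <- inject_outliers(y, mu, size, residual_cap = 4,
                          outlier_fraction = 0.1)
    boundary <- pmax(floor(mu + 4 * sd3), 0)
    expect_true(all(yb <= boundary))
  })
})

test_that("structural zeros null out down-regulated taxa in group 2", {
  scn <- sim_scenario(template = bench_template(), n_taxa = 60,
                      n_samples = 30, seed = 77)
  sim <- suppressMessages(simulate_cross_sectional(scn))
  dn <- sim$truth$taxon[sim$truth$direction == "down"]
  g2 <- sim$meta$sample_id[sim$meta$group == "group2"]
  g1 <- sim$meta$sample_id[sim$meta$group == "group1"]
  expect_true(all(sim$counts[dn, g2] == 0))
  expect_true(any(sim$counts[dn, g1] > 0))
})

test_that("coverage scaling halves or doubles depth as documented", {
  with_seed(41, {
    y <- matrix(rnbinom(30000, mu = 40, size = 1), 30, 1000)
    half <- scale_coverage(y, 0.5)
    expect_lt(abs(mean(colSums(half)) / mean(colSums(y)) - 0.5), 0.05)
    expect_true(all(half[y == 0] == 0))  # thinning preserves zeros
    expect_error(scale_coverage(y, 2), "requires the NB parameters")
    mu <- matrix(40, 30, 1000)
    dbl <- scale_coverage(y, 2, mu = mu, size = rep(1, 30))
    expect_lt(abs(mean(colSums(dbl)) / mean(colSums(y)) - 2), 0.05)
  })
})

test_that("the copula induces the requested correlation structure", {
  with_seed(8, {
    cop <- induce_correlation(40, edge_prob = 0.08,
                              rho_range = c(0.3, 0.7))
    C <- cop$corr
    expect_equal(diag(C), rep(1, 40))
    expect_equal(C, t(C))
    expect_gt(min(eigen(C, only.values = TRUE)$values), 0)
    off <- C[upper.tri(C)]
    expect_true(any(off != 0))
    # marginals are preserved: correlated draws keep the NB mean
    mu <- matrix(20, 40, 4000)
    y <- cop$sample(mu, size = rep(2, 40))
    expect_lt(max(abs(rowMeans(y) - 20) / 20), 0.08)
    # an empty graph is exactly independent sampling
    cop0 <- induce_correlation(10, edge_prob = 0)
    expect_equal(cop0$corr, diag(10))
  })
})

test_that("abundance strata split 10/80/10 by quantile rank", {
  m <- make_counts(40, 10, seed = 61)
  m <- m[rowSums(m) > 0, ]
  st <- stratify_abundance(m)
  expect_equal(levels(st), c("low", "intermediate", "high"))
  frac <- table(st) / length(st)
  expect_lt(abs(frac[["low"]] - 0.10), 0.05)
  expect_lt(abs(frac[["high"]] - 0.10), 0.05)
  # the most abundant taxon is in the high stratum
  rel <- rowMeans(sweep(m, 2, colSums(m), `/`))
  expect_equal(unname(as.character(st[which.max(rel)])), "high")
})

test_that("longitudinal simulation places the signal on the interaction", {
  scn <- sim_scenario(template = bench_template(), n_taxa = 30,
                      n_samples = 24, n_occasions = 2, fold_change = 4,
                      correlation = FALSE, structural_zeros = FALSE,
                      residual_cap = Inf, seed = 19)
  sim <- simulate_longitudinal(scn)
  expect_equal(nlevels(factor(sim$meta$occasion)), 2)
  expect_true(all(table(sim$meta$subject_id) == 2))
  mu <- sim$params$mu
  up <- sim$truth$taxon[sim$truth$direction == "up"][1]
  # within group2, occasion 2 means are fold x the subject-matched baseline
  s2 <- sim$meta$subject_id[sim$meta$group == "group2" &
                              sim$meta$occasion == "2"]
  r <- mu[up, paste0(s2, "_t2")] / mu[up, paste0(s2, "_t1")]
  base <- setdiff(rownames(mu), sim$truth$taxon)[1]
  r_base <- mu[base, paste0(s2, "_t2")] / mu[base, paste0(s2, "_t1")]
  expect_equal(unname(r / r_base), rep(4, length(s2)), tolerance = 1e-10)
  # group1 sees no fold anywhere
  s1 <- unique(sim$meta$subject_id[sim$meta$group == "group1"])
  r1 <- mu[up, paste0(s1, "_t2")] / mu[up, paste0(s1, "_t1")]
  r1_base <- mu[base, paste0(s1, "_t2")] / mu[base, paste0(s1, "_t1")]
  expect_equal(unname(r1 / r1_base), rep(1, length(s1)), tolerance = 1e-10)
  expect_error(simulate_longitudinal(sim_scenario(
    template = bench_template(), n_occasions = 1)), "n_occasions = 2")
})

test_that("scenario validation and serialization work", {
  expect_error(sim_scenario(template = NULL, fold_change = 0.5))
  expect_error(sim_scenario(template = NULL, n_occasions = 3))
  sim <- suppressMessages(simulate_cross_sectional(sim_scenario(
    template = bench_template(), n_taxa = 20, n_samples = 12, seed = 2)))
  d <- tempfile()
  write_simulation(sim, d)
  back <- read_count_table(file.path(d, "counts.tsv"))
  expect_equal(unname(back), unname(sim$counts), ignore_attr = TRUE)
  expect_true(file.exists(file.path(d, "truth.tsv")))
})
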