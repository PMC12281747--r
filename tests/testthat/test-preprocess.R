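test_that("prevalence filter boundary is inclusive", {
  m <- make_counts(1, 20, seed = 2)
  m <- rbind(m, at_floor = 0L, below = 0L)
  m["at_floor", 1:2] <- 5L   # prevalence exactly 0.10
  m["below", 1] <- 5L        # prevalence 0.05
  res <- filter_low_prevalence(m, 0.10)
  expect_true("at_floor" %in% rownames(res$counts))
  expect_false("below" %in% rownames(res$counts))
  expect_equal(res$report$removed_taxa$taxon, "below")
  expect_error(filter_low_prevalence(m * 0L, 0.10), "all taxa removed")
})

test_that("library-size filter removes the documented example sample", {
  m <- matrix(c(900L, 1500L, 2000L), 1, 3,
              dimnames = list("t1", c("s1", "s2", "s3")))
  res <- filter_low_depth_samples(m, 1000L)
  expect_equal(colnames(res$counts), c("s2", "s3"))
  expect_equal(res$report$removed_samples$sample, "s1")
  expect_error(filter_low_depth_samples(m, 10000L), "all samples removed")
})

test_that("zero labels partition the matrix", {
  tpl <- bench_template()
  sim <- simulate_cross_sectional(sim_scenario(template = tpl, seed = 21))
  lab <- classify_zeros(sim$counts, sim$meta)
  expect_equal(dim(lab), dim(sim$counts))
  tab <- table(factor(lab, levels = c("observed", "structural_zero",
                                      "sampling_zero", "outlier_zero")))
  expect_equal(sum(tab), length(sim$counts))
  expect_identical(unname(lab == "observed"), unname(sim$counts > 0))
})

test_that("all-zero within a group is structural, depth-explained is sampling", {
  # group g1: taxon A always zero (structural); taxon B zero only in the
  # shallow sample (sampling)
  cnt <- rbind(A = c(0L, 0L, 0L, 50L, 60L, 70L),
               B = c(0L, 40L, 45L, 50L, 60L, 70L),
               C = c(900L, 800L, 850L, 700L, 600L, 500L))
  colnames(cnt) <- paste0("s", 1:6)
  meta <- make_meta(cnt, n_group1 = 3)
  lab <- classify_zeros(cnt, meta)
  expect_equal(unname(lab["A", 1:3]), rep("structural_zero", 3))
  expect_equal(unname(lab["B", 1]), "sampling_zero")
})

test_that("an unexplained zero in a near-always-present taxon is an outlier zero", {
  # 20 samples in one group; taxon non-zero in 19 with values near 100;
  # the zero sits in the deepest sample, so depth cannot explain it
  set.seed(4)
  vals <- c(0L, 95L + sample(0:10, 19, replace = TRUE))
  cnt <- rbind(t1 = vals, filler = rep(60L, 20))
  colnames(cnt) <- sprintf("s%02d", 1:20)
  cnt["filler", 1] <- 5000L
  meta <- data.frame(sample_id = colnames(cnt), subject_id = colnames(cnt),
                     group = factor(rep(c("g1", "g2"), each = 10)),
                     occasion = factor(rep("1", 20)))
  lab <- classify_zeros(cnt, meta)
  expect_equal(unname(lab["t1", 1]), "outlier_zero")
})

test_that("the robust-z rule flags the documented outlier example", {
  cnt <- matrix(c(10L, 12L, 11L, 9L, 10000L), 1, 5,
                dimnames = list("t1", paste0("s", 1:5)))
  meta <- data.frame(sample_id = colnames(cnt), subject_id = colnames(cnt),
                     group = factor(rep("g1", 5)),
                     occasion = factor(rep("1", 5)))
  flag <- detect_outlier_values(cnt, meta, k = 3)
  expect_identical(unname(flag[1, ]), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # hand check: the rule is |log(y+1) - median| > 3 * mad on the logs
  v <- log(as.numeric(cnt) + 1)
  expect_true(abs(v[5] - median(v)) > 3 * mad(v))
  expect_true(all(abs(v[1:4] - median(v)) <= 3 * mad(v)))
})

test_that("degenerate groups produce no outlier flags", {
  cnt <- matrix(c(7L, 7L, 7L, 7L, 7L, 7L), 1, 6,
                dimnames = list("t1", paste0("s", 1:6)))
  meta <- make_meta(cnt, n_group1 = 3)
  expect_true(!any(detect_outlier_values(cnt, meta)))   # MAD = 0
  cnt2 <- matrix(c(5L, 0L, 0L, 9L, 11L, 10L), 1, 6,
                 dimnames = list("t1", paste0("s", 1:6)))
  expect_true(!any(detect_outlier_values(cnt2, meta)))  # < 3 non-zero in g1
})

test_that("preprocessing reaches a fixed point (idempotence)", {
  tpl <- bench_template()
  sim <- simulate_cross_sectional(sim_scenario(template = tpl, seed = 33))
  ctrl <- microgee_control(min_library_size = 0)
  p1 <- apply_preprocessing(sim$counts, sim$meta, ctrl)
  # one more masking pass on the converged output flags nothing new
  m <- sim$meta[sim$meta$sample_id %in% colnames(p1$counts), , drop = FALSE]
  lab <- classify_zeros(p1$counts, m, ctrl$structural_fraction,
                        ctrl$outlier_zero_prevalence)
  vflag <- detect_outlier_values(p1$counts, m, ctrl$outlier_k)
  new_mask <- (!is.na(lab) & lab == "outlier_zero") | vflag
  expect_true(!any(new_mask[!is.na(p1$counts)]))
  # and the whole pass is deterministic
  p2 <- apply_preprocessing(sim$counts, sim$meta, ctrl)
  expect_identical(p2$counts, p1$counts)
  # masked cells are NA; retained zeros stay zero
  expect_equal(p1$report$cells_masked, sum(is.na(p1$counts)))
  expect_true(all(p1$counts[!is.na(p1$counts)] >= 0))
})

test_that("preprocessing outputs serialize", {
  tpl <- bench_template()
  sim <- simulate_cross_sectional(sim_scenario(
    template = tpl, n_taxa = 30, n_samples = 20, seed = 8))
  prep <- apply_preprocessing(sim$counts, sim$meta,
                              microgee_control(min_library_size = 0))
  d <- tempfile()
  write_preprocessing(prep, d)
  expect_true(file.exists(file.path(d, "filter_report.json")))
  expect_true(file.exists(file.path(d, "zero_labels.tsv")))
  rep <- jsonlite::read_json(file.path(d, "filter_report.json"))
  expect_equal(rep$cells_masked, sum(is.na(prep$counts)))
})
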