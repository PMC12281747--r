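# A small stacked design from a simulated dataset, reused across tests.
gee_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) {
      tpl <- bench_template()
      sim <- simulate_cross_sectional(sim_scenario(
        template = tpl, n_taxa = 40, n_samples = 24, seed = 15))
      prep <- apply_preprocessing(sim$counts, sim$meta,
                                  microgee_control(min_library_size = 0))
      clr <- clr_transform(add_pseudocount(ctf_normalize(prep$counts)$adjusted))
      meta <- sim$meta[sim$meta$sample_id %in% colnames(clr), , drop = FALSE]
      fx <<- build_design(clr, meta)
    }
    fx
  }
})

test_that("the independence fit is exactly ordinary least squares", {
  des <- gee_fixture()
  fit <- fit_gee(des$Y, des$X, des$cluster, corstr = "independence")
  ols <- qr.coef(qr(des$X), des$Y)
  expect_lt(max(abs(fit$beta - ols)), 1e-10)
})

test_that("singleton clusters reduce the sandwich to HC0", {
  set.seed(2)
  n <- 80
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  Y <- X %*% c(1, 2, -1) + rnorm(n) * (1 + X[, 3])
  fit <- suppressWarnings(
    fit_gee(as.numeric(Y), X, factor(seq_len(n)), corstr = "exchangeable"))
  lmfit <- lm(Y ~ 0 + X)
  hc0 <- sandwich::vcovHC(lmfit, type = "HC0")
  expect_lt(max(abs(fit$robust_cov - hc0)), 1e-10)
  # and the moment estimator warns when no within-cluster pairs exist
  expect_warning(estimate_alpha(rnorm(10), factor(1:10)), "size 1")
})

test_that("alpha recovers a known exchangeable correlation", {
  set.seed(10)
  n_sub <- 200
  ni <- 4
  rho <- 0.5
  R <- matrix(rho, ni, ni)
  diag(R) <- 1
  U <- chol(R)
  est <- replicate(100, {
    E <- matrix(rnorm(n_sub * ni), n_sub, ni) %*% U
    Y <- as.numeric(t(E))
    cl <- factor(rep(seq_len(n_sub), each = ni))
    X <- matrix(1, length(Y), 1)
    fit_gee(Y, X, cl)$alpha
  })
  expect_lt(abs(mean(est) - rho), 0.05)
})

test_that("the exchangeable fit matches a dense-matrix oracle", {
  des <- gee_fixture()
  fit <- fit_gee(des$Y, des$X, des$cluster)
  orc <- oracle_gee_dense(des$Y, des$X, des$cluster, fit$alpha,
                          beta = fit$beta)
  expect_lt(max(abs(fit$beta - orc$beta)), 1e-6)
  rel <- max(abs(fit$robust_cov - orc$robust)) /
    max(abs(orc$robust))
  expect_lt(rel, 1e-8)
})

test_that("coefficients and covariance scale correctly with the response", {
  des <- gee_fixture()
  f1 <- fit_gee(des$Y, des$X, des$cluster)
  f2 <- fit_gee(2 * des$Y, des$X, des$cluster)
  expect_equal(f2$beta, 2 * f1$beta, tolerance = 1e-7)
  expect_equal(f2$robust_cov, 4 * f1$robust_cov, tolerance = 1e-6)
})

test_that("intercepts are reference-group baseline CLR means", {
  des <- gee_fixture()
  fit <- fit_gee(des$Y, des$X, des$cluster, corstr = "independence")
  nm <- names(fit$beta)
  ints <- grep("\\(Intercept\\)$", nm)
  for (j in ints[1:3]) {
    tx <- sub("\\|.*$", "", nm[j])
    in_ref <- des$row_info$taxon == tx &
      des$X[, j] == 1 &
      rowSums(des$X[, setdiff(seq_along(nm), ints), drop = FALSE]) == 0
    expect_equal(unname(fit$beta[j]), mean(des$Y[in_ref]),
                 tolerance = 1e-10)
  }
})

test_that("design construction rejects empty cells and aliased columns", {
  tpl <- bench_template()
  sim <- simulate_longitudinal(sim_scenario(
    template = tpl, n_taxa = 25, n_samples = 12, n_occasions = 2, seed = 4))
  prep <- apply_preprocessing(sim$counts, sim$meta,
                              microgee_control(min_library_size = 0))
  clr <- clr_transform(add_pseudocount(ctf_normalize(prep$counts)$adjusted))
  meta <- sim$meta[sim$meta$sample_id %in% colnames(clr), , drop = FALSE]
  des <- build_design(clr, meta)
  expect_true(all(c("Y", "X", "cluster") %in% names(des)))
  # drop all group2/occasion2 samples -> empty cell
  bad <- meta[!(meta$group == "group2" & meta$occasion == "2"), ]
  expect_error(build_design(clr[, bad$sample_id], bad), "design error")
  expect_error(build_design(clr, within(meta, group <- factor("g"))),
               "at least 2 groups")
})

test_that("masked responses are dropped, not imputed", {
  des <- gee_fixture()
  tpl <- bench_template()
  sim <- simulate_cross_sectional(sim_scenario(
    template = tpl, n_taxa = 25, n_samples = 16, seed = 44))
  clr <- clr_transform(add_pseudocount(
    ctf_normalize(sim$counts + 0.0)$adjusted))
  clr[2, 5] <- NA
  des2 <- build_design(clr, sim$meta)
  expect_equal(length(des2$Y), 25 * 16 - 1)
  expect_true(!anyNA(des2$Y))
})

test_that("generic working correlations run and degenerate sensibly", {
  set.seed(6)
  n_sub <- 30
  ni <- 3
  Y <- rnorm(n_sub * ni)
  X <- cbind(1, rnorm(n_sub * ni))
  cl <- factor(rep(seq_len(n_sub), each = ni))
  f_ar <- fit_gee(Y, X, cl, corstr = "ar1")
  expect_true(f_ar$converged)
  expect_lt(abs(f_ar$alpha), 0.2)   # iid data -> small lag-1 correlation
  f_un <- fit_gee(Y, X, cl, corstr = "unstructured")
  expect_true(f_un$converged)
  # unequal cluster sizes are rejected for unstructured
  cl2 <- factor(c(rep(1, 2), rep(seq(2, n_sub), each = ni),
                  rep(n_sub + 1, 1)))
  expect_error(fit_gee(Y, X, cl2, corstr = "unstructured"),
               "equal cluster sizes")
})

test_that("gee_fit methods and serialization work", {
  des <- gee_fixture()
  fit <- fit_gee(des$Y, des$X, des$cluster)
  expect_identical(coef(fit), fit$beta)
  expect_identical(vcov(fit), fit$robust_cov)
  expect_output(print(fit), "working correlation")
  tf <- tempfile(fileext = ".json")
  write_gee_fit(fit, tf)
  j <- jsonlite::read_json(tf)
  expect_equal(j$alpha, fit$alpha, tolerance = 1e-12)
  expect_true(j$converged)
})
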