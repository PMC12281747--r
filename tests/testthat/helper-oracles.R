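# Independent oracles and small fixtures shared across the test files.
# Each oracle is written from the published definition, deliberately using
# different primitives than the package implementation.

# Brute-force TMM factor for one sample pair: explicit order-statistic
# trimming (no rank()), inverse-variance weighted mean of surviving M.
oracle_tmm <- function(sample, reference, lib_sizes = NULL,
                       trim_M = 0.30, trim_A = 0.05) {
  if (is.null(lib_sizes)) {
    lib_sizes <- c(sum(sample, na.rm = TRUE), sum(reference, na.rm = TRUE))
  }
  ok <- which(!is.na(sample) & !is.na(reference) & sample > 0 & reference > 0)
  ps <- sample[ok] / lib_sizes[1L]
  pr <- reference[ok] / lib_sizes[2L]
  M <- log2(ps / pr)
  A <- (log2(ps) + log2(pr)) / 2
  v <- (lib_sizes[1L] - sample[ok]) / (lib_sizes[1L] * sample[ok]) +
    (lib_sizes[2L] - reference[ok]) / (lib_sizes[2L] * reference[ok])
  n <- length(ok)
  # a taxon survives a tail fraction f when its rank lies in
  # [floor(n f) + 1, n - floor(n f)]; ties share mid-ranks
  in_band <- function(x, f) {
    r <- rank(x)
    lo <- floor(n * f) + 1
    r >= lo & r <= n + 1 - lo
  }
  keep <- in_band(M, trim_M) & in_band(A, trim_A)
  if (!any(keep)) return(1)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

# Step-up Benjamini-Hochberg from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Dense-matrix exchangeable GEE quantities at a fixed working correlation:
# builds every V_i explicitly and accumulates bread/meat with solve().
oracle_gee_dense <- function(Y, X, cluster, alpha, beta = NULL) {
  cluster <- as.factor(cluster)
  idx <- split(seq_along(Y), cluster)
  p <- ncol(X)
  B <- matrix(0, p, p)
  rhs <- numeric(p)
  for (ii in idx) {
    ni <- length(ii)
    V <- matrix(alpha, ni, ni)
    diag(V) <- 1
    Vi <- solve(V)
    Xi <- X[ii, , drop = FALSE]
    B <- B + t(Xi) %*% Vi %*% Xi
    rhs <- rhs + t(Xi) %*% Vi %*% Y[ii]
  }
  beta_gls <- solve(B, rhs)
  if (is.null(beta)) beta <- beta_gls
  r <- Y - X %*% beta
  M <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    V <- matrix(alpha, ni, ni)
    diag(V) <- 1
    Vi <- solve(V)
    Xi <- X[ii, , drop = FALSE]
    g <- t(Xi) %*% Vi %*% r[ii]
    M <- M + g %*% t(g)
  }
  Binv <- solve(B)
  list(beta = as.numeric(beta_gls), robust = Binv %*% M %*% Binv)
}

# Small random count fixture.
make_counts <- function(n_taxa, n_samples, mu = 50, size = 1, seed = 1) {
  with_seed(seed, {
    m <- matrix(rnbinom(n_taxa * n_samples, mu = mu, size = size),
                n_taxa, n_samples,
                dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

# Minimal cross-sectional sample frame for a count fixture.
make_meta <- function(counts, n_group1 = ceiling(ncol(counts) / 2)) {
  ids <- colnames(counts)
  data.frame(
    sample_id = ids, subject_id = ids,
    group = factor(rep(c("g1", "g2"),
                       c(n_group1, length(ids) - n_group1)),
                   levels = c("g1", "g2")),
    occasion = factor(rep("1", length(ids))),
    stringsAsFactors = FALSE
  )
}

# Pipeline call with the simulator chatter silenced.
quiet_microgee <- function(...) {
  suppressMessages(suppressWarnings(microgee(...)))
}

# Shared benchmark template (deterministic); fitted once per test run.
bench_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) {
      tpl <<- suppressWarnings(fit_template(synthetic_template(seed = 3)))
    }
    tpl
  }
})
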