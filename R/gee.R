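#' Build the stacked design for the joint GEE
#'
#' Stacks the CLR matrix into long format, one row per unmasked
#' (subject, occasion, taxon) cell, and builds the design with per-taxon
#' intercepts, per-taxon group effects, per-taxon occasion effects and
#' per-taxon group x occasion interactions.  Reference levels (first group
#' level, earliest occasion) are absorbed into the taxon intercepts, so the
#' intercept is the mean CLR value of the taxon in the reference group at
#' baseline.  For single-occasion designs the occasion and interaction
#' blocks are omitted.  Clusters are subjects: all taxon x occasion
#' measurements of one subject form one cluster.
#'
#' @param clr CLR matrix (taxa x samples), `NA` for masked cells.
#' @param meta Sample frame (see [as_sample_frame()]).
#' @return A list with `Y` (response vector), `X` (design matrix, column
#'   names `taxon|term`), `cluster` (factor of subject ids), `taxon` and
#'   `term` (per-column annotations), and `row_info` (taxon/sample per
#'   row).
#' @export
build_design <- function(clr, meta) {
  meta <- meta[match(colnames(clr), meta$sample_id), , drop = FALSE]
  meta$group <- droplevels(meta$group)
  meta$occasion <- droplevels(meta$occasion)
  if (nlevels(meta$group) < 2L) {
    stop("at least 2 groups are required")
  }
  cell <- table(meta$group, meta$occasion)
  if (any(cell == 0L)) {
    bad <- which(cell == 0L, arr.ind = TRUE)[1L, ]
    stop("design error: no samples for group '",
         rownames(cell)[bad[1L]], "' at occasion '",
         colnames(cell)[bad[2L]], "'")
  }
  multi_occ <- nlevels(meta$occasion) > 1L
  form <- if (multi_occ) ~ group * occasion else ~ group
  Ms <- stats::model.matrix(form, data = meta)
  q <- ncol(Ms)
  K <- nrow(clr)
  n_s <- ncol(clr)
  taxa <- rownames(clr)
  # stable row order: (taxon within sample within subject/occasion)
  samp_ord <- order(meta$subject_id, as.integer(meta$occasion),
                    meta$sample_id)
  X <- matrix(0, n_s * K, K * q)
  Y <- numeric(n_s * K)
  cl <- character(n_s * K)
  row_taxon <- character(n_s * K)
  row_sample <- character(n_s * K)
  terms_s <- colnames(Ms)
  colnames(X) <- paste(rep(taxa, each = q), rep(terms_s, K), sep = "|")
  r <- 0L
  for (s in samp_ord) {
    idx <- r + seq_len(K)
    Y[idx] <- clr[, s]
    for (k in seq_len(K)) {
      X[idx[k], ((k - 1L) * q + 1L):(k * q)] <- Ms[s, ]
    }
    cl[idx] <- meta$subject_id[s]
    row_taxon[idx] <- taxa
    row_sample[idx] <- meta$sample_id[s]
    r <- r + K
  }
  keep <- !is.na(Y)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep]
  cl <- factor(cl[keep])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design error: rank-deficient design (", ncol(X) - qrX$rank,
         " aliased column(s)); check for empty group x occasion cells or ",
         "fully masked taxa")
  }
  list(Y = Y, X = X, cluster = cl,
       taxon = rep(taxa, each = q), term = rep(terms_s, K),
       row_info = data.frame(taxon = row_taxon[keep],
                             sample = row_sample[keep]))
}

#' Moment estimator of the exchangeable correlation
#'
#' Average product of all distinct pairs of standardized residuals within
#' clusters.  Returns 0 with a warning when every cluster has a single
#' observation; the estimate is clipped to the validity bound
#' `(-1/(n_max - 1), 1)` with a warning.
#'
#' @param residuals Residuals standardized by the scale (Pearson
#'   residuals).
#' @param clusters Cluster membership (factor or vector).
#' @return The exchangeable correlation estimate.
#' @export
estimate_alpha <- function(residuals, clusters) {
  clusters <- as.factor(clusters)
  n_i <- tabulate(clusters)
  n_pairs <- sum(n_i * (n_i - 1) / 2)
  if (n_pairs == 0) {
    warning("all clusters have size 1; exchangeable correlation set to 0")
    return(0)
  }
  s1 <- tapply(residuals, clusters, sum)
  s2 <- tapply(residuals^2, clusters, sum)
  alpha <- sum((s1^2 - s2) / 2) / n_pairs
  lo <- -1 / (max(n_i) - 1)
  if (alpha >= 1 || alpha <= lo) {
    warning("exchangeable correlation estimate ", signif(alpha, 4),
            " outside validity bound; clipped")
    alpha <- min(max(alpha, lo + 1e-6), 1 - 1e-6)
  }
  alpha
}

# Exchangeable-structure cluster summaries exploiting
# V^-1 = (1/(s2 (1-a))) [I - a/(1 + (n_i - 1) a) 11'] (Sherman-Morrison),
# so X'V^-1X etc. reduce to X'X minus rank-one per-cluster corrections.
exch_quantities <- function(X, Y, cluster, alpha) {
  n_i <- tabulate(cluster)
  a_i <- alpha / (1 + (n_i - 1) * alpha)
  S <- rowsum(X, cluster)                 # n_cl x p column sums per cluster
  t_i <- rowsum(Y, cluster)[, 1L]
  A <- crossprod(X) - crossprod(S, a_i * S)
  b <- crossprod(X, Y) - crossprod(S, a_i * t_i)
  list(A = A, b = b, S = S, a_i = a_i)
}

#' Fit a Gaussian identity-link GEE
#'
#' Solves the estimating equation
#' `sum_i D_i' V_i^-1 (Y_i - mu_i) = 0` with `mu_i = X_i beta`, iterating
#' coefficient updates with moment re-estimation of the working
#' correlation and scale from Pearson residuals until the maximum
#' coefficient change falls below `tol`.  The robust covariance is the
#' sandwich `B^-1 M B^-1` with bread `B = sum_i X_i' V_i^-1 X_i` and meat
#' `M = sum_i X_i' V_i^-1 r_i r_i' V_i^-1 X_i`.  Under the independence
#' structure the fit is exactly ordinary least squares, and with all
#' clusters of size one the sandwich equals the HC0 heteroskedasticity-
#' robust covariance.
#'
#' @param Y Response vector.
#' @param X Design matrix (full column rank).
#' @param clusters Cluster ids (subjects).
#' @param corstr Working correlation: `"exchangeable"` (default),
#'   `"independence"`, `"ar1"`, or `"unstructured"`.
#' @param tol Convergence tolerance on `max |delta beta|`.
#' @param max_iter Iteration cap.
#' @return An object of class `"gee_fit"`: `beta`, `robust_cov`, `naive_cov`,
#'   `alpha`, `scale`, `n_iter`, `converged`, `corstr`, `residuals`,
#'   `fitted`, `clusters`.
#' @export
fit_gee <- function(Y, X, clusters, corstr = "exchangeable",
                    tol = 1e-8, max_iter = 60L) {
  corstr <- match.arg(corstr, c("exchangeable", "independence", "ar1",
                                "unstructured"))
  clusters <- droplevels(as.factor(clusters))
  if (nlevels(clusters) < 2L) stop("at least 2 clusters are required")
  p <- ncol(X)
  n <- length(Y)
  if (corstr %in% c("ar1", "unstructured")) {
    return(fit_gee_generic(Y, X, clusters, corstr, tol, max_iter))
  }
  # OLS initialization (exact under independence)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, Y))
  alpha <- 0
  converged <- corstr == "independence"
  iter <- 1L
  if (corstr == "exchangeable") {
    for (iter in seq_len(max_iter)) {
      r <- Y - X %*% beta
      scale <- sum(r^2) / (n - p)
      alpha <- suppressWarnings(estimate_alpha(r / sqrt(scale), clusters))
      alpha <- min(max(alpha, -1 / (max(tabulate(clusters)) - 1) + 1e-6),
                   1 - 1e-6)
      eq <- exch_quantities(X, Y, clusters, alpha)
      beta_new <- solve(eq$A, eq$b)
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  r <- as.numeric(Y - X %*% beta)
  scale <- sum(r^2) / (n - p)
  eq <- exch_quantities(X, Y, clusters, alpha)
  # meat via per-cluster generalized scores; the scale factors cancel in
  # B^-1 M B^-1, leaving A^-1 crossprod(G) A^-1
  G <- rowsum(X * r, clusters) -
    (eq$a_i * rowsum(r, clusters)[, 1L]) * eq$S
  A_inv <- solve(eq$A)
  robust <- A_inv %*% crossprod(G) %*% A_inv
  robust <- (robust + t(robust)) / 2
  naive <- scale * (1 - alpha) * A_inv
  structure(list(
    beta = setNames(as.numeric(beta), colnames(X)),
    robust_cov = robust, naive_cov = naive,
    alpha = alpha, scale = scale, n_iter = iter,
    converged = converged, corstr = corstr,
    residuals = r, fitted = as.numeric(X %*% beta), clusters = clusters
  ), class = "gee_fit")
}

# Dense per-cluster path for ar1/unstructured working correlations.
fit_gee_generic <- function(Y, X, clusters, corstr, tol, max_iter) {
  p <- ncol(X)
  n <- length(Y)
  idx <- split(seq_len(n), clusters)
  n_i <- lengths(idx)
  beta <- solve(crossprod(X), crossprod(X, Y))
  alpha <- 0
  Rmat <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r <- as.numeric(Y - X %*% beta)
    scale <- sum(r^2) / (n - p)
    e <- r / sqrt(scale)
    if (corstr == "ar1") {
      num <- den <- 0
      for (ii in idx) {
        if (length(ii) < 2L) next
        num <- num + sum(e[ii[-length(ii)]] * e[ii[-1L]])
        den <- den + length(ii) - 1L
      }
      alpha <- if (den > 0) min(max(num / den, -0.999), 0.999) else 0
    } else { # unstructured: needs a common cluster size
      if (length(unique(n_i)) != 1L) {
        stop("unstructured working correlation requires equal cluster sizes")
      }
      E <- t(vapply(idx, function(ii) e[ii], numeric(n_i[1L])))
      Rmat <- crossprod(E) / nrow(E)
      d <- sqrt(diag(Rmat))
      Rmat <- Rmat / outer(d, d)
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      R_i <- if (corstr == "ar1") {
        alpha^abs(outer(seq_len(ni), seq_len(ni), `-`))
      } else Rmat[seq_len(ni), seq_len(ni), drop = FALSE]
      Vinv <- solve(R_i)
      Xi <- X[ii, , drop = FALSE]
      A <- A + crossprod(Xi, Vinv %*% Xi)
      b <- b + crossprod(Xi, Vinv %*% Y[ii])
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  r <- as.numeric(Y - X %*% beta)
  scale <- sum(r^2) / (n - p)
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    R_i <- if (corstr == "ar1") {
      alpha^abs(outer(seq_len(ni), seq_len(ni), `-`))
    } else Rmat[seq_len(ni), seq_len(ni), drop = FALSE]
    Vinv <- solve(R_i)
    Xi <- X[ii, , drop = FALSE]
    A <- A + crossprod(Xi, Vinv %*% Xi)
    g <- crossprod(Xi, Vinv %*% r[ii])
    M <- M + tcrossprod(g)
  }
  A_inv <- solve(A)
  robust <- A_inv %*% M %*% A_inv
  robust <- (robust + t(robust)) / 2
  structure(list(
    beta = setNames(as.numeric(beta), colnames(X)),
    robust_cov = robust, naive_cov = scale * A_inv,
    alpha = alpha, scale = scale, n_iter = iter,
    converged = converged, corstr = corstr,
    residuals = r, fitted = as.numeric(X %*% beta), clusters = clusters
  ), class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$beta

#' @export
vcov.gee_fit <- function(object, ...) object$robust_cov

#' @export
print.gee_fit <- function(x, ...) {
  cat("Gaussian identity-link GEE fit\n")
  cat("  coefficients:", length(x$beta),
      " clusters:", nlevels(x$clusters), "\n")
  cat("  working correlation:", x$corstr,
      sprintf(" (alpha = %.4f)", x$alpha), "\n")
  cat(sprintf("  scale: %.4f   iterations: %d   converged: %s\n",
              x$scale, x$n_iter, x$converged))
  invisible(x)
}

#' Serialize a GEE fit
#'
#' Writes `gee_fit.json` with coefficients, robust standard errors, the
#' working-correlation estimate, scale and convergence state.
#'
#' @param fit A [fit_gee()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gee_fit <- function(fit, path) {
  jsonlite::write_json(list(
    beta = as.list(fit$beta),
    robust_se = as.list(setNames(sqrt(diag(fit$robust_cov)),
                                 names(fit$beta))),
    alpha = fit$alpha, scale = fit$scale,
    working_correlation = fit$corstr,
    n_iter = fit$n_iter, converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
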