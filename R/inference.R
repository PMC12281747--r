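#' Per-coefficient (local) Wald tests
#'
#' For every non-intercept coefficient of the stacked fit, computes
#' `z = estimate / robust SE` and a two-sided p-value from the standard
#' normal.  Zero standard errors yield `NA` p-values and are flagged.
#'
#' @param fit A [fit_gee()] object whose coefficient names follow the
#'   `taxon|term` convention of [build_design()].
#' @return A data.frame with columns taxon, term, estimate, se, z, p and
#'   degenerate (logical flag for zero SE).
#' @export
local_tests <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("GEE fit did not converge; local tests unavailable")
  }
  nm <- names(fit$beta)
  parts <- strsplit(nm, "|", fixed = TRUE)
  taxon <- vapply(parts, `[[`, character(1L), 1L)
  term <- vapply(parts, function(x) paste(x[-1L], collapse = "|"),
                 character(1L))
  keep <- term != "(Intercept)"
  se <- sqrt(diag(fit$robust_cov))
  est <- fit$beta
  z <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(taxon = taxon, term = term, estimate = est, se = se,
                    z = z, p = p, degenerate = se <= 0,
                    row.names = NULL)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-taxon (global) joint Wald tests
#'
#' For every taxon, the joint Wald statistic `W = b' C^-1 b` over all of
#' the taxon's non-intercept coefficients `b`, with `C` the corresponding
#' robust-covariance block; p-value from the chi-squared distribution with
#' `df = length(b)`.  Singular blocks fall back to the Moore-Penrose
#' inverse with `df = rank`, flagged in the `singular` column.
#'
#' @inheritParams local_tests
#' @return A data.frame with columns taxon, wald, df, p, singular.
#' @export
global_tests <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("GEE fit did not converge; global tests unavailable")
  }
  nm <- names(fit$beta)
  parts <- strsplit(nm, "|", fixed = TRUE)
  taxon <- vapply(parts, `[[`, character(1L), 1L)
  term <- vapply(parts, function(x) paste(x[-1L], collapse = "|"),
                 character(1L))
  taxa <- unique(taxon)
  res <- lapply(taxa, function(tx) {
    j <- which(taxon == tx & term != "(Intercept)")
    b <- fit$beta[j]
    C <- fit$robust_cov[j, j, drop = FALSE]
    W <- tryCatch({
      as.numeric(crossprod(b, solve(C, b)))
    }, error = function(e) NA_real_)
    df <- length(b)
    singular <- FALSE
    if (!is.finite(W) || W < 0) {
      Ci <- MASS::ginv(C)
      W <- as.numeric(crossprod(b, Ci %*% b))
      df <- qr(C)$rank
      singular <- TRUE
    }
    data.frame(taxon = tx, wald = W, df = df,
               p = pchisq(W, df, lower.tail = FALSE), singular = singular)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment with monotone enforcement.  `NA` p-values are
#' propagated as `NA` and excluded from the family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return The adjusted p-values, same length and order as the input.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Significance calls
#'
#' Flags records with adjusted p strictly below `alpha_level`.
#'
#' @param records A data.frame with a `p_adj` column.
#' @param alpha_level Significance level (default 0.05).
#' @return The records with a logical `significant` column.
#' @export
call_significance <- function(records, alpha_level = 0.05) {
  records$significant <- !is.na(records$p_adj) &
    records$p_adj < alpha_level
  records
}

# Assemble local + global DA tables from a fit: BH within the global
# family and within each local term family, deterministic ordering.
build_da_tables <- function(fit, alpha_level = 0.05) {
  loc <- local_tests(fit)
  glo <- global_tests(fit)
  loc$p_adj <- NA_real_
  for (tm in unique(loc$term)) {
    i <- loc$term == tm
    loc$p_adj[i] <- adjust_bh(loc$p[i])
  }
  glo$p_adj <- adjust_bh(glo$p)
  loc <- call_significance(loc, alpha_level)
  glo <- call_significance(glo, alpha_level)
  loc <- loc[order(loc$term, loc$p, loc$taxon), , drop = FALSE]
  glo <- glo[order(glo$p, glo$taxon), , drop = FALSE]
  rownames(loc) <- rownames(glo) <- NULL
  list(local = loc, global = glo)
}
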