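#' M and A values between two samples
#'
#' Computes, per taxon, the log2 fold change (M value) and the mean log2
#' abundance (A value) between a sample and a reference sample on
#' library-size-normalized counts.  Taxa with a zero (or masked) count in
#' either sample are excluded via the usable mask.
#'
#' @param sample,reference Count vectors of equal length.
#' @param lib_sizes Length-2 numeric: library sizes of `sample` and
#'   `reference` (defaults to their sums over unmasked cells).
#' @return A list with `M`, `A` (NA where unusable) and logical `usable`.
#' @examples
#' # library sizes 16 and 16: normalized 8/16 vs 2/16 gives M = 2, A = -2
#' compute_MA(c(8, 8), c(2, 14), lib_sizes = c(16, 16))
#' @export
compute_MA <- function(sample, reference, lib_sizes = NULL) {
  stopifnot(length(sample) == length(reference))
  if (is.null(lib_sizes)) {
    lib_sizes <- c(sum(sample, na.rm = TRUE), sum(reference, na.rm = TRUE))
  }
  stopifnot(length(lib_sizes) == 2L, all(lib_sizes > 0))
  usable <- !is.na(sample) & !is.na(reference) & sample > 0 & reference > 0
  if (!any(usable)) {
    stop("no taxon is non-zero in both samples; M/A values undefined")
  }
  p_s <- sample / lib_sizes[1L]
  p_r <- reference / lib_sizes[2L]
  M <- A <- rep(NA_real_, length(sample))
  M[usable] <- log2(p_s[usable] / p_r[usable])
  A[usable] <- (log2(p_s[usable]) + log2(p_r[usable])) / 2
  list(M = M, A = A, usable = usable)
}

# Delta-method (asymptotic binomial) variance of an M value on raw counts;
# the trimmed mean weights by its inverse.
tmm_variance <- function(sample, reference, lib_sizes) {
  (lib_sizes[1L] - sample) / (lib_sizes[1L] * sample) +
    (lib_sizes[2L] - reference) / (lib_sizes[2L] * reference)
}

#' Trimmed-mean-of-M-values factor for one sample pair
#'
#' Double-trims the M values (default 30% per tail) and A values (default
#' 5% per tail); a taxon survives only if inside both trims.  Returns
#' `2^(weighted mean of surviving M)` with inverse-variance weights.
#' Trimming is rank-based: with `n` usable taxa and per-tail fraction `f`,
#' taxa ranked in `[floor(n f) + 1, n - floor(n f)]` survive.
#'
#' @param sample,reference Raw count vectors.
#' @param lib_sizes Length-2 library sizes (defaults to column sums).
#' @param trim_M,trim_A Per-tail trim fractions.
#' @return The positive normalization factor (1 with a warning when no
#'   taxon survives trimming).
#' @export
trimmed_factor <- function(sample, reference, lib_sizes = NULL,
                           trim_M = 0.30, trim_A = 0.05) {
  if (is.null(lib_sizes)) {
    lib_sizes <- c(sum(sample, na.rm = TRUE), sum(reference, na.rm = TRUE))
  }
  ma <- compute_MA(sample, reference, lib_sizes)
  u <- which(ma$usable)
  M <- ma$M[u]
  A <- ma$A[u]
  w <- 1 / tmm_variance(sample[u], reference[u], lib_sizes)
  n <- length(u)
  loM <- floor(n * trim_M) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    warning("no taxon survived double-trimming; factor set to 1")
    return(1)
  }
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# Reference sample: 75th percentile of library-size-normalized counts
# closest to the mean of those percentiles; ties broken by sample id so the
# choice is invariant to column order.
select_reference_sample <- function(counts, lib_sizes) {
  q75 <- apply(counts, 2L, function(x) {
    quantile(x[!is.na(x)], 0.75, names = FALSE)
  }) / lib_sizes
  d <- abs(q75 - mean(q75))
  cand <- which(d == min(d))
  cand[order(colnames(counts)[cand])][1L]
}

#' CTF normalization (counts adjusted with TMM)
#'
#' Computes one TMM factor per sample against a reference sample, rescales
#' the factors to geometric mean 1, and returns counts adjusted by both the
#' factor and the relative library size:
#' `adjusted = count / (factor * lib_size / mean(lib_size))`.
#' Masked (`NA`) cells are excluded from factor computation and stay masked.
#'
#' @param counts Count matrix (taxa x samples), possibly with `NA` masks.
#' @param trim_M,trim_A Per-tail trim fractions passed to
#'   [trimmed_factor()].
#' @return A list with `adjusted` (real matrix), `factors` (named,
#'   geometric mean 1) and `reference_sample` (a sample id).
#' @export
ctf_normalize <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts, na.rm = TRUE)
  if (any(lib == 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib == 0], collapse = ", "),
         "; remove low-depth samples first")
  }
  if (ncol(counts) < 2L) {
    f <- setNames(rep(1, ncol(counts)), colnames(counts))
    adj <- sweep(counts, 2L, lib / mean(lib), `/`)
    return(list(adjusted = adj, factors = f,
                reference_sample = colnames(counts)[1L]))
  }
  ref <- select_reference_sample(counts, lib)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    ok <- !is.na(counts[, j]) & !is.na(counts[, ref]) &
      counts[, j] > 0 & counts[, ref] > 0
    if (!any(ok)) {
      warning("sample ", colnames(counts)[j], " shares no non-zero taxon ",
              "with the reference; factor set to 1")
      return(1)
    }
    trimmed_factor(counts[, j], counts[, ref], lib_sizes = lib[c(j, ref)],
                   trim_M = trim_M, trim_A = trim_A)
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  adj <- sweep(counts, 2L, f * lib / mean(lib), `/`)
  list(adjusted = adj, factors = f,
       reference_sample = colnames(counts)[ref])
}

#' Add a pseudocount
#'
#' Increments every unmasked cell by `pseudocount` (default 1) so that the
#' subsequent log-ratio transform is defined at zeros.  Masked cells stay
#' masked.
#'
#' @param x Numeric matrix.
#' @param pseudocount Positive offset.
#' @return The shifted matrix.
#' @export
add_pseudocount <- function(x, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  x + pseudocount
}

#' Centered log-ratio transform
#'
#' Per sample, `CLR(x)_k = log(x_k) - log(G(x))` with `G(x)` the geometric
#' mean over the sample's unmasked taxa (natural log).  Requires strictly
#' positive unmasked cells (apply [add_pseudocount()] first).
#'
#' @param x Positive real matrix (taxa x samples), possibly with `NA`
#'   masks.
#' @return The CLR matrix, with the per-sample geometric means in
#'   `attr(, "geometric_mean")`.  Within each sample, the CLR values of
#'   unmasked taxa sum to zero.
#' @examples
#' clr_transform(matrix(c(1, 4, 16), 3, 1,
#'                      dimnames = list(paste0("t", 1:3), "s1")))
#' @export
clr_transform <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) {
    stop("CLR requires strictly positive values; add a pseudocount first")
  }
  lg <- log(x)
  gm <- colMeans(lg, na.rm = TRUE)
  out <- sweep(lg, 2L, gm, `-`)
  attr(out, "geometric_mean") <- exp(gm)
  out
}

#' Serialize normalization factors
#'
#' Writes `factors.tsv` (sample, factor, reference flag).
#'
#' @param norm Result of [ctf_normalize()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_factors <- function(norm, path) {
  df <- data.frame(sample = names(norm$factors),
                   factor = norm$factors,
                   reference = names(norm$factors) == norm$reference_sample)
  write_result_table(df, path)
}
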