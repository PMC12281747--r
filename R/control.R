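#' Pipeline configuration
#'
#' Collects the tunable parameters of the DA pipeline.  Defaults follow the
#' method's standard operating point: a 10% prevalence floor, a 1000-read
#' library-size floor, pseudocount 1, TMM double-trimming of 30% (M values)
#' and 5% (A values) per tail, an exchangeable working correlation, and a
#' 0.05 significance level on BH-adjusted p-values.
#'
#' @param prevalence_min Minimum fraction of samples in which a taxon must be
#'   non-zero to be retained (in `[0, 1)`).
#' @param min_library_size Minimum per-sample read total; lower-depth samples
#'   are dropped.
#' @param pseudocount Positive offset added to normalized counts before the
#'   log-ratio transform.
#' @param trim_M,trim_A Per-tail trim fractions for M and A values in the
#'   TMM factor (in `[0, 0.5)`).
#' @param working_correlation Working correlation structure for the GEE:
#'   `"exchangeable"` (default), `"independence"`, `"ar1"` or
#'   `"unstructured"`.
#' @param alpha_level Significance level applied to adjusted p-values.
#' @param structural_fraction Within-group zero fraction at or above which a
#'   taxon's zeros in that group are called structural (default 1: zero in
#'   every sample of the group).
#' @param outlier_k Robust-z cutoff (multiples of 1.4826*MAD on
#'   log(count + 1)) for outlier masking within group x taxon.
#' @param outlier_zero_prevalence Within-group non-zero prevalence at or
#'   above which an unexplained zero (sample depth above the group median) is
#'   masked as an outlier zero.
#' @param joint Fit one stacked GEE across all taxa (`TRUE`, the model's
#'   definition) or one GEE per taxon (`FALSE`, a scalability fallback).
#' @param tol,max_iter GEE convergence tolerance on the coefficient update
#'   and iteration cap.
#' @param group_ref,occasion_ref Optional reference levels for the design.
#' @param seed Integer seed from which all pipeline randomness flows.
#' @return A list of class `"microgee_control"`.
#' @export
microgee_control <- function(prevalence_min = 0.10,
                             min_library_size = 1000L,
                             pseudocount = 1,
                             trim_M = 0.30,
                             trim_A = 0.05,
                             working_correlation = c("exchangeable",
                                                     "independence",
                                                     "ar1", "unstructured"),
                             alpha_level = 0.05,
                             structural_fraction = 1,
                             outlier_k = 3,
                             outlier_zero_prevalence = 0.90,
                             joint = TRUE,
                             tol = 1e-8,
                             max_iter = 60L,
                             group_ref = NULL,
                             occasion_ref = NULL,
                             seed = 1L) {
  working_correlation <- match.arg(working_correlation)
  stopifnot(
    is.numeric(prevalence_min), prevalence_min >= 0, prevalence_min < 1,
    is.numeric(min_library_size), min_library_size >= 0,
    is.numeric(pseudocount), pseudocount > 0,
    is.numeric(trim_M), trim_M >= 0, trim_M < 0.5,
    is.numeric(trim_A), trim_A >= 0, trim_A < 0.5,
    is.numeric(alpha_level), alpha_level > 0, alpha_level < 1,
    is.numeric(structural_fraction), structural_fraction > 0,
    structural_fraction <= 1,
    is.numeric(outlier_k), outlier_k > 0,
    is.numeric(outlier_zero_prevalence), outlier_zero_prevalence > 0,
    outlier_zero_prevalence <= 1,
    is.logical(joint), is.numeric(tol), tol > 0,
    is.numeric(max_iter), max_iter >= 1
  )
  structure(list(
    prevalence_min = prevalence_min,
    min_library_size = as.integer(min_library_size),
    pseudocount = pseudocount,
    trim_M = trim_M,
    trim_A = trim_A,
    working_correlation = working_correlation,
    alpha_level = alpha_level,
    structural_fraction = structural_fraction,
    outlier_k = outlier_k,
    outlier_zero_prevalence = outlier_zero_prevalence,
    joint = joint,
    tol = tol,
    max_iter = as.integer(max_iter),
    group_ref = group_ref,
    occasion_ref = occasion_ref,
    seed = as.integer(seed)
  ), class = "microgee_control")
}
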