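# Approximate-Bayes-factor fine-mapping under a single-causal-variant locus
# model, with log-domain arithmetic throughout: real association loci reach
# |z| around 40, where the Bayes factor overflows double precision.

#' Wakefield approximate Bayes factor
#'
#' For an estimated effect with variance \eqn{V = se^2}, \eqn{z = \beta/se}
#' and a normal effect-size prior with variance \eqn{W}:
#' \deqn{\log ABF = \tfrac12 \log\frac{V}{V+W} + \frac{z^2}{2}\cdot\frac{W}{V+W}}
#' Returned on the natural-log scale; larger values favor association.
#'
#' @param beta Estimated effect (vectorized).
#' @param se Standard error, > 0.
#' @param prior_w Prior variance of the true effect (default 0.04, i.e. prior
#'   SD 0.2 on the log-odds scale — the standard choice for binary traits).
#' @return log Bayes factor(s), natural log.
#' @export
wakefield_abf <- function(beta, se, prior_w = 0.04) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_w <= 0)) stop("prior_w must be positive")
  v <- se^2
  z <- beta / se
  0.5 * log(v / (v + prior_w)) + z^2 * prior_w / (2 * (v + prior_w))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Per-variant posterior probabilities within a locus
#'
#' Assumes exactly one causal variant per locus with a uniform prior over
#' variants: \eqn{pp_j = ABF_j / \sum_k ABF_k}, computed in the log domain via
#' logsumexp.
#'
#' @param records Summary-statistic data.frame for one locus (columns
#'   \code{variant_id}, \code{beta}, \code{se}).
#' @param prior_w Prior effect variance passed to \code{\link{wakefield_abf}}.
#' @param locus_id Optional locus label.
#' @return A list of class \code{locus_posterior}: \code{locus_id},
#'   \code{variant_ids}, \code{log_abf}, \code{pp}, \code{prior_w}.
#' @export
locus_pp <- function(records, prior_w = 0.04, locus_id = "locus") {
  if (nrow(records) == 0) stop("empty locus")
  log_abf <- wakefield_abf(records$beta, records$se, prior_w)
  pp <- exp(log_abf - .logsumexp(log_abf))
  structure(list(locus_id = locus_id, variant_ids = records$variant_id,
                 log_abf = log_abf, pp = pp, prior_w = prior_w),
            class = "locus_posterior")
}

#' Cross-method consensus causal-variant filter
#'
#' A variant is designated causal only if its posterior probability exceeds
#' the threshold in every supplied method's PP set (strict intersection).
#' With a single set this reduces to simple thresholding.
#'
#' @param pp_sets Named list; each element a named numeric vector mapping
#'   variant_id to posterior probability (one element per fine-mapping
#'   method, e.g. ABF plus externally computed FINEMAP / SuSiE files).
#' @param threshold PP threshold (default 0.8, strict >).
#' @return Character vector of consensus causal variant IDs.
#' @export
consensus_causal <- function(pp_sets, threshold = 0.8) {
  if (length(pp_sets) == 0) stop("empty pp set list")
  if (any(vapply(pp_sets, length, 1L) == 0)) stop("empty pp set")
  stopifnot(threshold > 0, threshold < 1)
  passing <- lapply(pp_sets, function(s) names(s)[s > threshold])
  Reduce(intersect, passing)
}

#' Read a per-method posterior-probability file
#'
#' Two-column whitespace-delimited text: variant_id, pp. Used to feed
#' externally computed fine-mapping posteriors into
#' \code{\link{consensus_causal}}.
#'
#' @param path File path.
#' @return Named numeric vector of posterior probabilities.
#' @export
read_pp_file <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(x[[2]]), as.character(x[[1]]))
}

#' Fine-map the loci of a meta-analysis scan
#'
#' Splits the scan into loci around the clumped index variants (all scan
#' variants within the window) and computes ABF posteriors per locus.
#'
#' @param meta Meta-analysis data.frame (needs \code{variant_id},
#'   \code{chrom}, \code{pos}, and \code{beta}/\code{se} columns; for
#'   \code{\link{meta_analyze}} output, supply per-variant \code{beta} and
#'   \code{se} via \code{beta_col}/\code{se_col}).
#' @param loci Output of \code{\link{significant_loci}}.
#' @param window_bp Locus half-width around each index variant (defaults to
#'   the clumping window).
#' @param prior_w Prior effect variance.
#' @param beta_col,se_col Column names holding the effect and its SE.
#' @return List of \code{locus_posterior} objects, one per index variant.
#' @export
finemap_loci <- function(meta, loci, window_bp = 500000L, prior_w = 0.04,
                         beta_col = "beta", se_col = "se") {
  lapply(seq_len(nrow(loci)), function(i) {
    inwin <- meta$chrom == loci$chrom[i] &
      abs(meta$pos - loci$pos[i]) <= window_bp
    rec <- data.frame(variant_id = meta$variant_id[inwin],
                      beta = meta[[beta_col]][inwin],
                      se = meta[[se_col]][inwin], stringsAsFactors = FALSE)
    locus_pp(rec, prior_w = prior_w, locus_id = loci$variant_id[i])
  })
}
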