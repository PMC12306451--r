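# Polygenic score construction: variant QC filters, dosage-weighted scoring
# with allele alignment, cohort standardization, quantile stratification, and
# a clump+threshold weight deriver for fully synthetic runs.

#' Variant QC filters for score construction
#'
#' Keeps variants that are in the inclusion panel, have imputation INFO above
#' \code{config$info_min}, MAF at or above \code{config$maf_min}, and (when a
#' reference frequency is supplied) an absolute allele-frequency discrepancy
#' below \code{max_freq_discrepancy}. The MAF rule excludes rare variants
#' (keep MAF >= threshold); the opposite direction is available via
#' \code{maf_direction} for completeness.
#'
#' @param records Summary-statistic data.frame (needs \code{variant_id},
#'   \code{eaf}, \code{info}; missing INFO is treated as passing only when
#'   \code{info_required = FALSE}).
#' @param panel Character vector of panel variant IDs (HapMap3-style
#'   inclusion list).
#' @param config A \code{\link{run_config}}.
#' @param ref_freq Optional named numeric vector of reference-panel effect
#'   allele frequencies.
#' @param max_freq_discrepancy Maximum |EAF - reference EAF| (default 0.2).
#' @param maf_direction \code{"exclude_rare"} (default) keeps MAF >= maf_min.
#' @param info_required Reject records with missing INFO (default TRUE).
#' @return List with \code{kept} (filtered records) and \code{rejection_log}
#'   (named counts per reason: panel, info, maf, freq_discrepancy).
#' @export
qc_filter <- function(records, panel, config = run_config(), ref_freq = NULL,
                      max_freq_discrepancy = 0.2,
                      maf_direction = c("exclude_rare", "exclude_common"),
                      info_required = TRUE) {
  maf_direction <- match.arg(maf_direction)
  in_panel <- records$variant_id %in% panel
  info <- records$info
  info_ok <- if (info_required) !is.na(info) & info > config$info_min
             else is.na(info) | info > config$info_min
  maf <- pmin(records$eaf, 1 - records$eaf)
  maf_ok <- if (maf_direction == "exclude_rare") !is.na(maf) & maf >= config$maf_min
            else !is.na(maf) & maf < config$maf_min
  freq_ok <- rep(TRUE, nrow(records))
  if (!is.null(ref_freq)) {
    rf <- ref_freq[records$variant_id]
    freq_ok <- is.na(rf) | abs(records$eaf - rf) < max_freq_discrepancy
  }
  reject_reason <- rep(NA_character_, nrow(records))
  reject_reason[!freq_ok] <- "freq_discrepancy"
  reject_reason[!maf_ok] <- "maf"
  reject_reason[!info_ok] <- "info"
  reject_reason[!in_panel] <- "panel"
  keep <- is.na(reject_reason)
  log <- table(factor(reject_reason[!keep],
                      levels = c("panel", "info", "maf", "freq_discrepancy")))
  if (!any(keep)) warning("qc_filter removed every variant")
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejection_log = c(log))
}

#' Compute dosage-weighted polygenic scores
#'
#' The raw score is the sum over variants of weight times effect-allele
#' dosage. When a weight's effect allele differs from the allele the dosage
#' column counts, the dosage is recoded (d -> 2 - d), which shifts the score
#' by a constant and flips that variant's contribution — standardized scores
#' are unaffected by the shift. Scores are standardized over the scored
#' cohort (mean 0, SD 1).
#'
#' @param dosages Numeric matrix (individuals x variants, values in [0, 2])
#'   with variant IDs as column names and, optionally, individual IDs as row
#'   names.
#' @param weights Weight data.frame (\code{variant_id}, \code{effect_allele},
#'   \code{weight}).
#' @param allele_alignment Optional named character vector giving the allele
#'   counted by each dosage column; columns absent from it are assumed to
#'   count the weight's effect allele.
#' @return Data.frame: \code{individual_id}, \code{raw_score},
#'   \code{z_score}, \code{n_variants_used}.
#' @export
compute_prs <- function(dosages, weights, allele_alignment = NULL) {
  missing <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing))
    stop("weight variants absent from dosage matrix: ",
         paste(missing, collapse = ", "))
  d <- dosages[, weights$variant_id, drop = FALSE]
  if (!is.null(allele_alignment)) {
    counted <- allele_alignment[weights$variant_id]
    flip <- !is.na(counted) & counted != weights$effect_allele
    if (any(flip)) d[, flip] <- 2 - d[, flip]
  }
  raw <- as.numeric(d %*% weights$weight)
  s <- stats::sd(raw)
  z <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- sprintf("id%06d", seq_len(nrow(dosages)))
  data.frame(individual_id = ids, raw_score = raw, z_score = z,
             n_variants_used = nrow(weights), stringsAsFactors = FALSE)
}

#' Clump-and-threshold weight derivation
#'
#' A simple weight deriver for synthetic end-to-end runs: the index variants
#' from distance clumping at \code{p_cut} are retained with their
#' meta-analysis effect sizes as weights.
#'
#' @param meta Meta-analysis data.frame (from \code{\link{meta_analyze}};
#'   needs \code{beta_meta} or \code{beta}).
#' @param p_cut P-value threshold.
#' @param window_bp Clumping half-window.
#' @return Weight data.frame (\code{variant_id}, \code{effect_allele},
#'   \code{weight}).
#' @export
clump_threshold_weights <- function(meta, p_cut = 5e-8, window_bp = 500000L) {
  idx <- significant_loci(meta, threshold = p_cut, window_bp = window_bp)
  bcol <- if ("beta_meta" %in% names(idx)) "beta_meta" else "beta"
  data.frame(variant_id = idx$variant_id,
             effect_allele = idx$effect_allele,
             weight = idx[[bcol]], stringsAsFactors = FALSE)
}

#' Stratify individuals by PRS quantiles
#'
#' Labels each individual \code{low}, \code{mid} or \code{high} by empirical
#' quantiles of the standardized score. \code{quantiles = c(0.5, 0.5)} gives
#' a median split with no mid group. Ties at a boundary are broken by a
#' stable sort on individual_id, so group sizes are deterministic.
#'
#' @param scores Data.frame from \code{\link{compute_prs}}.
#' @param quantiles Numeric \code{c(low, high)} with 0 < low <= high < 1.
#' @return Factor of labels in the original row order, levels
#'   \code{low}, \code{mid}, \code{high}.
#' @export
stratify_prs <- function(scores, quantiles = c(0.2, 0.8)) {
  lo <- quantiles[1]; hi <- quantiles[2]
  stopifnot(lo > 0, hi < 1, lo <= hi)
  n <- nrow(scores)
  ord <- order(scores$z_score, scores$individual_id)
  n_low <- floor(lo * n)
  n_high <- n - floor(hi * n)
  lab <- rep("mid", n)
  lab[ord[seq_len(n_low)]] <- "low"
  if (n_high > 0) lab[ord[seq.int(n - n_high + 1, n)]] <- "high"
  factor(lab, levels = c("low", "mid", "high"))
}

#' Write a PRS score table
#'
#' CSV with individual_id, raw_score, z_score, n_variants_used. Raw scores
#' are weighted sums (not averages) of effect-allele dosages.
#'
#' @param scores Data.frame from \code{\link{compute_prs}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
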