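# Sample-size-weighted fixed-effect meta-analysis (METAL's sample-size
# scheme): per-study z statistics combined with weights proportional to the
# square root of the effective sample size.

#' Effective sample size of a case-control study
#'
#' The binary-trait weighting base \eqn{4 / (1/n_{cases} + 1/n_{controls})};
#' equals the total N for a balanced design and saturates at four times the
#' smaller arm for extreme imbalance.
#'
#' @param n_cases,n_controls Positive case and control counts (vectorized).
#' @return Effective sample size(s).
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop("n_cases and n_controls must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Combine per-study z-scores by sample-size weighting
#'
#' \eqn{z_{meta} = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}} with
#' \eqn{w_i = \sqrt{n_{eff,i}}}; the two-sided p-value is the normal tail
#' probability. z-scores must be signed with respect to a common harmonized
#' effect allele.
#'
#' @param z_scores Numeric vector of per-study z statistics.
#' @param n_eff Positive effective sample sizes, same length.
#' @return List with \code{z_meta} and \code{p_meta}.
#' @export
combine_z <- function(z_scores, n_eff) {
  if (length(z_scores) == 0) stop("empty input")
  if (length(z_scores) != length(n_eff)) stop("z_scores and n_eff lengths differ")
  if (any(n_eff <= 0)) stop("all n_eff must be positive")
  w <- sqrt(n_eff)
  z_meta <- sum(w * z_scores) / sqrt(sum(w^2))
  list(z_meta = z_meta, p_meta = 2 * stats::pnorm(-abs(z_meta)))
}

#' Meta-analyze harmonized per-study summary statistics
#'
#' Harmonizes every study to the first study's allele coding, derives per-study
#' z as beta/se, and combines across studies by
#' \code{\link{combine_z}} with effective-sample-size weights. Variants present
#' in fewer than two studies are retained but flagged via
#' \code{n_studies_present}.
#'
#' @param studies List of summary-statistic data.frames (canonical columns).
#' @return Data.frame with \code{variant_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{z_meta}, \code{p_meta},
#'   \code{beta_meta} (inverse-n-weighted average beta, for downstream
#'   weighting), \code{direction} (one character per study: +, - or ?),
#'   \code{total_n_eff}, \code{n_studies_present}.
#' @export
meta_analyze <- function(studies) {
  stopifnot(length(studies) >= 1)
  ref <- studies[[1]]
  aligned <- vector("list", length(studies))
  aligned[[1]] <- ref
  if (length(studies) > 1) {
    for (k in 2:length(studies)) {
      h <- harmonize_alleles(studies[[k]], ref)
      aligned[[k]] <- h$harmonized
    }
  }
  ids <- ref$variant_id
  nstud <- length(studies)
  zmat <- nmat <- bmat <- matrix(NA_real_, length(ids), nstud)
  for (k in seq_len(nstud)) {
    st <- aligned[[k]]
    i <- match(st$variant_id, ids)
    ok <- !is.na(i)
    zmat[i[ok], k] <- st$beta[ok] / st$se[ok]
    nmat[i[ok], k] <- effective_sample_size(st$n_cases[ok], st$n_controls[ok])
    bmat[i[ok], k] <- st$beta[ok]
  }
  res <- lapply(seq_along(ids), function(j) {
    pres <- !is.na(zmat[j, ])
    cz <- combine_z(zmat[j, pres], nmat[j, pres])
    dir <- rep("?", nstud)
    dir[pres] <- ifelse(zmat[j, pres] >= 0, "+", "-")
    data.frame(z_meta = cz$z_meta, p_meta = cz$p_meta,
               beta_meta = sum(bmat[j, pres] * nmat[j, pres]) / sum(nmat[j, pres]),
               direction = paste(dir, collapse = ""),
               total_n_eff = sum(nmat[j, pres]),
               n_studies_present = sum(pres))
  })
  out <- cbind(ref[, c("variant_id", "chrom", "pos", "effect_allele",
                       "other_allele")],
               do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Extract independent significant loci by distance clumping
#'
#' Greedy clumping: among variants below the significance threshold, take the
#' smallest p-value as an index variant, suppress all significant variants
#' within \code{window_bp} on the same chromosome, and repeat.
#'
#' @param meta Data.frame with \code{variant_id}, \code{chrom}, \code{pos} and
#'   \code{p_meta} (or \code{pvalue}).
#' @param threshold Significance threshold (default \code{5e-8}).
#' @param window_bp Suppression half-window in base pairs (default 500 kb).
#' @return Data.frame of index variants (rows of \code{meta}) with a
#'   \code{locus} integer and a \code{n_members} count of suppressed
#'   significant variants (index included), ordered by p-value.
#' @export
significant_loci <- function(meta, threshold = 5e-8, window_bp = 500000L) {
  stopifnot(threshold > 0, threshold <= 1, window_bp > 0)
  pcol <- if ("p_meta" %in% names(meta)) "p_meta" else "pvalue"
  sig <- meta[meta[[pcol]] < threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(cbind(sig, locus = integer(0), n_members = integer(0)))
  sig <- sig[order(sig[[pcol]]), , drop = FALSE]
  taken <- rep(FALSE, nrow(sig))
  idx <- integer(0); members <- integer(0)
  locus <- 0L
  while (any(!taken)) {
    j <- which(!taken)[1]
    locus <- locus + 1L
    near <- !taken & sig$chrom == sig$chrom[j] &
      abs(sig$pos - sig$pos[j]) <= window_bp
    idx <- c(idx, j)
    members <- c(members, sum(near))
    taken[near] <- TRUE
  }
  out <- sig[idx, , drop = FALSE]
  out$locus <- seq_along(idx)
  out$n_members <- members
  rownames(out) <- NULL
  out
}

#' Spearman concordance of effect sizes between two variant sets
#'
#' Rank correlation of betas over the intersection of variants, used to check
#' replication consistency between two summary-statistic sets harmonized to
#' common effect alleles.
#'
#' @param set_a,set_b Data.frames with \code{variant_id} and \code{beta}.
#' @return List with \code{spearman_rho}, \code{p} and \code{n_shared}.
#' @export
effect_concordance <- function(set_a, set_b) {
  i <- match(set_a$variant_id, set_b$variant_id)
  ok <- !is.na(i)
  if (sum(ok) < 3) stop("fewer than 3 shared variants")
  ct <- suppressWarnings(
    stats::cor.test(set_a$beta[ok], set_b$beta[i[ok]], method = "spearman"))
  list(spearman_rho = unname(ct$estimate), p = ct$p.value, n_shared = sum(ok))
}

#' Write a METAL-style meta-analysis table
#'
#' Tab-delimited columns MarkerName, Allele1, Allele2, Zscore, P-value,
#' Direction, Weight.
#'
#' @param meta Output of \code{\link{meta_analyze}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_meta_table <- function(meta, path) {
  out <- data.frame(MarkerName = meta$variant_id,
                    Allele1 = meta$effect_allele, Allele2 = meta$other_allele,
                    Zscore = meta$z_meta, `P-value` = meta$p_meta,
                    Direction = meta$direction, Weight = meta$total_n_eff,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
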