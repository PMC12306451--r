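# Canonical column set for GWAS summary statistics. Coordinates are 1-based
# throughout, as in standard summary-stat conventions.
.sumstat_cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "beta", "se", "pvalue", "n_cases", "n_controls", "eaf", "info")

# Default header synonyms; METAL-style names included.
.default_column_map <- c(
  MarkerName = "variant_id", SNP = "variant_id", rsid = "variant_id",
  ID = "variant_id",
  CHR = "chrom", Chromosome = "chrom", chr = "chrom",
  BP = "pos", POS = "pos", Position = "pos", position = "pos",
  Allele1 = "effect_allele", A1 = "effect_allele", EA = "effect_allele",
  Allele2 = "other_allele", A2 = "other_allele", OA = "other_allele",
  Effect = "beta", BETA = "beta", b = "beta",
  StdErr = "se", SE = "se",
  `P-value` = "pvalue", P = "pvalue", `P.value` = "pvalue", p = "pvalue",
  N_CASES = "n_cases", Ncases = "n_cases", ncase = "n_cases",
  N_CONTROLS = "n_controls", Ncontrols = "n_controls", ncontrol = "n_controls",
  EAF = "eaf", FRQ = "eaf", freq = "eaf",
  INFO = "info", Rsq = "info"
)

#' Construct a run configuration
#'
#' Bundles the analysis-wide thresholds so every stage reads the same values
#' and every output can record them alongside the seed.
#'
#' @param significance_threshold Genome-wide significance level for the
#'   meta-analysis (default \code{5e-8}).
#' @param pp_threshold Posterior-probability threshold used by the fine-mapping
#'   consensus rule (default 0.8).
#' @param info_min Minimum imputation INFO retained by PRS variant QC.
#' @param maf_min Minimum minor allele frequency retained by PRS variant QC.
#' @param bootstrap_iters Bootstrap iterations for resampling-based intervals.
#' @param seed Integer seed recorded in outputs for reproducibility.
#' @param include_short_followup If \code{FALSE} (default), individuals with an
#'   event within 6 months of baseline are excluded from survival models; the
#'   sensitivity analysis sets this \code{TRUE}.
#' @param alpha Family-wise significance level for multiple-testing control.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(significance_threshold = 5e-8, pp_threshold = 0.8,
                       info_min = 0.9, maf_min = 0.01, bootstrap_iters = 1000,
                       seed = 1L, include_short_followup = FALSE, alpha = 0.05) {
  stopifnot(significance_threshold > 0, significance_threshold < 1,
            pp_threshold > 0, pp_threshold < 1,
            info_min >= 0, info_min <= 1, maf_min >= 0, maf_min < 0.5,
            bootstrap_iters >= 1, alpha > 0, alpha < 1)
  structure(list(significance_threshold = significance_threshold,
                 pp_threshold = pp_threshold, info_min = info_min,
                 maf_min = maf_min, bootstrap_iters = as.integer(bootstrap_iters),
                 seed = as.integer(seed),
                 include_short_followup = isTRUE(include_short_followup),
                 alpha = alpha),
            class = "run_config")
}

#' Read a GWAS summary-statistics table
#'
#' Reads whitespace- or tab-delimited summary statistics with a header row,
#' mapping METAL-style or custom headers onto the canonical column set.
#' Alleles are uppercased; p-values of exactly zero (finite-precision
#' underflow, common in large GWAS) are clamped to the smallest representable
#' positive double with a warning. Rows failing validation (non-positive SE,
#' invalid alleles, p outside (0,1]) are dropped and tallied by reason.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Optional named character vector mapping file headers to
#'   canonical names (\code{variant_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{se},
#'   \code{pvalue}, \code{n_cases}, \code{n_controls}, \code{eaf},
#'   \code{info}). Merged over built-in METAL-style synonyms.
#' @return A data.frame of records with attribute \code{"rejections"}, a named
#'   integer vector of per-reason rejection counts.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  map <- .default_column_map
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  hit <- names(raw) %in% names(map)
  names(raw)[hit] <- unname(map[names(raw)[hit]])
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("summary-statistics file is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in setdiff(.sumstat_cols, names(raw))) raw[[col]] <- NA
  df <- raw[, .sumstat_cols]
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$chrom <- as.character(df$chrom)
  for (col in c("pos", "n_cases", "n_controls")) df[[col]] <- as.integer(df[[col]])
  for (col in c("beta", "se", "pvalue", "eaf", "info")) df[[col]] <- as.numeric(df[[col]])

  n_zero <- sum(!is.na(df$pvalue) & df$pvalue == 0)
  if (n_zero > 0) {
    warning(n_zero, " p-value(s) of 0 clamped to smallest representable positive value")
    df$pvalue[!is.na(df$pvalue) & df$pvalue == 0] <- .Machine$double.xmin
  }

  bases <- c("A", "C", "G", "T")
  bad_allele <- !(df$effect_allele %in% bases) | !(df$other_allele %in% bases) |
    df$effect_allele == df$other_allele
  bad_se <- is.na(df$se) | df$se <= 0
  bad_p <- is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  bad_beta <- is.na(df$beta)
  rejections <- c(allele = sum(bad_allele), se = sum(bad_se & !bad_allele),
                  pvalue = sum(bad_p & !bad_allele & !bad_se),
                  beta = sum(bad_beta & !bad_allele & !bad_se & !bad_p))
  keep <- !(bad_allele | bad_se | bad_p | bad_beta)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Write a summary-statistics table
#'
#' Tab-delimited text with the canonical header; round-trips with
#' \code{\link{read_summary_stats}}.
#'
#' @param records Data.frame of summary-statistic records.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  utils::write.table(records[, intersect(.sumstat_cols, names(records))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics to a reference allele coding
#'
#' Aligns each target record's effect/other alleles to those of the matching
#' reference record (matched by \code{variant_id}). Matching allele pairs pass
#' unchanged; swapped pairs flip the sign of beta and replace eaf by 1-eaf;
#' strand-complement pairs are complemented and then matched. Palindromic
#' (A/T, C/G) variants cannot be disambiguated by strand and are rejected, as
#' are irreconcilable allele pairs and variants absent from the reference.
#'
#' @param target Data.frame of records to align.
#' @param reference Data.frame supplying the reference allele coding (columns
#'   \code{variant_id}, \code{effect_allele}, \code{other_allele}).
#' @return A list with \code{harmonized} (aligned records) and \code{rejected}
#'   (rejected rows with a \code{reason} column: "palindromic", "mismatch", or
#'   "absent").
#' @export
harmonize_alleles <- function(target, reference) {
  idx <- match(target$variant_id, reference$variant_id)
  reason <- rep(NA_character_, nrow(target))
  reason[is.na(idx)] <- "absent"

  rea <- reference$effect_allele[idx]
  roa <- reference$other_allele[idx]
  tea <- target$effect_allele
  toa <- target$other_allele

  pal <- .is_palindromic(tea, toa)
  reason[is.na(reason) & pal] <- "palindromic"

  same <- !is.na(idx) & !pal & tea == rea & toa == roa
  swap <- !is.na(idx) & !pal & tea == roa & toa == rea
  flip_same <- !is.na(idx) & !pal & !same & !swap &
    .complement(tea) == rea & .complement(toa) == roa
  flip_swap <- !is.na(idx) & !pal & !same & !swap &
    .complement(tea) == roa & .complement(toa) == rea
  unresolved <- is.na(reason) & !(same | swap | flip_same | flip_swap)
  reason[unresolved] <- "mismatch"

  out <- target
  out$effect_allele[flip_same | flip_swap] <- .complement(tea[flip_same | flip_swap])
  out$other_allele[flip_same | flip_swap] <- .complement(toa[flip_same | flip_swap])
  sw <- swap | flip_swap
  out$beta[sw] <- -out$beta[sw]
  if ("eaf" %in% names(out)) out$eaf[sw] <- 1 - out$eaf[sw]
  ea <- out$effect_allele[sw]
  out$effect_allele[sw] <- out$other_allele[sw]
  out$other_allele[sw] <- ea

  keep <- is.na(reason)
  rejected <- target[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  harmonized <- out[keep, , drop = FALSE]
  rownames(harmonized) <- rownames(rejected) <- NULL
  list(harmonized = harmonized, rejected = rejected)
}

#' Read a PRS weight file
#'
#' Three-column whitespace-delimited text (\code{variant_id},
#' \code{effect_allele}, \code{weight}), the PLINK \code{--score} layout.
#'
#' @param path Path to the weight file.
#' @return Data.frame with one row per variant.
#' @export
read_weight_file <- function(path) {
  w <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  names(w)[1:3] <- c("variant_id", "effect_allele", "weight")
  w$effect_allele <- toupper(w$effect_allele)
  w$weight <- as.numeric(w$weight)
  if (anyDuplicated(w$variant_id))
    stop("duplicate variant_id in weight file")
  w
}

#' @rdname read_weight_file
#' @param weights Data.frame with columns \code{variant_id},
#'   \code{effect_allele}, \code{weight}.
#' @export
write_weight_file <- function(weights, path) {
  utils::write.table(weights[, c("variant_id", "effect_allele", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a per-individual cohort table
#'
#' CSV with a header, one row per individual. Expected columns include
#' \code{individual_id}, \code{time} (years of follow-up), \code{event}
#' (0/1), \code{smoking} (0 = never, 1 = ever), \code{prs}, covariates, and
#' any per-variant dosage columns.
#'
#' @param path Path to a CSV file.
#' @return A data.frame.
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_cohort_table
#' @param cohort Cohort data.frame.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
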