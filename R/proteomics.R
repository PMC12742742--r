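# Post-search label-free proteomics pipeline: record filters, valid-value
# filtering, left-censored detection-limit imputation, within-sample LFQ
# normalization, and two-group differential gating. The stage order is
# fixed: filter_records -> valid_value_filter -> impute_missing ->
# differential_test.

#' Construct a protein quantification matrix
#'
#' @param intensity numeric matrix of log2 label-free intensities, proteins in
#'   rows (named), samples in columns (named); `NA` marks missing values.
#' @param groups character/factor of group labels, one per sample column.
#' @param proteotypic logical per protein: identified by at least one
#'   proteotypic peptide (default all `TRUE`).
#' @param qvalue numeric per protein: protein library q-value (default 0).
#' @return object of class `protein_quant`.
#' @export
protein_quant <- function(intensity, groups,
                          proteotypic = rep(TRUE, nrow(intensity)),
                          qvalue = rep(0, nrow(intensity))) {
  if (!is.matrix(intensity)) stop_config("'intensity' must be a matrix")
  if (length(groups) != ncol(intensity))
    stop_config("one group label per sample column is required")
  if (length(proteotypic) != nrow(intensity) || length(qvalue) != nrow(intensity))
    stop_config("per-protein metadata must match the number of rows")
  if (any(!is.finite(intensity) & !is.na(intensity)))
    stop_config("intensities must be finite where present")
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("P%04d", seq_len(nrow(intensity)))
  structure(list(intensity = intensity, groups = as.character(groups),
                 proteotypic = as.logical(proteotypic), qvalue = as.numeric(qvalue)),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("protein_quant:", nrow(x$intensity), "proteins x", ncol(x$intensity),
      "samples;", sum(is.na(x$intensity)), "missing values; groups:",
      paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}

subset_proteins <- function(x, keep) {
  x$intensity <- x$intensity[keep, , drop = FALSE]
  x$proteotypic <- x$proteotypic[keep]
  x$qvalue <- x$qvalue[keep]
  x
}

#' Identification-confidence record filter
#'
#' Drops proteins whose library q-value is 0.01 or higher, or that lack
#' proteotypic (protein-unique) peptide evidence.
#'
#' @param x a [protein_quant()].
#' @param q_cut library q-value cutoff (default 0.01, i.e. 1 percent).
#' @return the filtered `protein_quant`.
#' @export
filter_records <- function(x, q_cut = 0.01) {
  stopifnot(inherits(x, "protein_quant"))
  subset_proteins(x, x$proteotypic & x$qvalue < q_cut)
}

#' Valid-value filter
#'
#' Keeps a protein iff at least one sample group holds `min_valid` or more
#' non-missing values (the convention of label-free DE workflows built on
#' left-censored imputation). The stricter alternative reading - drop a
#' protein if ANY group falls below `min_valid` - is available via
#' `rule = "all_groups"`.
#'
#' @param x a [protein_quant()].
#' @param min_valid minimum number of valid values (default 3).
#' @param rule `"any_group"` (default) or `"all_groups"`.
#' @return the filtered `protein_quant`.
#' @export
valid_value_filter <- function(x, min_valid = 3,
                               rule = c("any_group", "all_groups")) {
  stopifnot(inherits(x, "protein_quant"))
  rule <- match.arg(rule)
  if (min_valid <= 0) return(x)
  counts <- vapply(unique(x$groups), function(g) {
    rowSums(!is.na(x$intensity[, x$groups == g, drop = FALSE]))
  }, numeric(nrow(x$intensity)))
  counts <- matrix(counts, nrow = nrow(x$intensity))
  keep <- if (rule == "any_group") {
    apply(counts >= min_valid, 1L, any)
  } else {
    apply(counts >= min_valid, 1L, all)
  }
  subset_proteins(x, keep)
}

#' Detection-limit imputation of missing intensities
#'
#' Missing log2 intensities are drawn, per sample, from a normal distribution
#' centred below the sample's observed distribution - a proxy for the
#' detection limit of left-censored label-free data:
#' `Normal(mean_s - downshift * sd_s, width * sd_s)` with `mean_s`/`sd_s`
#' the sample's observed mean and standard deviation.
#'
#' @param x a [protein_quant()].
#' @param seed integer seed; imputations are reproducible.
#' @param width imputation sd as a multiple of the sample sd (default 0.3).
#' @param downshift shift below the sample mean in sample sds (default 1.8).
#' @return a complete `protein_quant`; imputed positions are recorded in the
#'   `imputed` element (logical matrix).
#' @export
impute_missing <- function(x, seed, width = 0.3, downshift = 1.8) {
  stopifnot(inherits(x, "protein_quant"))
  assert_scalar_num(width, "width", lower = 0)
  assert_scalar_num(downshift, "downshift")
  m <- x$intensity
  if (any(colSums(!is.na(m)) < 2L))
    stop_config("every sample needs at least 2 observed values to impute")
  imputed <- is.na(m)
  if (any(imputed)) {
    set.seed(as.integer(seed))
    for (j in seq_len(ncol(m))) {
      miss <- imputed[, j]
      if (!any(miss)) next
      mu <- mean(m[!miss, j])
      s <- sd(m[!miss, j])
      m[miss, j] <- rnorm(sum(miss), mean = mu - downshift * s, sd = width * s)
    }
  }
  x$intensity <- m
  x$imputed <- imputed
  x
}

#' Within-sample normalized LFQ fractions
#'
#' Converts log2 intensities of one sample back to the linear scale and
#' expresses each protein as its fraction of the sample total:
#' `Normalized.LFQ_x = 2^log2_x / sum_x 2^log2_x`. Fractions sum to 1.
#'
#' @param x a [protein_quant()] without missing values in the chosen sample.
#' @param sample column name or index; `NULL` (default) returns the full
#'   proteins x samples fraction matrix.
#' @return named numeric vector (or matrix) of fractions.
#' @export
normalized_lfq <- function(x, sample = NULL) {
  stopifnot(inherits(x, "protein_quant"))
  if (!nrow(x$intensity)) stop_config("no proteins to normalize")
  lin <- 2^x$intensity
  fr <- sweep(lin, 2L, colSums(lin), "/")
  if (is.null(sample)) return(fr)
  if (length(sample) != 1L) stop_config("'sample' must select a single column")
  fr[, sample]
}

#' Two-group differential abundance test with fold-change gating
#'
#' Welch's two-sample t-test per protein on log2 intensities, followed by
#' Benjamini-Hochberg FDR adjustment. A protein is called significant iff
#' `q < fdr_cut` AND `|log2FC| >= fc_cut` (default: FDR < 0.05 and at least
#' 4-fold change). log2FC is `mean(group_b) - mean(group_a)`. Proteins whose
#' two groups have zero variance and identical means get p = 1 by convention.
#'
#' @param x an imputed, complete [protein_quant()].
#' @param group_a,group_b group labels to contrast (each >= 2 samples).
#' @param fc_cut absolute log2 fold-change gate (default 2).
#' @param fdr_cut FDR gate (default 0.05).
#' @return data.frame (class `de_result`): `protein`, `log2fc`, `p_value`,
#'   `q_value`, `significant`.
#' @export
differential_test <- function(x, group_a, group_b, fc_cut = 2, fdr_cut = 0.05) {
  stopifnot(inherits(x, "protein_quant"))
  ia <- x$groups == group_a
  ib <- x$groups == group_b
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop_config("both groups need at least 2 samples")
  ma <- x$intensity[, ia, drop = FALSE]
  mb <- x$intensity[, ib, drop = FALSE]
  if (anyNA(ma) || anyNA(mb))
    stop_config("missing values present; run impute_missing() first")
  na <- ncol(ma); nb <- ncol(mb)
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  var_a <- rowSums((ma - mean_a)^2) / (na - 1L)
  var_b <- rowSums((mb - mean_b)^2) / (nb - 1L)
  se2 <- var_a / na + var_b / nb
  tstat <- (mean_b - mean_a) / sqrt(se2)
  df <- se2^2 / ((var_a / na)^2 / (na - 1L) + (var_b / nb)^2 / (nb - 1L))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate & (mean_b == mean_a)] <- 1        # no variance, no difference
  p[degenerate & (mean_b != mean_a)] <- 0        # no variance, clear separation
  q <- p.adjust(p, method = "BH")
  log2fc <- mean_b - mean_a
  res <- data.frame(protein = rownames(x$intensity), log2fc = log2fc,
                    p_value = p, q_value = q,
                    significant = q < fdr_cut & abs(log2fc) >= fc_cut,
                    row.names = NULL)
  class(res) <- c("de_result", class(res))
  res
}
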