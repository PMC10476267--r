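# Stagewise differential expression within one multiplex: vehicle and TMX
# channels are first corrected to the per-protein untreated baseline, which
# removes vehicle/TMX interaction terms tied to the baseline; DE is then the
# TMX-corrected vs vehicle-corrected contrast across the whole proteome.

#' Correct vehicle and TMX channels to the untreated baseline
#'
#' Within the multiplex of one myogenic stage, subtracts each protein's mean
#' untreated log2 value from its vehicle and TMX log2 channel values
#' (untreated channels pass through unchanged). Proteins without any
#' untreated value at that stage are excluded from the stage and listed.
#'
#' @param bridged A `bridged_abundance`.
#' @param stage `"M"`, `"EM"` or `"LM"`.
#' @return List with `log2` (corrected proteins x 9 matrix for that stage's
#'   channels), `stage`, and `excluded` (protein ids without an untreated
#'   baseline).
#' @export
vehicle_correct <- function(bridged, stage = c("M", "EM", "LM")) {
  stopifnot(inherits(bridged, "bridged_abundance"))
  stage <- match.arg(stage)
  keys <- sample_keys(bridged, timepoint = stage)
  lg <- bridged$log2[, keys, drop = FALSE]
  untr <- sample_keys(bridged, "untreated", stage)
  baseline <- rowMeans(lg[, untr, drop = FALSE], na.rm = TRUE)
  excluded <- rownames(lg)[!is.finite(baseline)]
  keep <- is.finite(baseline)
  lg <- lg[keep, , drop = FALSE]
  baseline <- baseline[keep]
  treat_cols <- setdiff(keys, untr)
  lg[, treat_cols] <- lg[, treat_cols] - baseline
  list(log2 = lg, stage = stage, excluded = excluded)
}

#' Stagewise differential expression: TMX versus vehicle
#'
#' On baseline-corrected values, runs a two-sample pooled-variance two-tailed
#' t test of TMX vs vehicle per protein, adjusts with Benjamini-Hochberg
#' over all proteins tested at the stage, and calls a protein DE iff
#' `|log2fc| >= fc_threshold_log2` and `adj_p < alpha` (strict, i.e.
#' `-log10(adj_p) >= 1.3` at the default).
#'
#' @param bridged A `bridged_abundance`.
#' @param stage Myogenic stage.
#' @param alpha Significance level, strict inequality (default 0.05).
#' @param fc_threshold_log2 Minimum |log2FC| (default 1).
#' @param welch Use Welch's t test instead of the pooled form.
#' @return `data.frame` with `protein_id`, `stage`, `log2fc`, `p_value`,
#'   `adj_p`, `is_de`; attribute `excluded` lists proteins dropped for a
#'   missing untreated baseline or insufficient replicates.
#' @export
stage_de <- function(bridged, stage = c("M", "EM", "LM"), alpha = 0.05,
                     fc_threshold_log2 = 1, welch = FALSE) {
  stage <- match.arg(stage)
  vc <- vehicle_correct(bridged, stage)
  tmx_cols <- grep("\\.tmx\\.", colnames(vc$log2), value = TRUE)
  veh_cols <- grep("\\.vehicle\\.", colnames(vc$log2), value = TRUE)
  x <- vc$log2[, tmx_cols, drop = FALSE]
  y <- vc$log2[, veh_cols, drop = FALSE]
  res <- if (welch) row_welch_test(x, y) else row_t_test(x, y)
  tested <- !is.na(res$p_value)
  out <- data.frame(protein_id = rownames(vc$log2),
                    stage = stage,
                    log2fc = res$estimate,
                    p_value = res$p_value,
                    stringsAsFactors = FALSE)
  out <- out[tested, , drop = FALSE]
  out$adj_p <- bh_adjust(out$p_value)
  out$is_de <- abs(out$log2fc) >= fc_threshold_log2 & out$adj_p < alpha
  rownames(out) <- NULL
  attr(out, "excluded") <- c(vc$excluded,
                             rownames(vc$log2)[!tested])
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold_log2") <- fc_threshold_log2
  out
}
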