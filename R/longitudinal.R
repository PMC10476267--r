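# Longitudinal analysis within one treatment condition: EM/M and LM/M log2
# fold changes with two-sample pooled-variance (Student) t tests,
# Benjamini-Hochberg correction per comparison family, and the
# "myogenically regulated" (MR) call.

# Row-wise two-sample pooled-variance two-tailed t test on log2 values.
# Rows with fewer than 2 finite values in either group get NA statistics.
# Degenerate rows (pooled variance 0) get p = 1 if the means are equal and
# p = 0 otherwise.
row_t_test <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  n1 <- rowSums(is.finite(x))
  n2 <- rowSums(is.finite(y))
  m1 <- rowMeans(x, na.rm = TRUE)
  m2 <- rowMeans(y, na.rm = TRUE)
  ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  est <- m1 - m2
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- ok & sp2 == 0
  p[degen] <- ifelse(abs(est[degen]) < .Machine$double.eps^0.5, 1, 0)
  t[degen] <- ifelse(p[degen] == 1, 0, sign(est[degen]) * Inf)
  t[!ok] <- NA_real_
  p[!ok] <- NA_real_
  est[!ok] <- NA_real_
  data.frame(estimate = est, t = t, df = ifelse(ok, df, NA_real_),
             p_value = p, n1 = n1, n2 = n2)
}

#' Stage ratios: per-protein log2 fold change and t test versus myoblasts
#'
#' For one condition, computes `log2fc = mean(log2 later-stage replicates) -
#' mean(log2 M replicates)` per protein, with a two-sample pooled-variance
#' two-tailed Student t test on the bridged log2 abundances
#' (`df = n1 + n2 - 2`). Proteins with fewer than two finite replicates in
#' either group carry `NA` and are excluded from the BH family downstream.
#'
#' @param bridged A [bridge_correct()] result.
#' @param condition One of `"untreated"`, `"vehicle"`, `"tmx"`.
#' @param comparison `"EM_vs_M"` or `"LM_vs_M"`.
#' @param welch Use the Welch (unequal variance) form instead of the pooled
#'   Student form. Default `FALSE`.
#' @return `data.frame` with columns `protein_id`, `condition`,
#'   `comparison`, `log2fc`, `t`, `df`, `p_value`, `n1`, `n2`.
#' @export
stage_ratio <- function(bridged, condition,
                        comparison = c("EM_vs_M", "LM_vs_M"),
                        welch = FALSE) {
  stopifnot(inherits(bridged, "bridged_abundance"))
  comparison <- match.arg(comparison)
  condition <- match.arg(condition, conditions())
  later <- sub("_vs_M", "", comparison)
  x <- bridged$log2[, sample_keys(bridged, condition, later), drop = FALSE]
  y <- bridged$log2[, sample_keys(bridged, condition, "M"), drop = FALSE]
  res <- if (welch) row_welch_test(x, y) else row_t_test(x, y)
  data.frame(protein_id = rownames(bridged$log2),
             condition = condition,
             comparison = comparison,
             log2fc = res$estimate,
             t = res$t, df = res$df, p_value = res$p_value,
             n1 = res$n1, n2 = res$n2,
             stringsAsFactors = FALSE)
}

# Welch variant, offered behind the `welch` flag of stage_ratio()
row_welch_test <- function(x, y) {
  n1 <- rowSums(is.finite(x))
  n2 <- rowSums(is.finite(y))
  m1 <- rowMeans(x, na.rm = TRUE)
  m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- rowSums((x - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((y - m2)^2, na.rm = TRUE) / (n2 - 1)
  ok <- n1 >= 2 & n2 >= 2
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  est <- m1 - m2
  t <- est / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- ok & se2 == 0
  p[degen] <- ifelse(abs(est[degen]) < .Machine$double.eps^0.5, 1, 0)
  t[degen] <- ifelse(p[degen] == 1, 0, sign(est[degen]) * Inf)
  df[degen] <- n1[degen] + n2[degen] - 2
  t[!ok] <- NA_real_; p[!ok] <- NA_real_; est[!ok] <- NA_real_
  data.frame(estimate = est, t = t, df = ifelse(ok, df, NA_real_),
             p_value = p, n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false discovery rate adjustment over one family of
#' tests: `adj_p(i) = min over j with rank >= rank(i) of m * p(j) / rank(j)`,
#' capped at 1. `NA` entries are ignored (not counted in the family size)
#' and returned as `NA`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1] at positions: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  stats::p.adjust(p, method = "BH")
}

#' Call myogenically regulated (MR) proteins
#'
#' Runs both stage ratios (EM vs M, LM vs M) for one condition, adjusts each
#' comparison family with Benjamini-Hochberg, and applies the MR rule: a
#' protein is MR iff (a) BOTH adjusted p-values are `<= alpha` and (b) the
#' log2 fold change has magnitude `>= fc_threshold_log2` at EITHER stage.
#' Proteins missing either comparison (insufficient replicates) are excluded
#' and listed in the `excluded` attribute.
#'
#' @param bridged A `bridged_abundance`.
#' @param condition Condition to analyze.
#' @param alpha Significance level on the BH-adjusted p-values
#'   (default 0.05, inclusive).
#' @param fc_threshold_log2 Minimum |log2FC| at either stage (default 1, a
#'   two-fold change).
#' @param welch Passed to [stage_ratio()].
#' @return `data.frame` with one row per tested protein: fold changes,
#'   adjusted p-values per comparison, the two rule components
#'   (`passed_significance_both`, `passed_magnitude_either`) and `is_mr`.
#' @export
call_mr <- function(bridged, condition, alpha = 0.05,
                    fc_threshold_log2 = 1, welch = FALSE) {
  em <- stage_ratio(bridged, condition, "EM_vs_M", welch = welch)
  lm <- stage_ratio(bridged, condition, "LM_vs_M", welch = welch)
  em$adj_p <- bh_adjust(em$p_value)
  lm$adj_p <- bh_adjust(lm$p_value)
  stopifnot(identical(em$protein_id, lm$protein_id))
  complete <- !is.na(em$p_value) & !is.na(lm$p_value)
  out <- data.frame(
    protein_id = em$protein_id,
    condition = condition,
    log2fc_EM = em$log2fc, adj_p_EM = em$adj_p, p_EM = em$p_value,
    log2fc_LM = lm$log2fc, adj_p_LM = lm$adj_p, p_LM = lm$p_value,
    stringsAsFactors = FALSE
  )
  out <- out[complete, , drop = FALSE]
  out$passed_significance_both <- out$adj_p_EM <= alpha & out$adj_p_LM <= alpha
  out$passed_magnitude_either <- abs(out$log2fc_EM) >= fc_threshold_log2 |
    abs(out$log2fc_LM) >= fc_threshold_log2
  out$is_mr <- out$passed_significance_both & out$passed_magnitude_either
  rownames(out) <- NULL
  attr(out, "excluded") <- em$protein_id[!complete]
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold_log2") <- fc_threshold_log2
  out
}

#' Marker trajectory report
#'
#' Summarizes a set of marker proteins the way trajectory panels are drawn:
#' the standardized (median 0, SD 1, over all quantified proteins of the
#' condition) log2 mean myoblast intensity, the standardized log2 fold
#' changes at EM and LM, and the BH-adjusted p-values of both comparisons.
#' Markers absent from the data are listed under `not_quantified` rather
#' than raising an error.
#'
#' @param bridged A `bridged_abundance`.
#' @param markers Character vector of marker protein ids.
#' @param condition Condition to report (default `"untreated"`).
#' @param alpha Significance level for the per-stage flags (default 0.05).
#' @return `data.frame` with one row per quantified marker (`m_std`,
#'   `fc_EM_std`, `fc_LM_std`, `adj_p_EM`, `adj_p_LM`, `sig_EM`, `sig_LM`);
#'   attribute `not_quantified` lists absent markers.
#' @export
marker_report <- function(bridged, markers, condition = "untreated",
                          alpha = 0.05) {
  stopifnot(inherits(bridged, "bridged_abundance"))
  present <- intersect(markers, rownames(bridged$log2))
  absent <- setdiff(markers, present)
  calls <- call_mr(bridged, condition, alpha = alpha)
  m_mean <- rowMeans(bridged$log2[, sample_keys(bridged, condition, "M"),
                                  drop = FALSE], na.rm = TRUE)
  std <- function(v) (v - stats::median(v, na.rm = TRUE)) / pop_sd(v)
  m_std <- std(m_mean)
  fc_em_std <- std(calls$log2fc_EM)
  fc_lm_std <- std(calls$log2fc_LM)
  names(fc_em_std) <- names(fc_lm_std) <- calls$protein_id
  present <- intersect(present, calls$protein_id)
  out <- data.frame(
    protein_id = present,
    condition = condition,
    m_std = m_std[present],
    fc_EM_std = fc_em_std[present],
    fc_LM_std = fc_lm_std[present],
    adj_p_EM = calls$adj_p_EM[match(present, calls$protein_id)],
    adj_p_LM = calls$adj_p_LM[match(present, calls$protein_id)],
    stringsAsFactors = FALSE
  )
  out$sig_EM <- out$adj_p_EM <= alpha
  out$sig_LM <- out$adj_p_LM <= alpha
  rownames(out) <- NULL
  attr(out, "not_quantified") <- absent
  out
}

# population standard deviation (divisor n)
pop_sd <- function(v) {
  v <- v[is.finite(v)]
  sqrt(mean((v - mean(v))^2))
}
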