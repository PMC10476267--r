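# Two-layer normalization of a bridged multi-multiplex experiment:
# (1) per-channel sample-loading scaling to the grand mean of all channel
#     totals across multiplexes;
# (2) per-protein bridge correction aligning every multiplex's bridge log2
#     value to the reference multiplex.

#' Channel (sample loading) normalization across multiplexes
#'
#' Restricts the matrices to the proteins quantified in all multiplexes, then
#' scales every channel so all channel totals equal the grand mean of the
#' original channel totals. This makes channel intensities, including the
#' bridge channels, comparable within and across multiplexes.
#'
#' @param matrices List of [reporter_matrix()] objects (one per multiplex).
#' @return The list of normalized `reporter_matrix` objects, each carrying a
#'   `channel_factors` element (the applied multiplicative factors) and the
#'   whole list carrying attribute `dropped` (proteins absent from the
#'   intersection).
#' @export
channel_normalize <- function(matrices) {
  stopifnot(length(matrices) >= 1, all(vapply(matrices, inherits,
                                              logical(1), "reporter_matrix")))
  all_ids <- lapply(matrices, function(m) rownames(m$intensities))
  common <- Reduce(intersect, all_ids)
  if (!length(common)) stop("no proteins shared by all multiplexes")
  dropped <- setdiff(unique(unlist(all_ids)), common)
  matrices <- lapply(matrices, function(m) {
    m$intensities <- m$intensities[common, , drop = FALSE]
    m
  })
  totals <- unlist(lapply(matrices, function(m) {
    tot <- colSums(m$intensities)
    names(tot) <- paste(m$multiplex_id, names(tot), sep = ".")
    tot
  }))
  if (any(totals == 0)) {
    stop("channel total is zero for: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  grand <- mean(totals)
  out <- lapply(matrices, function(m) {
    f <- grand / colSums(m$intensities)
    m$intensities <- sweep(m$intensities, 2, f, "*")
    m$channel_factors <- f
    m
  })
  names(out) <- vapply(out, function(m) m$multiplex_id, character(1))
  attr(out, "dropped") <- dropped
  out
}

#' Bridge correction across multiplexes
#'
#' The bridge channel of every multiplex carries the same pooled sample, so
#' any per-protein discrepancy between bridges measures multiplex-level
#' batch effects. For each protein `p` and non-reference multiplex `m`, the
#' offset `log2(bridge(p, reference)) - log2(bridge(p, m))` is added to every
#' log2 channel value of `p` in `m`; the reference multiplex is untouched.
#' Proteins with a zero or missing bridge in any multiplex are dropped and
#' listed.
#'
#' Zero sample intensities become `NA` (absence of signal is non-
#' quantification, and log2 of zero is undefined).
#'
#' @param matrices List of (typically channel-normalized) `reporter_matrix`
#'   objects.
#' @param design The multiplex design.
#' @param reference Multiplex id to align to (default `"M"`, the myoblast /
#'   day 0 multiplex).
#' @return An object of class `bridged_abundance`: list with `log2`
#'   (proteins x 27 sample-channel log2 matrix, columns keyed
#'   `multiplex.condition.replicate`), `sample_design` (design rows for those
#'   columns, plus a `key` column), `bridge_log2` (corrected bridge values,
#'   identical across multiplexes by construction), `reference`, `dropped`
#'   and `channel_factors`.
#' @export
bridge_correct <- function(matrices, design, reference = "M") {
  stopifnot(all(vapply(matrices, inherits, logical(1), "reporter_matrix")))
  validate_design(design)
  mx_ids <- vapply(matrices, function(m) m$multiplex_id, character(1))
  names(matrices) <- mx_ids
  if (!reference %in% mx_ids) {
    stop("configuration error: reference multiplex '", reference,
         "' not among matrices (", paste(mx_ids, collapse = ", "), ")")
  }
  if (!reference %in% design$multiplex) {
    stop("configuration error: reference multiplex '", reference,
         "' not in design")
  }
  common <- Reduce(intersect, lapply(matrices, function(m) rownames(m$intensities)))
  if (!length(common)) stop("no proteins shared by all multiplexes")

  # raw bridge log2 values (zero intensity -> NA)
  bridge_raw <- do.call(cbind, lapply(mx_ids, function(mx) {
    ch <- bridge_channel_of(design, mx)
    v <- matrices[[mx]]$intensities[common, ch]
    ifelse(v > 0, log2(v), NA_real_)
  }))
  dimnames(bridge_raw) <- list(common, mx_ids)
  keep <- rowSums(is.na(bridge_raw)) == 0
  dropped <- common[!keep]
  common <- common[keep]
  if (!length(common)) stop("no proteins with a positive bridge in all multiplexes")
  bridge_raw <- bridge_raw[keep, , drop = FALSE]

  offsets <- bridge_raw[, reference] - bridge_raw  # proteins x multiplexes

  log2_cols <- list()
  sd_rows <- list()
  for (mx in mx_ids) {
    d <- multiplex_samples(design, mx)
    m <- matrices[[mx]]$intensities[common, d$channel, drop = FALSE]
    lg <- ifelse(m > 0, log2(m), NA_real_)
    lg <- lg + offsets[, mx]
    colnames(lg) <- paste(mx, d$condition, d$replicate, sep = ".")
    log2_cols[[mx]] <- lg
    d$key <- colnames(lg)
    sd_rows[[mx]] <- d
  }
  log2_mat <- do.call(cbind, log2_cols)
  sample_design <- do.call(rbind, sd_rows)
  rownames(sample_design) <- NULL
  bridge_corr <- bridge_raw + offsets

  channel_factors <- lapply(matrices, function(m) m$channel_factors)
  structure(
    list(log2 = log2_mat,
         sample_design = sample_design,
         bridge_log2 = bridge_corr,
         reference = reference,
         dropped = dropped,
         channel_factors = channel_factors),
    class = "bridged_abundance"
  )
}

#' @export
print.bridged_abundance <- function(x, ...) {
  cat("bridged_abundance: ", nrow(x$log2), " proteins x ",
      ncol(x$log2), " sample channels (reference multiplex '",
      x$reference, "'; ", length(x$dropped),
      " proteins dropped for missing bridge)\n", sep = "")
  invisible(x)
}

# column keys of the sample channels for a condition and/or timepoint
sample_keys <- function(bridged, condition = NULL, timepoint = NULL) {
  sd <- bridged$sample_design
  sel <- rep(TRUE, nrow(sd))
  if (!is.null(condition)) sel <- sel & sd$condition == condition
  if (!is.null(timepoint)) sel <- sel & sd$timepoint == timepoint
  sd$key[sel]
}

#' Normalize and bridge a set of reporter matrices in one call
#'
#' Convenience composition of [channel_normalize()] then [bridge_correct()].
#'
#' @inheritParams bridge_correct
#' @return A `bridged_abundance` object.
#' @export
normalize_experiment <- function(matrices, design, reference = "M") {
  bridge_correct(channel_normalize(matrices), design, reference)
}
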