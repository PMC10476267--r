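# Experimental layout: one TMT 10-plex multiplex per myogenic stage,
# 9 sample channels ({untreated, vehicle, tmx} x 3 replicates) + 1 bridge.

#' TMT 10-plex reporter channel labels
#'
#' @return Character vector of the ten reporter channel names, in mass order.
#' @export
tmt_channels <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C", "131")
}

#' Treatment conditions and myogenic stages
#'
#' `conditions()` returns the three sample conditions (the bridge is a pseudo
#' condition used only in design files); `stages()` returns the myogenic
#' stages in temporal order: M = myoblast (day 0), EM = early myotube (day 5),
#' LM = late myotube (day 9).
#'
#' @return Character vector.
#' @export
conditions <- function() c("untreated", "vehicle", "tmx")

#' @rdname conditions
#' @export
stages <- function() c("M", "EM", "LM")

#' Construct the canonical three-multiplex design
#'
#' Builds the standard layout: three multiplexes, one per myogenic stage,
#' each with nine sample channels (three conditions x three replicates) and
#' one bridge channel.
#'
#' @param multiplexes Character vector of three multiplex identifiers, one per
#'   stage in M, EM, LM order. Defaults to the stage names themselves.
#' @param bridge_channel Reporter channel carrying the bridge sample
#'   (default `"131"`).
#' @return A validated design `data.frame` with columns `multiplex`,
#'   `channel`, `condition`, `timepoint`, `replicate` (`NA` for the bridge).
#' @export
default_design <- function(multiplexes = stages(), bridge_channel = "131") {
  if (length(multiplexes) != 3L || anyDuplicated(multiplexes)) {
    stop("'multiplexes' must be three distinct identifiers, one per stage")
  }
  if (!bridge_channel %in% tmt_channels()) {
    stop("unknown bridge channel: ", bridge_channel)
  }
  sample_channels <- setdiff(tmt_channels(), bridge_channel)
  rows <- lapply(seq_along(multiplexes), function(i) {
    data.frame(
      multiplex = multiplexes[i],
      channel = c(sample_channels, bridge_channel),
      condition = c(rep(conditions(), each = 3L), "bridge"),
      timepoint = stages()[i],
      replicate = c(rep(1:3, times = 3L), NA_integer_),
      stringsAsFactors = FALSE
    )
  })
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  validate_design(design)
}

#' Validate a multiplex design
#'
#' Checks the invariants of the bridged layout: exactly one bridge channel per
#' multiplex, all sample channels of a multiplex at a single timepoint, each
#' (condition, timepoint, replicate) triple present exactly once, and exactly
#' three replicates per condition per timepoint.
#'
#' @param design A design `data.frame` as produced by [default_design()] or
#'   [read_design()].
#' @return The design, invisibly validated (returned unchanged).
#' @export
validate_design <- function(design) {
  required <- c("multiplex", "channel", "condition", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols)) {
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_cond <- setdiff(unique(design$condition), c(conditions(), "bridge"))
  if (length(bad_cond)) {
    stop("design has unknown conditions: ", paste(bad_cond, collapse = ", "))
  }
  bad_tp <- setdiff(unique(design$timepoint), stages())
  if (length(bad_tp)) {
    stop("design has unknown timepoints: ", paste(bad_tp, collapse = ", "))
  }
  for (m in unique(design$multiplex)) {
    d <- design[design$multiplex == m, ]
    n_bridge <- sum(d$condition == "bridge")
    if (n_bridge != 1L) {
      stop("multiplex '", m, "' must have exactly one bridge channel, found ",
           n_bridge)
    }
    tps <- unique(d$timepoint[d$condition != "bridge"])
    if (length(tps) != 1L) {
      stop("multiplex '", m, "' mixes sample timepoints: ",
           paste(tps, collapse = ", "))
    }
    if (anyDuplicated(d$channel)) {
      stop("multiplex '", m, "' has duplicate channels: ",
           paste(unique(d$channel[duplicated(d$channel)]), collapse = ", "))
    }
  }
  samp <- design[design$condition != "bridge", ]
  key <- paste(samp$condition, samp$timepoint, samp$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, timepoint, replicate) triple: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  tab <- table(samp$condition, samp$timepoint)
  for (co in rownames(tab)) {
    for (tp in colnames(tab)) {
      if (tab[co, tp] != 3L) {
        stop("condition '", co, "' at timepoint '", tp, "' has ",
             tab[co, tp], " replicates; expected 3")
      }
    }
  }
  design
}

#' Read or write a design file
#'
#' The design is a TSV with columns `multiplex`, `channel`, `condition`,
#' `timepoint`, `replicate` (empty for the bridge channel). Reading validates
#' the layout invariants and fails with the specific violation.
#'
#' @param path File path.
#' @param design Design `data.frame` (for writing).
#' @return `read_design()` returns a validated design `data.frame`;
#'   `write_design()` returns `path` invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  design <- utils::read.delim(path, colClasses = "character")
  design$replicate <- suppressWarnings(as.integer(design$replicate))
  validate_design(design)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# design rows for the sample channels of one multiplex
multiplex_samples <- function(design, multiplex) {
  d <- design[design$multiplex == multiplex & design$condition != "bridge", ]
  if (!nrow(d)) stop("multiplex '", multiplex, "' not in design")
  d
}

# bridge channel id of one multiplex
bridge_channel_of <- function(design, multiplex) {
  ch <- design$channel[design$multiplex == multiplex &
                         design$condition == "bridge"]
  if (length(ch) != 1L) stop("multiplex '", multiplex, "' not in design")
  ch
}

# timepoint covered by a multiplex's sample channels
multiplex_stage <- function(design, multiplex) {
  unique(design$timepoint[design$multiplex == multiplex &
                            design$condition != "bridge"])
}
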