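# Synthetic TMT data generator: plants known longitudinal programs and
# treatment effects in the three-multiplex, ten-channel bridged design, and
# keeps a ledger of everything planted for recovery benchmarking.

ARCHETYPES <- c("C1_decrease", "C2_dip_recover", "C3_peak_EM",
                "C4_gradual_up", "C5_early_jump", "flat")

# (M, EM, LM) log2 offsets per archetype. C5's +2 jump corresponds to a
# four-fold increase from myoblast to early myotube; the others encode the
# qualitative cluster trends (continuous decrease; dip then recovery; EM
# peak; gradual rise; early jump then plateau).
default_archetype_offsets <- function() {
  m <- rbind(
    C1_decrease    = c(0, -1.0, -2.0),
    C2_dip_recover = c(0, -1.0,  0.5),
    C3_peak_EM     = c(0,  1.0,  0.0),
    C4_gradual_up  = c(0,  0.7,  1.4),
    C5_early_jump  = c(0,  2.0,  2.0),
    flat           = c(0,  0.0,  0.0)
  )
  colnames(m) <- stages()
  m
}

# Per-archetype baseline log2 shifts. Abundance classes differ between
# functional groups (proliferation machinery is abundant in myoblasts,
# sarcomeric proteins accumulate only later), so the myoblast baseline
# carries archetype signal; within an archetype proteins scatter around it.
default_archetype_base_shift <- function() {
  c(C1_decrease = 1, C2_dip_recover = 0.5, C3_peak_EM = 0,
    C4_gradual_up = -0.5, C5_early_jump = -1, flat = 0)
}

#' Configure a synthetic bridged-TMT simulation
#'
#' Defines the generative model: each protein gets an archetype (one of five
#' longitudinal trajectory shapes, or flat), a baseline log2 intensity, and
#' optional vehicle-only and TMX-specific log2 effects per timepoint. A
#' reporter intensity is
#' `2^(base + archetype offset + condition effects + multiplex batch +
#' channel loading + N(0, noise_sd_log2))`; vehicle channels receive the
#' vehicle effect, TMX channels receive vehicle + TMX effects (TMX is
#' administered in vehicle). The bridge channel of every multiplex carries
#' the same pooled sample: the linear-scale mean of one designated replicate
#' per condition x timepoint, subject only to that multiplex's batch,
#' loading and measurement noise.
#'
#' Default fractions mirror a proteome of which roughly one protein in ten is
#' myogenically regulated, split across archetypes like the observed cluster
#' sizes; the remainder is flat.
#'
#' @param n_proteins Number of proteins (default 10000).
#' @param fractions Named fractions per archetype (names among
#'   `C1_decrease`, `C2_dip_recover`, `C3_peak_EM`, `C4_gradual_up`,
#'   `C5_early_jump`); must be nonnegative and sum to at most 1. The
#'   remainder of the proteome is flat.
#' @param noise_sd_log2 SD of the additive Gaussian measurement noise on the
#'   log2 scale (multiplicative on the linear scale), default 0.25.
#' @param base_log2_mean,base_log2_sd Mean and SD of per-protein baseline
#'   log2 intensity (defaults 10 and 1).
#' @param archetype_offsets 6 x 3 matrix of (M, EM, LM) log2 offsets, rows
#'   named by archetype.
#' @param archetype_base_shift Named numeric: baseline log2 shift added per
#'   archetype.
#' @param multiplex_batch_log2 Length-3 numeric, additive log2 batch factor
#'   of each multiplex (M, EM, LM order).
#' @param channel_loading_log2 3 x 10 matrix of per-channel log2 loading
#'   factors (rows = multiplexes, columns = channels), or a single length-10
#'   vector recycled to all multiplexes. Default all zero.
#' @param effect_grid Optional `data.frame` with columns `condition`
#'   (`"vehicle"` or `"tmx"`), `timepoint` (`"M"`, `"EM"`, `"LM"`),
#'   `effect_log2`, `fraction`: each row plants `effect_log2` on a random
#'   `fraction` of proteins at that condition/timepoint.
#' @param bridge_replicate Replicate index pooled into the bridge (default 1).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 10000,
                       fractions = c(C1_decrease = 0.031,
                                     C2_dip_recover = 0.035,
                                     C3_peak_EM = 0.018,
                                     C4_gradual_up = 0.017,
                                     C5_early_jump = 0.006),
                       noise_sd_log2 = 0.25,
                       base_log2_mean = 10,
                       base_log2_sd = 1,
                       archetype_offsets = default_archetype_offsets(),
                       archetype_base_shift = default_archetype_base_shift(),
                       multiplex_batch_log2 = c(0, 0, 0),
                       channel_loading_log2 = NULL,
                       effect_grid = NULL,
                       bridge_replicate = 1L,
                       seed = 1L) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1) {
    stop("configuration error in 'n_proteins': must be a positive integer")
  }
  n_proteins <- as.integer(n_proteins)
  # YAML-sourced configs arrive as lists
  if (is.list(fractions)) fractions <- unlist(fractions)
  if (is.list(multiplex_batch_log2)) {
    multiplex_batch_log2 <- unlist(multiplex_batch_log2)
  }
  if (is.list(effect_grid)) effect_grid <- as.data.frame(effect_grid)
  if (length(fractions)) {
    if (is.null(names(fractions)) ||
        !all(names(fractions) %in% setdiff(ARCHETYPES, "flat"))) {
      stop("configuration error in 'fractions': names must be archetypes ",
           paste(setdiff(ARCHETYPES, "flat"), collapse = ", "))
    }
    if (any(fractions < 0) || sum(fractions) > 1 + 1e-12) {
      stop("configuration error in 'fractions': must be nonnegative and sum to <= 1")
    }
  }
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 < 0) {
    stop("configuration error in 'noise_sd_log2': must be nonnegative")
  }
  if (length(multiplex_batch_log2) != 3L) {
    stop("configuration error in 'multiplex_batch_log2': need one value per multiplex")
  }
  if (is.null(channel_loading_log2)) {
    channel_loading_log2 <- matrix(0, nrow = 3, ncol = 10)
  } else if (is.vector(channel_loading_log2) &&
             length(channel_loading_log2) == 10L) {
    channel_loading_log2 <- matrix(rep(channel_loading_log2, each = 3),
                                   nrow = 3)
  }
  if (!is.matrix(channel_loading_log2) ||
      !all(dim(channel_loading_log2) == c(3, 10))) {
    stop("configuration error in 'channel_loading_log2': need a 3 x 10 matrix")
  }
  colnames(channel_loading_log2) <- tmt_channels()
  if (!all(rownames(archetype_offsets) == ARCHETYPES)) {
    stop("configuration error in 'archetype_offsets': rows must be ",
         paste(ARCHETYPES, collapse = ", "))
  }
  if (!is.null(effect_grid)) {
    need <- c("condition", "timepoint", "effect_log2", "fraction")
    if (!all(need %in% names(effect_grid))) {
      stop("configuration error in 'effect_grid': needs columns ",
           paste(need, collapse = ", "))
    }
    if (!all(effect_grid$condition %in% c("vehicle", "tmx"))) {
      stop("configuration error in 'effect_grid': condition must be vehicle or tmx")
    }
    if (!all(effect_grid$timepoint %in% stages())) {
      stop("configuration error in 'effect_grid': timepoint must be M, EM or LM")
    }
    if (any(effect_grid$fraction < 0 | effect_grid$fraction > 1)) {
      stop("configuration error in 'effect_grid': fraction must be in [0, 1]")
    }
  }
  structure(
    list(n_proteins = n_proteins,
         fractions = fractions,
         noise_sd_log2 = noise_sd_log2,
         base_log2_mean = base_log2_mean,
         base_log2_sd = base_log2_sd,
         archetype_offsets = archetype_offsets,
         archetype_base_shift = archetype_base_shift,
         multiplex_batch_log2 = as.numeric(multiplex_batch_log2),
         channel_loading_log2 = channel_loading_log2,
         effect_grid = effect_grid,
         bridge_replicate = as.integer(bridge_replicate),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate the ground-truth protein table
#'
#' Draws each protein's archetype, baseline log2 intensity and planted
#' vehicle/TMX effects. Archetype counts match the configured fractions to
#' rounding; all randomness comes from the single seeded stream, so a fixed
#' configuration is byte-identical across runs.
#'
#' The returned table is the planted-effect ledger: columns `offset_M/EM/LM`
#' (archetype program), `veh_M/EM/LM` and `tmx_M/EM/LM` (treatment effects),
#' plus `planted_mr` — `TRUE` where the archetype program is nonzero at both
#' later stages and reaches |log2FC| >= 1 at either, i.e. the proteins the
#' longitudinal regulation rule targets.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `ground_truth`, one row per protein.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  counts <- if (length(config$fractions)) {
    round(config$fractions * n)
  } else {
    integer(0)
  }
  counts <- counts[counts > 0]
  if (sum(counts) > n) counts[length(counts)] <- counts[length(counts)] - (sum(counts) - n)
  archetype <- rep("flat", n)
  if (length(counts)) {
    archetype[seq_len(sum(counts))] <- rep(names(counts), counts)
  }
  # shuffle so archetypes are not positionally confounded with planted effects
  archetype <- sample(archetype)
  ids <- sprintf("P%05d", seq_len(n))
  base <- config$base_log2_mean +
    config$archetype_base_shift[archetype] +
    stats::rnorm(n, 0, config$base_log2_sd)
  off <- config$archetype_offsets[archetype, , drop = FALSE]
  truth <- data.frame(
    protein_id = ids,
    archetype = archetype,
    base_log2 = as.numeric(base),
    offset_M = off[, "M"], offset_EM = off[, "EM"], offset_LM = off[, "LM"],
    veh_M = 0, veh_EM = 0, veh_LM = 0,
    tmx_M = 0, tmx_EM = 0, tmx_LM = 0,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  if (!is.null(config$effect_grid)) {
    for (i in seq_len(nrow(config$effect_grid))) {
      g <- config$effect_grid[i, ]
      k <- round(g$fraction * n)
      if (k < 1) next
      chosen <- sample.int(n, k)
      col <- paste(ifelse(g$condition == "vehicle", "veh", "tmx"),
                   g$timepoint, sep = "_")
      truth[[col]][chosen] <- truth[[col]][chosen] + g$effect_log2
    }
  }
  truth$planted_mr <- truth$offset_EM != 0 & truth$offset_LM != 0 &
    (abs(truth$offset_EM) >= 1 | abs(truth$offset_LM) >= 1)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

# noiseless log2 program of every protein for one (condition, timepoint);
# vehicle channels carry the vehicle effect, TMX channels vehicle + TMX
program_log2 <- function(truth, condition, timepoint) {
  x <- truth$base_log2 + truth[[paste0("offset_", timepoint)]]
  if (condition %in% c("vehicle", "tmx")) {
    x <- x + truth[[paste0("veh_", timepoint)]]
  }
  if (condition == "tmx") {
    x <- x + truth[[paste0("tmx_", timepoint)]]
  }
  x
}

#' Simulate the three bridged multiplex reporter matrices
#'
#' Realizes the generative model over the canonical design: for each
#' multiplex, nine sample channels at that stage and one bridge channel
#' whose underlying sample is identical across multiplexes (the linear-scale
#' mean of the designated replicate of each condition x timepoint). Batch,
#' loading and measurement noise are applied per channel measurement.
#'
#' @param truth A [generate_ground_truth()] table.
#' @param config The same [sim_config()].
#' @return A list with `matrices` (list of three [reporter_matrix()] objects
#'   named by multiplex), `design` (the canonical design) and `truth`.
#' @export
simulate_multiplexes <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(truth)) stop("ground truth is empty")
  set.seed(config$seed + 1L)
  design <- default_design()
  n <- nrow(truth)
  # the pooled bridge sample: mean linear abundance over the 9 pooled aliquots
  pool <- matrix(0, n, 9)
  j <- 0
  for (co in conditions()) {
    for (tp in stages()) {
      j <- j + 1
      pool[, j] <- 2^program_log2(truth, co, tp)
    }
  }
  bridge_linear <- rowMeans(pool)
  mats <- vector("list", 3L)
  names(mats) <- stages()
  for (m in seq_along(stages())) {
    mx <- stages()[m]
    d <- design[design$multiplex == mx, ]
    intens <- matrix(NA_real_, n, nrow(d),
                     dimnames = list(truth$protein_id, d$channel))
    for (r in seq_len(nrow(d))) {
      loading <- config$channel_loading_log2[m, d$channel[r]]
      noise <- if (config$noise_sd_log2 > 0) {
        stats::rnorm(n, 0, config$noise_sd_log2)
      } else 0
      if (d$condition[r] == "bridge") {
        intens[, r] <- bridge_linear *
          2^(config$multiplex_batch_log2[m] + loading + noise)
      } else {
        base_log2 <- program_log2(truth, d$condition[r], d$timepoint[r])
        intens[, r] <- 2^(base_log2 + config$multiplex_batch_log2[m] +
                            loading + noise)
      }
    }
    mats[[mx]] <- reporter_matrix(mx, intens)
  }
  list(matrices = mats, design = design, truth = truth)
}

#' Write a simulated data set to disk
#'
#' Emits one reporter TSV per multiplex, the design TSV and the ground-truth
#' ledger TSV into `dir`.
#'
#' @param sim Result of [simulate_multiplexes()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mx in names(sim$matrices)) {
    write_reporter_matrix(sim$matrices[[mx]],
                          file.path(dir, paste0("reporter_", mx, ".tsv")))
  }
  write_design(sim$design, file.path(dir, "design.tsv"))
  write_result_table(sim$truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
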