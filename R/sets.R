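# Set logic over MR and DE calls: three-way Venn partitions, exclusion of
# vehicle-only regulation, DE/MR intersections, and the "highly regulated"
# multi-stage call.

#' Three-way Venn partition of MR sets
#'
#' Partitions the union of the three MR protein sets (untreated, vehicle,
#' TMX) into the seven exclusive Venn regions.
#'
#' @param untreated,vehicle,tmx Character vectors of MR protein ids.
#' @return Object of class `mr_venn`: list with `regions` (seven sorted
#'   member vectors: `untreated_only`, `vehicle_only`, `tmx_only`,
#'   `untreated_vehicle`, `untreated_tmx`, `vehicle_tmx`, `all_three`) and
#'   `sizes` (named integer vector).
#' @export
mr_venn <- function(untreated, vehicle, tmx) {
  u <- unique(as.character(untreated))
  v <- unique(as.character(vehicle))
  t <- unique(as.character(tmx))
  all_ids <- union(union(u, v), t)
  in_u <- all_ids %in% u
  in_v <- all_ids %in% v
  in_t <- all_ids %in% t
  regions <- list(
    untreated_only = sort(all_ids[in_u & !in_v & !in_t]),
    vehicle_only = sort(all_ids[!in_u & in_v & !in_t]),
    tmx_only = sort(all_ids[!in_u & !in_v & in_t]),
    untreated_vehicle = sort(all_ids[in_u & in_v & !in_t]),
    untreated_tmx = sort(all_ids[in_u & !in_v & in_t]),
    vehicle_tmx = sort(all_ids[!in_u & in_v & in_t]),
    all_three = sort(all_ids[in_u & in_v & in_t])
  )
  structure(list(regions = regions,
                 sizes = vapply(regions, length, integer(1))),
            class = "mr_venn")
}

#' @export
print.mr_venn <- function(x, ...) {
  cat("mr_venn partition (", sum(x$sizes), " proteins in union):\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' Exclude vehicle-only regulated proteins from the TMX analysis set
#'
#' Proteins regulated only when vehicle is present (the `vehicle_tmx` and
#' `vehicle_only`-adjacent regions of the TMX set) reflect a vehicle/TMX
#' interaction, not a TMX effect. The retained clustering input is the union
#' of the `all_three`, `tmx_only` and `untreated_tmx` regions — the TMX MR
#' set minus regions that require vehicle without untreated.
#'
#' @param venn An [mr_venn()] partition.
#' @return Sorted character vector of retained protein ids.
#' @export
exclude_vehicle_only <- function(venn) {
  stopifnot(inherits(venn, "mr_venn"))
  sort(c(venn$regions$all_three, venn$regions$tmx_only,
         venn$regions$untreated_tmx))
}

#' Intersect differential expression with the myogenic program
#'
#' Splits the DE protein set by its relation to the longitudinal programs:
#' DE proteins inside the untreated myogenic program, DE proteins added to
#' the program by TMX (MR in TMX but not untreated), and DE proteins outside
#' both programs.
#'
#' @param de Character vector of DE protein ids (union over stages).
#' @param mr_untreated,mr_tmx MR protein id vectors.
#' @return List with sorted members `de_and_mr_untreated`,
#'   `added_to_program`, `outside_program` and their `sizes`.
#' @export
de_mr_intersections <- function(de, mr_untreated, mr_tmx) {
  de <- unique(as.character(de))
  res <- list(
    de_and_mr_untreated = sort(intersect(de, mr_untreated)),
    added_to_program = sort(setdiff(intersect(de, mr_tmx), mr_untreated)),
    outside_program = sort(setdiff(de, union(mr_untreated, mr_tmx)))
  )
  res$sizes <- vapply(res, length, integer(1))
  res
}

#' Highly regulated proteins: DE at multiple stages
#'
#' @param de_calls `data.frame` of stage DE calls (rows from [stage_de()]
#'   over the stages, i.e. columns `protein_id`, `stage`, `is_de`).
#' @param min_stages Minimum number of stages with `is_de` (default 2).
#' @return `data.frame` with `protein_id`, per-stage logical flags `de_M`,
#'   `de_EM`, `de_LM` and `n_stages`, sorted by decreasing `n_stages` then
#'   protein id; only proteins meeting `min_stages` are kept.
#' @export
highly_regulated <- function(de_calls, min_stages = 2) {
  stopifnot(all(c("protein_id", "stage", "is_de") %in% names(de_calls)))
  de <- de_calls[de_calls$is_de, c("protein_id", "stage")]
  ids <- sort(unique(de$protein_id))
  flags <- vapply(stages(), function(tp) {
    ids %in% de$protein_id[de$stage == tp]
  }, logical(length(ids)))
  if (length(ids) == 1L) flags <- matrix(flags, nrow = 1)
  out <- data.frame(protein_id = ids,
                    de_M = flags[, 1], de_EM = flags[, 2], de_LM = flags[, 3],
                    stringsAsFactors = FALSE)
  out$n_stages <- rowSums(out[, c("de_M", "de_EM", "de_LM")])
  out <- out[out$n_stages >= min_stages, , drop = FALSE]
  out <- out[order(-out$n_stages, out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Overlap with an external reference protein list
#'
#' Compares an MR set against a caller-supplied reference list (for example
#' homolog-mapped regulated proteins from an independent study) and reports
#' the intersection size and its percentage of the reference, rounded to the
#' nearest integer percent.
#'
#' @param mr_set Character vector of protein ids.
#' @param reference Nonempty character vector of reference ids (homolog
#'   mapping is the caller's responsibility).
#' @return List with `n_overlap`, `n_reference`, `percent`.
#' @export
external_overlap <- function(mr_set, reference) {
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("validation error: empty reference list")
  n <- length(intersect(unique(as.character(mr_set)), reference))
  list(n_overlap = n,
       n_reference = length(reference),
       percent = round(100 * n / length(reference)))
}
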