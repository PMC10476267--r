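# Trajectory representation and k-means clustering of regulated proteins,
# plus cross-condition cluster matching by minimum-cost label assignment.

#' Build standardized trajectory vectors
#'
#' Each protein's trajectory is the triple (log2 mean myoblast abundance,
#' log2FC EM vs M, log2FC LM vs M) for one condition, after column-wise
#' standardization over the selected set: subtract the column median, divide
#' by the column (population) standard deviation, so every column has median
#' 0 and SD 1.
#'
#' @param bridged A `bridged_abundance`.
#' @param proteins Protein ids to include (typically an MR set).
#' @param condition Condition whose channels are used.
#' @return Numeric matrix (proteins x 3, columns `M_abund`, `log2fc_EM`,
#'   `log2fc_LM`) of standardized components, with the raw components in
#'   attribute `raw`.
#' @export
build_trajectories <- function(bridged, proteins, condition = "untreated") {
  stopifnot(inherits(bridged, "bridged_abundance"))
  if (!length(proteins)) stop("empty protein set")
  missing <- setdiff(proteins, rownames(bridged$log2))
  if (length(missing)) {
    stop("proteins not in data: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  lg <- bridged$log2[proteins, , drop = FALSE]
  m <- rowMeans(lg[, sample_keys(bridged, condition, "M"), drop = FALSE],
                na.rm = TRUE)
  em <- rowMeans(lg[, sample_keys(bridged, condition, "EM"), drop = FALSE],
                 na.rm = TRUE)
  lm <- rowMeans(lg[, sample_keys(bridged, condition, "LM"), drop = FALSE],
                 na.rm = TRUE)
  raw <- cbind(M_abund = m, log2fc_EM = em - m, log2fc_LM = lm - m)
  rownames(raw) <- proteins
  std <- raw
  for (j in seq_len(ncol(std))) {
    s <- pop_sd(std[, j])
    if (!is.finite(s) || s == 0) {
      stop("standardization error: column '", colnames(std)[j],
           "' has zero standard deviation")
    }
    std[, j] <- (std[, j] - stats::median(std[, j])) / s
  }
  attr(std, "raw") <- raw
  std
}

# k-means++ initial centers: first uniform, then proportional to squared
# distance to the nearest chosen center; points at distance 0 (duplicates)
# have probability 0, so centers are always distinct.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 <= 0)) stop("clustering error: fewer than k distinct points")
    i <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' k-means clustering of trajectory vectors
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_restarts` restarts
#' by within-cluster sum of squares. Deterministic for a fixed seed.
#'
#' @param x Numeric matrix of trajectory vectors (rows named by protein).
#' @param k Number of clusters (default 5).
#' @param seed RNG seed (default 17).
#' @param n_restarts Restarts (default 50).
#' @param max_iter Lloyd iterations per restart (default 100).
#' @return An object of class `cluster_model`: `k`, `centers`,
#'   `assignments` (named integer vector), `sizes`, `inertia` (total
#'   within-cluster sum of squares), `seed`, `n_restarts`.
#' @export
kmeans_cluster <- function(x, k = 5, seed = 17, n_restarts = 50,
                           max_iter = 100) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x))) stop("'x' needs protein row names")
  if (nrow(unique(x)) < k) {
    stop("clustering error: fewer than k = ", k, " distinct points")
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_init(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = max_iter,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("clustering error: all k-means restarts failed")
  structure(
    list(k = k,
         centers = best$centers,
         assignments = stats::setNames(best$cluster, rownames(x)),
         sizes = as.integer(best$size),
         inertia = best$tot.withinss,
         seed = seed,
         n_restarts = n_restarts),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k = ", x$k, ", n = ", length(x$assignments),
      ", sizes = [", paste(x$sizes, collapse = ", "),
      "], inertia = ", format(x$inertia, digits = 6), "\n", sep = "")
  invisible(x)
}

# all permutations of a vector (used for exact assignment at small k)
permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(permutations(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

#' Match clusters across two models
#'
#' Finds the one-to-one cluster label mapping minimizing the total Euclidean
#' distance between matched centroids (exact minimum over all k!
#' permutations; guarded at k <= 8), then reports per matched pair the
#' protein overlap over the proteins shared by both models.
#'
#' @param model_a,model_b `cluster_model` objects with equal `k`.
#' @return List with `mapping` (integer vector: cluster i of `model_a`
#'   corresponds to `mapping[i]` of `model_b`), `total_distance`, and
#'   `overlap`, a `data.frame` with `cluster_a`, `cluster_b`, `n_shared`,
#'   `n_a_only`, `n_b_only` computed over the shared protein universe.
#' @export
match_clusters <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "cluster_model"),
            inherits(model_b, "cluster_model"))
  if (model_a$k != model_b$k) {
    stop("matching error: models have different k (", model_a$k,
         " vs ", model_b$k, ")")
  }
  k <- model_a$k
  if (k > 8) stop("matching error: exact assignment supported for k <= 8")
  shared <- intersect(names(model_a$assignments), names(model_b$assignments))
  if (!length(shared)) stop("matching error: models share no proteins")
  dmat <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      dmat[i, j] <- sqrt(sum((model_a$centers[i, ] - model_b$centers[j, ])^2))
    }
  }
  best_perm <- NULL
  best_cost <- Inf
  for (p in permutations(seq_len(k))) {
    cost <- sum(dmat[cbind(seq_len(k), p)])
    if (cost < best_cost) {
      best_cost <- cost
      best_perm <- p
    }
  }
  a <- model_a$assignments[shared]
  b <- model_b$assignments[shared]
  overlap <- do.call(rbind, lapply(seq_len(k), function(i) {
    in_a <- shared[a == i]
    in_b <- shared[b == best_perm[i]]
    data.frame(cluster_a = i, cluster_b = best_perm[i],
               n_shared = length(intersect(in_a, in_b)),
               n_a_only = length(setdiff(in_a, in_b)),
               n_b_only = length(setdiff(in_b, in_a)))
  }))
  list(mapping = best_perm, total_distance = best_cost, overlap = overlap)
}
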