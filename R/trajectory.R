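# Fold-change trajectories over the five lifetime stages, hierarchical
# clustering with correlation distance + complete linkage, and Pearson
# correlation networks.

#' Stage-wise fold-change trajectories
#'
#' For each feature, the ordered 5-vector of log2(mean DKO / mean control)
#' across lifetime stages I-V; the space in which trajectory clusters and
#' networks are computed.
#'
#' @param table A `feature_table`.
#' @param lifetimes Output of [annotate_lifetime()].
#' @param feature_subset Feature ids to profile (typically the globally
#'   significant set); nonempty.
#' @return Numeric matrix, features x 5 stages.
#' @export
build_trajectories <- function(table, lifetimes, feature_subset) {
  stopifnot(inherits(table, "feature_table"))
  if (length(feature_subset) == 0) stop("feature_subset must be nonempty")
  sub <- subset_features(table, features = feature_subset,
                         samples = lifetimes$sample_id)
  prof <- matrix(NA_real_, length(feature_subset), length(STAGE_LEVELS),
                 dimnames = list(feature_subset, STAGE_LEVELS))
  for (st in STAGE_LEVELS) {
    sel <- lifetimes[lifetimes$stage == st, , drop = FALSE]
    a_ids <- sel$sample_id[sel$group == "DKO"]
    b_ids <- sel$sample_id[sel$group == "control"]
    if (length(a_ids) == 0 || length(b_ids) == 0)
      stop("stage ", st, " has an empty group")
    prof[, st] <- log2_fold_change(sub, a_ids, b_ids)
  }
  prof
}

#' Correlation distance
#'
#' `1 - Pearson(x, y)`, in \[0, 2\]; invariant under positive affine
#' rescaling of either argument.
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Distance in \[0, 2\].
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation distance undefined for a zero-variance vector")
  1 - stats::cor(x, y)
}

# all-pairs correlation-distance matrix over profile rows
correlation_distance_matrix <- function(profiles) {
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile(s): ",
         paste(utils::head(rownames(profiles)[sds == 0], 5), collapse = ", "))
  1 - stats::cor(t(profiles))
}

#' Complete-linkage hierarchical clustering of trajectories
#'
#' Agglomerative clustering under correlation distance with complete
#' (maximum) linkage, cut to `k` clusters labelled A, B, C, ... in order of
#' first appearance along the input. Ties in the merge distance are broken
#' deterministically toward the pair with the smallest feature indices, so
#' the result is reproducible for any input order.
#'
#' @param profiles Numeric matrix of trajectories (rows = features), e.g.
#'   from [build_trajectories()].
#' @param k Number of clusters; default 4.
#' @return List with `labels` (named cluster letters), `merge` (hclust-style
#'   merge matrix), `height` (merge distances, nondecreasing for complete
#'   linkage) and `order_k` cluster sizes.
#' @export
hca_complete <- function(profiles, k = 4) {
  n <- nrow(profiles)
  if (is.null(n) || n < k) stop("need at least k profiles")
  d <- correlation_distance_matrix(profiles)
  diag(d) <- Inf

  # active cluster list; each holds its member indices and an hclust code
  # (negative singleton index or positive merge-step number)
  codes <- -seq_len(n)           # hclust merge codes of active clusters
  cd <- d                        # complete-linkage cluster distances
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- cd[idx, idx, drop = FALSE]
    best <- min(sub)
    # smallest-index tie-break: first (i, j) in row-major order of indices
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- idx[hit[1, 1]]; j <- idx[hit[1, 2]]
    height[step] <- best
    merge[step, ] <- sort(c(codes[i], codes[j]))
    codes[i] <- step
    active[j] <- FALSE
    # complete linkage: distance to the merged cluster is the max
    upd <- setdiff(which(active), c(i, j))
    cd[i, upd] <- pmax(cd[i, upd], cd[j, upd])
    cd[upd, i] <- cd[i, upd]
  }

  # cut at k clusters: replay the first n - k merges with union-find
  grp <- seq_len(n)
  step_rep <- integer(n - 1)  # representative point of each merge step
  for (step in seq_len(n - 1)) {
    pi <- if (merge[step, 1] < 0) -merge[step, 1] else step_rep[merge[step, 1]]
    pj <- if (merge[step, 2] < 0) -merge[step, 2] else step_rep[merge[step, 2]]
    step_rep[step] <- min(pi, pj)
    if (step <= n - k) grp[grp == grp[pj]] <- grp[pi]
  }
  labels_idx <- match(grp, unique(grp))
  # letters in order of first appearance along the input rows
  first_seen <- unique(labels_idx)
  relabel <- match(labels_idx, first_seen)
  labels <- stats::setNames(LETTERS[relabel], rownames(profiles))

  list(labels = labels, merge = merge, height = height,
       order_k = table(labels))
}

#' Pearson correlation network of trajectories
#'
#' Nodes are features; an edge joins every pair whose trajectory Pearson
#' correlation is at least `r_threshold`. No self edges.
#'
#' @param profiles Trajectory matrix (rows = features).
#' @param cluster Optional named cluster labels attached to nodes.
#' @param r_threshold Minimum Pearson r for an edge; default 0.5.
#' @return List with `nodes` (data frame: feature_id, cluster) and `edges`
#'   (data frame: from, to, r).
#' @export
correlation_network <- function(profiles, cluster = NULL, r_threshold = 0.5) {
  n <- nrow(profiles)
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  cmat <- stats::cor(t(profiles))
  from <- character(0); to <- character(0); rv <- numeric(0)
  if (n >= 2) {
    pairs <- which(upper.tri(cmat) & cmat >= r_threshold, arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    from <- ids[pairs[, 1]]; to <- ids[pairs[, 2]]
    rv <- cmat[pairs]
  }
  nodes <- data.frame(feature_id = ids,
                      cluster = if (is.null(cluster)) NA_character_
                                else unname(cluster[ids]))
  list(nodes = nodes,
       edges = data.frame(from = from, to = to, r = rv))
}
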