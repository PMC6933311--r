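#' Subset and close dietary fatty-acid profiles
#'
#' Keeps the fatty acids (FAs) on `dietary_list` whose study-wide mean
#' percentage meets `threshold`, then re-closes every profile to sum to
#' 100. Dropping trace and non-dietary FAs before compositional analysis
#' focuses the clustering on diet-driven variation.
#'
#' @param profiles `data.frame` with a `trip_id` column and one numeric
#'   column per FA (percent by mass)
#' @param threshold minimum study-wide mean percentage (default 0.5)
#' @param dietary_list FA column names considered dietary; default all FA
#'   columns
#' @return `data.frame` with `trip_id` and the surviving FA columns, rows
#'   re-closed to 100
#' @export
select_dietary_fas <- function(profiles, threshold = 0.5,
                               dietary_list = NULL) {
  fa_cols <- setdiff(names(profiles), "trip_id")
  if (is.null(dietary_list)) dietary_list <- fa_cols
  fa_cols <- intersect(fa_cols, dietary_list)
  mat <- as.matrix(profiles[, fa_cols, drop = FALSE])
  if (any(mat < 0)) stop("FA percentages must be non-negative", call. = FALSE)
  keep <- fa_cols[colMeans(mat) >= threshold]
  if (length(keep) < 2)
    stop("fewer than 2 FAs survive the ", threshold, "% mean threshold",
         call. = FALSE)
  mat <- mat[, keep, drop = FALSE]
  mat <- 100 * mat / rowSums(mat)
  cbind(profiles[, "trip_id", drop = FALSE], as.data.frame(mat))
}

#' Centred log ratio transform
#'
#' Maps closed compositions to unconstrained space:
#' `clr(x)_i = ln(x_i / g(x))` with `g` the geometric mean. Zeros are
#' first replaced multiplicatively by `zero_replacement` times the
#' smallest nonzero component of the row, and the row re-closed, so the
#' log is always defined. Rows of clr output sum to zero and the transform
#' is invariant to rescaling a composition.
#'
#' @param x numeric matrix or `data.frame` of closed compositions (rows),
#'   or a single composition vector
#' @param zero_replacement fraction of the row's smallest nonzero value
#'   used in place of zeros (default 0.65)
#' @return matrix of clr coordinates (same shape as the input rows)
#' @export
clr_transform <- function(x, zero_replacement = 0.65) {
  one_row <- is.null(dim(x))
  m <- if (one_row) matrix(as.numeric(x), nrow = 1,
                           dimnames = list(NULL, names(x)))
       else as.matrix(x)
  total <- rowSums(m)
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (any(z)) {
      repl <- zero_replacement * min(m[i, !z])
      m[i, z] <- repl
      m[i, ] <- m[i, ] * total[i] / sum(m[i, ])  # re-close
    }
  }
  out <- log(m) - rowMeans(log(m))
  if (one_row) out[1, ] else out
}

#' Ward hierarchical clustering on squared Euclidean distances
#'
#' Agglomerative clustering with the Lance–Williams Ward update applied to
#' squared Euclidean distances (the `ward.D`-on-squared-distances dialect:
#' merge heights are in squared-distance units and each merge minimizes
#' the increase in total within-cluster sum of squares). Tie-breaking
#' follows the deterministic order of the underlying agglomeration.
#'
#' @param vectors numeric matrix (rows = profiles, e.g. clr coordinates)
#' @param dialect `"squared"` (default, heights in squared-distance units)
#'   or `"ward.D2"` (heights on the distance scale)
#' @return an [stats::hclust] tree
#' @export
ward_cluster <- function(vectors, dialect = c("squared", "ward.D2")) {
  dialect <- match.arg(dialect)
  m <- as.matrix(vectors)
  if (nrow(m) < 2) stop("need >= 2 vectors", call. = FALSE)
  if (dialect == "squared")
    stats::hclust(stats::dist(m)^2, method = "ward.D")
  else
    stats::hclust(stats::dist(m), method = "ward.D2")
}

#' Adaptive (dynamic) cut of a Ward tree
#'
#' Instead of one fixed cut height, branches are examined for the
#' "join-jump" signature of a cluster core: a subtree whose internal
#' merge heights are all small compared with the height at which the
#' subtree joins the rest of the tree. A node is marked as a cluster
#' core when it holds at least `min_cluster_size` members and the height
#' of its parent merge exceeds `gap_ratio` times its own merge height.
#' The minimal marked nodes (those without a marked descendant) become
#' clusters, so nested separation is resolved at its finest stable
#' granularity; remaining points adopt, walking up the tree, the label
#' of the first marked cluster their branch merges with — fully
#' deterministic, no fixed cut height. A marked node that sits inside a
#' larger cluster does not fragment it: the surrounding points re-adopt
#' its label through the same tree walk. When no node is marked (a
#' homogeneous cloud, or all profiles identical so every height is below
#' `h_tol`) everything is one cluster.
#'
#' The threshold was calibrated by simulation: over Ward trees of
#' homogeneous Gaussian clouds the largest parent/child height ratio at
#' eligible sizes stays near 3, while even weakly separated clusters
#' jump above 5, motivating the default `gap_ratio = 4`.
#'
#' @param tree an [stats::hclust] tree from [ward_cluster()]
#' @param min_cluster_size smallest admissible cluster core (default 20)
#' @param gap_ratio threshold on the parent/own merge-height ratio
#'   (default 4)
#' @param h_tol heights at or below this are treated as zero (identical
#'   profiles; default 1e-8)
#' @return integer cluster labels in `1..k`, numbered by decreasing
#'   cluster size (ties by first appearance)
#' @export
dynamic_tree_cut <- function(tree, min_cluster_size = 20, gap_ratio = 4,
                             h_tol = 1e-8) {
  n <- length(tree$order)
  if (n < 2) return(rep(1L, n))
  merge <- tree$merge; height <- tree$height
  m <- n - 1L
  size <- integer(m)
  for (i in seq_len(m)) {
    s <- function(c) if (c < 0) 1L else size[c]
    size[i] <- s(merge[i, 1]) + s(merge[i, 2])
  }
  parent <- rep(NA_integer_, m)
  for (i in seq_len(m)) for (c in merge[i, ]) if (c > 0) parent[c] <- i
  marked <- !is.na(parent) & size >= min_cluster_size &
    height[parent] > h_tol &
    height[parent] > gap_ratio * pmax(height, h_tol)
  # keep only minimal marked nodes (no marked descendant)
  has_marked_desc <- logical(m)
  for (i in seq_len(m)) {
    for (c in merge[i, ]) if (c > 0 && (marked[c] || has_marked_desc[c]))
      has_marked_desc[i] <- TRUE
  }
  cores <- which(marked & !has_marked_desc)
  labels <- rep(NA_integer_, n)
  if (!length(cores)) return(rep(1L, n))
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    c(leaves_of(merge[node, 1]), leaves_of(merge[node, 2]))
  }
  for (j in seq_along(cores)) labels[leaves_of(cores[j])] <- j
  # unlabelled branches adopt the first labelled cluster they merge with,
  # processed bottom-up so adoption follows the tree order
  node_lab <- rep(NA_integer_, m)
  for (j in seq_along(cores)) node_lab[cores[j]] <- j
  lab_of <- function(c) {
    if (c < 0) labels[-c] else node_lab[c]
  }
  for (i in seq_len(m)) {
    if (!is.na(node_lab[i])) next
    l1 <- lab_of(merge[i, 1]); l2 <- lab_of(merge[i, 2])
    take <- if (!is.na(l1)) l1 else l2
    if (!is.na(take)) {
      node_lab[i] <- take
      for (c in merge[i, ]) {
        if (c < 0 && is.na(labels[-c])) labels[-c] <- take
        if (c > 0 && is.na(node_lab[c])) {
          idx <- leaves_of(c)
          labels[idx[is.na(labels[idx])]] <- take
          node_lab[c] <- take
        }
      }
    }
  }
  labels[is.na(labels)] <- node_lab[m]
  # renumber by decreasing size, ties by first appearance
  sizes <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  as.integer(map[as.character(labels)])
}

#' Fisher linear discriminant loadings for cluster-separating FAs
#'
#' Multiclass Fisher LDA on clr coordinates: eigenvectors of
#' `Sw^- Sb` (within- and between-class scatter), using a pseudo-inverse
#' so the rank deficiency that the clr sum-to-zero constraint induces is
#' handled exactly; a degenerate within-class scatter (e.g. identical
#' members within classes) is ridge-regularized with a warning. Variables
#' are ranked by the absolute standardized loading (raw loading times
#' pooled within-class SD) on the leading discriminant.
#'
#' @param vectors numeric matrix (rows = profiles, clr coordinates)
#' @param labels cluster labels, >= 2 clusters with >= 2 members each
#' @return list of class `fa_lda` with `loadings` (variables x
#'   discriminants), `standardized` (same shape), `ranking` (variable
#'   names, most discriminating first), `eigenvalues`
#' @export
discriminating_fas <- function(vectors, labels) {
  v <- as.matrix(vectors)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 clusters", call. = FALSE)
  if (any(table(labels) < 2)) stop("each cluster needs >= 2 members",
                                   call. = FALSE)
  p <- ncol(v); n <- nrow(v)
  grand <- colMeans(v)
  sw <- matrix(0, p, p); sb <- matrix(0, p, p)
  for (l in levels(labels)) {
    vi <- v[labels == l, , drop = FALSE]
    ci <- colMeans(vi)
    sw <- sw + crossprod(sweep(vi, 2, ci))
    sb <- sb + nrow(vi) * tcrossprod(ci - grand)
  }
  ev <- eigen(sw, symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  if (max(ev$values) <= 0 || all(ev$values < .Machine$double.eps)) {
    warning("singular within-class scatter: ridge-regularizing")
    sw <- sw + diag(1e-6, p)
    ev <- eigen(sw, symmetric = TRUE)
    tol <- max(ev$values) * 1e-10
  }
  pos <- ev$values > tol
  sw_pinv <- ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  eg <- eigen(sw_pinv %*% sb)
  nd <- min(nlevels(labels) - 1, p)
  ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(nd)]
  load <- Re(eg$vectors[, ord, drop = FALSE])
  rownames(load) <- colnames(v)
  colnames(load) <- paste0("LD", seq_len(nd))
  within_sd <- sqrt(diag(sw) / (n - nlevels(labels)))
  std <- load * within_sd
  ranking <- rownames(load)[order(abs(std[, 1]), decreasing = TRUE)]
  structure(list(loadings = load, standardized = std, ranking = ranking,
                 eigenvalues = Re(eg$values[ord])),
            class = "fa_lda")
}

#' Full fatty-acid diet-clustering pipeline
#'
#' Dietary subsetting and closure, clr transform, Ward clustering on
#' squared Euclidean distances, adaptive tree cut, and LDA ranking of the
#' FAs that separate the clusters.
#'
#' @inheritParams select_dietary_fas
#' @inheritParams dynamic_tree_cut
#' @param zero_replacement see [clr_transform()]
#' @return list of class `fa_cluster_model`: `labels` (per trip),
#'   `tree`, `lda`, `clr` matrix, `profiles` (closed subset),
#'   `n_clusters`
#' @export
fa_cluster_pipeline <- function(profiles, threshold = 0.5,
                                dietary_list = NULL,
                                zero_replacement = 0.65,
                                min_cluster_size = 20, gap_ratio = 4) {
  sel <- select_dietary_fas(profiles, threshold, dietary_list)
  clr <- clr_transform(sel[, setdiff(names(sel), "trip_id")],
                       zero_replacement)
  tree <- ward_cluster(clr)
  labels <- dynamic_tree_cut(tree, min_cluster_size, gap_ratio)
  lda <- if (length(unique(labels)) >= 2 && all(table(labels) >= 2))
    discriminating_fas(clr, labels) else NULL
  structure(list(labels = stats::setNames(labels, sel$trip_id),
                 tree = tree, lda = lda, clr = clr, profiles = sel,
                 n_clusters = length(unique(labels))),
            class = "fa_cluster_model")
}
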