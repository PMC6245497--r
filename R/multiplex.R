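#' Skeleton multiplex network
#'
#' Stacks each subject's salient skeleton as one layer of a multiplex network
#' over the shared supervoxel universe. Layer edges are the skeleton edges
#' weighted by the absolute Pearson correlation looked up in that subject's
#' dense network; the overall matrix `O` marks node pairs linked in at least
#' one layer.
#'
#' @param skeletons List of [extract_skeleton()] results, one per subject.
#' @param dense_nets List of the matching [correlation_network()] objects
#'   (same subject ids, shared node universe).
#' @return An object of class `multiplex_network`: `node_ids` (the full
#'   supervoxel universe), `layers` (named list of edge tibbles `i`, `j`,
#'   `w`), the binary `O` matrix, `subject_ids`, and `M` (layer count).
#'   Layers are ordered by subject id.
#' @export
build_multiplex <- function(skeletons, dense_nets) {
  if (length(skeletons) != length(dense_nets) || length(skeletons) == 0L) {
    abort("need one skeleton and one dense network per subject.",
          class = "salnet_error_validation")
  }
  skel_ids <- vapply(skeletons, function(s) s$subject_id, character(1))
  net_ids <- vapply(dense_nets, function(n) n$subject_id, character(1))
  ord_s <- order(skel_ids)
  ord_n <- order(net_ids)
  if (!identical(skel_ids[ord_s], net_ids[ord_n])) {
    abort("skeleton and network subject ids do not match.",
          class = "salnet_error_validation")
  }
  skeletons <- skeletons[ord_s]
  dense_nets <- dense_nets[ord_n]
  universe <- dense_nets[[1]]$node_ids
  for (net in dense_nets) {
    if (!identical(net$node_ids, universe)) {
      abort("all dense networks must share one supervoxel universe.",
            class = "salnet_error_validation")
    }
  }
  n <- length(universe)
  O <- matrix(0L, n, n, dimnames = list(universe, universe))
  layers <- purrr::map2(skeletons, dense_nets, function(sk, net) {
    if (!all(sk$node_ids %in% universe)) {
      abort(sprintf("skeleton '%s' has nodes outside the supervoxel universe.",
                    sk$subject_id),
            class = "salnet_error_validation")
    }
    ii <- match(sk$edges$i, universe)
    jj <- match(sk$edges$j, universe)
    tibble(i = sk$edges$i, j = sk$edges$j,
           w = abs(net$weights[cbind(ii, jj)]))
  })
  names(layers) <- skel_ids[ord_s]
  for (lay in layers) {
    ii <- match(lay$i, universe)
    jj <- match(lay$j, universe)
    O[cbind(ii, jj)] <- 1L
    O[cbind(jj, ii)] <- 1L
  }
  structure(
    list(node_ids = universe, layers = layers, O = O,
         subject_ids = names(layers), M = length(layers)),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network> %d layers over %d nodes; |O| = %d edges\n",
              x$M, length(x$node_ids), sum(x$O) / 2))
  invisible(x)
}

# Per-node sums of layer edge weights and squared weights, plus layer degree,
# over the full universe (absent nodes get 0).
layer_sums <- function(edges, universe) {
  n <- length(universe)
  s <- ssq <- k <- numeric(n)
  if (nrow(edges)) {
    idx <- c(match(edges$i, universe), match(edges$j, universe))
    w <- c(edges$w, edges$w)
    agg_s <- rowsum(w, idx)
    agg_q <- rowsum(w^2, idx)
    agg_k <- rowsum(rep(1, length(idx)), idx)
    at <- as.integer(rownames(agg_s))
    s[at] <- agg_s[, 1]
    ssq[at] <- agg_q[, 1]
    k[at] <- agg_k[, 1]
  }
  list(strength = s, ssq = ssq, degree = k)
}

get_layer <- function(mux, layer) {
  if (is.character(layer)) {
    pos <- match(layer, mux$subject_ids)
    if (is.na(pos)) abort(sprintf("no layer '%s'.", layer),
                          class = "salnet_error_validation")
    mux$layers[[pos]]
  } else {
    mux$layers[[layer]]
  }
}

#' Per-layer and multiplex node centralities
#'
#' `layer_strength()` is the sum of a node's edge weights within one layer;
#' `layer_ipr()` the inverse participation ratio
#' `Y_i = sum_j (w_ij / s_i)^2`, measuring how concentrated the strength is
#' across the node's edges (1/k for k equal weights, 1 for a single edge).
#' The multiplex variants divide the layer quantity by the node's overall
#' degree `k_i^O` (its link count in the overall matrix `O`), weighting each
#' node by its footprint on the whole multiplex. Nodes absent from the layer
#' (or with overall degree 0) return 0.
#'
#' @param mux A [build_multiplex()] result.
#' @param layer Layer index or subject id.
#' @param nodes Node ids (default: all universe nodes).
#' @return Named numeric vector over `nodes`.
#' @export
layer_strength <- function(mux, layer, nodes = mux$node_ids) {
  ls <- layer_sums(get_layer(mux, layer), mux$node_ids)
  setNames(ls$strength, mux$node_ids)[as.character(nodes)]
}

#' @rdname layer_strength
#' @export
layer_ipr <- function(mux, layer, nodes = mux$node_ids) {
  ls <- layer_sums(get_layer(mux, layer), mux$node_ids)
  ipr <- ifelse(ls$strength > 0, ls$ssq / ls$strength^2, 0)
  setNames(ipr, mux$node_ids)[as.character(nodes)]
}

overall_degree <- function(mux) rowSums(mux$O)

#' @rdname layer_strength
#' @export
multiplex_strength <- function(mux, layer, nodes = mux$node_ids) {
  s <- layer_strength(mux, layer, nodes)
  kO <- overall_degree(mux)[as.character(nodes)]
  ifelse(kO > 0, s / kO, 0)
}

#' @rdname layer_strength
#' @export
multiplex_ipr <- function(mux, layer, nodes = mux$node_ids) {
  y <- layer_ipr(mux, layer, nodes)
  kO <- overall_degree(mux)[as.character(nodes)]
  ifelse(kO > 0, y / kO, 0)
}

#' Degree-conditional means of a per-node quantity
#'
#' Replaces each node's value by the mean of that quantity over all nodes with
#' the same layer degree; nodes with degree 0 get 0. Degree classes are formed
#' from the layer degrees (edge counts), where the base quantities live.
#'
#' @param values Numeric vector of per-node values.
#' @param degrees Integer vector of matching layer degrees.
#' @return Numeric vector of conditional means.
#' @export
conditional_means <- function(values, degrees) {
  stopifnot(length(values) == length(degrees))
  out <- stats::ave(values, degrees, FUN = mean)
  out[degrees == 0] <- 0
  out
}

feature_kinds <- c("strength", "ipr", "mux_strength", "mux_ipr",
                   "cm_strength", "cm_ipr", "cm_mux_strength", "cm_mux_ipr")

# The 8 per-node quantities of one layer, given the frozen overall degree.
layer_feature_block <- function(edges, universe, kO) {
  ls <- layer_sums(edges, universe)
  s <- ls$strength
  ipr <- ifelse(s > 0, ls$ssq / s^2, 0)
  mux_s <- ifelse(kO > 0, s / kO, 0)
  mux_y <- ifelse(kO > 0, ipr / kO, 0)
  k <- ls$degree
  c(s, ipr, mux_s, mux_y,
    conditional_means(s, k), conditional_means(ipr, k),
    conditional_means(mux_s, k), conditional_means(mux_y, k))
}

#' Multiplex feature matrix (8N features x M subjects)
#'
#' Stacks, for every layer, the eight per-node quantities — strength, inverse
#' participation ratio, their multiplex-weighted variants, and the four
#' degree-conditional means — over the full supervoxel universe (nodes never
#' appearing in any skeleton carry zeros, keeping the row count at 8N).
#'
#' @param mux A [build_multiplex()] result.
#' @param labels Optional tibble/data.frame with columns `subject_id` and
#'   `class`.
#' @return An object of class `feature_matrix`: `features` (numeric matrix,
#'   rows named `<kind>:<node>`, columns = subject ids), `node_ids`, `labels`.
#' @export
feature_matrix <- function(mux, labels = NULL) {
  stopifnot(inherits(mux, "multiplex_network"))
  kO <- overall_degree(mux)
  cols <- vapply(mux$layers, layer_feature_block, universe = mux$node_ids,
                 kO = kO, numeric(8L * length(mux$node_ids)))
  rownames(cols) <- paste(rep(feature_kinds, each = length(mux$node_ids)),
                          rep(mux$node_ids, times = 8L), sep = ":")
  colnames(cols) <- mux$subject_ids
  if (!is.null(labels)) {
    labels <- as_tibble(labels)
    stopifnot(all(c("subject_id", "class") %in% names(labels)))
    labels <- labels[match(mux$subject_ids, labels$subject_id), ]
    if (anyNA(labels$subject_id)) {
      abort("labels missing for some subjects.",
            class = "salnet_error_validation")
    }
  }
  structure(list(features = cols, node_ids = mux$node_ids, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d subjects%s\n",
              nrow(x$features), ncol(x$features),
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  out <- as_tibble(x$features, rownames = "feature")
  tidyr::pivot_longer(out, -"feature", names_to = "subject_id",
                      values_to = "value")
}

#' Project a held-out subject into a frozen multiplex
#'
#' Computes the 8N feature column for a new subject against the training
#' multiplex while holding the overall matrix `O` fixed: skeleton edges absent
#' from `O` still contribute to the layer quantities but never enlarge the
#' overall degree used by the multiplex normalizations (such edges are counted
#' and reported). The multiplex is not mutated; projecting a training subject
#' reproduces its training column exactly.
#'
#' @param mux The trained [build_multiplex()] result.
#' @param skeleton The new subject's [extract_skeleton()] result.
#' @param dense The new subject's [correlation_network()] on the same
#'   universe.
#' @return Named numeric vector of length 8N.
#' @export
project_subject <- function(mux, skeleton, dense) {
  stopifnot(inherits(mux, "multiplex_network"),
            inherits(skeleton, "salient_skeleton"),
            inherits(dense, "correlation_network"))
  universe <- mux$node_ids
  if (!all(skeleton$node_ids %in% universe)) {
    abort("subject has nodes outside the supervoxel universe.",
          class = "salnet_error_validation")
  }
  if (!identical(dense$node_ids, universe)) {
    abort("dense network universe does not match the multiplex.",
          class = "salnet_error_validation")
  }
  ii <- match(skeleton$edges$i, universe)
  jj <- match(skeleton$edges$j, universe)
  edges <- tibble(i = skeleton$edges$i, j = skeleton$edges$j,
                  w = abs(dense$weights[cbind(ii, jj)]))
  if (nrow(edges)) {
    outside <- sum(mux$O[cbind(ii, jj)] == 0L)
    if (outside > 0L) {
      inform(sprintf(
        "%d skeleton edge(s) of '%s' are outside the frozen overall matrix.",
        outside, skeleton$subject_id))
    }
  }
  col <- layer_feature_block(edges, universe, overall_degree(mux))
  names(col) <- paste(rep(feature_kinds, each = length(universe)),
                      rep(universe, times = 8L), sep = ":")
  col
}

#' Write a feature matrix as TSV (+ labels CSV)
#'
#' @param fm A [feature_matrix()] result.
#' @param path TSV path; header row = subject ids, first column = feature
#'   names. Labels, when present, go to a 2-column CSV alongside.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  write.table(fm$features, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  if (!is.null(fm$labels)) {
    utils::write.csv(as.data.frame(fm$labels),
                     sub("\\.tsv$", "_labels.csv", path), row.names = FALSE)
  }
  invisible(path)
}
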