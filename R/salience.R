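#' Reciprocal-weight distance matrix
#'
#' Distances between linked supervoxels are the reciprocals of their
#' correlation weights, so strongly correlated nodes are close. Entries exist
#' only where the thresholded network has an edge.
#'
#' @param network A [apply_threshold()] result with strictly positive weights.
#' @return An object of class `distance_matrix`: `node_ids`, `edges` tibble
#'   (`i`, `j`, `dist`), and the matrix `D` (`NA` where no edge exists,
#'   diagonal 0).
#' @export
distance_matrix <- function(network) {
  stopifnot(inherits(network, "scale_free_network"))
  if (any(network$edges$w <= 0)) {
    abort("all edge weights must be positive to define reciprocal distances.",
          class = "salnet_error_domain")
  }
  np <- length(network$node_ids)
  D <- matrix(NA_real_, np, np, dimnames = list(network$node_ids,
                                                network$node_ids))
  diag(D) <- 0
  ii <- match(network$edges$i, network$node_ids)
  jj <- match(network$edges$j, network$node_ids)
  D[cbind(ii, jj)] <- D[cbind(jj, ii)] <- 1 / network$edges$w
  structure(
    list(node_ids = network$node_ids,
         edges = tibble(i = network$edges$i, j = network$edges$j,
                        dist = 1 / network$edges$w),
         D = D, subject_id = network$subject_id),
    class = "distance_matrix"
  )
}

dm_graph <- function(dm) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(dm$edges$i), to = as.character(dm$edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(dm$node_ids))
  )
  igraph::E(g)$dist <- dm$edges$dist
  g
}

# Edge (i,j) lies on some minimum-distance path from source n iff
# d(n,i) + D_ij == d(n,j) (or the symmetric condition). Ties are kept: every
# edge on any tied shortest path is marked. `drow` is the vector of distances
# from the source to all nodes.
edges_on_spt <- function(drow, ii, jj, dist_e, tol = 1e-9) {
  di <- drow[ii]
  dj <- drow[jj]
  on <- (abs(di + dist_e - dj) <= tol * pmax(1, dj)) |
    (abs(dj + dist_e - di) <= tol * pmax(1, di))
  on[!is.finite(di) | !is.finite(dj)] <- FALSE
  on
}

#' Shortest-path tree of a reference node
#'
#' Marks every edge lying on at least one minimum-total-distance path from the
#' reference node `n` to any reachable node — the full shortest-path DAG, since
#' shortest-path uniqueness is not assured on weighted graphs. Unreachable
#' components contribute no marks. Path-length ties are detected with relative
#' tolerance `tol` (reciprocal weights create near-ties from rounding).
#'
#' @param D A [distance_matrix()].
#' @param n Reference node id (must be one of `D$node_ids`).
#' @param tol Relative tie tolerance.
#' @return An object of class `shortest_path_tree`: `reference`, `node_ids`,
#'   and the binary symmetric matrix `T_mat`.
#' @export
shortest_path_tree <- function(D, n, tol = 1e-9) {
  stopifnot(inherits(D, "distance_matrix"))
  v <- match(n, D$node_ids)
  if (is.na(v)) {
    abort(sprintf("node %s is not in the network.", n),
          class = "salnet_error_validation")
  }
  g <- dm_graph(D)
  drow <- as.numeric(igraph::distances(g, v = v,
                                       weights = igraph::E(g)$dist))
  ii <- match(D$edges$i, D$node_ids)
  jj <- match(D$edges$j, D$node_ids)
  on <- edges_on_spt(drow, ii, jj, D$edges$dist, tol)
  np <- length(D$node_ids)
  T_mat <- matrix(0L, np, np, dimnames = list(D$node_ids, D$node_ids))
  T_mat[cbind(ii[on], jj[on])] <- 1L
  T_mat[cbind(jj[on], ii[on])] <- 1L
  structure(list(reference = n, node_ids = D$node_ids, T_mat = T_mat),
            class = "shortest_path_tree")
}

#' Edge salience from shortest-path trees
#'
#' The salience of an edge is the fraction of shortest-path trees (one per
#' reference node, over all N' nodes) that contain it: the entrywise mean of
#' the tree matrices. Salience is characteristically bimodal — edges are
#' either essential for nearly every reference node (s near 1) or for almost
#' none (s near 0) — which is what makes the skeleton threshold choice
#' immaterial in practice.
#'
#' @param network A non-degenerate [apply_threshold()] result.
#' @param tol Relative tolerance for shortest-path ties.
#' @return An object of class `salience_matrix`: `node_ids`, `edges` tibble
#'   (`i`, `j`, `s`), the symmetric matrix `S`, and `n_prime`. For fragmented
#'   networks the denominator remains N' (all surviving nodes), so small
#'   components dilute their edges' salience (reported via message).
#' @export
salience_matrix <- function(network, tol = 1e-9) {
  stopifnot(inherits(network, "scale_free_network"))
  if (network$degenerate) {
    abort("cannot compute salience of a degenerate (edgeless) network.",
          class = "salnet_error_degenerate")
  }
  dm <- distance_matrix(network)
  g <- dm_graph(dm)
  d <- igraph::distances(g, weights = igraph::E(g)$dist)
  np <- length(dm$node_ids)
  if (igraph::count_components(g) > 1L) {
    inform(sprintf(
      "network '%s' is fragmented (%d components); salience denominator stays N'=%d.",
      network$subject_id, igraph::count_components(g), np))
  }
  ii <- match(dm$edges$i, dm$node_ids)
  jj <- match(dm$edges$j, dm$node_ids)
  ne <- nrow(dm$edges)
  Di <- d[, ii, drop = FALSE]
  Dj <- d[, jj, drop = FALSE]
  De <- matrix(dm$edges$dist, nrow = np, ncol = ne, byrow = TRUE)
  on <- (abs(Di + De - Dj) <= tol * pmax(1, Dj)) |
    (abs(Dj + De - Di) <= tol * pmax(1, Di))
  on[!is.finite(Di) | !is.finite(Dj)] <- FALSE
  s <- unname(colSums(on)) / np
  S <- matrix(0, np, np, dimnames = list(dm$node_ids, dm$node_ids))
  S[cbind(ii, jj)] <- S[cbind(jj, ii)] <- s
  structure(
    list(subject_id = network$subject_id, node_ids = dm$node_ids,
         edges = tibble(i = dm$edges$i, j = dm$edges$j, s = s),
         S = S, n_prime = np),
    class = "salience_matrix"
  )
}

#' @export
print.salience_matrix <- function(x, ...) {
  cat(sprintf("<salience_matrix '%s'> N'=%d nodes, %d edges, %.1f%% salient (s >= 0.5)\n",
              x$subject_id, x$n_prime, nrow(x$edges),
              100 * mean(x$edges$s >= 0.5)))
  invisible(x)
}

#' @method tidy salience_matrix
#' @export
tidy.salience_matrix <- function(x, ...) x$edges

#' Extract the high-salience skeleton
#'
#' Keeps the edges whose salience is at least `s_thr` (inclusive comparison;
#' under the bimodal salience distribution any threshold between the modes
#' selects the same backbone) and drops nodes left without skeleton edges.
#'
#' @param S A [salience_matrix()].
#' @param s_thr Salience threshold in `(0, 1]`; default 0.5.
#' @return An object of class `salient_skeleton`: `subject_id`, `edges`
#'   (`i`, `j`, `s`), surviving `node_ids`, `s_thr`, `n_prime` (node count of
#'   the source network), and a `degenerate` flag when the skeleton is empty.
#' @export
extract_skeleton <- function(S, s_thr = 0.5) {
  stopifnot(inherits(S, "salience_matrix"))
  if (s_thr <= 0 || s_thr > 1) {
    abort("`s_thr` must lie in (0, 1].", class = "salnet_error_validation")
  }
  ed <- S$edges[S$edges$s >= s_thr, , drop = FALSE]
  structure(
    list(subject_id = S$subject_id,
         edges = as_tibble(ed),
         node_ids = sort(unique(c(ed$i, ed$j))),
         s_thr = s_thr, n_prime = S$n_prime,
         degenerate = nrow(ed) == 0L),
    class = "salient_skeleton"
  )
}

#' @export
print.salient_skeleton <- function(x, ...) {
  cat(sprintf("<salient_skeleton '%s'> %d nodes, %d edges (s_thr=%.2f)%s\n",
              x$subject_id, length(x$node_ids), nrow(x$edges), x$s_thr,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @method tidy salient_skeleton
#' @export
tidy.salient_skeleton <- function(x, ...) x$edges

#' Histogram of edge-salience values
#'
#' Percentage frequency of salience over the existing edges, plus the
#' bimodality share: the fraction of values below 0.1 or above 0.9.
#'
#' @param S A [salience_matrix()].
#' @param bins Number of equal-width bins on `[0, 1]` (at least 2).
#' @return A tibble of class `salience_histogram` with `bin_lo`, `bin_hi`,
#'   `count`, `percent`; the bimodality share is in
#'   `attr(, "bimodality_share")` and via [glance()].
#' @export
salience_histogram <- function(S, bins = 20) {
  stopifnot(inherits(S, "salience_matrix"))
  if (bins < 2) abort("`bins` must be >= 2.", class = "salnet_error_validation")
  s <- S$edges$s
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L), bins)
  cnt <- tabulate(idx, nbins = bins)
  out <- tibble(bin_lo = breaks[-(bins + 1)], bin_hi = breaks[-1],
                count = cnt, percent = 100 * cnt / length(s))
  attr(out, "bimodality_share") <- mean(s < 0.1 | s > 0.9)
  class(out) <- c("salience_histogram", class(out))
  out
}

#' @method glance salience_histogram
#' @export
glance.salience_histogram <- function(x, ...) {
  tibble(bimodality_share = attr(x, "bimodality_share"),
         n_edges = sum(x$count))
}

#' @method autoplot salience_histogram
#' @export
autoplot.salience_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$percent)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1]) +
    ggplot2::labs(x = "edge salience", y = "percentage frequency")
}

#' Node and link reduction achieved by the skeleton
#'
#' Fractions of nodes and links removed relative to the original dense
#' network.
#'
#' @param original The source network: a [correlation_network()] (links =
#'   nonzero off-diagonal weights) or a [apply_threshold()] result.
#' @param skeleton The [extract_skeleton()] result derived from it.
#' @return A one-row tibble with `node_reduction` and `link_reduction`.
#' @export
reduction_stats <- function(original, skeleton) {
  stopifnot(inherits(skeleton, "salient_skeleton"))
  if (inherits(original, "correlation_network")) {
    n_nodes <- length(original$node_ids)
    n_links <- sum(original$weights[upper.tri(original$weights)] != 0)
  } else if (inherits(original, "scale_free_network")) {
    n_nodes <- length(original$node_ids)
    n_links <- nrow(original$edges)
  } else {
    abort("`original` must be a correlation_network or scale_free_network.",
          class = "salnet_error_validation")
  }
  tibble(node_reduction = 1 - length(skeleton$node_ids) / n_nodes,
         link_reduction = 1 - nrow(skeleton$edges) / n_links)
}

#' Write a salience matrix or skeleton as a TSV edge list
#'
#' @param x A [salience_matrix()] or [extract_skeleton()] result.
#' @param path Output path (columns `i`, `j`, `s`).
#' @return `path`, invisibly.
#' @export
write_salience <- function(x, path) {
  stopifnot(inherits(x, "salience_matrix") || inherits(x, "salient_skeleton"))
  write.table(as.data.frame(x$edges), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
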