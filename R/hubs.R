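#' Node betweenness centrality
#'
#' Betweenness of every node, normalized by `(N'-1)(N'-2)/2` (the number of
#' node pairs a node could mediate). On weighted thresholded networks shortest
#' paths use the reciprocal-weight distance (consistent with the salience
#' construction); on binary skeletons hop counts are used — salient links are
#' consensus objects whose weights have already been consumed. `mode`
#' overrides the default per input type.
#'
#' @param network A [apply_threshold()] result or an [extract_skeleton()]
#'   result.
#' @param mode `"auto"` (weighted for thresholded networks, binary for
#'   skeletons), `"weighted"`, or `"binary"`.
#' @return Named numeric vector of normalized betweenness over the network's
#'   nodes.
#' @export
node_betweenness <- function(network, mode = c("auto", "weighted", "binary")) {
  mode <- match.arg(mode)
  if (inherits(network, "scale_free_network")) {
    if (network$degenerate) {
      abort("cannot compute betweenness of a degenerate network.",
            class = "salnet_error_degenerate")
    }
    edges <- network$edges
    node_ids <- network$node_ids
    if (mode == "auto") mode <- "weighted"
  } else if (inherits(network, "salient_skeleton")) {
    if (network$degenerate) {
      abort("cannot compute betweenness of an empty skeleton.",
            class = "salnet_error_degenerate")
    }
    edges <- network$edges
    node_ids <- network$node_ids
    if (mode == "auto") mode <- "binary"
  } else {
    abort("`network` must be a scale_free_network or salient_skeleton.",
          class = "salnet_error_validation")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(node_ids))
  )
  weights <- if (mode == "weighted" && !is.null(edges$w)) 1 / edges$w else NA
  b <- igraph::betweenness(g, weights = weights, normalized = TRUE)
  setNames(as.numeric(b), node_ids)
}

hub_cutoff <- function(values) {
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Detect hubs as betweenness outliers
#'
#' Hubs are nodes whose betweenness exceeds `Q3 + 1.5 * IQR` of the network's
#' betweenness distribution, with quartiles by linear interpolation between
#' order statistics (the common "type 7" rule — the hub set depends on the
#' quartile convention, so it is fixed and documented). When all values are
#' equal the IQR is 0 and no node exceeds the cutoff.
#'
#' @param x A network accepted by [node_betweenness()], or a named numeric
#'   vector of betweenness values.
#' @param mode Passed to [node_betweenness()] when `x` is a network.
#' @param strength Optional named per-node strength to carry into the report
#'   (for skeletons, the subject's absolute correlations restored onto
#'   skeleton edges keep strength informative after binarization).
#' @param subject_id Subject identifier for the report.
#' @return An object of class `hub_set`: `subject_id`, `nodes` tibble
#'   (`node_id`, `betweenness`, `strength`, `is_hub`), `hub_ids`, `cutoff`.
#' @export
detect_hubs <- function(x, mode = "auto", strength = NULL,
                        subject_id = NULL) {
  if (is.numeric(x)) {
    b <- x
    if (is.null(names(b))) names(b) <- seq_along(b)
    subject_id <- subject_id %||% "subject"
  } else {
    b <- node_betweenness(x, mode)
    subject_id <- subject_id %||% x$subject_id
  }
  if (length(b) < 4L) {
    abort("hub detection needs at least 4 nodes.",
          class = "salnet_error_validation")
  }
  cutoff <- hub_cutoff(b)
  is_hub <- unname(b > cutoff)
  ids <- names(b)
  ids_int <- suppressWarnings(as.integer(ids))
  nodes <- tibble(
    node_id = if (anyNA(ids_int)) ids else ids_int,
    betweenness = unname(as.numeric(b)),
    strength = if (is.null(strength)) NA_real_
               else unname(as.numeric(strength[ids])),
    is_hub = is_hub
  )
  structure(list(subject_id = subject_id, nodes = nodes,
                 hub_ids = nodes$node_id[is_hub], cutoff = cutoff),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set '%s'> %d hub(s) of %d nodes (cutoff %.4g)\n",
              x$subject_id, length(x$hub_ids), nrow(x$nodes), x$cutoff))
  invisible(x)
}

#' @method tidy hub_set
#' @export
tidy.hub_set <- function(x, ...) x$nodes

#' Hub conservation between a dense network and its skeleton
#'
#' Fraction of the dense network's hubs that survive in the skeleton:
#' `|dense_hubs intersect skeleton_hubs| / |dense_hubs|`. Undefined (NA, with
#' a message) when the dense hub set is empty.
#'
#' @param dense_hubs,skeleton_hubs [detect_hubs()] results for the same
#'   subject.
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
hub_overlap <- function(dense_hubs, skeleton_hubs) {
  stopifnot(inherits(dense_hubs, "hub_set"), inherits(skeleton_hubs, "hub_set"))
  if (!identical(dense_hubs$subject_id, skeleton_hubs$subject_id)) {
    abort("hub sets belong to different subjects.",
          class = "salnet_error_validation")
  }
  if (length(dense_hubs$hub_ids) == 0L) {
    inform("dense hub set empty; overlap undefined.")
    return(NA_real_)
  }
  length(intersect(dense_hubs$hub_ids, skeleton_hubs$hub_ids)) /
    length(dense_hubs$hub_ids)
}

#' Hubs common to all subjects
#'
#' @param hubsets List of [detect_hubs()] results (at least one).
#' @return Integer node ids present in every subject's hub set.
#' @export
common_hubs <- function(hubsets) {
  if (length(hubsets) == 0L) {
    abort("at least one hub set is required.", class = "salnet_error_validation")
  }
  Reduce(intersect, lapply(hubsets, function(h) h$hub_ids))
}

#' Rank-sum test of a hub metric between clinical groups
#'
#' Two-sided Wilcoxon Mann-Whitney test of per-subject metric values (e.g. a
#' hub's betweenness or strength) between two groups. The exact null
#' distribution is used for combined n <= 20 without ties; otherwise the
#' normal approximation with tie correction.
#'
#' @param values Numeric vector, one value per subject.
#' @param labels Group label per subject.
#' @param groups Length-2 character vector naming the two groups to compare
#'   (default: the two levels present).
#' @param node_id,metric Identifiers carried into the result row.
#' @param alpha Significance level for the `significant` flag (default 0.01).
#' @return A one-row tibble: `node_id`, `metric`, `group_pair`, `p_value`,
#'   `significant`.
#' @export
hub_group_test <- function(values, labels, groups = NULL,
                           node_id = NA_integer_, metric = "betweenness",
                           alpha = 0.01) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  groups <- groups %||% unique(labels)
  if (length(groups) != 2L) {
    abort("exactly two groups are required.", class = "salnet_error_validation")
  }
  xa <- values[labels == groups[1]]
  xb <- values[labels == groups[2]]
  if (length(xa) < 2L || length(xb) < 2L) {
    abort("each group needs at least 2 subjects.",
          class = "salnet_error_validation")
  }
  exact <- (length(xa) + length(xb)) <= 20L
  p <- suppressWarnings(
    wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value
  )
  tibble(node_id = node_id, metric = metric,
         group_pair = paste(groups, collapse = "-"),
         p_value = p, significant = p < alpha)
}
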