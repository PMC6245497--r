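#' Threshold a correlation network
#'
#' Keeps only edges whose signed correlation strictly exceeds `r_thr` and drops
#' nodes left without any edge. Negative correlations are therefore removed at
#' any non-negative threshold, which downstream salience requires (distances
#' are reciprocal weights).
#'
#' @param network A [correlation_network()].
#' @param r_thr Correlation threshold in `[0, 1)`.
#'
#' @return An object of class `scale_free_network`: `subject_id`, surviving
#'   `node_ids`, an `edges` tibble (`i`, `j`, `w`), `r_thr`, the original node
#'   count `n_original`, and a `degenerate` flag (TRUE when no edge survives;
#'   flagged, not an error).
#' @export
apply_threshold <- function(network, r_thr) {
  if (inherits(network, "scale_free_network")) {
    ed <- network$edges[network$edges$w > r_thr, , drop = FALSE]
    n_orig <- network$n_original
    sid <- network$subject_id
  } else {
    stopifnot(inherits(network, "correlation_network"))
    if (r_thr < 0 || r_thr >= 1) {
      abort("`r_thr` must lie in [0, 1).", class = "salnet_error_validation")
    }
    ed <- tidy.correlation_network(network)
    ed <- ed[ed$w > r_thr, , drop = FALSE]
    n_orig <- length(network$node_ids)
    sid <- network$subject_id
  }
  node_ids <- sort(unique(c(ed$i, ed$j)))
  structure(
    list(subject_id = sid, node_ids = node_ids, edges = as_tibble(ed),
         r_thr = r_thr, n_original = n_orig,
         degenerate = nrow(ed) == 0L),
    class = "scale_free_network"
  )
}

#' @export
print.scale_free_network <- function(x, ...) {
  cat(sprintf("<scale_free_network '%s'> N'=%d nodes, %d edges (r_thr=%.3g)%s\n",
              x$subject_id, length(x$node_ids), nrow(x$edges), x$r_thr,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @method tidy scale_free_network
#' @export
tidy.scale_free_network <- function(x, ...) x$edges

# igraph view of a thresholded network; vertex order == x$node_ids.
sfn_graph <- function(x) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(x$edges$i), to = as.character(x$edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(x$node_ids))
  )
  igraph::E(g)$weight <- x$edges$w
  g
}

adj_r2_from_degrees <- function(deg, n_nodes) {
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3L) return(NA_real_)
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / n_nodes
  y <- log(pk)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)  # flat histogram: slope/variance undefined
  fit <- lm(y ~ log(k))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  n <- length(y)
  1 - (1 - r2) * (n - 1) / (n - 2)
}

#' Power-law goodness of fit of the degree distribution
#'
#' Fits an ordinary least-squares line to (log k, log p(k)) over raw
#' integer-degree bins with nonzero count (probabilities normalized by the
#' surviving node count N') and returns the adjusted R-squared,
#' `1 - (1 - R^2) (n - 1) / (n - 2)` for `n` bins. High values diagnose
#' scale-free (power-law) degree structure.
#'
#' @param network A [apply_threshold()] result.
#' @return Adjusted R-squared, or `NA` when fewer than 3 distinct degrees
#'   exist (undefined fit, reported with a message).
#' @export
powerlaw_adjusted_r2 <- function(network) {
  stopifnot(inherits(network, "scale_free_network"))
  if (network$degenerate) return(NA_real_)
  deg <- igraph::degree(sfn_graph(network))
  r2 <- adj_r2_from_degrees(deg, length(network$node_ids))
  if (is.na(r2)) inform("power-law fit undefined: fewer than 3 distinct degrees.")
  r2
}

# Mean local clustering (unweighted; nodes with degree < 2 count 0) and mean
# unweighted shortest-path hop length over reachable pairs.
clustering_and_path <- function(g) {
  C <- mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
  L <- igraph::mean_distance(g, weights = NA, unconnected = TRUE)
  c(C = C, L = L)
}

#' Small-worldness of a thresholded network
#'
#' Computes `(C / C_r) / (L / L_r)` where `C` is the mean unweighted local
#' clustering coefficient, `L` the mean unweighted shortest-path hop length
#' over reachable pairs, and the reference values come from an Erdos-Renyi
#' graph with the same node count N' and link probability `p = k_bar / N'`
#' (`k_bar` = mean degree): analytically `C_r = p`, `L_r = ln N' / ln k_bar`,
#' or empirically as the mean over `n_ref` sampled graphs. Values well above 1
#' indicate small-world structure.
#'
#' @param network A [apply_threshold()] result with at least 4 nodes.
#' @param reference `"analytic"` (default) or `"empirical"`.
#' @param n_ref Number of sampled reference graphs for the empirical option.
#' @param seed Seed for the empirical reference sampling.
#' @return The small-worldness ratio, or `NA` when the mean degree is <= 1
#'   (reference path length undefined).
#' @export
small_worldness <- function(network, reference = c("analytic", "empirical"),
                            n_ref = 20, seed = 1L) {
  stopifnot(inherits(network, "scale_free_network"))
  reference <- match.arg(reference)
  if (network$degenerate || length(network$node_ids) < 4L) return(NA_real_)
  g <- sfn_graph(network)
  np <- length(network$node_ids)
  kbar <- 2 * nrow(network$edges) / np
  if (kbar <= 1) {
    inform("small-worldness undefined: mean degree <= 1.")
    return(NA_real_)
  }
  cl <- clustering_and_path(g)
  if (reference == "analytic") {
    C_r <- kbar / np
    L_r <- log(np) / log(kbar)
  } else {
    refs <- with_local_seed(seed, {
      vapply(seq_len(n_ref), function(i) {
        clustering_and_path(igraph::sample_gnp(np, kbar / np))
      }, numeric(2))
    })
    C_r <- mean(refs["C", ])
    L_r <- mean(refs["L", ])
  }
  if (C_r <= 0 || L_r <= 0 || cl["L"] <= 0) return(NA_real_)
  unname((cl["C"] / C_r) / (cl["L"] / L_r))
}

#' Scan correlation thresholds for scale-free and small-world emergence
#'
#' For every threshold on the grid, each subject's dense network is
#' thresholded, the power-law adjusted R-squared and small-worldness are
#' computed, and the across-subject mean and standard deviation of both are
#' recorded. The scan then chooses a working threshold automatically: the
#' smallest grid value at which both mean curves sit within 5% of their local
#' plateau (the mean over the current and next `plateau_window` grid points)
#' and the across-subject variability, summed over the two indicators as
#' coefficients of variation, is minimal among such plateau candidates.
#' Degenerate subjects are excluded from a threshold's summaries (count
#' reported via message).
#'
#' @param networks List of [correlation_network()] objects (the cohort).
#' @param thresholds Increasing grid in `[0, 1)`.
#' @param reference,n_ref,seed Passed to [small_worldness()].
#' @param plateau_window Grid points ahead included in the plateau mean.
#' @param plateau_tol Relative tolerance for the plateau condition.
#'
#' @return A tibble of class `threshold_scan` with columns `threshold`,
#'   `mean_adj_r2`, `sd_adj_r2`, `mean_sw`, `sd_sw`, `n_degenerate`; the chosen
#'   threshold is in `attr(, "chosen_threshold")` and via [glance()].
#' @export
threshold_scan <- function(networks, thresholds = seq(0, 0.9, by = 0.05),
                           reference = c("analytic", "empirical"), n_ref = 20,
                           seed = 1L, plateau_window = 2L, plateau_tol = 0.05) {
  reference <- match.arg(reference)
  if (length(networks) == 0L) {
    abort("at least one network is required.", class = "salnet_error_validation")
  }
  thresholds <- sort(unique(as.numeric(thresholds)))
  if (any(thresholds < 0 | thresholds >= 1)) {
    abort("thresholds must lie in [0, 1).", class = "salnet_error_validation")
  }
  per <- purrr::map(thresholds, function(t) {
    vals <- purrr::map(networks, function(net) {
      sfn <- apply_threshold(net, t)
      if (sfn$degenerate) return(c(r2 = NA_real_, sw = NA_real_, degen = 1))
      c(r2 = suppressMessages(powerlaw_adjusted_r2(sfn)),
        sw = suppressMessages(small_worldness(sfn, reference, n_ref, seed)),
        degen = 0)
    })
    m <- do.call(rbind, vals)
    r2 <- m[, "r2"]; sw <- m[, "sw"]
    tibble(
      threshold = t,
      mean_adj_r2 = mean_or_na(r2), sd_adj_r2 = sd_or_zero(r2),
      mean_sw = mean_or_na(sw), sd_sw = sd_or_zero(sw),
      n_degenerate = sum(m[, "degen"])
    )
  })
  res <- dplyr::bind_rows(per)
  if (all(is.na(res$mean_adj_r2)) && all(is.na(res$mean_sw))) {
    abort("all subjects degenerate at every threshold.",
          class = "salnet_error_scan")
  }
  if (any(res$n_degenerate > 0)) {
    inform(sprintf("degenerate subject-networks excluded at %d threshold(s).",
                   sum(res$n_degenerate > 0)))
  }
  chosen <- choose_threshold(res, plateau_window, plateau_tol)
  attr(res, "chosen_threshold") <- chosen
  class(res) <- c("threshold_scan", class(res))
  res
}

mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
sd_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) return(if (length(x)) 0 else NA_real_)
  sd(x)
}

# Plateau-plus-minimum-variance rule; see threshold_scan().
choose_threshold <- function(res, window = 2L, tol = 0.05) {
  nt <- nrow(res)
  plateau_of <- function(curve) {
    vapply(seq_len(nt), function(i) {
      mean(curve[i:min(nt, i + window)], na.rm = TRUE)
    }, numeric(1))
  }
  near <- function(curve) {
    p <- plateau_of(curve)
    ok <- is.finite(curve) & is.finite(p) &
      abs(curve - p) <= tol * pmax(abs(p), 1e-12)
    ok
  }
  # the plateau condition needs a full forward window; tail grid points
  # where the window is truncated cannot be assessed
  assessable <- seq_len(nt) + window <= nt
  cand <- near(res$mean_adj_r2) & near(res$mean_sw) & assessable
  score <- res$sd_adj_r2 / pmax(abs(res$mean_adj_r2), 1e-12) +
    res$sd_sw / pmax(abs(res$mean_sw), 1e-12)
  score[!is.finite(score)] <- Inf
  if (!any(cand)) {
    warn("no plateau candidate found; choosing the minimum-variance threshold.")
    cand <- rep(TRUE, nt)
  }
  idx <- which(cand)[which.min(score[cand])]
  res$threshold[idx]
}

#' @method glance threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble(chosen_threshold = attr(x, "chosen_threshold"),
         n_thresholds = nrow(x))
}

#' @method autoplot threshold_scan
#' @export
autoplot.threshold_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble(threshold = object$threshold,
           `adjusted R2` = object$mean_adj_r2,
           `small-worldness` = object$mean_sw,
           sd_r2 = object$sd_adj_r2, sd_sw = object$sd_sw),
    cols = c("adjusted R2", "small-worldness"),
    names_to = "indicator", values_to = "mean"
  )
  long$sd <- ifelse(long$indicator == "adjusted R2", long$sd_r2, long$sd_sw)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_threshold"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "correlation threshold", y = "cohort mean ± sd")
}

#' Write a threshold scan to TSV plus a JSON summary
#'
#' @param scan A [threshold_scan()] result.
#' @param path TSV output path; a `.json` summary with the chosen threshold is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(chosen_threshold = attr(scan, "chosen_threshold")),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
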