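pipeline_defaults <- function() {
  list(
    out_dir = NULL, seed = 1L,
    thresholds = seq(0, 0.9, by = 0.05), r_thr = NULL, s_thr = 0.5,
    rounds = 100, folds = 5, trees = 500, repetitions = 10,
    positive = NULL, task = NULL,
    networks_dir = NULL, network_format = "dense", labels = NULL,
    synthetic = NULL
  )
}

#' Run the full salient-network pipeline
#'
#' Orchestrates the stages end to end: load (or synthesize) a cohort of dense
#' correlation networks, scan thresholds (or use a fixed `r_thr`), extract per
#' subject the thresholded network, salience matrix and skeleton, detect and
#' compare hubs, assemble the skeleton multiplex and feature matrix, select
#' features with the Random-Forest wrapper, and evaluate the classification
#' task. Intermediates are written under `out_dir` when given, and a run
#' manifest (JSON) records parameters, seeds and per-stage counts. When the
#' wrapper selects no feature, the evaluation falls back to the full feature
#' set (with a warning).
#'
#' @param config A named list, or a path to a JSON file with the same fields:
#'   `seed`, `out_dir`, `thresholds` or fixed `r_thr`, `s_thr`, `rounds`,
#'   `folds`, `trees`, `repetitions`, `positive`, plus either
#'   `networks_dir`/`network_format`/`labels` (a directory of network TSVs and
#'   a `subject_id,class` CSV) or `synthetic` (arguments for
#'   [network_cohort_spec()]).
#' @return The manifest, invisibly a list (also written to
#'   `out_dir/manifest.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "salnet_error_input")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_to <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)

  # -- inputs (validated before any compute) -------------------------------
  if (!is.null(cfg$synthetic)) {
    spec <- do.call(network_cohort_spec,
                    utils::modifyList(list(seed = cfg$seed),
                                      as.list(cfg$synthetic)))
    cohort <- make_network_cohort(spec)
    networks <- cohort$networks
    labels <- cohort$labels
  } else {
    if (is.null(cfg$networks_dir) || is.null(cfg$labels)) {
      abort("config needs either `synthetic` or `networks_dir` + `labels`.",
            class = "salnet_error_input")
    }
    if (!file.exists(cfg$labels)) {
      abort(sprintf("labels file not found: %s", cfg$labels),
            class = "salnet_error_input")
    }
    files <- list.files(cfg$networks_dir, pattern = "\\.tsv$",
                        full.names = TRUE)
    if (length(files) == 0L) {
      abort("no network TSV files found.", class = "salnet_error_input")
    }
    networks <- lapply(files, read_network, format = cfg$network_format)
    names(networks) <- vapply(networks, function(n) n$subject_id, character(1))
    labels <- as_tibble(utils::read.csv(cfg$labels))
    missing <- setdiff(names(networks), labels$subject_id)
    if (length(missing)) {
      abort(sprintf("labels missing for subject(s): %s",
                    paste(head(missing, 3), collapse = ", ")),
            class = "salnet_error_input")
    }
    labels <- labels[match(names(networks), labels$subject_id), ]
  }
  M <- length(networks)

  # -- topology ------------------------------------------------------------
  if (is.null(cfg$r_thr)) {
    scan <- threshold_scan(networks, cfg$thresholds)
    r_thr <- attr(scan, "chosen_threshold")
    if (!is.null(out_dir)) write_scan(scan, save_to("scan.tsv"))
  } else {
    scan <- NULL
    r_thr <- cfg$r_thr
  }
  thresholded <- lapply(networks, apply_threshold, r_thr = r_thr)

  # -- salience ------------------------------------------------------------
  usable <- !vapply(thresholded, function(x) x$degenerate, logical(1))
  if (!any(usable)) {
    abort("every subject is degenerate at the working threshold.",
          class = "salnet_error_scan")
  }
  saliences <- lapply(thresholded[usable],
                      function(x) suppressMessages(salience_matrix(x)))
  skeletons <- lapply(saliences, extract_skeleton, s_thr = cfg$s_thr)
  red <- purrr::map2(networks[usable], skeletons, reduction_stats)
  red <- dplyr::bind_rows(red)

  # -- hubs ----------------------------------------------------------------
  dense_hubs <- lapply(thresholded[usable], detect_hubs)
  skel_ok <- !vapply(skeletons, function(s) s$degenerate, logical(1))
  skel_hubs <- lapply(skeletons[skel_ok], detect_hubs)
  overlaps <- purrr::map2_dbl(dense_hubs[skel_ok], skel_hubs, function(d, s) {
    suppressMessages(hub_overlap(d, s))
  })
  common <- common_hubs(skel_hubs)
  hub_tests <- hub_tests_at_common(skel_hubs, labels, common)
  if (!is.null(out_dir)) {
    hub_tab <- dplyr::bind_rows(purrr::map(skel_hubs, function(h) {
      dplyr::mutate(h$nodes, subject_id = h$subject_id, .before = 1)
    }))
    utils::write.csv(as.data.frame(hub_tab), save_to("hubs.csv"),
                     row.names = FALSE)
    if (nrow(hub_tests)) {
      utils::write.csv(as.data.frame(hub_tests), save_to("hub_tests.csv"),
                       row.names = FALSE)
    }
  }

  # -- multiplex features --------------------------------------------------
  mux <- build_multiplex(skeletons, networks[usable])
  lab_used <- labels[match(mux$subject_ids, labels$subject_id), ]
  fm <- feature_matrix(mux, labels = lab_used)
  if (!is.null(out_dir)) write_features(fm, save_to("features.tsv"))

  # -- learning ------------------------------------------------------------
  sel <- wrapper_select(fm, rounds = cfg$rounds, folds = cfg$folds,
                        trees = cfg$trees, seed = cfg$seed)
  selected <- sel$selected
  if (length(selected) == 0L) {
    warn("wrapper selected no feature; evaluating on the full feature set.")
    selected <- sel$occurrence$feature
  }
  task <- cfg$task %||% paste(levels(droplevels(factor(lab_used$class))),
                              collapse = "-vs-")
  report <- train_eval(fm, selected = selected, folds = cfg$folds,
                       trees = cfg$trees, repetitions = cfg$repetitions,
                       positive = cfg$positive, task = task, seed = cfg$seed)
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(sel$occurrence), save_to("selection.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(task = report$task,
           metrics = as.data.frame(report$metrics),
           confusion = as.list(report$confusion)),
      save_to("report.json"), auto_unbox = TRUE, digits = NA
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("salnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    parameters = list(r_thr = r_thr, s_thr = cfg$s_thr, rounds = cfg$rounds,
                      folds = cfg$folds, trees = cfg$trees,
                      repetitions = cfg$repetitions),
    counts = list(
      subjects = M, subjects_usable = sum(usable),
      nodes_dense = length(networks[[1]]$node_ids),
      mean_nodes_thresholded = mean(vapply(thresholded[usable], function(x)
        length(x$node_ids), numeric(1))),
      mean_node_reduction = mean(red$node_reduction),
      mean_link_reduction = mean(red$link_reduction),
      mean_hub_overlap = mean(overlaps, na.rm = TRUE),
      n_common_hubs = length(common),
      n_selected = length(sel$selected)
    ),
    chosen_threshold = r_thr,
    common_hubs = common,
    metrics = setNames(as.list(report$metrics$mean), report$metrics$metric)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, save_to("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                         save_to("config.resolved.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

# Group tests of betweenness at each common hub (skipped when a group has
# fewer than 2 usable subjects).
hub_tests_at_common <- function(skel_hubs, labels, common) {
  if (length(common) == 0L) {
    return(tibble(node_id = integer(0), metric = character(0),
                  group_pair = character(0), p_value = numeric(0),
                  significant = logical(0)))
  }
  sids <- vapply(skel_hubs, function(h) h$subject_id, character(1))
  grp <- as.character(labels$class[match(sids, labels$subject_id)])
  groups <- unique(grp)
  if (length(groups) != 2L || min(table(grp)) < 2L) {
    return(tibble(node_id = integer(0), metric = character(0),
                  group_pair = character(0), p_value = numeric(0),
                  significant = logical(0)))
  }
  dplyr::bind_rows(purrr::map(common, function(node) {
    vals <- vapply(skel_hubs, function(h) {
      v <- h$nodes$betweenness[h$nodes$node_id == node]
      if (length(v)) v else 0
    }, numeric(1))
    hub_group_test(vals, grp, groups = groups, node_id = node,
                   metric = "betweenness")
  }))
}
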