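# Small two-subject fixture built entirely in code: a 6-node universe where
# subject a's skeleton is a path 1-2-3 and subject b's a star at node 4.
make_fixture <- function() {
  W <- function(edges, w) {
    M <- matrix(0, 6, 6)
    for (k in seq_along(edges)) {
      e <- edges[[k]]
      M[e[1], e[2]] <- M[e[2], e[1]] <- w[k]
    }
    M
  }
  Wa <- W(list(c(1, 2), c(2, 3), c(4, 5)), c(0.8, 0.7, 0.3))
  Wb <- W(list(c(4, 5), c(4, 6), c(4, 3), c(1, 2)), c(0.9, -0.6, 0.8, 0.2))
  net_a <- correlation_network(Wa, subject_id = "a")
  net_b <- correlation_network(Wb, subject_id = "b")
  skel <- function(edges, sid) {
    structure(list(subject_id = sid,
                   edges = tibble::tibble(i = vapply(edges, `[`, 1L, 1),
                                          j = vapply(edges, `[`, 1L, 2),
                                          s = 1),
                   node_ids = sort(unique(unlist(edges))),
                   s_thr = 0.5, n_prime = 6L, degenerate = FALSE),
              class = "salient_skeleton")
  }
  sk_a <- skel(list(c(1L, 2L), c(2L, 3L)), "a")
  sk_b <- skel(list(c(4L, 5L), c(4L, 6L), c(4L, 3L)), "b")
  list(nets = list(net_a, net_b), skels = list(sk_a, sk_b))
}

test_that("the overall matrix is the OR of layers with |r| layer weights", {
  fx <- make_fixture()
  mux <- build_multiplex(fx$skels, fx$nets)
  expect_equal(mux$M, 2L)
  expect_equal(sum(mux$O) / 2, 5)  # 2 + 3 disjoint-ish edges
  expect_equal(mux$O[1, 2], 1L); expect_equal(mux$O[4, 6], 1L)
  # layer weights are absolute correlations
  lb <- mux$layers[["b"]]
  expect_equal(lb$w[lb$i == 4 & lb$j == 6], 0.6)

  # single subject: O equals the skeleton adjacency
  one <- build_multiplex(fx$skels[1], fx$nets[1])
  expect_equal(sum(one$O) / 2, 2)

  # a shared edge is counted once
  sk_b2 <- fx$skels[[2]]
  sk_b2$edges <- dplyr::bind_rows(sk_b2$edges,
                                  tibble::tibble(i = 1L, j = 2L, s = 1))
  sk_b2$node_ids <- sort(unique(c(sk_b2$node_ids, 1L, 2L)))
  mux2 <- build_multiplex(list(fx$skels[[1]], sk_b2), fx$nets)
  expect_equal(mux2$O[1, 2], 1L)
  expect_equal(sum(mux2$O) / 2, 5)

  # id mismatch is rejected
  bad <- fx$nets[[2]]; bad$subject_id <- "zz"
  expect_error(build_multiplex(fx$skels, list(fx$nets[[1]], bad)),
               class = "salnet_error_validation")
})

test_that("layer strength and participation follow the stated formulas", {
  fx <- make_fixture()
  mux <- build_multiplex(fx$skels, fx$nets)
  # node 2 in layer a: weights 0.8 and 0.7
  expect_equal(unname(layer_strength(mux, "a", 2)), 1.5)
  # node absent from layer
  expect_equal(unname(layer_strength(mux, "a", 6)), 0)
  # single edge of weight w: strength w, ipr 1
  expect_equal(unname(layer_strength(mux, "a", 1)), 0.8)
  expect_equal(unname(layer_ipr(mux, "a", 1)), 1)
  # weights {0.8, 0.7}: ipr = (0.8/1.5)^2 + (0.7/1.5)^2
  expect_equal(unname(layer_ipr(mux, "a", 2)), (0.8 / 1.5)^2 + (0.7 / 1.5)^2)
  # k equal weights -> 1/k (star at 4 with equal weights)
  netc <- correlation_network(star_W(3, 0.5), subject_id = "c")
  skc <- structure(list(subject_id = "c",
                        edges = tibble::tibble(i = 1L, j = 2:4, s = 1),
                        node_ids = 1:4, s_thr = 0.5, n_prime = 4L,
                        degenerate = FALSE), class = "salient_skeleton")
  muxc <- build_multiplex(list(skc), list(netc))
  expect_equal(unname(layer_ipr(muxc, "c", 1)), 1 / 3)
})

test_that("multiplex quantities divide by the overall degree", {
  fx <- make_fixture()
  mux <- build_multiplex(fx$skels, fx$nets)
  kO4 <- sum(mux$O[4, ])  # node 4: edges 4-5, 4-6, 4-3
  expect_equal(kO4, 3)
  expect_equal(unname(multiplex_strength(mux, "b", 4)),
               unname(layer_strength(mux, "b", 4)) / 3)
  # node present in O but absent from this layer -> 0
  expect_equal(unname(multiplex_strength(mux, "a", 6)), 0)
  # single-layer multiplex, k equal weights w: multiplex strength = w
  netc <- correlation_network(star_W(4, 0.6), subject_id = "c")
  skc <- structure(list(subject_id = "c",
                        edges = tibble::tibble(i = 1L, j = 2:5, s = 1),
                        node_ids = 1:5, s_thr = 0.5, n_prime = 5L,
                        degenerate = FALSE), class = "salient_skeleton")
  muxc <- build_multiplex(list(skc), list(netc))
  expect_equal(unname(multiplex_strength(muxc, "c", 1)), 0.6)
})

test_that("conditional means average within layer-degree classes", {
  expect_equal(conditional_means(c(1, 2, 5), c(2, 2, 1)), c(1.5, 1.5, 5))
  expect_equal(conditional_means(c(1, 2, 3), c(2, 2, 2)), rep(2, 3))
  expect_equal(conditional_means(c(7, 1, 2), c(3, 1, 1)), c(7, 1.5, 1.5))
  expect_equal(conditional_means(c(4, 0), c(1, 0)), c(4, 0))
  # conservation: class sum equals class size times class mean
  set.seed(1)
  vals <- runif(30); degs <- sample(0:4, 30, replace = TRUE)
  cm <- conditional_means(vals, degs)
  for (d in setdiff(unique(degs), 0)) {
    expect_equal(sum(cm[degs == d]),
                 sum(degs == d) * mean(vals[degs == d]))
  }
})

test_that("the feature matrix is 8N x M with deterministic rows", {
  fx <- make_fixture()
  mux <- build_multiplex(fx$skels, fx$nets)
  fm <- feature_matrix(mux)
  expect_equal(dim(fm$features), c(48L, 2L))
  expect_equal(sum(grepl("^strength:", rownames(fm$features))), 6)
  expect_false(anyNA(fm$features))
  # named rows agree with the per-node accessors
  expect_equal(fm$features["strength:2", "a"],
               unname(layer_strength(mux, "a", 2)))
  expect_equal(fm$features["mux_ipr:4", "b"],
               unname(multiplex_ipr(mux, "b", 4)))

  # duplicated subject duplicates the column
  fx2 <- make_fixture()
  dup_net <- fx2$nets[[1]]; dup_net$subject_id <- "a2"
  dup_sk <- fx2$skels[[1]]; dup_sk$subject_id <- "a2"
  mux2 <- build_multiplex(c(fx2$skels, list(dup_sk)),
                          c(fx2$nets, list(dup_net)))
  fm2 <- feature_matrix(mux2)
  expect_equal(unname(fm2$features[, "a"]), unname(fm2$features[, "a2"]))

  # empty layer gives an all-zero column
  empty_sk <- structure(list(subject_id = "e",
                             edges = tibble::tibble(i = integer(), j = integer(),
                                                    s = numeric()),
                             node_ids = integer(), s_thr = 0.5, n_prime = 6L,
                             degenerate = TRUE), class = "salient_skeleton")
  empty_net <- fx2$nets[[1]]; empty_net$subject_id <- "e"
  mux3 <- build_multiplex(c(fx2$skels, list(empty_sk)),
                          c(fx2$nets, list(empty_net)))
  expect_equal(unname(feature_matrix(mux3)$features[, "e"]), rep(0, 48))
})

test_that("multiplex invariants hold on random cohorts", {
  co <- make_network_cohort(network_cohort_spec(
    n_per_group = 3, n_nodes = 60, seed = 4
  ))
  sfns <- lapply(co$networks, apply_threshold, r_thr = 0.5)
  skels <- lapply(sfns, function(x)
    extract_skeleton(suppressMessages(salience_matrix(x))))
  mux <- build_multiplex(skels, co$networks)

  # O idempotence: rebuilding from the multiplex's own layers reproduces O
  layer_skels <- purrr::imap(mux$layers, function(lay, sid) {
    structure(list(subject_id = sid,
                   edges = tibble::tibble(i = lay$i, j = lay$j, s = 1),
                   node_ids = sort(unique(c(lay$i, lay$j))),
                   s_thr = 0.5, n_prime = 60L, degenerate = FALSE),
              class = "salient_skeleton")
  })
  mux2 <- build_multiplex(layer_skels, co$networks[mux$subject_ids])
  expect_equal(mux2$O, mux$O)

  for (sid in mux$subject_ids) {
    s <- layer_strength(mux, sid)
    ms <- multiplex_strength(mux, sid)
    expect_true(all(ms <= s + 1e-12))
    ipr <- layer_ipr(mux, sid)
    k <- salnet:::layer_sums(mux$layers[[sid]], mux$node_ids)$degree
    pos <- k >= 1
    expect_true(all(ipr[pos] >= 1 / k[pos] - 1e-12))
    expect_true(all(ipr[pos] <= 1 + 1e-12))
    expect_true(all(ipr[!pos] == 0))
  }

  # relabeling equivariance: permuting node ids across all layers permutes
  # the per-node feature blocks consistently
  fm <- feature_matrix(mux)
  set.seed(17)
  perm <- sample(60)
  relabel <- function(v) perm[v]
  skels_p <- lapply(skels, function(sk) {
    sk$edges$i <- relabel(sk$edges$i); sk$edges$j <- relabel(sk$edges$j)
    swap <- sk$edges$i > sk$edges$j
    tmp <- sk$edges$i[swap]
    sk$edges$i[swap] <- sk$edges$j[swap]; sk$edges$j[swap] <- tmp
    sk$node_ids <- sort(relabel(sk$node_ids))
    sk
  })
  nets_p <- lapply(co$networks, function(net) {
    inv <- order(perm)
    correlation_network(net$weights[inv, inv], subject_id = net$subject_id)
  })
  fm_p <- feature_matrix(build_multiplex(skels_p, nets_p))
  for (kind in c("strength", "ipr", "mux_strength", "cm_ipr")) {
    a <- fm$features[paste0(kind, ":", 1:60), ]
    b <- fm_p$features[paste0(kind, ":", perm), ]
    expect_equal(unname(b), unname(a))
  }
})

test_that("projection against a frozen multiplex is consistent and guarded", {
  fx <- make_fixture()
  mux <- build_multiplex(fx$skels, fx$nets)
  fm <- feature_matrix(mux)

  col <- project_subject(mux, fx$skels[[1]], fx$nets[[1]])
  expect_equal(unname(col), unname(fm$features[, "a"]))

  empty_sk <- structure(list(subject_id = "new",
                             edges = tibble::tibble(i = integer(), j = integer(),
                                                    s = numeric()),
                             node_ids = integer(), s_thr = 0.5, n_prime = 6L,
                             degenerate = TRUE), class = "salient_skeleton")
  expect_equal(unname(project_subject(mux, empty_sk, fx$nets[[1]])),
               rep(0, 48))

  # a skeleton edge outside O feeds layer features but not the multiplex
  # normalization (frozen overall degree)
  out_sk <- structure(list(subject_id = "new",
                           edges = tibble::tibble(i = c(5L, 1L), j = c(6L, 2L),
                                                  s = 1),
                           node_ids = c(1L, 2L, 5L, 6L), s_thr = 0.5,
                           n_prime = 6L, degenerate = FALSE),
                      class = "salient_skeleton")
  Wn <- matrix(0, 6, 6)
  Wn[5, 6] <- Wn[6, 5] <- 0.5
  Wn[1, 2] <- Wn[2, 1] <- 0.4
  net_new <- correlation_network(Wn, subject_id = "new")
  expect_message(colp <- project_subject(mux, out_sk, net_new),
                 "outside the frozen")
  expect_equal(unname(colp["strength:5"]), 0.5)       # layer feature sees it
  kO5 <- sum(mux$O[5, ])                              # frozen degree: only 4-5
  expect_equal(unname(colp["mux_strength:5"]), 0.5 / kO5)
  expect_equal(unname(colp["mux_strength:1"]), 0.4 / sum(mux$O[1, ]))
  # O untouched
  expect_equal(mux$O[5, 6], 0L)
})
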