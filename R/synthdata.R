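#' Specification of a synthetic volume cohort
#'
#' Describes a cohort of spatially aligned volumes: a shared smooth baseline
#' field, per-subject noise, and — in the case group — a latent signal mixed
#' into designated supervoxel boxes so that the inter-box Pearson correlations
#' differ by group in a computable way. With mixing coefficient `c` and noise
#' standard deviation `sigma` (and no baseline), the expected correlation
#' between two affected boxes is `c / (1 + sigma^2)`, which serves as a
#' closed-form oracle.
#'
#' @param n_per_group Subjects per class (control, case).
#' @param grid_dim Grid shape (voxels per axis).
#' @param voxel_size mm per axis.
#' @param box_volume_mm3 Supervoxel volume used to index `affected_boxes`.
#' @param baseline_amplitude Standard deviation of the shared smooth baseline
#'   field (0 disables it).
#' @param baseline_corr_length_mm Spatial correlation length of the baseline.
#' @param noise_sd Per-subject, per-voxel noise standard deviation.
#' @param affected_boxes Box indices (into the partition) receiving the group
#'   signal.
#' @param effect Named coupling coefficients in `[0, 1]` per group; the latent
#'   signal enters each affected box as
#'   `sqrt(c) * z_shared + sqrt(1 - c) * eps_box`.
#' @param effect_amplitude Scale of the mixed signal.
#' @param seed Integer seed; cohorts are deterministic given the spec.
#' @return A `volume_cohort_spec` list.
#' @export
volume_cohort_spec <- function(n_per_group = 20, grid_dim = c(30, 30, 30),
                               voxel_size = c(1, 1, 1), box_volume_mm3 = 3000,
                               baseline_amplitude = 1,
                               baseline_corr_length_mm = 6, noise_sd = 0.2,
                               affected_boxes = c(1, 2),
                               effect = c(control = 0, case = 0.8),
                               effect_amplitude = 1, seed = 1L) {
  if (any(effect < 0 | effect > 1)) {
    abort("effect coefficients must lie in [0, 1].",
          class = "salnet_error_validation")
  }
  structure(
    list(n_per_group = n_per_group, grid_dim = as.integer(grid_dim),
         voxel_size = as.numeric(voxel_size), box_volume_mm3 = box_volume_mm3,
         baseline_amplitude = baseline_amplitude,
         baseline_corr_length_mm = baseline_corr_length_mm,
         noise_sd = noise_sd, affected_boxes = as.integer(affected_boxes),
         effect = effect, effect_amplitude = effect_amplitude,
         seed = as.integer(seed)),
    class = "volume_cohort_spec"
  )
}

# Separable Gaussian smoothing of a 3D array along all axes (reflect padding).
smooth_field3d <- function(x, sigma_vox) {
  d <- dim(x)
  smooth1 <- function(v, kern, half) {
    n <- length(v)
    padded <- c(rev(v[seq_len(half)]), v, rev(v[n - seq_len(half) + 1]))
    as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n)]
  }
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- min(max(1L, ceiling(3 * s)), d[ax] - 1L)
    kern <- dnorm(seq(-half, half), sd = s)
    kern <- kern / sum(kern)
    if (ax == 1) {
      for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        x[, j, k] <- smooth1(x[, j, k], kern, half)
      }
    } else if (ax == 2) {
      for (i in seq_len(d[1])) for (k in seq_len(d[3])) {
        x[i, , k] <- smooth1(x[i, , k], kern, half)
      }
    } else {
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        x[i, j, ] <- smooth1(x[i, j, ], kern, half)
      }
    }
  }
  x
}

#' Generate a synthetic aligned-volume cohort
#'
#' Each subject's volume is the shared smooth baseline plus independent voxel
#' noise; subjects of a group with coupling `c > 0` additionally receive, in
#' every affected box, a per-subject latent pattern mixed as
#' `effect_amplitude * (sqrt(c) * z + sqrt(1 - c) * eps)` with `z` shared
#' across the subject's affected boxes, so affected box pairs are correlated
#' by construction.
#'
#' @param spec A [volume_cohort_spec()].
#' @return A list with `volumes` (list of [brain_volume()]), `labels` (tibble
#'   `subject_id`, `class` with levels control/case), and `partition`.
#' @export
make_volume_cohort <- function(spec) {
  stopifnot(inherits(spec, "volume_cohort_spec"))
  proto <- brain_volume(array(0, spec$grid_dim), spec$voxel_size,
                        subject_id = "template")
  part <- partition_supervoxels(proto, spec$box_volume_mm3)
  if (any(spec$affected_boxes < 1 | spec$affected_boxes > part$n_boxes)) {
    abort(sprintf("affected boxes must lie in 1..%d.", part$n_boxes),
          class = "salnet_error_validation")
  }
  nvox_box <- prod(part$box_shape_voxels)
  groups <- names(spec$effect)
  with_local_seed(spec$seed, {
    baseline <- if (spec$baseline_amplitude > 0) {
      f <- smooth_field3d(array(rnorm(prod(spec$grid_dim)), spec$grid_dim),
                          spec$baseline_corr_length_mm / spec$voxel_size)
      f / sd(f) * spec$baseline_amplitude
    } else {
      array(0, spec$grid_dim)
    }
    volumes <- list()
    labels <- character(0)
    for (g in groups) {
      cc <- spec$effect[[g]]
      for (s in seq_len(spec$n_per_group)) {
        sid <- sprintf("%s_%02d", g, s)
        vol <- baseline + array(rnorm(prod(spec$grid_dim), sd = spec$noise_sd),
                                spec$grid_dim)
        if (cc > 0) {
          z <- rnorm(nvox_box)
          for (b in spec$affected_boxes) {
            bx <- part$boxes[b, ]
            eff <- spec$effect_amplitude *
              (sqrt(cc) * z + sqrt(1 - cc) * rnorm(nvox_box))
            vol[(bx$x0 + 1):bx$x1, (bx$y0 + 1):bx$y1, (bx$z0 + 1):bx$z1] <-
              vol[(bx$x0 + 1):bx$x1, (bx$y0 + 1):bx$y1, (bx$z0 + 1):bx$z1] +
              array(eff, part$box_shape_voxels)
          }
        }
        volumes[[sid]] <- brain_volume(vol, spec$voxel_size,
                                       subject_id = sid)
        labels <- c(labels, g)
      }
    }
    list(volumes = volumes,
         labels = tibble(subject_id = names(volumes),
                         class = factor(labels, levels = groups)),
         partition = part)
  })
}

#' Specification of a synthetic network cohort
#'
#' Describes a cohort of weighted correlation-like networks sharing one
#' heavy-tailed (preferential-attachment) backbone — emulating common anatomy
#' under registration — with per-subject weights. Backbone weights live above,
#' and random noise-edge weights below, a constructed gap, so a correct
#' threshold scan should land inside it. The planted (group-discriminative)
#' structure is a star among the last `n_planted` node ids — a planted hub
#' whose leaves are the remaining planted nodes — attached to the backbone by
#' a single connector edge. Being tree-like, the star is fully salient and
#' survives skeleton extraction, and because its leaves are dead ends the
#' shift cannot re-route shortest paths elsewhere in the network. The case
#' group's star-edge weights are shifted by `effect` with alternating sign
#' across leaves, so each planted edge is individually discriminative while
#' class-wide weight sums (hence degree-conditional feature means) stay
#' unchanged — the group signal is confined to the planted nodes.
#'
#' @param n_per_group Subjects per class.
#' @param n_nodes Nodes per network.
#' @param backbone_m Preferential-attachment edges per new node.
#' @param backbone_w Weight range of backbone edges (within `(r_thr, 1]`).
#' @param noise_density Noise edges as a fraction of non-backbone pairs,
#'   redrawn per subject.
#' @param noise_w Weight range of noise edges (below the gap).
#' @param n_planted Planted node count (star hub + leaves; at least 2).
#' @param effect Weight shift on planted-pair (star) edges in the case group
#'   (0 disables the group difference).
#' @param seed Integer seed.
#' @return A `network_cohort_spec` list.
#' @export
network_cohort_spec <- function(n_per_group = 30, n_nodes = 200,
                                backbone_m = 2, backbone_w = c(0.65, 0.95),
                                noise_density = 0.02,
                                noise_w = c(0.15, 0.45), n_planted = 20,
                                effect = 0.15, seed = 1L) {
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[2] <= 1 && r[1] <= r[2]
  if (!rng_ok(backbone_w) || !rng_ok(noise_w)) {
    abort("weight ranges must lie within (0, 1].",
          class = "salnet_error_validation")
  }
  if (n_planted < 2 || n_planted >= n_nodes) {
    abort("`n_planted` must be at least 2 and below `n_nodes`.",
          class = "salnet_error_validation")
  }
  structure(
    list(n_per_group = n_per_group, n_nodes = as.integer(n_nodes),
         backbone_m = backbone_m, backbone_w = backbone_w,
         noise_density = noise_density, noise_w = noise_w,
         n_planted = as.integer(n_planted),
         effect = effect, seed = as.integer(seed)),
    class = "network_cohort_spec"
  )
}

#' Generate a synthetic weighted-network cohort
#'
#' @param spec A [network_cohort_spec()].
#' @return A list with `networks` (list of [correlation_network()]), `labels`
#'   (tibble `subject_id`, `class`, levels control/case), `backbone` (edge
#'   tibble), `planted_nodes`, and `planted_edges`.
#' @export
make_network_cohort <- function(spec) {
  stopifnot(inherits(spec, "network_cohort_spec"))
  n <- spec$n_nodes
  with_local_seed(spec$seed, {
    n_core <- n - spec$n_planted
    g <- igraph::sample_pa(n_core, m = spec$backbone_m, directed = FALSE)
    bedges <- igraph::as_edgelist(g, names = FALSE)
    bedges <- unique(t(apply(bedges, 1, sort)))
    # planted star: hub = first planted id, leaves = the rest; one connector
    # edge ties the hub to the highest-degree core node
    planted <- (n_core + 1L):n
    hub <- planted[1]
    pe <- cbind(hub, planted[-1])
    connector <- c(which.max(igraph::degree(g)), hub)
    bedges <- rbind(bedges, pe, connector)
    planted_mask <- c(rep(FALSE, nrow(bedges) - nrow(pe) - 1L),
                      rep(TRUE, nrow(pe)), FALSE)
    n_backbone <- nrow(bedges)
    all_pairs <- n * (n - 1) / 2
    n_noise <- round(spec$noise_density * (all_pairs - n_backbone))
    if (n_noise > all_pairs - n_backbone) {
      abort("noise density too high for a simple graph.",
            class = "salnet_error_validation")
    }
    networks <- list()
    labels <- character(0)
    for (grp in c("control", "case")) {
      for (s in seq_len(spec$n_per_group)) {
        sid <- sprintf("%s_%02d", grp, s)
        w <- runif(n_backbone, spec$backbone_w[1], spec$backbone_w[2])
        if (grp == "case" && spec$effect > 0) {
          # balanced +/- shift across the star leaves: each planted edge is
          # individually discriminative while the net shift (hence any
          # degree-class mean) stays near zero, confining the group signal
          # to the planted nodes themselves
          signs <- rep_len(c(1, -1), sum(planted_mask))
          w[planted_mask] <- pmin(pmax(w[planted_mask] + signs * spec$effect,
                                       spec$backbone_w[1]),
                                  spec$backbone_w[2])
        }
        W <- matrix(0, n, n)
        W[bedges] <- w
        if (n_noise > 0) {
          free <- which(upper.tri(W) & W == 0)
          pick <- sample(free, n_noise)
          W[pick] <- runif(n_noise, spec$noise_w[1], spec$noise_w[2])
        }
        W[lower.tri(W)] <- t(W)[lower.tri(W)]
        networks[[sid]] <- correlation_network(W, subject_id = sid)
        labels <- c(labels, grp)
      }
    }
    list(networks = networks,
         labels = tibble(subject_id = names(networks),
                         class = factor(labels, levels = c("control", "case"))),
         backbone = tibble(i = as.integer(bedges[, 1]),
                           j = as.integer(bedges[, 2]),
                           planted = planted_mask),
         planted_nodes = as.integer(planted),
         planted_edges = tibble(i = as.integer(pe[, 1]),
                                j = as.integer(pe[, 2])))
  })
}
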