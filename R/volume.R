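#' Registered 3D intensity volume
#'
#' Container for a single subject's intensity-normalized, spatially registered
#' scan: a 3D grid of intensities plus voxel geometry. All downstream network
#' construction assumes volumes in a cohort share one grid (they have been
#' registered to a common template); registration itself is outside this
#' package.
#'
#' @param intensities 3D numeric array of voxel intensities (arbitrary units).
#' @param voxel_size numeric length-3, mm per axis; all components > 0.
#' @param origin numeric length-3, mm offset of voxel (0,0,0).
#' @param subject_id character scalar identifying the subject.
#'
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(intensities, voxel_size = c(1, 1, 1),
                         origin = c(0, 0, 0), subject_id = "subject") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array.", class = "salnet_error_shape")
  }
  n_bad <- sum(!is.finite(intensities))
  if (n_bad > 0L) {
    abort(sprintf("volume contains %d non-finite voxel(s).", n_bad),
          class = "salnet_error_validation")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 positive numbers (mm).",
          class = "salnet_error_validation")
  }
  structure(
    list(intensities = intensities, voxel_size = voxel_size,
         origin = as.numeric(origin), subject_id = as.character(subject_id)),
    class = "brain_volume"
  )
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<brain_volume '%s'> %d x %d x %d voxels, voxel %.3g x %.3g x %.3g mm\n",
              x$subject_id, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Read a registered volume from disk
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) or the package's plain-text array
#' format: two header lines (grid shape; voxel size in mm) followed by
#' whitespace-separated intensities in raster order, first axis fastest.
#'
#' @param path File path.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#'
#' @return A [brain_volume()].
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("volume file not found: %s", path),
          class = "salnet_error_input")
  }
  subject_id <- subject_id %||% sub("\\.(nii(\\.gz)?|txt|vol)$", "", basename(path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L) {
      abort(sprintf("expected a 3D image, got %dD.", length(d)),
            class = "salnet_error_shape")
    }
    n_bad <- sum(!is.finite(img))
    if (n_bad > 0L) {
      abort(sprintf("volume contains %d non-finite voxel(s).", n_bad),
            class = "salnet_error_validation")
    }
    vox <- RNifti::pixdim(img)[seq_len(3)]
    hdr <- RNifti::niftiHeader(img)
    origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    return(brain_volume(array(as.numeric(img), dim = d), vox, origin, subject_id))
  }
  lines <- readLines(path, n = 2L)
  shape <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  vox <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(shape) != 3L) {
    abort(sprintf("expected a 3D shape header, got %d dims.", length(shape)),
          class = "salnet_error_shape")
  }
  vals <- scan(path, skip = 2L, quiet = TRUE)
  if (length(vals) != prod(shape)) {
    abort(sprintf("expected %d values, found %d.", prod(shape), length(vals)),
          class = "salnet_error_shape")
  }
  brain_volume(array(vals, dim = shape), vox, subject_id = subject_id)
}

#' Write a volume to disk
#'
#' Writes NIfTI-1 when the extension is `.nii`/`.nii.gz`, otherwise the plain
#' text format read by [read_volume()].
#'
#' @param volume A [brain_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume$intensities)
    RNifti::pixdim(img) <- volume$voxel_size
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste(dim(volume$intensities), collapse = " "),
                 paste(format(volume$voxel_size, digits = 12), collapse = " ")),
               con)
    writeLines(paste(format(as.vector(volume$intensities), digits = 12),
                     collapse = " "), con)
  }
  invisible(path)
}

# Integer box-edge rule: among all integer edge triples, minimize the absolute
# difference between box volume (voxels x voxel volume) and the target, subject
# to a near-cubic constraint max(edge mm)/min(edge mm) <= ratio_max; ties are
# broken lexicographically on the voxel-count triple.
choose_box_edges <- function(voxel_size, box_volume_mm3, ratio_max = 1.2) {
  voxvol <- prod(voxel_size)
  cube_mm <- box_volume_mm3^(1 / 3)
  emax <- pmax(1L, as.integer(ceiling(ratio_max * cube_mm / voxel_size)) + 1L)
  best <- NULL
  best_key <- c(Inf, Inf, Inf, Inf)
  for (e1 in seq_len(emax[1])) {
    for (e2 in seq_len(emax[2])) {
      mm12 <- c(e1 * voxel_size[1], e2 * voxel_size[2])
      for (e3 in seq_len(emax[3])) {
        mm <- c(mm12, e3 * voxel_size[3])
        if (max(mm) / min(mm) > ratio_max) next
        diff <- abs(e1 * e2 * e3 * voxvol - box_volume_mm3)
        key <- c(diff, e1, e2, e3)
        if (compare_lex(key, best_key) < 0) {
          best_key <- key
          best <- c(e1, e2, e3)
        }
      }
    }
  }
  if (is.null(best)) {
    abort("no integer box shape satisfies the near-cubic constraint.",
          class = "salnet_error_degenerate_partition")
  }
  as.integer(best)
}

compare_lex <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  0L
}

#' Partition a volume into fixed-volume supervoxel boxes
#'
#' Tiles the grid with equal rectangular boxes ("supervoxels") whose physical
#' volume is as close as possible to `box_volume_mm3` under a near-cubic
#' constraint (longest/shortest box edge, in mm, at most 1.2). The lattice is
#' anchored at voxel (0,0,0); partial boxes at the far boundary are discarded.
#' Boxes are listed in raster order, first axis fastest. With an optional
#' brain mask, only boxes with at least `mask_min_frac` in-mask voxels are
#' retained.
#'
#' @param volume A [brain_volume()].
#' @param box_volume_mm3 Target box volume in cubic millimetres (default 3000,
#'   the characteristic size of the anatomical regions of interest).
#' @param mask Optional [brain_volume()] or 3D array of 0/1 on the same grid.
#' @param mask_min_frac Minimum in-mask voxel fraction for a box to be kept.
#'
#' @return An object of class `supervoxel_partition` with fields
#'   `box_shape_voxels`, `boxes` (a tibble of half-open, 0-based voxel ranges),
#'   `box_volume_mm3` (achieved), `n_boxes`, `grid_dim`, `voxel_size`.
#' @export
partition_supervoxels <- function(volume, box_volume_mm3 = 3000,
                                  mask = NULL, mask_min_frac = 0.5) {
  stopifnot(inherits(volume, "brain_volume"))
  voxvol <- prod(volume$voxel_size)
  if (box_volume_mm3 <= voxvol) {
    abort("`box_volume_mm3` must exceed the voxel volume.",
          class = "salnet_error_validation")
  }
  gd <- dim(volume$intensities)
  e <- choose_box_edges(volume$voxel_size, box_volume_mm3)
  if (any(e > gd)) {
    abort(sprintf("box shape %s exceeds grid %s.",
                  paste(e, collapse = "x"), paste(gd, collapse = "x")),
          class = "salnet_error_degenerate_partition")
  }
  nb <- gd %/% e
  grid <- expand.grid(x = seq_len(nb[1]) - 1L, y = seq_len(nb[2]) - 1L,
                      z = seq_len(nb[3]) - 1L)  # x fastest
  boxes <- tibble(
    box = seq_len(nrow(grid)),
    x0 = grid$x * e[1], x1 = (grid$x + 1L) * e[1],
    y0 = grid$y * e[2], y1 = (grid$y + 1L) * e[2],
    z0 = grid$z * e[3], z1 = (grid$z + 1L) * e[3]
  )
  if (!is.null(mask)) {
    m <- if (inherits(mask, "brain_volume")) mask$intensities else mask
    if (!identical(dim(m), gd)) {
      abort("mask grid does not match the volume grid.",
            class = "salnet_error_validation")
    }
    frac <- vapply(seq_len(nrow(boxes)), function(b) {
      bx <- boxes[b, ]
      mean(m[(bx$x0 + 1):bx$x1, (bx$y0 + 1):bx$y1, (bx$z0 + 1):bx$z1] > 0)
    }, numeric(1))
    boxes <- boxes[frac >= mask_min_frac, ]
    boxes$box <- seq_len(nrow(boxes))
  }
  structure(
    list(box_shape_voxels = e,
         boxes = boxes,
         box_volume_mm3 = prod(e) * voxvol,
         target_volume_mm3 = box_volume_mm3,
         n_boxes = nrow(boxes),
         grid_dim = gd,
         voxel_size = volume$voxel_size),
    class = "supervoxel_partition"
  )
}

#' @export
print.supervoxel_partition <- function(x, ...) {
  cat(sprintf("<supervoxel_partition> %d boxes of %s voxels (%.0f mm^3 each) on a %s grid\n",
              x$n_boxes, paste(x$box_shape_voxels, collapse = "x"),
              x$box_volume_mm3, paste(x$grid_dim, collapse = "x")))
  invisible(x)
}

# Voxel vector of one box, raster order with axis 1 fastest (R column-major).
box_vector <- function(intensities, bx) {
  as.vector(intensities[(bx$x0 + 1):bx$x1, (bx$y0 + 1):bx$y1, (bx$z0 + 1):bx$z1])
}

#' Build a supervoxel Pearson-correlation network
#'
#' For every pair of supervoxels the link weight is the Pearson correlation of
#' their voxel-intensity vectors (read in a shared raster order), giving a
#' dense weighted undirected network per subject. Boxes with constant
#' intensity get zero correlation to every other box (node retained, with a
#' warning) so node indexing stays stable across subjects.
#'
#' @param volume A [brain_volume()].
#' @param partition A [partition_supervoxels()] result computed on the same
#'   grid.
#'
#' @return An object of class `correlation_network`: `subject_id`, `node_ids`,
#'   and the symmetric `weights` matrix (diagonal zeroed).
#' @export
build_correlation_network <- function(volume, partition) {
  stopifnot(inherits(volume, "brain_volume"),
            inherits(partition, "supervoxel_partition"))
  if (!identical(dim(volume$intensities), partition$grid_dim)) {
    abort("partition was derived from a different grid shape.",
          class = "salnet_error_validation")
  }
  bxs <- partition$boxes
  X <- vapply(seq_len(nrow(bxs)),
              function(b) box_vector(volume$intensities, bxs[b, ]),
              numeric(prod(partition$box_shape_voxels)))
  sds <- apply(X, 2, sd)
  const <- sds == 0
  W <- suppressWarnings(cor(X))
  if (any(const)) {
    warn(sprintf("%d constant-intensity box(es); their correlations set to 0.",
                 sum(const)))
    W[const, ] <- 0
    W[, const] <- 0
  }
  W[is.na(W)] <- 0
  diag(W) <- 0
  correlation_network(W, node_ids = bxs$box, subject_id = volume$subject_id)
}

#' Construct a correlation network from a weight matrix
#'
#' @param weights Symmetric numeric matrix of pairwise Pearson correlations;
#'   values in \[-1, 1\], diagonal ignored.
#' @param node_ids Integer node identifiers (default `1:n`).
#' @param subject_id Subject identifier.
#' @return An object of class `correlation_network`.
#' @export
correlation_network <- function(weights, node_ids = NULL,
                                subject_id = "subject") {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) abort("`weights` must be square.",
                                class = "salnet_error_validation")
  if (max(abs(weights - t(weights))) > 1e-8) {
    abort("`weights` must be symmetric.", class = "salnet_error_validation")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(abs(weights) > 1 + 1e-8)) {
    abort("correlation weights must lie in [-1, 1].",
          class = "salnet_error_validation")
  }
  node_ids <- as.integer(node_ids %||% seq_len(n))
  stopifnot(length(node_ids) == n)
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(subject_id = as.character(subject_id),
                 node_ids = node_ids, weights = weights),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network '%s'> %d nodes, dense\n",
              x$subject_id, length(x$node_ids)))
  invisible(x)
}

#' @describeIn correlation_network Edge tibble (`i`, `j`, `w`), upper triangle.
#' @param x A `correlation_network`.
#' @param ... Unused.
#' @method tidy correlation_network
#' @export
tidy.correlation_network <- function(x, ...) {
  ut <- upper.tri(x$weights)
  idx <- which(ut, arr.ind = TRUE)
  tibble(i = x$node_ids[idx[, 1]], j = x$node_ids[idx[, 2]],
         w = x$weights[ut])
}

#' Write a network to disk
#'
#' @param network A `correlation_network`.
#' @param path Output path.
#' @param format `"dense"` (TSV matrix, row/col names = node ids) or
#'   `"edgelist"` (TSV of `i`, `j`, `w`).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  if (format == "dense") {
    write.table(network$weights, path, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
  } else {
    write.table(tidy.correlation_network(network), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"dense"` or `"edgelist"`.
#' @param subject_id Subject identifier; defaults to the file name.
#' @return A `correlation_network`.
#' @export
read_network <- function(path, format = c("dense", "edgelist"),
                         subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("network file not found: %s", path),
          class = "salnet_error_input")
  }
  subject_id <- subject_id %||% sub("\\.[^.]+$", "", basename(path))
  if (format == "dense") {
    tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                      check.names = FALSE)
    W <- as.matrix(tab)
    correlation_network(W, node_ids = as.integer(rownames(tab)),
                        subject_id = subject_id)
  } else {
    ed <- read.table(path, sep = "\t", header = TRUE)
    ids <- sort(unique(c(ed$i, ed$j)))
    n <- length(ids)
    W <- matrix(0, n, n)
    ii <- match(ed$i, ids); jj <- match(ed$j, ids)
    W[cbind(ii, jj)] <- ed$w
    W[cbind(jj, ii)] <- ed$w
    correlation_network(W, node_ids = ids, subject_id = subject_id)
  }
}
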