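#' Skeletonize a binary mask to a one-voxel-wide medial line
#'
#' Reduces a single-component binary volume to a thin curve skeleton by
#' sequential topological thinning: border voxels are deleted one at a time,
#' only when deletion provably preserves topology (the simple-point
#' criterion: exactly one 26-connected foreground component among the 26
#' neighbours and exactly one 6-connected background component in the
#' 18-neighbourhood touching a face), sweeping the six face directions in
#' turn so the line stays centred. Curve endpoints (voxels with a single
#' foreground neighbour) are never deleted, so an open tube keeps its two
#' ends and a closed tube keeps its loop.
#'
#' @param mask A binary [label_volume()] (as returned by [binarize()] or
#'   [voxelize_tube()]).
#' @param keep_largest If `TRUE`, a multi-component mask is reduced to its
#'   largest 26-connected component with a warning instead of an error
#'   (disconnected segmentations are normally fixed upstream by manual
#'   editing).
#' @param prune_spurs_vox Branches of at most this many voxels hanging off a
#'   junction are removed after thinning; they are artifacts of the tube end
#'   caps, not anatomy. Set to 0 to keep every branch.
#' @return A `skeleton_mask`: the thinned logical array plus geometry.
#' @export
skeletonize3d <- function(mask, keep_largest = FALSE, prune_spurs_vox = 4) {
  vox <- mask$voxels > 0
  if (!any(vox))
    stop_tortr("mask is empty: nothing to skeletonize", "empty_structure")
  lab <- label_components_cpp(as.logical(vox), dim(vox))
  ncomp <- max(lab)
  kept_largest <- FALSE
  if (ncomp > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    if (!keep_largest)
      stop_tortr(sprintf(
        "mask has %d disconnected components (sizes: %s); fix the segmentation or set keep_largest = TRUE",
        ncomp, paste(sort(sizes, decreasing = TRUE), collapse = ", ")),
        "multi_component")
    keep <- which.max(sizes)
    vox <- array(lab == keep, dim(vox))
    kept_largest <- TRUE
    warn_tortr(sprintf(
      "mask had %d components; kept the largest (%d voxels)",
      ncomp, sizes[keep]), "kept_largest_component")
  }
  ax <- affine_axis_map(mask$affine)
  thin <- array(thin_skeleton_cpp(as.logical(vox), dim(vox),
                                  ax$map, ax$sign), dim(vox))
  if (prune_spurs_vox > 0) thin <- prune_spurs(thin, prune_spurs_vox)
  structure(list(voxels = thin, affine = mask$affine,
                 spacing = mask$spacing, n_foreground = sum(thin),
                 kept_largest = kept_largest),
            class = "skeleton_mask")
}

# dominant array axis (and sign) carrying each world axis, so thinning can
# sweep in world-canonical order whatever the array orientation
affine_axis_map <- function(affine) {
  M <- affine[1:3, 1:3]
  map <- integer(3); sgn <- integer(3)
  for (w in 1:3) {
    a <- which.max(abs(M[w, ]))
    map[w] <- a - 1L
    sgn[w] <- if (M[w, a] >= 0) 1L else -1L
  }
  if (length(unique(map)) < 3) {  # degenerate affine: fall back to identity
    map <- 0:2; sgn <- rep(1L, 3)
  }
  list(map = map, sign = sgn)
}

# remove end-cap artifact branches: walk inward from each endpoint; if a
# junction (>= 3 neighbours) is met within maxlen voxels, drop the walked
# stub. Iterated until stable. Never fires on a clean two-endpoint line.
prune_spurs <- function(vox, maxlen) {
  dims <- dim(vox)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbrs <- function(p) {
    nb <- sweep(offs, 2, -p)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    nb[vox[nb], , drop = FALSE]
  }
  repeat {
    if (sum(vox) <= maxlen + 2) break
    counts <- array(neighbor_count_cpp(as.logical(vox), dims), dims)
    eps <- which(!is.na(counts) & counts == 1L)
    changed <- FALSE
    for (e in eps) {
      cur <- arrayInd(e, dims)[1, ]
      if (!vox[matrix(cur, 1)]) next
      walked <- list()
      prev <- NULL
      repeat {
        if (length(walked) > maxlen) break
        nb <- nbrs(cur)
        if (!is.null(prev))
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2] &
                       nb[, 3] == prev[3]), , drop = FALSE]
        if (counts[matrix(cur, 1)] >= 3) {
          for (w in walked) vox[matrix(w, 1)] <- FALSE
          changed <- TRUE
          break
        }
        if (nrow(nb) != 1) break  # other end or ambiguous: keep
        walked <- c(walked, list(cur))
        prev <- cur
        cur <- nb[1, ]
      }
    }
    if (!changed) break
  }
  vox
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat("<skeleton_mask> ", paste(dim(x$voxels), collapse = " x "),
      " grid, ", x$n_foreground, " skeleton voxels\n", sep = "")
  invisible(x)
}

#' Detect skeleton endpoints by neighbourhood counting
#'
#' A skeleton voxel is a terminal iff its 3x3x3 neighbourhood contains
#' exactly one other foreground voxel. Returns the endpoints sorted
#' lexicographically by voxel index so the result is deterministic.
#'
#' @param skeleton A `skeleton_mask` from [skeletonize3d()].
#' @return Integer matrix (one row per endpoint) of 0-based voxel indices.
#' @export
find_endpoints <- function(skeleton) {
  vox <- skeleton$voxels
  nfg <- sum(vox)
  if (nfg == 0)
    stop_tortr("skeleton is empty", "empty_structure")
  if (nfg == 1)
    stop_tortr("skeleton is a single isolated voxel", "degenerate_structure")
  counts <- array(neighbor_count_cpp(as.logical(vox), dim(vox)), dim(vox))
  ep <- which(!is.na(counts) & counts == 1L)
  if (length(ep) == 0)
    stop_tortr(
      "skeleton has no endpoints: the structure is a closed loop; an open artery is expected",
      "loop_topology")
  ijk <- arrayInd(ep, dim(vox)) - 1L
  ijk[order(ijk[, 1], ijk[, 2], ijk[, 3]), , drop = FALSE]
}

# weighted 26-adjacency graph over skeleton voxels; edge weights are
# inter-voxel-centre distances in mm
skeleton_graph <- function(skeleton) {
  vox <- skeleton$voxels
  dims <- dim(vox)
  fg <- which(vox)
  id <- array(0L, dims); id[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(offs)); wts <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, -offs[r, ])
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    nid <- rep(0L, length(fg))
    nid[ok] <- id[nb[ok, , drop = FALSE]]
    sel <- nid > 0L
    if (!any(sel)) next
    edges[[r]] <- rbind(which(sel), nid[sel])
    wts[[r]] <- rep(sqrt(sum((offs[r, ] * skeleton$spacing)^2)), sum(sel))
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el))
    g <- igraph::add_edges(g, as.vector(el),
                           weight = unlist(wts))
  list(graph = g, coords = coords, id = id)
}

#' Order the skeleton into a start-to-end centerline
#'
#' Traverses the 26-adjacency graph of skeleton voxels from `start` to `end`.
#' For a clean two-endpoint skeleton this visits every voxel once; when
#' spurious side branches are present the Euclidean-weighted shortest path is
#' taken, side branches are dropped, and a `spur_dropped` warning is
#' recorded. World coordinates are computed through the volume affine.
#'
#' @param skeleton A `skeleton_mask`.
#' @param start,end 0-based voxel indices (length-3 integer vectors), usually
#'   rows of [find_endpoints()].
#' @return A `centerline_path` tibble with 0-based voxel indices (`i`, `j`,
#'   `k`) and world coordinates (`x`, `y`, `z`, mm); attributes record the
#'   endpoint count and any degradation warnings.
#' @export
order_path <- function(skeleton, start, end) {
  sg <- skeleton_graph(skeleton)
  vs <- sg$id[matrix(as.integer(start) + 1L, 1)]
  ve <- sg$id[matrix(as.integer(end) + 1L, 1)]
  if (is.na(vs) || is.na(ve) || vs == 0L || ve == 0L)
    stop_tortr("start/end are not skeleton voxels", "invalid_spec")
  sp <- suppressWarnings(igraph::shortest_paths(sg$graph, from = vs, to = ve,
                                                output = "vpath"))
  vpath <- sp$vpath[[1]]
  if (length(vpath) == 0)
    stop_tortr("start and end voxels are not connected on the skeleton",
               "disconnection")
  warnings <- character()
  if (length(vpath) < nrow(sg$coords)) {
    warnings <- "spur_dropped"
    warn_tortr(sprintf(
      "path covers %d of %d skeleton voxels; side branches dropped",
      length(vpath), nrow(sg$coords)), "spur_dropped")
  }
  ijk <- sg$coords[as.integer(vpath), , drop = FALSE] - 1L
  vol <- list(affine = skeleton$affine)
  xyz <- voxel_to_world(vol, ijk)
  out <- tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  structure(out, class = c("centerline_path", class(out)),
            warnings = warnings, spacing = skeleton$spacing,
            n_skeleton_voxels = nrow(sg$coords))
}

#' Recenter a centerline at sub-voxel precision
#'
#' Skeleton voxels lie on the grid, so an ordered path through them carries
#' quantization jitter of roughly half a voxel that inflates
#' squared-curvature metrics. This pass restores sub-voxel accuracy using
#' the mask itself: each path point is moved to the centroid of the
#' foreground voxel centers inside a thin slab perpendicular to the local
#' path tangent, with the correction restricted to the plane normal to the
#' tangent (so the path is not shortened) and capped at one voxel per pass.
#' The slab radius adapts to the local vessel radius, estimated from the
#' distance to the nearest background voxel.
#'
#' @param path A `centerline_path` from [order_path()].
#' @param mask The binary [label_volume()] the skeleton came from.
#' @param passes Number of recentering sweeps (2 is enough in practice).
#' @return The path with updated world coordinates (voxel indices are kept
#'   as the original skeleton voxels).
#' @export
recenter_path <- function(path, mask, passes = 2) {
  vox <- mask$voxels > 0
  dims <- dim(vox)
  sp0 <- mean(mask$spacing)
  fg <- which(vox)
  Fg <- voxel_to_world(mask, arrayInd(fg, dims) - 1L)
  mat <- as.matrix(path[, c("x", "y", "z")])
  n <- nrow(mat)
  # local vessel radius: distance from each path voxel to nearest background
  r_max <- 4  # mm; generous for intracranial arteries
  hw <- as.integer(ceiling(r_max / mask$spacing)) + 1L
  radius <- vapply(seq_len(n), function(ii) {
    ctr <- c(path$i[ii], path$j[ii], path$k[ii]) + 1L
    lo <- pmax(ctr - hw, 1L); hi <- pmin(ctr + hw, dims)
    win <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    bg <- which(!win)
    if (length(bg) == 0) return(r_max)
    bijk <- sweep(arrayInd(bg, dim(win)), 2, 2L - lo)  # back to 0-based
    bw <- voxel_to_world(mask, bijk)
    sqrt(min(colSums((t(bw) - mat[ii, ])^2)))
  }, numeric(1))
  radius <- pmin(pmax(radius + 0.5 * sp0, 1.5 * sp0), r_max)
  for (p in seq_len(passes)) {
    out <- mat
    for (ii in seq_len(n)) {
      a <- max(1, ii - 2); b <- min(n, ii + 2)
      tg <- mat[b, ] - mat[a, ]
      nt <- sqrt(sum(tg^2)); if (nt == 0) next
      tg <- tg / nt
      d <- sweep(Fg, 2, mat[ii, ])
      proj <- as.vector(d %*% tg)
      r2 <- rowSums(d^2) - proj^2
      sel <- abs(proj) <= 0.75 * sp0 & r2 <= radius[ii]^2
      if (sum(sel) < 3) next
      delta <- colMeans(Fg[sel, , drop = FALSE]) - mat[ii, ]
      delta <- delta - sum(delta * tg) * tg
      nd <- sqrt(sum(delta^2))
      if (nd > sp0) delta <- delta * sp0 / nd
      out[ii, ] <- mat[ii, ] + delta
    }
    mat <- out
  }
  path$x <- mat[, 1]; path$y <- mat[, 2]; path$z <- mat[, 3]
  attr(path, "recentered") <- passes
  path
}

#' Extract an ordered centerline for one label
#'
#' Composes [binarize()], [skeletonize3d()], [find_endpoints()] and
#' [order_path()]. With more than two endpoints the endpoint pair with the
#' maximal geodesic path length is used (spurs are dropped with a warning);
#' the start is the lexicographically smaller endpoint, a purely cosmetic
#' choice since all metrics are reversal-invariant.
#'
#' @inheritParams skeletonize3d
#' @param volume A [label_volume()].
#' @param label Integer label of the target artery.
#' @param recenter Apply sub-voxel [recenter_path()] to the ordered path
#'   (default `TRUE`).
#' @return A `centerline_path` (see [order_path()]).
#' @export
extract_centerline <- function(volume, label = 1L, keep_largest = FALSE,
                               recenter = TRUE) {
  mask <- binarize(volume, label)
  skel <- skeletonize3d(mask, keep_largest = keep_largest)
  eps <- find_endpoints(skel)
  warnings <- character()
  if (skel$kept_largest) warnings <- c(warnings, "kept_largest_component")
  if (nrow(eps) > 2) {
    warnings <- c(warnings, "multiple_endpoints")
    warn_tortr(sprintf("skeleton has %d endpoints; using the farthest pair",
                       nrow(eps)), "multiple_endpoints")
    sg <- skeleton_graph(skel)
    vids <- sg$id[eps + 1L]
    dd <- igraph::distances(sg$graph, v = vids, to = vids)
    best <- which(dd == max(dd[is.finite(dd)]), arr.ind = TRUE)[1, ]
    pair <- eps[sort(best), , drop = FALSE]
  } else {
    pair <- eps
  }
  path <- order_path(skel, pair[1, ], pair[2, ])
  if (recenter) path <- recenter_path(path, mask)
  attr(path, "warnings") <- unique(c(warnings, attr(path, "warnings")))
  attr(path, "n_endpoints") <- nrow(eps)
  path
}
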