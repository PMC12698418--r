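# Collagen segmentation: image -> mask -> skeleton -> traced fibers and
# crosslink points.
#
# Conventions: pixel coordinates are (row, col) with origin at the top-left;
# internally 1-based (R), exported JSON is 0-based. 8-connectivity throughout.

#' Collapse a multi-channel image to grayscale
#'
#' Three-channel input is collapsed by the unweighted channel mean;
#' single-channel input passes through unchanged.
#'
#' @param x numeric matrix (gray) or 3-d array with 3 channels in the third
#'   dimension, or an [roi_image()].
#' @param pixel_size_um pixel size, um/pixel (ignored when `x` is already an
#'   `roi_image`).
#' @param source_id identifier carried into the result.
#' @return an [roi_image()].
#' @export
to_grayscale <- function(x, pixel_size_um = 1, source_id = "") {
  if (inherits(x, "roi_image")) return(x)
  if (is.matrix(x)) return(roi_image(x, pixel_size_um, source_id))
  d <- dim(x)
  if (length(d) == 3 && d[3] == 3) {
    g <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
    return(roi_image(g, pixel_size_um, source_id))
  }
  if (length(d) == 3 && d[3] == 1) {
    return(roi_image(x[, , 1], pixel_size_um, source_id))
  }
  stop("expected a 1- or 3-channel image, got ",
       if (length(d) == 3) paste0(d[3], " channels") else "unsupported dims")
}

#' Segment collagen by global Otsu thresholding
#'
#' Applies Otsu's threshold to the gray histogram, then removes connected
#' components smaller than `min_object_px` pixels. A constant or effectively
#' empty image yields an empty mask with a warning rather than an error.
#'
#' @param img an [roi_image()].
#' @param min_object_px minimum connected-component size kept, pixels.
#' @return object of class `collagen_mask`: `mask` (logical matrix),
#'   `pixel_size_um`, `collagen_area_um2`, `threshold`, `degenerate` flag.
#' @export
segment_collagen <- function(img, min_object_px = 16) {
  stopifnot(inherits(img, "roi_image"))
  g <- img$pixels
  rng <- range(g)
  degenerate <- FALSE
  if (diff(rng) < .Machine$double.eps) {
    warning("constant image: empty collagen mask")
    mask <- matrix(FALSE, nrow(g), ncol(g))
    degenerate <- TRUE
    thr <- NA_real_
  } else {
    thr <- EBImage::otsu(EBImage::Image(t(g)), range = rng, levels = 256)
    mask <- g > thr
    if (min_object_px > 1 && any(mask)) {
      lab <- label_components8(mask)
      sz <- tabulate(lab[lab > 0])
      keep <- which(sz >= min_object_px)
      mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    }
    if (!any(mask)) {
      warning("no collagen detected: empty mask")
      degenerate <- TRUE
    }
  }
  structure(list(mask = mask, pixel_size_um = img$pixel_size_um,
                 collagen_area_um2 = sum(mask) * img$pixel_size_um^2,
                 threshold = thr, degenerate = degenerate),
            class = "collagen_mask")
}

# 8-connected component labels of a logical matrix. (EBImage::bwlabel is
# 4-connected, which would split diagonal fiber runs.)
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  nr <- nrow(mask)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    a <- id
    b <- shift_mat(id, off[1], off[2])
    sel <- a > 0L & b > 0L
    if (any(sel)) edges <- rbind(edges, cbind(a[sel], b[sel]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) -
                                       igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(idx)]
  }
  lab[idx] <- as.integer(comp)
  lab
}

# Shift a matrix by (dr, dc), zero-filling: out[i, j] = m[i + dr, j + dc].
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
  if (r0 <= r1 && c0 <= c1) {
    out[r0:r1, c0:c1] <- m[(r0:r1) + dr, (c0:c1) + dc]
  }
  out
}

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels under the Zhang-Suen conditions until
#' stable, yielding a 1-pixel-wide, 8-connected skeleton contained in the
#' mask.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_thin(mask)
}

# --- skeleton graph machinery (internal) -------------------------------------
# Skeletons are handled as linear indices into a 1-pixel zero-padded copy so
# neighbour arithmetic needs no bounds checks.

pad_skeleton <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- S
  P
}

skeleton_degree <- function(P) {
  Nr <- nrow(P)
  offs <- c(-1L, 1L, -Nr, Nr, -Nr - 1L, -Nr + 1L, Nr - 1L, Nr + 1L)
  deg <- matrix(0L, nrow(P), ncol(P))
  idx <- which(P)
  for (o in offs) deg[idx] <- deg[idx] + P[idx + o]
  deg
}

# Walk along a degree-2 chain starting at `start` stepping into `nxt`.
# Stops on a pixel with degree != 2, or when returning to `start` (cycle).
# Returns the path of linear indices including both terminals.
walk_chain <- function(P, deg, offs, start, nxt, maxlen = sum(P) + 2L) {
  path <- integer(maxlen)
  path[1L] <- start
  path[2L] <- nxt
  k <- 2L
  prev <- start
  cur <- nxt
  while (deg[cur] == 2L && cur != start && k < maxlen) {
    nbr <- cur + offs
    nbr <- nbr[P[nbr] & nbr != prev]
    if (length(nbr) == 0) break
    prev <- cur
    cur <- nbr[1]
    k <- k + 1L
    path[k] <- cur
  }
  path[seq_len(k)]
}

# Decompose a skeleton into segments between junction nodes (degree >= 3) and
# endpoints (degree 1), plus isolated cycles. Returns a list with the padded
# skeleton, degrees, node linear indices and a list of segment index paths.
skeleton_segments <- function(S) {
  P <- pad_skeleton(S)
  Nr <- nrow(P)
  offs <- c(-1L, 1L, -Nr, Nr, -Nr - 1L, -Nr + 1L, Nr - 1L, Nr + 1L)
  deg <- skeleton_degree(P)
  is_node <- P & deg >= 3L
  nodes <- which(is_node)
  visited <- matrix(FALSE, nrow(P), ncol(P))
  maxlen <- sum(P) + 2L
  segs <- vector("list", 256L)
  nseg <- 0L
  add_seg <- function(path) {
    nseg <<- nseg + 1L
    if (nseg > length(segs)) length(segs) <<- 2L * nseg # grow geometrically
    segs[[nseg]] <<- path
  }

  for (nd in nodes) {
    for (o in offs) {
      m <- nd + o
      if (!P[m]) next
      if (is_node[m]) {
        if (nd < m) add_seg(c(nd, m))
      } else if (!visited[m]) {
        path <- walk_chain(P, deg, offs, nd, m, maxlen)
        interior <- path[!is_node[path]]
        visited[interior] <- TRUE
        add_seg(path)
      }
    }
  }
  ends <- which(P & deg == 1L)
  for (e in ends) {
    if (visited[e]) next
    visited[e] <- TRUE
    nbr <- e + offs
    nbr <- nbr[P[nbr]]
    if (length(nbr) == 0) { add_seg(e); next } # isolated pixel
    path <- walk_chain(P, deg, offs, e, nbr[1], maxlen)
    visited[path[!is_node[path]]] <- TRUE
    add_seg(path)
  }
  # remaining unvisited degree-2 pixels form closed cycles
  left <- which(P & deg == 2L & !visited)
  while (length(left) > 0) {
    s <- left[1]
    nbr <- s + offs
    nbr <- nbr[P[nbr]]
    path <- walk_chain(P, deg, offs, s, nbr[1], maxlen)
    visited[path] <- TRUE
    add_seg(path)
    left <- which(P & deg == 2L & !visited)
  }
  list(P = P, deg = deg, offs = offs, is_node = is_node, nodes = nodes,
       segments = segs[seq_len(nseg)])
}

idx_to_rc <- function(idx, Nr) {
  # padded linear index -> unpadded (row, col)
  cbind(((idx - 1L) %% Nr) + 1L - 1L, ((idx - 1L) %/% Nr) + 1L - 1L)
}

# Remove spurs: endpoint-to-junction chains shorter than spur_min_um. Walks
# only from endpoints, so each pass costs O(spur pixels), and iterates until
# stable (spur removal can expose new endpoints).
prune_spurs <- function(S, pixel_size_um, spur_min_um, max_iter = 10L) {
  max_px <- as.integer(ceiling(spur_min_um / pixel_size_um)) + 2L
  for (it in seq_len(max_iter)) {
    P <- pad_skeleton(S)
    Nr <- nrow(P)
    offs <- c(-1L, 1L, -Nr, Nr, -Nr - 1L, -Nr + 1L, Nr - 1L, Nr + 1L)
    deg <- skeleton_degree(P)
    ends <- which(P & deg == 1L)
    removed <- FALSE
    for (e in ends) {
      nbr <- e + offs
      nbr <- nbr[P[nbr]]
      if (length(nbr) == 0) next
      path <- walk_chain(P, deg, offs, e, nbr[1], maxlen = max_px + 2L)
      term <- path[length(path)]
      if (deg[term] < 3L) next # endpoint-endpoint chain, not a spur
      rc <- idx_to_rc(path, Nr)
      len <- sum(sqrt(diff(rc[, 1])^2 + diff(rc[, 2])^2)) * pixel_size_um
      if (len < spur_min_um && length(path) <= max_px) {
        drop <- idx_to_rc(path[-length(path)], Nr)
        S[drop] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  S
}

# Cluster integer-coordinate points by single-linkage at radius h: 8-adjacent
# node pixels always collapse (one structural junction), and nodes within
# node_merge_um merge spatially. Connected components of the radius graph,
# with edges found by vectorized grid shifts (points are pixel coordinates).
cluster_points_radius <- function(rc, h) {
  n <- nrow(rc)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
  id <- matrix(0L, max(rc[, 1]) - r0 + 1L, max(rc[, 2]) - c0 + 1L)
  id[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- seq_len(n)
  hh <- floor(h)
  edges <- vector("list", 0)
  for (dr in 0:hh) {
    for (dc in -hh:hh) {
      if (dr == 0 && dc <= 0) next # forward half-plane only
      if (dr^2 + dc^2 > h^2) next
      b <- shift_mat(id, dr, dc)
      sel <- id > 0L & b > 0L
      if (any(sel)) edges[[length(edges) + 1L]] <- cbind(id[sel], b[sel])
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) return(seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  as.integer(igraph::components(g)$membership)
}

cluster_nodes <- function(node_rc, pixel_size_um, node_merge_um) {
  n <- nrow(node_rc)
  if (n == 0) return(list(id = integer(0), centers = matrix(0, 0, 2)))
  if (n == 1) return(list(id = 1L, centers = node_rc))
  h <- max(node_merge_um / pixel_size_um, sqrt(2) + 1e-6)
  cl <- cluster_points_radius(node_rc, h)
  centers <- t(vapply(seq_len(max(cl)), function(k) {
    colMeans(node_rc[cl == k, , drop = FALSE])
  }, numeric(2)))
  list(id = cl, centers = centers)
}

# Moving-average smoothing of a pixel path: suppresses the staircase zigzag
# of 8-connected skeleton walks, which otherwise inflates path length (and so
# deflates straightness) by up to ~8% for oblique fibers. Window edges keep
# the raw coordinates.
smooth_path <- function(rc, w = 5L) {
  n <- nrow(rc)
  if (n <= w) return(rc)
  sr <- as.vector(stats::filter(rc[, 1], rep(1 / w, w)))
  sc <- as.vector(stats::filter(rc[, 2], rep(1 / w, w)))
  bad <- is.na(sr)
  sr[bad] <- rc[bad, 1]
  sc[bad] <- rc[bad, 2]
  cbind(sr, sc)
}

# Direction of a segment at one of its terminals, pointing away from the
# terminal into the segment. Angle in (-pi, pi], math convention (row axis
# points down, so dy = -(dr)).
end_direction <- function(rc, from_start, k = 7L) {
  n <- nrow(rc)
  k <- min(k, n)
  if (from_start) {
    v <- rc[k, ] - rc[1, ]
  } else {
    v <- rc[n - k + 1L, ] - rc[n, ]
  }
  atan2(-v[1], v[2])
}

#' Trace fibers and detect crosslinks from a collagen mask
#'
#' Skeletonizes the mask, prunes short spurs, decomposes the skeleton into
#' segments between junction nodes (skeleton pixels with >= 3 neighbours,
#' 8-connectivity) and endpoints, and greedily merges segments across
#' junctions when the continuation bends by at most `merge_angle_tol`
#' degrees, so that crossing fibers are traced through their intersection.
#' Fiber width is twice the mean Euclidean distance-transform value along the
#' centerline; orientation is the doubled-angle mean axis of the centerline
#' steps; straightness is endpoint chord length over path length.
#'
#' @param mask a `collagen_mask` from [segment_collagen()].
#' @param img the source [roi_image()] (used for metadata only).
#' @param spur_min_um skeleton spurs shorter than this are pruned, um.
#' @param node_merge_um junction nodes closer than this collapse to their
#'   centroid, um.
#' @param merge_angle_tol maximum bend for merging segments across a
#'   junction, degrees.
#' @param fiber_min_um traced fibers shorter than this are discarded, um.
#' @return object of class `fiber_set`: `fibers` (list with `centerline`
#'   (row, col) pixel matrix, `length_um`, `mean_width_um`, `straightness`,
#'   `orientation`), `crosslinks` ((row, col) pixel matrix), `skeleton`
#'   (logical matrix), `pixel_size_um`, and the tracing parameters.
#' @export
extract_fibers <- function(mask, img = NULL,
                           spur_min_um = 4, node_merge_um = 3,
                           merge_angle_tol = 20, fiber_min_um = 10) {
  stopifnot(inherits(mask, "collagen_mask"))
  px <- mask$pixel_size_um
  params <- list(spur_min_um = spur_min_um, node_merge_um = node_merge_um,
                 merge_angle_tol = merge_angle_tol, fiber_min_um = fiber_min_um)
  empty <- structure(list(fibers = list(), crosslinks = matrix(0, 0, 2),
                          raw_nodes = matrix(0, 0, 2),
                          skeleton = matrix(FALSE, nrow(mask$mask),
                                            ncol(mask$mask)),
                          pixel_size_um = px, params = params),
                     class = "fiber_set")
  if (!any(mask$mask)) return(empty)

  S <- skeletonize(mask$mask)
  S <- prune_spurs(S, px, spur_min_um)
  if (!any(S)) return(empty)
  sg <- skeleton_segments(S)
  Nr <- nrow(sg$P)
  node_rc <- idx_to_rc(sg$nodes, Nr)
  cl <- cluster_nodes(node_rc, px, node_merge_um)

  seg_rc <- lapply(sg$segments, idx_to_rc, Nr = Nr)
  nseg <- length(seg_rc)
  if (nseg == 0) return(empty)

  # terminal pixel of each segment end, its cluster id (NA when the terminal
  # is an endpoint rather than a junction node) and its away-direction
  term_px <- cbind(
    vapply(sg$segments, `[`, integer(1), 1L),
    vapply(sg$segments, function(p) p[length(p)], integer(1))
  )
  term_cluster <- matrix(cl$id[match(term_px, sg$nodes)], nseg, 2)
  term_dir <- matrix(NA_real_, nseg, 2)
  for (s in seq_len(nseg)) {
    term_dir[s, 1] <- end_direction(seg_rc[[s]], from_start = TRUE)
    term_dir[s, 2] <- end_direction(seg_rc[[s]], from_start = FALSE)
  }

  # Greedy continuation pairing at each junction cluster: two segment ends
  # merge when their away-directions are anti-parallel within tolerance.
  tol <- merge_angle_tol * pi / 180
  links <- list() # each: c(seg1, end1, seg2, end2)
  cluster_of_end <- as.vector(term_cluster) # column-major over nseg x 2
  for (ends in split(seq_len(2L * nseg), cluster_of_end)) {
    if (length(ends) < 2) next
    seg_i <- ((ends - 1L) %% nseg) + 1L
    end_i <- ((ends - 1L) %/% nseg) + 1L
    dirs <- term_dir[cbind(seg_i, end_i)]
    d <- abs(outer(dirs, dirs, "-")) %% (2 * pi)
    cost <- abs(pi - pmin(d, 2 * pi - d)) # 0 = perfectly anti-parallel
    cost[outer(seg_i, seg_i, "==")] <- Inf # no self-closure, no diagonal
    repeat {
      m <- which.min(cost)
      if (length(m) == 0 || cost[m] > tol) break
      i <- ((m - 1L) %% length(ends)) + 1L
      j <- ((m - 1L) %/% length(ends)) + 1L
      links[[length(links) + 1L]] <-
        c(seg_i[i], end_i[i], seg_i[j], end_i[j])
      cost[c(i, j), ] <- Inf
      cost[, c(i, j)] <- Inf
    }
  }

  # Assemble fibers: segments chained through links.
  link_of <- matrix(0L, nseg, 2) # index into links, 0 = free
  for (li in seq_along(links)) {
    l <- links[[li]]
    link_of[l[1], l[2]] <- li
    link_of[l[3], l[4]] <- li
  }
  used <- rep(FALSE, nseg)
  fibers_rc <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    # find a free end to start from (fall back to end 1 for pure cycles)
    start_end <- if (link_of[s0, 1] == 0L) 1L else if (link_of[s0, 2] == 0L)
      2L else 1L
    coords <- NULL
    s <- s0; enter <- start_end
    repeat {
      used[s] <- TRUE
      rc <- seg_rc[[s]]
      if (enter == 2L) rc <- rc[rev(seq_len(nrow(rc))), , drop = FALSE]
      coords <- rbind(coords, rc)
      exit <- if (enter == 1L) 2L else 1L
      li <- link_of[s, exit]
      if (li == 0L) break
      l <- links[[li]]
      nxt <- if (l[1] == s && l[2] == exit) c(l[3], l[4]) else c(l[1], l[2])
      if (used[nxt[1]]) break # closed a cycle
      s <- nxt[1]; enter <- nxt[2]
    }
    fibers_rc[[length(fibers_rc) + 1L]] <- coords
  }

  dm <- EBImage::distmap(mask$mask)
  fibers <- list()
  for (rc in fibers_rc) {
    if (nrow(rc) < 2) next
    sm <- smooth_path(rc)
    dr <- diff(sm[, 1]); dc <- diff(sm[, 2])
    step <- sqrt(dr^2 + dc^2)
    len_um <- sum(step) * px
    if (len_um < fiber_min_um) next
    keep <- step > 0
    theta <- (atan2(-dr[keep], dc[keep])) %% pi
    chord <- sqrt((sm[nrow(sm), 1] - sm[1, 1])^2 +
                    (sm[nrow(sm), 2] - sm[1, 2])^2) * px
    w <- 2 * mean(dm[rc]) * px
    fibers[[length(fibers) + 1L]] <- list(
      centerline = rc,
      length_um = len_um,
      mean_width_um = w,
      straightness = min(1, if (sum(step) > 0) chord / (sum(step) * px) else 1),
      orientation = axial_mean(theta, step[keep])
    )
  }

  centers <- cl$centers
  colnames(centers) <- c("row", "col")
  structure(list(fibers = fibers, crosslinks = centers,
                 raw_nodes = node_rc, skeleton = S,
                 pixel_size_um = px, params = params),
            class = "fiber_set")
}

#' Crosslink points of a fiber set
#'
#' Crosslinks are the junction nodes of the spur-pruned skeleton; nodes
#' closer than `node_merge_um` (and structurally adjacent node pixels) are
#' collapsed to their centroid.
#'
#' @param fibers a `fiber_set` from [extract_fibers()].
#' @param node_merge_um merge radius, um; defaults to the value used at
#'   tracing time.
#' @return matrix of crosslink (row, col) pixel coordinates.
#' @export
detect_crosslinks <- function(fibers, node_merge_um = NULL) {
  stopifnot(inherits(fibers, "fiber_set"))
  node_merge_um <- node_merge_um %||% fibers$params$node_merge_um
  cl <- cluster_nodes(fibers$raw_nodes, fibers$pixel_size_um, node_merge_um)
  centers <- cl$centers
  colnames(centers) <- c("row", "col")
  centers
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set: %d fibers, %d crosslinks, %.3f um/px>\n",
              length(x$fibers), nrow(x$crosslinks), x$pixel_size_um))
  invisible(x)
}

#' Export a fiber set as JSON
#'
#' Coordinates are written 0-based (row, col) in pixels alongside um-scaled
#' per-fiber summaries.
#'
#' @param fibers a `fiber_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber_set <- function(fibers, path) {
  out <- list(
    pixel_size_um = fibers$pixel_size_um,
    params = fibers$params,
    n_fibers = length(fibers$fibers),
    crosslinks_rc0 = if (nrow(fibers$crosslinks) > 0)
      unname(fibers$crosslinks - 1) else list(),
    fibers = lapply(fibers$fibers, function(f) list(
      length_um = f$length_um, mean_width_um = f$mean_width_um,
      straightness = f$straightness, orientation = f$orientation,
      centerline_rc0 = unname(f$centerline - 1L)
    ))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
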