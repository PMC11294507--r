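# Low-level binary morphology on logical matrices/arrays.
# Connectivity conventions used throughout: 8-neighbour in 2D, 26-neighbour
# in 3D for foreground; 4-neighbour for background when filling holes.
# 2D slice matrices are indexed (x, z): rows run left-right, columns
# caudal-cranial.

neighbour_offsets <- function(ndim, connectivity) {
  off <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), ndim)))
  dimnames(off) <- NULL
  nz <- rowSums(off != 0L)
  keep <- switch(as.character(connectivity),
    "4" = nz == 1L & ndim == 2L,
    "8" = nz >= 1L,
    "6" = nz == 1L,
    "26" = nz >= 1L,
    stop("unsupported connectivity: ", connectivity)
  )
  off[keep, , drop = FALSE]
}

# Label connected components of a coordinate list (n x d integer matrix,
# 1-based positions inside a grid of dimension `dims`). Returns an integer
# membership vector aligned with the rows of `coords`.
label_coords <- function(coords, dims, connectivity) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  mult <- cumprod(c(1, dims[-length(dims)]))
  key <- as.numeric(coords %*% mult)
  off <- neighbour_offsets(ncol(coords), connectivity)
  okey <- as.numeric(off %*% mult)
  edges <- vector("list", length(okey))
  for (i in seq_along(okey)) {
    j <- match(key + okey[i], key)
    ok <- which(!is.na(j))
    if (length(ok)) edges[[i]] <- cbind(ok, j[ok])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) return(seq_len(n))
  g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Components of a logical matrix; returns an integer label matrix (0 = bg).
label_components_2d <- function(m, connectivity = 8L) {
  lab <- matrix(0L, nrow(m), ncol(m))
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(lab)
  lab[m] <- label_coords(idx, dim(m), connectivity)
  lab
}

label_components_3d <- function(a, connectivity = 26L) {
  idx <- which(a, arr.ind = TRUE)
  memb <- label_coords(idx, dim(a), connectivity)
  list(coords = idx, membership = memb)
}

# Keep the largest 26-connected component of a logical 3D array.
largest_component_3d <- function(a) {
  lab <- label_components_3d(a)
  if (length(lab$membership) == 0L) return(a)
  sizes <- tabulate(lab$membership)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # deterministic tie-break: component holding the first voxel in
    # column-major scan order
    first <- vapply(best, function(k) min(which(lab$membership == k)), integer(1))
    best <- best[which.min(first)]
  }
  out <- array(FALSE, dim(a))
  out[lab$coords[lab$membership == best, , drop = FALSE]] <- TRUE
  out
}

# Binary dilation by a 3x3 square structuring element (shift-OR).
dilate_3x3 <- function(m) {
  nx <- nrow(m); nz <- ncol(m)
  p <- matrix(FALSE, nx + 2L, nz + 2L)
  acc <- matrix(FALSE, nx + 2L, nz + 2L)
  for (dx in 0:2) for (dz in 0:2) {
    q <- matrix(FALSE, nx + 2L, nz + 2L)
    q[dx + seq_len(nx), dz + seq_len(nz)] <- m
    acc <- acc | q
  }
  acc[2:(nx + 1L), 2:(nz + 1L)]
}

# Fill the holes of a logical matrix: background is 4-connected, so an
# 8-connected closed curve seals its interior. Returns curve + interior.
fill_holes_2d <- function(m) {
  bg <- !m
  lab <- label_components_2d(bg, connectivity = 4L)
  if (!any(bg)) return(m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  m | (lab != 0L & !(lab %in% border))
}

# Voxels of a digital straight segment between two integer points (n x 2).
# Sampling is symmetric: exact half-integer crossings include both cells,
# so the set is invariant under reflection and translation.
line_voxels <- function(p, q) {
  d <- q - p
  n <- max(abs(d))
  if (n == 0L) return(matrix(p, 1L, 2L))
  t <- seq_len(n - 1L) / n
  fx <- t * d[1]; fz <- t * d[2]
  rx <- cbind(floor(fx + 0.5), ceiling(fx - 0.5))
  rz <- cbind(floor(fz + 0.5), ceiling(fz - 0.5))
  pts <- rbind(
    cbind(rx[, 1], rz[, 1]), cbind(rx[, 1], rz[, 2]),
    cbind(rx[, 2], rz[, 1]), cbind(rx[, 2], rz[, 2])
  )
  pts <- unique(pts)
  pts <- cbind(pts[, 1] + p[1], pts[, 2] + p[2])
  unique(rbind(matrix(p, 1L, 2L), pts, matrix(q, 1L, 2L)))
}

# Scan-order key sorting voxels by z then x (the tie-break frame).
scan_key <- function(coords, nx) (coords[, 2] - 1) * nx + coords[, 1]

# Order the voxels of a thin curve into a path by greedy walking.
# coords: n x 2 (x, z). If the set is an open 8-connected curve the walk
# starts at an endpoint (exactly one neighbour); a closed curve starts at
# the smallest scan-order voxel. 4-neighbours are preferred over diagonals
# so 1-voxel-thick curves trace without skipping. Voxels unreachable from
# the walk (spurs of thick corners) are dropped.
trace_path <- function(coords, nx) {
  n <- nrow(coords)
  if (n <= 1L) return(coords)
  key <- (coords[, 2] + 1) * (nx + 3) + coords[, 1]   # unique per voxel
  nb_count <- integer(n)
  off <- neighbour_offsets(2L, 8L)
  okey <- (off[, 2]) * (nx + 3) + off[, 1]
  nbr <- matrix(NA_integer_, n, 8L)
  for (i in seq_len(8L)) {
    j <- match(key + okey[i], key)
    nbr[, i] <- j
    nb_count <- nb_count + !is.na(j)
  }
  diag4 <- rowSums(abs(off)) == 1L
  sk <- scan_key(coords, nx)
  ends <- which(nb_count == 1L)
  start <- if (length(ends)) ends[which.min(sk[ends])] else which.min(sk)
  visited <- logical(n)
  order_out <- integer(n)
  stack <- integer(n)
  visited[start] <- TRUE; order_out[1] <- start; len <- 1L
  stack[1] <- start; top <- 1L
  while (top > 0L) {
    cur <- stack[top]
    cand <- nbr[cur, ]
    cand <- cand[!is.na(cand)]
    cand <- cand[!visited[cand]]
    if (!length(cand)) { top <- top - 1L; next }
    if (length(cand) > 1L) {
      is4 <- cand %in% nbr[cur, diag4]
      if (any(is4)) cand <- cand[is4]
      cand <- cand[which.min(sk[cand])]
    }
    visited[cand] <- TRUE
    len <- len + 1L
    order_out[len] <- cand
    top <- top + 1L
    stack[top] <- cand
  }
  coords[order_out[seq_len(len)], , drop = FALSE]
}
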