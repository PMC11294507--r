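# Independent brute-force oracles, written with explicit loops/BFS so they
# share no code path with the package implementation.

bf_dilate3x3 <- function(m) {
  nx <- nrow(m); nz <- ncol(m)
  out <- matrix(FALSE, nx, nz)
  for (i in seq_len(nx)) for (j in seq_len(nz)) {
    if (!m[i, j]) next
    for (di in -1:1) for (dj in -1:1) {
      a <- i + di; b <- j + dj
      if (a >= 1 && a <= nx && b >= 1 && b <= nz) out[a, b] <- TRUE
    }
  }
  out
}

bf_outline <- function(m) bf_dilate3x3(m) & !m

# BFS connected-component labelling of a logical matrix.
bf_label2d <- function(m, conn = 8L) {
  nx <- nrow(m); nz <- ncol(m)
  lab <- matrix(0L, nx, nz)
  nextlab <- 0L
  offs <- if (conn == 8L) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  }
  for (i in seq_len(nx)) for (j in seq_len(nz)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    nextlab <- nextlab + 1L
    queue <- list(c(i, j)); lab[i, j] <- nextlab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        a <- p[1] + o[1]; b <- p[2] + o[2]
        if (a >= 1 && a <= nx && b >= 1 && b <= nz &&
            m[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- nextlab
          queue[[length(queue) + 1L]] <- c(a, b)
        }
      }
    }
  }
  lab
}

bf_largest2d <- function(m) {
  lab <- bf_label2d(m, 8L)
  k <- max(lab)
  if (k <= 1L) return(m)
  sizes <- integer(k)
  for (g in seq_len(k)) sizes[g] <- sum(lab == g)
  best <- 0L; bestsize <- -1L; bestkey <- Inf
  for (g in seq_len(k)) {
    idx <- which(lab == g, arr.ind = TRUE)
    key <- min((idx[, 2] - 1) * nrow(m) + idx[, 1])  # z-then-x scan order
    if (sizes[g] > bestsize || (sizes[g] == bestsize && key < bestkey)) {
      best <- g; bestsize <- sizes[g]; bestkey <- key
    }
  }
  lab == best
}

# Spec rule for the costophrenic cut, re-derived independently.
# Returns NULL when the slice needs the fallback, else the unordered set of
# arc voxels as a logical matrix.
bf_cut <- function(outline, band_fraction = 0.25) {
  idx <- which(outline, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  x_min <- min(idx[, 1]); x_max <- max(idx[, 1])
  width <- x_max - x_min + 1L
  if (width < 4L) return(NULL)
  bw <- floor(band_fraction * width)
  if (bw < 1L) bw <- 1L
  pick <- function(cond, outermost_max) {
    sub <- idx[cond, , drop = FALSE]
    sub <- sub[sub[, 2] == min(sub[, 2]), , drop = FALSE]
    xs <- sub[, 1]
    x <- if (outermost_max) max(xs) else min(xs)
    sub[sub[, 1] == x, ][1:2]
  }
  r1 <- pick(idx[, 1] <= x_min + bw - 1L, outermost_max = FALSE)
  r2 <- pick(idx[, 1] >= x_max - bw + 1L, outermost_max = TRUE)
  cut <- outline
  cut[r1[1], r1[2]] <- FALSE
  cut[r2[1], r2[2]] <- FALSE
  lab <- bf_label2d(cut, 4L)
  if (max(lab) != 2L) return(NULL)
  n1 <- sum(lab == 1L); n2 <- sum(lab == 2L)
  if (n1 != n2) return(lab == which.min(c(n1, n2)))
  cidx <- which(cut, arr.ind = TRUE)
  caud <- cidx[cidx[, 2] == min(cidx[, 2]), , drop = FALSE]
  caud <- caud[caud[, 1] == min(caud[, 1]), ][1:2]
  lab == lab[caud[1], caud[2]]
}

# Digital straight segment via exact integer arithmetic (no floats):
# includes both cells at exact half-integer crossings.
bf_line <- function(p, q) {
  d <- q - p
  n <- max(abs(d))
  pts <- list(p)
  if (n > 0L) for (t in seq_len(n - 1L)) {
    cand_x <- unique(c((2L * t * d[1] + n) %/% (2L * n),
                       -((n - 2L * t * d[1]) %/% (2L * n))))
    cand_z <- unique(c((2L * t * d[2] + n) %/% (2L * n),
                       -((n - 2L * t * d[2]) %/% (2L * n))))
    for (x in cand_x) for (z in cand_z)
      pts[[length(pts) + 1L]] <- c(p[1] + x, p[2] + z)
  }
  pts[[length(pts) + 1L]] <- q
  unique(do.call(rbind, pts))
}

# Fill by BFS flood from the border over 4-connected background.
bf_fill <- function(curve) {
  nx <- nrow(curve); nz <- ncol(curve)
  outside <- matrix(FALSE, nx, nz)
  queue <- list()
  for (i in seq_len(nx)) for (j in c(1L, nz))
    if (!curve[i, j] && !outside[i, j]) { outside[i, j] <- TRUE; queue[[length(queue)+1L]] <- c(i, j) }
  for (j in seq_len(nz)) for (i in c(1L, nx))
    if (!curve[i, j] && !outside[i, j]) { outside[i, j] <- TRUE; queue[[length(queue)+1L]] <- c(i, j) }
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (o in list(c(-1,0), c(1,0), c(0,-1), c(0,1))) {
      a <- p[1] + o[1]; b <- p[2] + o[2]
      if (a >= 1 && a <= nx && b >= 1 && b <= nz &&
          !curve[a, b] && !outside[a, b]) {
        outside[a, b] <- TRUE
        queue[[length(queue) + 1L]] <- c(a, b)
      }
    }
  }
  curve | !outside
}

bf_stitch <- function(prev_path, cur_path, dims) {
  curve <- matrix(FALSE, dims[1], dims[2])
  curve[cur_path] <- TRUE
  if (is.null(prev_path)) return(curve)
  curve[prev_path] <- TRUE
  pe <- prev_path[c(1, nrow(prev_path)), , drop = FALSE]
  ce <- cur_path[c(1, nrow(cur_path)), , drop = FALSE]
  d2 <- function(a, b) sum((a - b)^2)
  if (d2(pe[1, ], ce[1, ]) + d2(pe[2, ], ce[2, ]) <=
      d2(pe[1, ], ce[2, ]) + d2(pe[2, ], ce[1, ])) {
    pair <- list(c(1, 1), c(2, 2))
  } else {
    pair <- list(c(1, 2), c(2, 1))
  }
  for (pr in pair) {
    seg <- bf_line(pe[pr[1], ], ce[pr[2], ])
    for (r in seq_len(nrow(seg))) {
      if (seg[r, 1] >= 1 && seg[r, 1] <= dims[1] &&
          seg[r, 2] >= 1 && seg[r, 2] <= dims[2])
        curve[seg[r, 1], seg[r, 2]] <- TRUE
    }
  }
  bf_fill(curve)
}

# Brute-force 1.5 IQR outlier rule with hand-rolled type-7 quartiles.
bf_quartile <- function(v, p) {
  x <- sort(v)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

bf_outliers <- function(v) {
  q1 <- bf_quartile(v, 0.25)
  q3 <- bf_quartile(v, 0.75)
  iqr <- q3 - q1
  v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr
}

# Random test fixtures ------------------------------------------------------

# Union of random discs: a blobby region whose outline exercises the
# morphology operators.
rand_blob <- function(nx = 48, nz = 48, ndisc = 3) {
  m <- matrix(FALSE, nx, nz)
  for (k in seq_len(ndisc)) {
    cx <- runif(1, 8, nx - 8); cz <- runif(1, 8, nz - 8)
    r <- runif(1, 3, 10)
    for (i in seq_len(nx)) for (j in seq_len(nz))
      if ((i - cx)^2 + (j - cz)^2 <= r^2) m[i, j] <- TRUE
  }
  m
}

# Random open 8-connected arc: a function graph z(x) with steps in {-1,0,1}.
rand_arc <- function(nx = 40, z0 = 20) {
  x0 <- sample(2:6, 1)
  x1 <- nx - sample(2:6, 1)
  xs <- x0:x1
  z <- cumsum(c(z0, sample(-1:1, length(xs) - 1L, replace = TRUE)))
  z <- pmin(pmax(z, 3), 38)
  cbind(xs, z)
}
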