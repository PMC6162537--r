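# Independent brute-force oracles used across the suite. These work by
# direct enumeration (explicit structuring-element offsets, flood fill,
# dense-grid ECDF evaluation) and never call the package's fast paths.

# Explicit voxel offsets of a physical-units ball of radius r. Ball
# membership uses the same inclusive tolerance as the package (offsets
# exactly on the sphere surface are inside), so tie handling matches.
ball_offsets <- function(r, spacing) {
  rv <- floor(r / spacing + 1e-6)
  g <- expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3])
  keep <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dx * spacing[3])^2 <= r^2 + 1e-9 * max(1, r^2)
  as.matrix(g[keep, , drop = FALSE])
}

# Erosion by explicit offsets; voxels outside the array are treated as
# foreground (same convention as the EDT-based path, which assumes the
# mask never touches the stack border).
brute_erode <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    ok <- TRUE
    for (j in seq_len(nrow(off))) {
      q <- p + off[j, ]
      if (all(q >= 1) && all(q <= d) && !mask[q[1], q[2], q[3]]) {
        ok <- FALSE
        break
      }
    }
    out[p[1], p[2], p[3]] <- ok
  }
  out
}

brute_dilate <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    for (j in seq_len(nrow(off))) {
      q <- p + off[j, ]
      if (all(q >= 1) && all(q <= d)) out[q[1], q[2], q[3]] <- TRUE
    }
  }
  out
}

brute_open <- function(mask, r, spacing) {
  off <- ball_offsets(r, spacing)
  brute_dilate(brute_erode(mask, off), off)
}

# 6-connected flood-fill component count (independent of cpp_label3d,
# which uses 26-connectivity; on the blocky ground-truth geometries used
# in tests the two agree).
brute_flood_count <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  count <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- arrayInd(cur, d)
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        q <- p + step
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1 + d[2] * (q[3] - 1))
        if (mask[qi] && !seen[qi]) {
          seen[qi] <- TRUE
          queue <- c(queue, qi)
        }
      }
    }
  }
  count
}

# Vectorized 26-connected flood-fill component count for full-size
# masks: BFS by repeated one-voxel box dilation (separable axis shifts
# compose to the full 26-neighbourhood). Independent of the package's
# stack-based C++ labeling.
flood_count_shift <- function(mask) {
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  mask <- mask[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
               drop = FALSE]
  d <- dim(mask)
  grow_axis <- function(m, ax) {
    out <- m
    n <- d[ax]
    if (n == 1L) return(out)
    if (ax == 1) {
      out[2:n, , ] <- out[2:n, , ] | m[1:(n - 1), , ]
      out[1:(n - 1), , ] <- out[1:(n - 1), , ] | m[2:n, , ]
    } else if (ax == 2) {
      out[, 2:n, ] <- out[, 2:n, ] | m[, 1:(n - 1), ]
      out[, 1:(n - 1), ] <- out[, 1:(n - 1), ] | m[, 2:n, ]
    } else {
      out[, , 2:n] <- out[, , 2:n] | m[, , 1:(n - 1)]
      out[, , 1:(n - 1)] <- out[, , 1:(n - 1)] | m[, , 2:n]
    }
    out
  }
  remaining <- mask
  count <- 0L
  while (any(remaining)) {
    count <- count + 1L
    cur <- array(FALSE, d)
    cur[which(remaining)[1]] <- TRUE
    n_cur <- 1L
    repeat {
      grown <- grow_axis(grow_axis(grow_axis(cur, 1), 2), 3) & remaining
      n_grown <- sum(grown)
      if (n_grown == n_cur) break
      cur <- grown
      n_cur <- n_grown
    }
    remaining <- remaining & !cur
  }
  count
}

# KS D by dense-grid ECDF evaluation.
brute_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  grid <- c(grid, grid - 1e-9)
  fx <- vapply(grid, function(g) mean(x <= g), 0)
  fy <- vapply(grid, function(g) mean(y <= g), 0)
  max(abs(fx - fy))
}

# Sphere mask helper for fixtures.
make_ball_mask <- function(dims, spacing, centre, r) {
  zc <- (seq_len(dims[1]) - 1) * spacing[1]
  yc <- (seq_len(dims[2]) - 1) * spacing[2]
  xc <- (seq_len(dims[3]) - 1) * spacing[3]
  a <- outer(outer((zc - centre[1])^2, (yc - centre[2])^2, `+`),
             (xc - centre[3])^2, `+`)
  array(a <= r^2, dims)
}
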