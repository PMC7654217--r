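# Independent brute-force oracles used across test files. These deliberately
# use naive per-element loops, not the package's vectorized code paths.

# Per-sample JPD quadrant classifier.
jpd_bruteforce <- function(a, b, frac = 0.10, per_muscle = TRUE,
                           floor = 1e-9) {
  if (max(a) < floor && max(b) < floor) {
    return(c(pct_isolated_a = 0, pct_isolated_b = 0,
             pct_coco_high = 0, pct_coco_low = 100))
  }
  th_a <- if (per_muscle) frac * max(a) else frac * max(max(a), max(b))
  th_b <- if (per_muscle) frac * max(b) else th_a
  counts <- c(0, 0, 0, 0)
  for (i in seq_along(a)) {
    aa <- a[i] > th_a
    bb <- b[i] > th_b
    q <- if (aa && !bb) 1 else if (!aa && bb) 2 else if (aa && bb) 3 else 4
    counts[q] <- counts[q] + 1
  }
  stats::setNames(100 * counts / length(a),
                  c("pct_isolated_a", "pct_isolated_b",
                    "pct_coco_high", "pct_coco_low"))
}

# Brute-force axial projection by looping over voxels.
project_bruteforce <- function(lesion3d) {
  d <- dim(lesion3d)
  out <- matrix(FALSE, d[1], d[2])
  for (x in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (z in seq_len(d[3]))
        if (lesion3d[x, y, z]) out[x, y] <- TRUE
  out
}

# Shift a 2-D logical mask by whole pixels.
shift_mask <- function(m, dx, dy) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)) - dx
  ys <- seq_len(ncol(m)) - dy
  ok_x <- xs >= 1 & xs <= nrow(m)
  ok_y <- ys >= 1 & ys <= ncol(m)
  out[ok_x, ok_y] <- m[xs[ok_x], ys[ok_y]]
  out
}

profile_vec <- function(p) unclass(p)
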