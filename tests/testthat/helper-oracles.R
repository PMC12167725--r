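# Independent brute-force oracles, deliberately implemented with different
# algorithms than the package internals.

# Breadth-first flood fill over the 26-neighbourhood, in pure R.
# Returns the label array with only the largest `target` component kept
# (ties: component containing the smallest linear index).
oracle_keep_largest <- function(lab, target) {
  d <- dim(lab)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  visited <- array(FALSE, d)
  comps <- list()
  for (s in which(lab == target)) {
    if (visited[s]) next
    queue <- integer(512)
    queue[1] <- s
    head <- 1L; tail_ <- 1L
    visited[s] <- TRUE
    while (head <= tail_) {
      v <- queue[head]; head <- head + 1L
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(offsets))) {
        p <- ijk + offsets[r, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (!visited[w] && lab[w] == target) {
          visited[w] <- TRUE
          tail_ <- tail_ + 1L
          if (tail_ > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail_] <- w
        }
      }
    }
    comps[[length(comps) + 1L]] <- queue[seq_len(tail_)]
  }
  if (length(comps) <= 1L) return(lab)
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L)
    best <- best[which.min(vapply(comps[best], min, numeric(1)))]
  out <- lab
  for (i in seq_along(comps))
    if (i != best[1]) out[comps[[i]]] <- 0L
  out
}

# Brute-force binary dilation with the full 3x3x3 structuring element.
oracle_dilate26 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (v in which(mask != 0)) {
    ijk <- arrayInd(v, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      p <- ijk + c(dx, dy, dz)
      if (any(p < 1) || any(p > d)) next
      out[p[1], p[2], p[3]] <- TRUE
    }
  }
  out
}

# Hand-rolled Spearman via the rank-difference formula (no ties).
oracle_spearman_noties <- function(x, y) {
  n <- length(x)
  1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
}
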