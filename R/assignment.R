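# Hungarian algorithm (shortest augmenting paths with potentials, O(n^3))
# for square cost matrices.  Returns, for each row, the assigned column.
# Validated against brute-force permutation search in the test suite.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n == m)
  INF <- .Machine$double.xmax / 4
  # 1-based with index m+1 playing the role of the "virtual" column 0
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)      # p[j] = row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) assignment[p[j]] <- j
  assignment
}

# Gated linear assignment between two point sets: candidate pairs must be
# within max_dist; unmatched points pay the alternative cost max_dist^2.
# Returns an integer vector over rows of a: the matched index in b, or NA.
lap_link <- function(ax, ay, bx, by, max_dist) {
  n <- length(ax); m <- length(bx)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  BIG <- 1e12
  alt <- max_dist^2
  d2 <- outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2
  d2[d2 > max_dist^2] <- BIG
  sz <- n + m
  cost <- matrix(0, sz, sz)
  cost[seq_len(n), seq_len(m)] <- d2
  cost[seq_len(n), m + seq_len(n)] <- BIG
  cost[n + seq_len(m), seq_len(m)] <- BIG
  for (i in seq_len(n)) cost[i, m + i] <- alt
  for (j in seq_len(m)) cost[n + j, j] <- alt
  # lower-right block: transposed gated costs allow unmatched-unmatched pairs
  cost[n + seq_len(m), m + seq_len(n)] <- 0
  asg <- solve_assignment(cost)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- asg[i]
    if (j <= m && d2[i, j] < BIG) out[i] <- j
  }
  out
}
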