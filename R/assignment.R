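# Minimum-cost one-to-one assignment.
#
# Hungarian algorithm in the shortest-augmenting-path (potentials) form,
# O(n^2 m); no assignment-solver package is available in the supported
# dependency set, so this is implemented here and cross-checked against an
# exhaustive permutation oracle in the tests.

# cost: n x m matrix with n <= m. Returns integer vector match[i] = column
# assigned to row i (every row is matched since n <= m).
lsap_rows_le_cols <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- 1e300
  u <- numeric(n + 1)        # row potentials, index row+1 (row 0 = sentinel)
  v <- numeric(m + 1)        # column potentials, index col+1 (col 0 = sentinel)
  p <- integer(m + 1)        # p[j+1] = row matched to column j (0 = free)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    way <- integer(m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])            # unused real columns
      cur <- cost[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free + 1]
      minv[free + 1][upd] <- cur[upd]
      way[free + 1][upd] <- j0
      jj <- which.min(minv[free + 1])
      j1 <- free[jj]
      delta <- minv[j1 + 1]
      us <- which(used)
      u[p[us] + 1] <- u[p[us] + 1] + delta
      v[us] <- v[us] - delta
      minv[-us] <- minv[-us] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) match[p[j + 1]] <- j
  match
}

# General rectangular wrapper: returns match[i] = column for row i (0 = none).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(integer(n))
  if (n <= m) {
    lsap_rows_le_cols(cost)
  } else {
    colmatch <- lsap_rows_le_cols(t(cost))
    match <- integer(n)
    match[colmatch] <- seq_len(m)
    match
  }
}
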