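# Jonker-Volgenant style shortest-augmenting-path solver for the square
# linear assignment problem. Costs must be finite; infeasible entries are
# encoded by the caller as a large finite penalty. Returns, for each row,
# the assigned column. O(n^3).
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), all(is.finite(cost)))
  if (n == 0) return(integer(0))
  # column 1 in u/v/p/way is a virtual slot; real columns are 2..n+1
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j]: row currently assigned to column j-1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      free <- which(!used[-1]) + 1L
      if (length(free)) {
        cur <- cost[i0, free - 1L] - u[i0 + 1] - v[free]
        upd <- cur < minv[free]
        if (any(upd)) {
          minv[free[upd]] <- cur[upd]
          way[free[upd]] <- j0
        }
        j1 <- free[which.min(minv[free])]
        delta <- minv[j1]
      }
      sel <- which(used)
      u[p[sel] + 1] <- u[p[sel] + 1] + delta
      v[sel] <- v[sel] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_of_row <- integer(n)
  for (j in 2:(n + 1)) assign_of_row[p[j]] <- j - 1L
  assign_of_row
}
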