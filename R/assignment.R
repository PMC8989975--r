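# Optimal linear assignment (Hungarian method, Jonker-Volgenant style
# shortest augmenting paths with dual potentials). Solves
# min sum_i cost[i, perm[i]] over column permutations of a square cost
# matrix; Inf entries mark forbidden pairs (they are replaced by a cost
# larger than any feasible total, so they are never chosen when a feasible
# perfect matching exists). Frame-to-frame microbubble linking relies on
# this optimal (not greedy) assignment, as in Munkres-based particle
# trackers.
#
# Returns an integer vector `perm` with perm[i] = column assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n)
  C <- cost
  if (any(!is.finite(C))) {
    big <- sum(C[is.finite(C)]) + 1
    if (!is.finite(big) || big <= 0) big <- 1
    C[!is.finite(C)] <- big * (n + 1)
  }
  # e-maxx formulation: columns indexed 2..n+1, index 1 is the virtual start
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row matched to column j-1 (0 = free)
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
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- C[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
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
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1)) perm[p[j]] <- j - 1L
  perm
}
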