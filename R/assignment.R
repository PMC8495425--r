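# Linear-sum assignment (Hungarian / Jonker-Volgenant shortest augmenting
# path with potentials). Used by the linker to pick the global
# minimum-total-displacement frame-to-frame matching; verified against
# exhaustive permutation enumeration in the tests.

#' Solve the linear-sum assignment problem
#'
#' Minimizes the total cost of a one-to-one assignment of rows to columns.
#' Requires \code{nrow(cost) <= ncol(cost)}; every row is assigned.
#' Forbidden pairings should be encoded as a large finite cost and
#' filtered by the caller afterwards.
#'
#' @param cost Numeric cost matrix (finite entries).
#' @return Integer vector: for each row, the assigned column index.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (n > m) stop("solve_assignment needs nrow <= ncol", call. = FALSE)
  if (any(!is.finite(cost)))
    stop("cost matrix must be finite (use a large value for forbidden links)",
         call. = FALSE)
  # columns indexed 0..m stored at R positions 1..m+1 (position 1 virtual)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)      # p[j+1] = row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}
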