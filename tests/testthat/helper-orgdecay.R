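# Shared test utilities: random sequences and independent alignment oracles
# (clean-room exhaustive dynamic programming, written separately from the
# package kernels and kept deliberately simple and slow).

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NEGINF <- -1e9

# Exhaustive Smith-Waterman with affine gaps (gap of length L costs
# open + (L-1) * extend). Returns the optimal local score and the longest
# exact match run on one optimal path.
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = -5, extend = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(NEGINF, n + 1, m + 1)
  X <- matrix(NEGINF, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(NEGINF, n + 1, m + 1)  # gap in a (consume b)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (av[i - 1] == bv[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0) + s
    X[i, j] <- max(M[i - 1, j] + open, Y[i - 1, j] + open,
                   X[i - 1, j] + extend)
    Y[i, j] <- max(M[i, j - 1] + open, X[i, j - 1] + open,
                   Y[i, j - 1] + extend)
    h <- max(M[i, j], X[i, j], Y[i, j])
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  run <- 0; maxrun <- 0
  if (best > 0) {
    i <- bi; j <- bj
    state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
    repeat {
      if (state == 1) {
        s <- if (av[i - 1] == bv[j - 1]) match else mismatch
        run <- if (s == match) run + 1 else 0
        maxrun <- max(maxrun, run)
        target <- M[i, j] - s
        prevs <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
        if (abs(target) < 1e-9 && max(prevs) <= 0) break  # local start
        state <- which(abs(prevs - target) < 1e-9)[1]
        i <- i - 1; j <- j - 1
      } else if (state == 2) {
        run <- 0
        target <- X[i, j]
        prevs <- c(M[i - 1, j] + open, X[i - 1, j] + extend,
                   Y[i - 1, j] + open)
        state <- which(abs(prevs - target) < 1e-9)[1]
        i <- i - 1
      } else {
        run <- 0
        target <- Y[i, j]
        prevs <- c(M[i, j - 1] + open, X[i, j - 1] + open,
                   Y[i, j - 1] + extend)
        state <- c(1, 2, 3)[which(abs(prevs - target) < 1e-9)[1]]
        j <- j - 1
      }
      if (i <= 1 || j <= 1) break
    }
  }
  list(score = best, max_match_run = maxrun)
}

# Exhaustive semi-global score: full query aligned, reference end gaps free.
nw_semiglobal_oracle <- function(ref, qry, match = 2, mismatch = -3,
                                 open = -5, extend = -2) {
  rv <- strsplit(ref, "")[[1]]; qv <- strsplit(qry, "")[[1]]
  n <- length(rv); m <- length(qv)
  M <- matrix(NEGINF, n + 1, m + 1)
  X <- matrix(NEGINF, n + 1, m + 1)
  Y <- matrix(NEGINF, n + 1, m + 1)
  M[, 1] <- 0  # free skip of any reference prefix
  if (m >= 1) Y[1, 2:(m + 1)] <- open + extend * (0:(m - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (rv[i - 1] == qv[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] + open, Y[i - 1, j] + open,
                   X[i - 1, j] + extend)
    Y[i, j] <- max(M[i, j - 1] + open, X[i, j - 1] + open,
                   Y[i, j - 1] + extend)
  }
  max(pmax(M[, m + 1], X[, m + 1], Y[, m + 1]))
}
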