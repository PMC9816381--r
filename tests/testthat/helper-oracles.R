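# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: alignment scores come from exhaustive enumeration (and a
# plain-R affine DP for sizes where enumeration explodes), optimal-rotation
# RMSDs from a grid-plus-polish search over Euler angles.

BL62 <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
})

# exhaustive enumeration of all global alignments (three moves: diagonal,
# gap-in-b, gap-in-a), affine cost: a gap of length L costs open + L * ext.
# Exponential; keep sequences short (<= 5).
enumerate_best_score <- function(a, b, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + BL62[av[i], bv[j]], "m")
    }
    if (i <= length(av)) {
      pen <- ext + if (last == "x") 0 else open
      rec(i + 1, j, score - pen, "x")
    }
    if (j <= length(bv)) {
      pen <- ext + if (last == "y") 0 else open
      rec(i, j + 1, score - pen, "y")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# plain-R Gotoh three-state affine DP (maximization), same gap convention
gotoh_score <- function(a, b, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- BL62[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# minimum RMSD over all proper rotations (translation solved at centroids),
# independent of the SVD route: Euler-angle grid then Nelder-Mead polish.
brute_force_min_rmsd <- function(P, Q, grid_step = 20, n_polish = 8) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3, 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3, 3)
    Rz2 %*% Ry %*% Rz1
  }
  obj <- function(ang) sqrt(mean(rowSums((P0 %*% t(rot(ang)) - Q0)^2)))
  grid <- expand.grid(
    a = seq(0, 2 * pi, by = grid_step * pi / 180),
    b = seq(0, pi, by = grid_step * pi / 180),
    c = seq(0, 2 * pi, by = grid_step * pi / 180)
  )
  vals <- apply(as.matrix(grid), 1, obj)
  starts <- as.matrix(grid)[order(vals)[seq_len(n_polish)], , drop = FALSE]
  best <- min(vals)
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 2000))
    best <- min(best, fit$value)
  }
  best
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
    collapse = ""
  )
}
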