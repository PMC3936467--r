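# Independent oracles used across tests.  These deliberately re-derive
# results with different algorithms than the package (brute force, textbook
# formulas) so agreement is informative.

# Brute-force connected components: O(n^2) pairwise adjacency + BFS flood
# fill over the adjacency matrix.
flood_fill_oracle <- function(mask, connectivity = 26) {
  act <- which(mask)
  d <- dim(mask)
  out <- array(0L, d)
  if (!length(act)) return(list(labels = out, clusters = list()))
  co <- arr_ind <- which(mask, arr.ind = TRUE)
  n <- length(act)
  dx <- abs(outer(co[, 1], co[, 1], "-"))
  dy <- abs(outer(co[, 2], co[, 2], "-"))
  dz <- abs(outer(co[, 3], co[, 3], "-"))
  adj <- switch(as.character(connectivity),
    "6"  = (dx + dy + dz) == 1,
    "18" = pmax(dx, dy, dz) == 1 & (dx + dy + dz) <= 2,
    "26" = pmax(dx, dy, dz) == 1)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out[act] <- lab
  clusters <- lapply(split(act, lab), sort)
  list(labels = out, clusters = unname(clusters))
}

# partition of active voxels as a canonical set of sorted member vectors
partition_sets <- function(label_array) {
  act <- which(label_array != 0)
  cl <- split(act, label_array[act])
  sets <- unname(lapply(cl, sort))
  sets[order(vapply(sets, `[`, 0L, 1))]
}

# Textbook iteratively reweighted least squares for logistic regression.
irls_logistic_oracle <- function(X, y, tol = 1e-12, maxit = 200) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X1, w * X1), crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  drop(beta)
}

# small default test grid
test_grid <- function() volume_grid(c(12, 12, 10), c(3, 3, 3))

ijk_to_lin_test <- function(grid, ijk) {
  d <- grid$dims
  (ijk[1] - 1) + d[1] * ((ijk[2] - 1) + d[2] * (ijk[3] - 1)) + 1
}

# tiny scan for plumbing tests (white noise everywhere, no planted signal)
make_test_scan <- function(grid = test_grid(), T = 48, tr = 1.7, seed = 11) {
  V <- prod(grid$dims)
  brain <- array(TRUE, grid$dims)
  wm <- array(FALSE, grid$dims); wm[2:3, 2:3, 2:3] <- TRUE
  csf <- array(FALSE, grid$dims); csf[9:10, 2:3, 2:3] <- TRUE
  list(bold = matrix(rnorm_seeded(V * T, seed), V, T),
       motion = matrix(rnorm_seeded(T * 6, seed + 1), T, 6),
       masks = list(brain = brain, wm = wm, csf = csf),
       grid = grid, tr = tr)
}
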