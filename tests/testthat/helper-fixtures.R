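# Shared fixtures (memoised: the phantom atlas and connectome are reused
# across test files) and independent brute-force oracles.

.fixtures <- new.env(parent = emptyenv())

stage_seed <- function(seed, stage) lesionet:::.stage_seed(seed, stage)

fixture_atlas <- function() {
  if (is.null(.fixtures$atlas))
    .fixtures$atlas <- make_phantom_atlas(default_phantom_spec())
  .fixtures$atlas
}

fixture_connectome <- function() {
  if (is.null(.fixtures$conn))
    .fixtures$conn <- simulate_connectome(
      fixture_atlas(), connectome_spec(seed = stage_seed(1, "connectome")))
  .fixtures$conn
}

fixture_cohort <- function(n = 76, beta = 0.25, seed = stage_seed(1, "cohort")) {
  key <- sprintf("cohort_%d_%g_%d", n, beta, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_lesion_cohort(
      fixture_atlas(),
      cohort_spec(n_patients = n, effect_beta = beta, seed = seed))
  .fixtures[[key]]
}

# tiny geometry for unit tests that do not need the full phantom
small_geometry <- function(shape = c(8L, 8L, 8L), mm = 2) {
  aff <- diag(c(mm, mm, mm, 1))
  aff[1:3, 4] <- -mm * (shape - 1) / 2
  volume_geometry(shape, aff, "test")
}

random_mask <- function(geom, n_vox = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- array(FALSE, geom$shape)
  v[sample(prod(geom$shape), n_vox)] <- TRUE
  lesion_mask(v, geom, sprintf("P%04d", sample.int(9999, 1)))
}

# Brute-force TFCE oracle: explicit per-threshold connected-component
# labelling (breadth-first search), independent of the package kernel.
tfce_oracle <- function(arr, E = 0.5, H = 2, nsteps = 100, conn = 26) {
  d <- dim(arr)
  pos <- pmax(arr, 0)
  mx <- max(pos)
  out <- array(0, d)
  if (mx <= 0) return(out)
  dh <- mx / nsteps
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (conn == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  for (s in seq_len(nsteps)) {
    h <- s * dh
    supra <- pos >= h
    idx <- which(supra)
    if (!length(idx)) next
    lab <- array(0L, d)
    nl <- 0L
    for (v in idx) {
      if (lab[v] > 0L) next
      nl <- nl + 1L
      queue <- v
      lab[v] <- nl
      while (length(queue)) {
        cur <- queue[1]
        queue <- queue[-1]
        co <- arrayInd(cur, d)[1, ]
        for (o in seq_len(nrow(offs))) {
          nb <- co + offs[o, ]
          if (any(nb < 1) || any(nb > d)) next
          w <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
          if (supra[w] && lab[w] == 0L) {
            lab[w] <- nl
            queue <- c(queue, w)
          }
        }
      }
    }
    sizes <- tabulate(lab, nl)
    out[idx] <- out[idx] + sizes[lab[idx]]^E * h^H * dh
  }
  out
}

# Independent closed-form solution of the single-behaviour sparse component:
# soft-threshold the voxel-behaviour covariance at the support-fraction
# quantile, keep the dominant sign for s >= 0, normalise.
sparse_component_oracle <- function(X, y, s) {
  yc <- y - mean(y)
  cv <- drop(crossprod(X, yc / sqrt(sum(yc^2))))
  tau <- if (abs(s) >= 1) 0 else quantile(abs(cv), 1 - abs(s), names = FALSE)
  u <- sign(cv) * pmax(abs(cv) - tau, 0)
  if (s >= 0 && any(u != 0)) {
    pos <- sum(u[u > 0]^2)
    neg <- sum(u[u < 0]^2)
    u[if (pos >= neg) u < 0 else u > 0] <- 0
  }
  n2 <- sqrt(sum(u^2))
  if (n2 > 0) u / n2 else u
}

# naive Benjamini-Hochberg step-up, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
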