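# Shared fixtures, built in code.  Everything is seeded so the suite is
# deterministic.

fixture_spacing <- c(1.17, 1.17, 2.5)

# small random binary mask with at least one foreground voxel
random_mask <- function(d, p = 0.25) {
  m <- array(stats::rbinom(prod(d), 1, p), d)
  if (sum(m) == 0) m[ceiling(prod(d) / 2)] <- 1
  m
}

# brute-force directed nearest-surface distances (all-pairs oracle)
oracle_surface_distances <- function(pred, gt, spacing) {
  surf <- function(m) {
    sm <- m > 0.5
    d <- dim(sm)
    interior <- array(TRUE, d)
    shift <- function(x, axis, by) {
      out <- array(FALSE, d)
      idx_src <- lapply(d, seq_len); idx_dst <- idx_src
      n <- d[axis]
      if (by > 0) { idx_dst[[axis]] <- (by + 1):n; idx_src[[axis]] <- 1:(n - by) }
      else { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out
    }
    for (ax in 1:3) for (by in c(-1, 1)) interior <- interior & shift(sm, ax, by)
    which(sm & !interior, arr.ind = TRUE)
  }
  sp_ <- surf(pred); sg_ <- surf(gt)
  pc <- sweep(sp_ - 1, 2, spacing, `*`)
  gc <- sweep(sg_ - 1, 2, spacing, `*`)
  D2 <- outer(rowSums(pc^2), rowSums(gc^2), `+`) - 2 * pc %*% t(gc)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  list(pred_to_gt = apply(D, 1, min), gt_to_pred = apply(D, 2, min))
}

# tiny benchmark reused by training tests (built once per test run)
tiny_spec <- function(grid = c(24L, 24L, 16L)) phantom_spec(grid = grid)

make_ct_volume <- function(d = c(16, 16, 8), seed = 1) {
  set.seed(seed)
  hu <- array(stats::rnorm(prod(d), mean = 30, sd = 60), d)
  hu <- pmin(pmax(hu, -1000), 1400)
  volume(hu, fixture_spacing, modality = "CT")
}
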