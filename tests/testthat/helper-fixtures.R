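# Shared fixtures and independent brute-force oracles.

tiny_grid <- function(nr = 4, nc = 4, px = 30) geo_grid(nr, nc, px)

# Scene with spatially constant bands (optionally per-pixel overrides).
uniform_scene <- function(red, nir, mir = NULL, grid = tiny_grid(),
                          date = "2007-06-01") {
  bands <- list(RED = matrix(red, grid$n_rows, grid$n_cols),
                NIR = matrix(nir, grid$n_rows, grid$n_cols))
  if (!is.null(mir)) bands$MIR <- matrix(mir, grid$n_rows, grid$n_cols)
  ms_scene(bands, grid, date)
}

# A scene with pixel-wise variation so regression fits are well-posed.
varied_scene <- function(grid = tiny_grid(10, 10), date = "2007-06-01",
                         seed = 99) {
  set.seed(seed)
  mk <- function(mu) matrix(pmax(mu + stats::runif(grid$n_rows * grid$n_cols,
                                                   -0.5, 0.5) * mu, 0.001),
                            grid$n_rows, grid$n_cols)
  ms_scene(list(RED = mk(0.1), NIR = mk(0.4), MIR = mk(0.2)), grid, date)
}

# --- independent oracles ---------------------------------------------------

# Majority filter by explicit per-pixel neighbourhood enumeration with
# reflect-with-duplicate padding (index 0 -> 1, n+1 -> n, ...).
oracle_majority <- function(m, k) {
  h <- (k - 1) %/% 2
  refl <- function(i, n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i; i }
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    votes <- 0
    for (di in -h:h) for (dj in -h:h)
      votes <- votes + m[refl(i + di, nrow(m)), refl(j + dj, ncol(m))]
    out[i, j] <- votes * 2 > k * k
  }
  out
}

# Connected components by queue-based flood fill (no igraph).
oracle_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
        else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                  c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  cur <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!m[i0, j0] || lab[i0, j0] > 0) next
    cur <- cur + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in nb) {
        i <- p[1] + d[1]; j <- p[2] + d[2]
        if (i >= 1 && i <= nr && j >= 1 && j <= nc && m[i, j] && lab[i, j] == 0) {
          lab[i, j] <- cur; queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  lab
}

oracle_remove_small <- function(m, mmu_ha, px_ha, connectivity = 8) {
  lab <- oracle_label(m, connectivity)
  keep <- matrix(FALSE, nrow(m), ncol(m))
  if (max(lab) > 0)
    for (l in seq_len(max(lab)))
      if (sum(lab == l) * px_ha >= mmu_ha) keep[lab == l] <- TRUE
  keep
}

# Scene pair wrapping a truth burn matrix using the synthetic signatures,
# noise-free, constructed directly (not via simulate_scene_pair).
signature_pair <- function(burn, grid = geo_grid(nrow(burn), ncol(burn), 30)) {
  mk <- function(healthy, burnt) {
    m <- matrix(healthy, nrow(burn), ncol(burn)); m[burn] <- burnt; m
  }
  pre <- ms_scene(list(RED = matrix(0.05, nrow(burn), ncol(burn)),
                       NIR = matrix(0.45, nrow(burn), ncol(burn)),
                       MIR = matrix(0.18, nrow(burn), ncol(burn))),
                  grid, "2007-06-01")
  post <- ms_scene(list(RED = mk(0.05, 0.08), NIR = mk(0.45, 0.12),
                        MIR = mk(0.18, 0.30)), grid, "2007-09-01")
  scene_pair(pre, post)
}
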