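# Small programmatic fixtures shared across tests.

# solid ball mask of radius r (voxel units) centered in a d^3 grid
ball_mask <- function(d, r, center = (d + 1) / 2) {
  cx <- seq_len(d) - center
  r2 <- outer(outer(cx^2, cx^2, `+`), cx^2, `+`)
  r2 <= r^2
}

# axis-aligned cuboid mask
box_mask <- function(dims, lo, hi) {
  m <- array(FALSE, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# single-tissue cubic phantom (all voxels one label)
cube_phantom <- function(n = 6, spacing = 5, tissue = "Muscle") {
  lab <- array(1L, c(n, n, n))
  label_volume(lab, spacing = spacing, labels = setNames(1L, tissue))
}

# tissue table with one row overridden (for closed-form thermal oracles)
table_with <- function(tissue, ...) {
  tab <- load_tissue_table()
  i <- match(tissue, tab$tissue)
  stopifnot(!is.na(i))
  over <- list(...)
  for (nm in names(over)) tab[[nm]][i] <- over[[nm]]
  tab
}

# brute-force symmetric average boundary distance between two masks (mm);
# independent of the package implementation: plain outer-product distances
# over boundary voxels found by explicit neighbor checks
avg_hausdorff_oracle <- function(X, Y, spacing) {
  d <- dim(X)
  boundary_pts <- function(M) {
    pts <- NULL
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (!M[i, j, k]) next
      nb <- c(
        i == 1 || !M[i - 1, j, k], i == d[1] || !M[i + 1, j, k],
        j == 1 || !M[i, j - 1, k], j == d[2] || !M[i, j + 1, k],
        k == 1 || !M[i, j, k - 1], k == d[3] || !M[i, j, k + 1])
      if (any(nb)) pts <- rbind(pts, c(i, j, k) * spacing)
    }
    pts
  }
  px <- boundary_pts(X != 0); py <- boundary_pts(Y != 0)
  dmat <- sqrt(outer(rowSums(px^2), rowSums(py^2), `+`) - 2 * px %*% t(py))
  dmat <- pmax(dmat, 0)
  (mean(apply(dmat, 1, min)) + mean(apply(dmat, 2, min))) / 2
}

# brute-force centered-cube mass-averaged SAR (in-domain cubes only)
mass_avg_sar_oracle <- function(sar, rho, spacing, tissue, target_g = 10) {
  d <- dim(sar)
  vox_g <- spacing^3 * 1e-9 * 1e3
  m <- ifelse(tissue, rho * vox_g, 0)
  S <- sar * m
  out <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!tissue[i, j, k]) next
    prevM <- 0; prevS <- 0
    for (r in 0:(min(d) %/% 2)) {
      if (i - r < 1 || j - r < 1 || k - r < 1 ||
          i + r > d[1] || j + r > d[2] || k + r > d[3]) break
      M <- sum(m[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)])
      Sc <- sum(S[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)])
      if (M >= target_g) {
        w <- if (M > prevM) (target_g - prevM) / (M - prevM) else 0
        out[i, j, k] <- (prevS + w * (Sc - prevS)) / target_g
        break
      }
      prevM <- M; prevS <- Sc
    }
  }
  out
}
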