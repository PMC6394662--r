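# Geometric fixtures and brute-force oracles shared across tests.

# 0/1 matrix with rasterised discs at the given centres/radii
make_disk_mask <- function(h, w, centers, radii) {
  m <- matrix(0L, h, w)
  rw <- row(m); cl <- col(m)
  centers <- matrix(centers, ncol = 2)
  for (i in seq_len(nrow(centers))) {
    m[(rw - centers[i, 1])^2 + (cl - centers[i, 2])^2 <= radii[i]^2] <- 1L
  }
  m
}

# RGB plate_image with a given per-channel constant background and discs
# drawn in a per-channel colony colour (hard edges, no noise)
make_flat_plate <- function(h, w, bg_rgb, colony_rgb, centers = NULL,
                            radii = NULL, dpi = 600) {
  px <- array(0, dim = c(h, w, 3))
  disk <- if (!is.null(centers)) make_disk_mask(h, w, centers, radii)
  for (k in 1:3) {
    ch <- matrix(bg_rgb[k], h, w)
    if (!is.null(disk)) ch[disk == 1L] <- colony_rgb[k]
    px[, , k] <- ch
  }
  plate_image(px, dpi = dpi)
}

# brute-force grayscale opening with a disc structuring element:
# erosion (min) then dilation (max) over in-bounds disc offsets
brute_opening <- function(img, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  h <- nrow(img); w <- ncol(img)
  sweep_one <- function(x, fun) {
    out <- matrix(NA_real_, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      rs <- r + offs$dr; cs <- c + offs$dc
      ok <- rs >= 1 & rs <= h & cs >= 1 & cs <= w
      out[r, c] <- fun(x[cbind(rs[ok], cs[ok])])
    }
    out
  }
  sweep_one(sweep_one(img, min), max)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
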