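# Shared fixtures, built once per test run. Small sizes keep the suite fast;
# the acceptance tests use full-size sweeps.

fixture_env <- new.env(parent = emptyenv())

# 256 px marrow section with mid-range composition
small_section <- function() {
  if (is.null(fixture_env$section)) {
    spec <- synthetic_spec(dims = c(256L, 256L), frac_hemato = 0.5,
                           frac_adipo = 0.2, frac_interstitium = 0.2,
                           frac_undetected = 0.03, trabecula_count = 2L,
                           seed = 42L)
    fixture_env$section <- generate_marrow_section(spec)
  }
  fixture_env$section
}

small_segmentation <- function() {
  if (is.null(fixture_env$seg)) {
    sec <- small_section()
    masks <- rasterize(sec$annotations, dim(sec$truth$labels))
    fixture_env$masks <- masks
    fixture_env$seg <- segment_section(sec$image, masks,
                                       default_config("marrow"))
  }
  list(section = small_section(), masks = fixture_env$masks,
       seg = fixture_env$seg)
}

# brute-force even-odd point-in-polygon, the oracle for rasterize()
brute_polygon_mask <- function(vertices, dims) {
  H <- dims[1]; W <- dims[2]
  out <- matrix(FALSE, H, W)
  n <- nrow(vertices)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      px <- c - 0.5; py <- r - 0.5
      crossings <- 0L
      j <- n
      for (i in seq_len(n)) {
        y1 <- vertices[j, 2]; y2 <- vertices[i, 2]
        x1 <- vertices[j, 1]; x2 <- vertices[i, 1]
        if ((y1 <= py) != (y2 <= py)) {
          xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
          if (xc > px) crossings <- crossings + 1L
        }
        j <- i
      }
      out[r, c] <- (crossings %% 2L) == 1L
    }
  }
  out
}

disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(seq_len(W), each = H), H, W) - 0.5
  ys <- matrix(rep(seq_len(H), W), H, W) - 0.5
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}
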