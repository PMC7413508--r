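# Shared in-code fixtures: small grids, shapes and TACs built fresh per use.

lu177 <- nuclideData("lu177")

# a uniformly filled rasterized shape painted at `conc` MBq/ml
uniform_phantom <- function(kind, volume_ml, conc = 1.53, spacing = 2,
                            half_size = 30, supersample = 2, t_h = 24) {
  n <- 2L * ceiling(half_size / spacing)
  g <- VoxelGrid(c(n, n, n), spacing = spacing)
  m <- rasterizeShape(shapeSpec(kind, volume_ml, name = "voi"), g,
                      supersample = supersample)
  list(grid = g, mask = m,
       image = paintActivity(m, c(voi = conc), background = 0,
                             timePostInjection = t_h))
}

# direct triple-loop convolution oracle (shifted-sum form)
direct_convolve <- function(x, k) {
  d <- dim(x); R <- (dim(k) - 1L) %/% 2L
  out <- array(0, d)
  for (di in -R[1]:R[1]) for (dj in -R[2]:R[2]) for (dk in -R[3]:R[3]) {
    w <- k[di + R[1] + 1L, dj + R[2] + 1L, dk + R[3] + 1L]
    if (w == 0) next
    si <- max(1, 1 - di):min(d[1], d[1] - di)
    sj <- max(1, 1 - dj):min(d[2], d[2] - dj)
    sk <- max(1, 1 - dk):min(d[3], d[3] - dk)
    xs <- array(0, d)
    xs[si + di, sj + dj, sk + dk] <- x[si, sj, sk]
    out <- out + xs * w
  }
  out
}

# monoexponential TAC sampled on the clinical 5-scan schedule
monoexp_tac <- function(A0 = 100, T_half_h = 40,
                        schedule = c(1, 4, 24, 44, 72), region = "organ") {
  TimeActivityCurve(region, schedule, A0 * exp(-log(2) / T_half_h * schedule))
}
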