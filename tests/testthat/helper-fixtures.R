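# Shared fixtures and independent pure-R oracles. All fixtures are built in
# code; the compact plan uses the same cone geometry as the defaults on a
# smaller lattice so per-file runtimes stay low.

small_plan_spec <- function(...) {
  plan_spec(dim = c(64, 72, 96), noise_sd_fraction = 0, ...)
}

# memoised compact plan (per test file)
local({
  cache <- new.env()
  small_plan <<- function() {
    if (is.null(cache$plan)) cache$plan <- generate_plan_dose(small_plan_spec())
    cache$plan
  }
})

# smooth random dose grid: blurred uniform noise, scaled to max_dose
smooth_random_grid <- function(dim = c(20, 20, 20), spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), max_dose = 10,
                               sigma = 2, seed = 1) {
  set.seed(seed)
  a <- e2edose:::gaussian_blur3(array(runif(prod(dim)), dim), sigma, spacing)
  dose_grid(a * (max_dose / max(a)), origin, spacing)
}

# pure-R trilinear oracle for a single point (no validity handling)
r_trilinear <- function(grid, p) {
  d <- dim(grid$values)
  t <- (p - grid$origin) / grid$spacing
  if (any(t < -1e-9 | t > d - 1 + 1e-9)) return(NA_real_)
  t <- pmin(pmax(t, 0), d - 1)
  i0 <- pmin(floor(t), pmax(d - 2, 0))
  f <- ifelse(d == 1, 0, t - i0)
  acc <- 0
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    b <- c(bx, by, bz)
    i <- pmin(i0 + b, d - 1)
    w <- prod(ifelse(b == 1, f, 1 - f))
    acc <- acc + w * grid$values[i[1] + 1, i[2] + 1, i[3] + 1]
  }
  acc
}

# pure-R exhaustive gamma oracle for small grids (global normalisation)
r_gamma_oracle <- function(ref, ev, params) {
  rmax <- max(ref$values)
  thr <- params$threshold_fraction * rmax
  dd <- params$dose_criterion_fraction * rmax
  dta <- params$distance_criterion
  step <- params$evaluated_upsampling_step * dta
  radius <- params$search_radius_factor * dta
  m <- floor(radius / step + 1e-9)
  off <- as.matrix(expand.grid(x = (-m:m) * step, y = (-m:m) * step,
                               z = (-m:m) * step))
  off <- off[rowSums(off^2) <= radius^2 + 1e-12, , drop = FALSE]
  d <- dim(ref$values)
  gam <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    dr <- ref$values[i, j, k]
    if (dr < thr) next
    r <- ref$origin + (c(i, j, k) - 1) * ref$spacing
    best <- Inf
    for (q in seq_len(nrow(off))) {
      de <- r_trilinear(ev, r + off[q, ])
      if (is.na(de)) next
      g2 <- sum(off[q, ]^2) / dta^2 + ((de - dr) / dd)^2
      if (g2 < best) best <- g2
    }
    if (is.finite(best)) gam[i, j, k] <- sqrt(best)
  }
  gam
}
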