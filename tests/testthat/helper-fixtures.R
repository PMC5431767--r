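# Shared fixtures, built in code at test time.

# small phantom spec (default geometry is already modest; tests mostly tweak
# class / deficit / noise / seed)
tiny_spec <- function(...) {
  phantom_spec(...)
}

# brute-force two-sided exact signed-rank p over all 2^n sign assignments;
# independent of the package's dynamic-programming path
oracle_exact_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  wplus <- as.numeric(signs %*% r)
  obs <- sum(r[d > 0])
  mean(abs(wplus - total / 2) >= abs(obs - total / 2) - 1e-9)
}

# piecewise-linear interpolation oracle evaluated pointwise, independent of
# stats::approx
oracle_linear_interp <- function(x, y, xout) {
  vapply(xout, function(q) {
    if (q <= x[1]) return(y[1])
    if (q >= x[length(x)]) return(y[length(y)])
    i <- max(which(x <= q))
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# straight-line single transect through the phantom's band centres
phantom_transect <- function(phantom, area = c("normal", "lesion"),
                             round = 1, width_um = 0) {
  area <- match.arg(area)
  lm <- phantom_landmarks(phantom)
  row <- lm[lm$area == area & lm$round == round, ]
  extract_transect(phantom$volume,
                   c(row$surface_z, row$surface_y, row$surface_x),
                   c(row$dej_z, row$dej_y, row$dej_x),
                   width_um = width_um)
}
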