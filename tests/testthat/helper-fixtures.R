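# Shared fixtures: small cells/configs keep every simulation desk-sized.

toy_cell <- function() unit_cell(25, 30, 35)

toy_config <- function(...) {
  args <- list(...)
  defaults <- list(n_crystals = 6, cell0 = toy_cell(), sg = "P212121",
                   d_min = 3, wedge_width = 60, frames_per_wedge = 5,
                   seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# brute-force orbit of one index: apply every rotation (and optionally
# Friedel inversion) explicitly -- independent of map_to_asu internals
brute_orbit <- function(hkl, sg, friedel = TRUE) {
  sg <- space_group(sg$symbol, sg$operators, friedel_merged = friedel)
  ims <- lapply(sg$operators, function(op) as.vector(hkl %*% op$rot))
  if (friedel) ims <- c(ims, lapply(ims, function(v) -v))
  unique(do.call(rbind, ims))
}

# independent d-spacing oracle: build the reciprocal basis from cross
# products and measure |h a* + k b* + l c*|
brute_resolution <- function(cell, hkl) {
  p <- as.numeric(cell)
  deg <- pi / 180
  a <- p[1] * c(1, 0, 0)
  b <- p[2] * c(cos(p[6] * deg), sin(p[6] * deg), 0)
  cx <- cos(p[5] * deg)
  cy <- (cos(p[4] * deg) - cos(p[5] * deg) * cos(p[6] * deg)) /
    sin(p[6] * deg)
  cz <- sqrt(1 - cx^2 - cy^2)
  cc <- p[3] * c(cx, cy, cz)
  vol <- sum(a * xprod(b, cc))
  astar <- xprod(b, cc) / vol
  bstar <- xprod(cc, a) / vol
  cstar <- xprod(a, b) / vol
  q <- hkl[1] * astar + hkl[2] * bstar + hkl[3] * cstar
  1 / sqrt(sum(q * q))
}

xprod <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# adjusted Rand index between two labelings (closed-form contingency sum)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(as.vector(tab))
  b1 <- sum_comb(rowSums(tab))
  b2 <- sum_comb(colSums(tab))
  expected <- b1 * b2 / choose(n, 2)
  maximum <- (b1 + b2) / 2
  (a - expected) / (maximum - expected)
}
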