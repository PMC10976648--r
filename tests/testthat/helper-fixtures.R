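# shared fixtures: compact grids and example models used across test files

ar_like_lj <- function() potential_model("LJ12-6", c(epsilon = 0.996, sigma = 3.405))

example_models <- function() {
  list(
    "LJ12-6" = potential_model("LJ12-6", c(epsilon = 1.19, sigma = 3.35)),
    "LJ8-6"  = potential_model("LJ8-6",  c(epsilon = 1.19, sigma = 3.76)),
    "WBH"    = potential_model("WBH",    c(epsilon = 1.19, sigma = 3.76, gamma = 11.1)),
    "MBH"    = potential_model("MBH",    c(epsilon = 1.19, sigma = 3.76, gamma = 13.1)),
    "MRS"    = potential_model("MRS",    c(epsilon = 1.19, sigma = 3.76, gamma = 6.55)),
    "BHA"    = potential_model("BHA",    c(A = 850000, C6 = 6200, b = 3.48)),
    "GBH"    = potential_model("GBH",    c(epsilon = 1.19, sigma = 3.76, gamma = 13.1, delta = 6.2)),
    "LJ14-7" = potential_model("LJ14-7", c(epsilon = 1.19, sigma = 3.76, gamma = 0.12, delta = 0.07)),
    "TT"     = potential_model("TT",
                 c(A = 451676.4713957143, b = 13.1, C6 = 1.459824022, C8 = 0.41, C10 = 0.17),
                 constants = list(Re = 3.76, De = 1.19))
  )
}

# random rotation matrix (uniform via QR of Gaussian)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force three-body sum over all triplets, independent of the package path
brute_force_three_body <- function(config, coefficients, cutoff) {
  co <- cbind(config$x, config$y, config$z)
  el <- config$element
  n <- nrow(co)
  total <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    rij <- sqrt(sum((co[i, ] - co[j, ])^2))
    rik <- sqrt(sum((co[i, ] - co[k, ])^2))
    rjk <- sqrt(sum((co[j, ] - co[k, ])^2))
    if (max(rij, rik, rjk) > cutoff) next
    V <- coefficients[[paste(sort(el[c(i, j, k)]), collapse = "-")]]
    total <- total + axilrod_teller_energy(co[i, ], co[j, ], co[k, ], V)
  }
  total
}
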