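# Independent oracle transcriptions of the shape-fidelity score formulas,
# coded directly from the raw measurement vectors (no package internals),
# plus small numeric helpers shared across tests.

oracle_S <- function(diams, d_needle) 100 * sum(diams) / length(diams) / d_needle

oracle_U <- function(diams, d_needle) {
  l_real <- sum(diams) / length(diams)
  l_ideal <- d_needle * (100 * l_real / d_needle) / 100
  if (length(diams) < 2) return(1)
  sdl <- sqrt(sum((diams - l_real)^2) / (length(diams) - 1))
  1 - sdl / l_ideal
}

oracle_Pe <- function(l0x, l0y, sx, sy) {
  mx <- sum(sx) / length(sx); my <- sum(sy) / length(sy)
  sdx <- if (length(sx) < 2) 0 else sqrt(sum((sx - mx)^2) / (length(sx) - 1))
  sdy <- if (length(sy) < 2) 0 else sqrt(sum((sy - my)^2) / (length(sy) - 1))
  (mx - sdx + my - sdy) / (l0x + l0y)
}

oracle_Pr <- function(l0x, l0y, sx, sy) {
  (sum(sx) / length(sx)) * (sum(sy) / length(sy)) / (l0x * l0y)
}

oracle_P <- function(U, Pe, Pr) U * Pe * Pr

# Spherical-cap volume from height and contact radius
oracle_cap_volume <- function(h, a) pi * h / 6 * (3 * a^2 + h^2)

# Brute-force bisection root for the cap height, independent of the
# package implementation (different bracket and update rule)
oracle_cap_height <- function(volume, deq, iters = 200) {
  a <- deq / 2
  lo <- 1e-12; hi <- deq
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oracle_cap_volume(mid, a) < volume) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

make_uniform_binary_disk <- function(side, r_px) {
  c0 <- (side + 1) / 2
  ix <- seq_len(side)
  m <- outer((ix - c0)^2, (ix - c0)^2, "+") <= r_px^2
  m * 1
}
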