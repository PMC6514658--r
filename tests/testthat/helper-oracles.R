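# Independent brute-force colour-conversion oracle: scalar, one pixel at a
# time, written directly from the CIE 1976 textbook formulas (sRGB decoding,
# D65 white). Deliberately shares no code with the package's vectorized path.

oracle_lab_luv <- function(r, g, b) {
  dec <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  rl <- dec(r); gl <- dec(g); bl <- dec(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  Xn <- 0.95047; Yn <- 1; Zn <- 1.08883
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  L <- 116 * f(Y / Yn) - 16
  a <- 500 * (f(X / Xn) - f(Y / Yn))
  bb <- 200 * (f(Y / Yn) - f(Z / Zn))
  den <- X + 15 * Y + 3 * Z
  dn <- Xn + 15 * Yn + 3 * Zn
  up <- if (den > 0) 4 * X / den else 4 * Xn / dn
  vp <- if (den > 0) 9 * Y / den else 9 * Yn / dn
  u <- 13 * L * (up - 4 * Xn / dn)
  v <- 13 * L * (vp - 9 * Yn / dn)
  c(L = L, a = a, b = bb, u = u, v = v)
}

# uniform single-colour image helper
uniform_image <- function(r, g, b, h = 2, w = 2, id = "uniform") {
  px <- array(0, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  rgb_image(px, source_id = id)
}

# planes for a single pixel colour
pixel_planes <- function(r, g, b) color_planes(uniform_image(r, g, b, 1, 1))
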