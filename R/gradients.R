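# Analytic Euclidean gradients of the geometric primitives, vectorized over
# row-paired point matrices. These are the building blocks of the training
# objective's gradient; correctness is pinned by central-difference tests.

# d(u,v) and its Euclidean gradients wrt u and v.
# Returns list(d, gu, gv); rows of U and V are paired.
dist_grad <- function(U, V) {
  su <- rowSums(U * U)
  sv <- rowSums(V * V)
  sq <- rowSums((U - V)^2)
  a <- 1 - su
  b <- 1 - sv
  gam <- 1 + 2 * sq / (a * b)
  d <- acosh(gam)
  den <- pmax(sqrt(pmax(gam^2 - 1, 0)), .EPS_DENOM)
  uv <- rowSums(U * V)
  cu <- 4 / (b * den)
  cv <- 4 / (a * den)
  Au <- (sv - 2 * uv + 1) / a^2
  Av <- (su - 2 * uv + 1) / b^2
  gu <- cu * (Au * U - V / a)
  gv <- cv * (Av * V - U / b)
  list(d = d, gu = gu, gv = gv)
}

# d(0,x) = 2*artanh(||x||) and its gradient (2/(1-r^2)) * x/r, row-wise.
origin_dist_grad <- function(X) {
  r2 <- rowSums(X * X)
  r <- pmax(sqrt(r2), .EPS_DENOM)
  d <- 2 * atanh(sqrt(r2))
  g <- X * (2 / ((1 - r2) * r))
  list(d = d, g = g)
}

# Apex angle and gradients wrt apex X and target Y (row-paired).
# The arccos argument is clamped; on the clamped set the function is flat
# and the gradient is reported as 0.
angle_grad <- function(X, Y) {
  sa <- rowSums(X * X)
  sy <- rowSums(Y * Y)
  D <- X - Y
  sb <- rowSums(D * D)
  a <- pmax(sqrt(sa), .EPS_DENOM)
  b <- pmax(sqrt(sb), .EPS_DENOM)
  num <- sy - sa - sb
  den <- pmax(2 * a * b, .EPS_DENOM)
  cb <- num / den
  c_cl <- pmax(pmin(cb, 1), -1)
  ang <- acos(c_cl)
  active <- abs(cb) < 1
  dth_dc <- ifelse(active, -1 / pmax(sqrt(1 - c_cl^2), .EPS_DENOM), 0)
  # partials of num and den
  dnum_dx <- -2 * X - 2 * D
  dnum_dy <- 2 * Y + 2 * D
  dden_dx <- 2 * (b / a) * X + 2 * (a / b) * D
  dden_dy <- -2 * (a / b) * D
  dc_dx <- (dnum_dx * den - num * dden_dx) / den^2
  dc_dy <- (dnum_dy * den - num * dden_dy) / den^2
  list(angle = ang,
       gx = dc_dx * dth_dc,
       gy = dc_dy * dth_dc)
}

# Aperture psi(x) = asin(K(1-a^2)/a) and gradient wrt X, for rows where the
# aperture is defined; undefined rows get NA aperture and zero gradient.
aperture_grad <- function(X, K) {
  sa <- rowSums(X * X)
  a <- pmax(sqrt(sa), .EPS_DENOM)
  s <- K * (1 - sa) / a
  ok <- s <= 1
  psi <- rep(NA_real_, length(s))
  psi[ok] <- asin(pmax(pmin(s[ok], 1), -1))
  dpsi_da <- numeric(length(s))
  strict <- ok & s < 1
  dpsi_da[strict] <- (-K * (1 / sa[strict] + 1)) /
    pmax(sqrt(1 - s[strict]^2), .EPS_DENOM)
  g <- X * (dpsi_da / a)
  g[!ok, ] <- 0
  list(psi = psi, g = g, defined = ok)
}

# Hinge cone energy max(0, angle - psi) with gradients wrt apex and target.
# Gated rows (undefined aperture) contribute zero energy and zero gradient.
# `aperture_force = FALSE` drops the -dpsi/dx component from the apex
# gradient: that component always points radially inward (widening the cone
# by shrinking the apex radius) and, used for descent, ratchets every apex
# toward the gating radius without reducing angular misalignment; the
# optimizer's structural step uses only the axis-rotation part, while the
# full analytic gradient keeps both.
cone_energy_grad <- function(X, Y, K, aperture_force = TRUE) {
  ap <- aperture_grad(X, K)
  an <- angle_grad(X, Y)
  e <- numeric(nrow(X))
  gx <- matrix(0, nrow(X), ncol(X))
  gy <- matrix(0, nrow(X), ncol(X))
  act <- ap$defined & (an$angle - ap$psi > 0)
  act[is.na(act)] <- FALSE
  if (any(act)) {
    e[act] <- an$angle[act] - ap$psi[act]
    gx[act, ] <- an$gx[act, , drop = FALSE]
    if (aperture_force) {
      gx[act, ] <- gx[act, , drop = FALSE] - ap$g[act, , drop = FALSE]
    }
    gy[act, ] <- an$gy[act, , drop = FALSE]
  }
  list(e = e, gx = gx, gy = gy)
}
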