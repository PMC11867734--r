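# Independent oracles used to pin the geometry and evaluation code.
# These deliberately avoid the package's own implementations.

# Mobius addition on the Poincare ball (gyrovector form); the distance
# 2 * artanh(||(-u) (+) v||) is an independent closed form for the
# hyperbolic metric.
mobius_add <- function(a, b) {
  ab <- sum(a * b)
  na2 <- sum(a * a)
  nb2 <- sum(b * b)
  ((1 + 2 * ab + nb2) * a + (1 - na2) * b) / (1 + 2 * ab + na2 * nb2)
}

gyro_distance <- function(u, v) {
  2 * atanh(sqrt(sum(mobius_add(-u, v)^2)))
}

# r_min(K) by bisection on K (1 - r^2) / r = 1 (the package uses the
# closed form of the quadratic).
r_min_bisect <- function(K, tol = 1e-12) {
  f <- function(r) K * (1 - r^2) / r - 1
  lo <- 1e-9; hi <- 1 - 1e-9
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force mean average precision by explicit rank enumeration
map_brute <- function(emb, g) {
  ids <- rownames(emb)
  nbrs <- lapply(ids, function(u) {
    e <- g$edges
    unique(c(e$target[e$source == u], e$source[e$target == u]))
  })
  names(nbrs) <- ids
  aps <- c()
  for (u in ids) {
    tn <- nbrs[[u]]
    if (!length(tn)) next
    others <- setdiff(ids, u)
    dd <- vapply(others, function(v) {
      du <- emb[u, ]; dv <- emb[v, ]
      acosh(1 + 2 * sum((du - dv)^2) / ((1 - sum(du^2)) * (1 - sum(dv^2))))
    }, 1.0)
    o <- others[order(dd, rank(others))]
    hits <- which(o %in% tn)
    aps <- c(aps, mean(seq_along(hits) / hits))
  }
  mean(aps)
}

# random orthogonal matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), d)
}

# sample a point inside the cone at apex x (scale K), at a given radius
# factor; used by the transitivity property
sample_in_cone <- function(x, K, r_target) {
  psi <- cone_aperture(x, K)
  stopifnot(!is.na(psi))
  d <- length(x)
  xh <- x / sqrt(sum(x * x))
  t <- stats::rnorm(d)
  t <- t - sum(t * xh) * xh
  t <- t / sqrt(sum(t * t))
  alpha <- stats::runif(1, 0, 0.9 * psi)
  # walk outward from the apex inside the cone to the target radius
  dir <- cos(alpha) * xh + sin(alpha) * t
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    y <- x + mid * dir
    if (sqrt(sum(y * y)) < r_target) lo <- mid else hi <- mid
  }
  x + lo * dir
}
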