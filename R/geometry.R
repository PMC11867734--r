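# Exact Poincare-ball geometry: geodesic distance, ball projection,
# Riemannian gradient rescaling, and hyperbolic entailment-cone angles.
# All functions operate on plain numeric vectors (a point) or on matrices
# with one point per row; everything is curvature -1 on the open unit ball.

.EPS_DENOM <- 1e-15

row_norms2 <- function(x) {
  if (is.matrix(x)) rowSums(x * x) else sum(x * x)
}

as_point_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

check_in_ball <- function(x, arg = deparse(substitute(x))) {
  n2 <- row_norms2(as_point_matrix(x))
  if (any(n2 >= 1)) {
    stop(sprintf("`%s` must lie strictly inside the unit ball (norm < 1); got norm %.6g",
                 arg, sqrt(max(n2))), call. = FALSE)
  }
  invisible(x)
}

#' Hyperbolic distance in the Poincare ball
#'
#' Geodesic distance of the curvature \eqn{-1} Poincare-ball model,
#' \deqn{d(u,v) = \mathrm{arccosh}\left(1 +
#'   \frac{2\|u-v\|^2}{(1-\|u\|^2)(1-\|v\|^2)}\right),}
#' where \eqn{\|\cdot\|} is the Euclidean norm and both points lie in the
#' open unit ball. Distances blow up near the boundary, which is what lets
#' exponentially growing trees embed with low distortion.
#'
#' @param u,v numeric vectors of equal length (single points), or matrices
#'   with one point per row (distances are taken row-wise).
#' @return A nonnegative numeric vector of distances.
#' @examples
#' poincare_distance(c(0, 0), c(0.5, 0))      # 2 * atanh(0.5)
#' @export
poincare_distance <- function(u, v) {
  U <- as_point_matrix(u); V <- as_point_matrix(v)
  check_in_ball(U, "u"); check_in_ball(V, "v")
  a <- 1 - rowSums(U * U)
  b <- 1 - rowSums(V * V)
  sq <- rowSums((U - V)^2)
  acosh(1 + 2 * sq / (a * b))
}

#' Hyperbolic distance to the origin
#'
#' Closed form \eqn{d(0, x) = 2\,\mathrm{artanh}(\|x\|)}, equal to
#' [poincare_distance()] from the all-zeros point. Used by the root and
#' radial-ordering penalties.
#'
#' @param x a point or a matrix of row points in the open unit ball.
#' @return Nonnegative numeric vector.
#' @export
origin_distance <- function(x) {
  X <- as_point_matrix(x)
  check_in_ball(X, "x")
  2 * atanh(sqrt(rowSums(X * X)))
}

#' Project a vector into the open unit ball
#'
#' Points with norm at most `1 - eps_ball` are returned unchanged; anything
#' outside that radius is rescaled onto the sphere of radius `1 - eps_ball`,
#' preserving direction. Keeping iterates a hair inside the boundary keeps
#' the hyperbolic distance (and its gradient) finite.
#'
#' @param x numeric vector, or matrix of row vectors.
#' @param eps_ball boundary margin in `(0, 0.1)`; default `1e-5`.
#' @return Object of the same shape as `x`, every row with norm
#'   `<= 1 - eps_ball`.
#' @export
project_to_ball <- function(x, eps_ball = 1e-5) {
  stopifnot(is.numeric(eps_ball), length(eps_ball) == 1L,
            eps_ball > 0, eps_ball < 0.1)
  was_vec <- !is.matrix(x)
  X <- as_point_matrix(x)
  nrm <- sqrt(rowSums(X * X))
  lim <- 1 - eps_ball
  over <- which(nrm > lim)
  if (length(over)) X[over, ] <- X[over, , drop = FALSE] * (lim / nrm[over])
  if (was_vec) drop(X) else X
}

#' Riemannian rescaling of a Euclidean gradient
#'
#' Converts the Euclidean gradient `g` at ball point `x` into the Riemannian
#' gradient of the Poincare model by the inverse metric factor
#' \eqn{(1-\|x\|^2)^2/4}. Updates therefore shrink to zero as a point
#' approaches the boundary.
#'
#' @param x point (or matrix of row points) strictly inside the ball.
#' @param g Euclidean gradient with the same shape as `x`.
#' @return `g` scaled row-wise by \eqn{(1-\|x\|^2)^2/4}.
#' @export
riemannian_rescale <- function(x, g) {
  was_vec <- !is.matrix(x)
  X <- as_point_matrix(x); G <- as_point_matrix(g)
  stopifnot(all(dim(X) == dim(G)))
  check_in_ball(X, "x")
  fac <- (1 - rowSums(X * X))^2 / 4
  out <- G * fac
  if (was_vec) drop(out) else out
}

#' Minimum apex radius for a well-defined entailment cone
#'
#' The cone half-aperture \eqn{\psi(x) = \arcsin(K(1-\|x\|^2)/\|x\|)} is only
#' defined when the arcsin argument is at most 1, i.e. for
#' \eqn{\|x\| \ge r_{\min}(K)}, the unique root in `(0, 1)` of
#' \eqn{K(1-r^2)/r = 1}. In closed form
#' \eqn{r_{\min} = (\sqrt{1+4K^2}-1)/(2K)}.
#'
#' @param K positive aperture scale.
#' @return The threshold radius in `(0, 1)`.
#' @export
cone_r_min <- function(K) {
  stopifnot(is.numeric(K), all(K > 0))
  (sqrt(1 + 4 * K^2) - 1) / (2 * K)
}

#' Half-aperture of a hyperbolic entailment cone
#'
#' \eqn{\psi(x) = \arcsin(K(1-\|x\|^2)/\|x\|)}, the half-angle of the
#' outward-opening angular cone at apex `x` inside which the apex's
#' descendants are meant to lie. The aperture is undefined (returned as
#' `NA`) for apexes closer to the origin than [cone_r_min()]: such points
#' would need an aperture wider than a half-space.
#'
#' @param x apex point (or matrix of row apexes) strictly inside the ball.
#' @param K positive aperture scale.
#' @return Angle(s) in radians in `(0, pi/2]`, or `NA` where undefined.
#' @export
cone_aperture <- function(x, K) {
  stopifnot(is.numeric(K), length(K) == 1L, K > 0)
  X <- as_point_matrix(x)
  check_in_ball(X, "x")
  nrm <- sqrt(rowSums(X * X))
  arg <- K * (1 - nrm^2) / pmax(nrm, .EPS_DENOM)
  out <- rep(NA_real_, length(arg))
  ok <- arg <= 1
  out[ok] <- asin(pmax(pmin(arg[ok], 1), -1))
  out
}

#' Angle at a cone apex
#'
#' The angle \eqn{\angle_{xy}} between the half-line from apex `x` through
#' `y` and the outward continuation of the half-line from the origin through
#' `x`:
#' \deqn{\angle_{xy} = \arccos\frac{\|y\|^2 - \|x\|^2 - \|x-y\|^2}
#'   {2\,\|x\|\,\|x-y\|}.}
#' A point directly beyond the apex on its outgoing ray has angle 0; a point
#' between the origin and the apex has angle \eqn{\pi}.
#'
#' @param x apex point(s), nonzero; `y` target point(s) distinct from `x`.
#'   Either may be a matrix of row points.
#' @param y see `x`.
#' @return Angle(s) in radians in `[0, pi]`.
#' @export
angle_at_apex <- function(x, y) {
  X <- as_point_matrix(x); Y <- as_point_matrix(y)
  if (nrow(X) == 1L && nrow(Y) > 1L) X <- X[rep(1L, nrow(Y)), , drop = FALSE]
  if (nrow(Y) == 1L && nrow(X) > 1L) Y <- Y[rep(1L, nrow(X)), , drop = FALSE]
  nx2 <- rowSums(X * X)
  ny2 <- rowSums(Y * Y)
  d2 <- rowSums((X - Y)^2)
  if (any(nx2 == 0)) stop("apex `x` must not be the origin", call. = FALSE)
  if (any(d2 == 0)) stop("`y` must differ from the apex `x`", call. = FALSE)
  cosang <- (ny2 - nx2 - d2) / pmax(2 * sqrt(nx2) * sqrt(d2), .EPS_DENOM)
  acos(pmax(pmin(cosang, 1), -1))
}

#' Entailment-cone membership
#'
#' Tests whether `y` lies inside the angular cone at apex `x` with scale
#' `K`, i.e. whether \eqn{\angle_{xy} \le \psi(x)}.
#'
#' @inheritParams angle_at_apex
#' @param K positive aperture scale.
#' @return Logical vector.
#' @export
in_cone <- function(x, y, K) {
  psi <- cone_aperture(x, K)
  if (any(is.na(psi))) {
    stop("cone aperture undefined: apex norm below cone_r_min(K)", call. = FALSE)
  }
  angle_at_apex(x, y) <= psi
}

#' Hinge energy of a cone violation
#'
#' `max(0, angle_at_apex(x, y) - cone_aperture(x, K))`: zero when `y` lies
#' inside the cone at apex `x`, and growing linearly with the angular
#' violation outside it. Apexes whose aperture is undefined (norm below
#' [cone_r_min()]) are gated: their energy is 0 and they exert no force.
#'
#' @inheritParams in_cone
#' @return Nonnegative numeric vector.
#' @export
cone_energy <- function(x, y, K) {
  psi <- cone_aperture(x, K)
  out <- numeric(length(psi))
  ok <- !is.na(psi)
  if (any(ok)) {
    X <- as_point_matrix(x); Y <- as_point_matrix(y)
    if (nrow(X) == 1L && nrow(Y) > 1L) X <- X[rep(1L, nrow(Y)), , drop = FALSE]
    if (nrow(Y) == 1L && nrow(X) > 1L) Y <- Y[rep(1L, nrow(X)), , drop = FALSE]
    ang <- angle_at_apex(X[ok, , drop = FALSE], Y[ok, , drop = FALSE])
    out[ok] <- pmax(0, ang - psi[ok])
  }
  out
}
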