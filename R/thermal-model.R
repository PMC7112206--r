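#' Finite-cylinder cooling problem specification
#'
#' A collagen gel modeled as a homogeneous finite cylinder, initially at a
#' uniform temperature, whose entire surface is stepped to the bath
#' temperature at `t = 0` (Dirichlet condition on all faces: the gel is
#' submerged in pre-equilibrated media, so convective resistance is
#' neglected). The gel geometry and diffusivity are representative defaults
#' -- a thin 5 mm x 2 mm collagen disc with the thermal diffusivity of water
#' -- and should be overridden when the true values are known.
#'
#' @param radius_m cylinder radius in metres.
#' @param height_m cylinder height in metres.
#' @param diffusivity_m2s thermal diffusivity in m^2/s.
#' @param t_initial_C uniform initial temperature, degrees C.
#' @param t_bath_C bath (surface) temperature, degrees C.
#' @return object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(radius_m = 5e-3, height_m = 2e-3,
                          diffusivity_m2s = 1.4e-7,
                          t_initial_C = 37, t_bath_C = 33) {
  if (radius_m <= 0 || height_m <= 0 || diffusivity_m2s <= 0)
    stop("radius, height and diffusivity must be strictly positive")
  structure(list(radius_m = radius_m, height_m = height_m,
                 diffusivity_m2s = diffusivity_m2s,
                 t_initial_C = t_initial_C, t_bath_C = t_bath_C),
            class = "cylinder_spec")
}

# First n positive zeros of the Bessel function J0, by bisection from the
# McMahon asymptotic brackets.
bessel_j0_zeros <- function(n) {
  vapply(seq_len(n), function(k) {
    guess <- (k - 0.25) * pi
    lo <- guess - 1
    hi <- guess + 1
    uniroot(function(x) besselJ(x, 0), c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

# Dimensionless excess temperature of an infinite cylinder, theta(r, t),
# uniform unit initial condition, zero surface. Vectorized over r.
theta_cylinder <- function(r, t, R, alpha, n_terms) {
  lam <- bessel_j0_zeros(n_terms)
  fo <- alpha * t / R^2
  coef <- 2 / (lam * besselJ(lam, 1)) * exp(-lam^2 * fo)
  # outer(r/R, lam): rows points, cols modes
  bas <- besselJ(outer(r / R, lam), 0)
  as.numeric(bas %*% coef)
}

# Dimensionless excess temperature of a slab 0 <= z <= H, zero at both
# faces, unit initial condition. Vectorized over z.
theta_slab <- function(z, t, H, alpha, n_terms) {
  m <- 2 * seq_len(n_terms) - 1  # odd modes only
  coef <- 4 / (pi * m) * exp(-(m * pi / H)^2 * alpha * t)
  bas <- sin(outer(z, m * pi / H))
  as.numeric(bas %*% coef)
}

#' Temperature inside a cooling cylinder
#'
#' Separable eigenseries solution of the transient heat equation in a finite
#' cylinder with a uniform initial temperature and all surfaces stepped to
#' the bath temperature: the dimensionless excess is the product of an
#' infinite-cylinder Bessel-J0 radial series and a slab sine series in z,
#' each truncated at `n_terms`. At `t = 0` the series representation of the
#' discontinuous initial state converges only slowly (Gibbs oscillation), so
#' the exact initial/boundary values are returned directly. A conservative
#' truncation error bound (product of the first neglected modes' amplitude
#' envelopes) is attached as attribute `truncation_bound`.
#'
#' @param spec a [cylinder_spec()].
#' @param r radial coordinate(s), metres, in `[0, R]`.
#' @param z axial coordinate(s), metres, in `[0, H]` (0 and `H` are the two
#'   faces).
#' @param t time since the step, seconds (>= 0).
#' @param n_terms number of series terms per factor (>= 1).
#' @return temperature(s) in degrees C, vectorized over `r`/`z`.
#' @export
temperature <- function(spec, r, z, t, n_terms = 50L) {
  stopifnot(inherits(spec, "cylinder_spec"))
  if (t < 0) stop("t must be >= 0")
  if (n_terms < 1L) stop("n_terms must be >= 1")
  if (any(r < 0 | r > spec$radius_m)) stop("r out of [0, R]")
  if (any(z < 0 | z > spec$height_m)) stop("z out of [0, H]")
  k <- max(length(r), length(z))
  r <- rep_len(r, k); z <- rep_len(z, k)
  dT <- spec$t_initial_C - spec$t_bath_C
  if (t == 0) {
    on_surface <- r == spec$radius_m | z == 0 | z == spec$height_m
    out <- ifelse(on_surface, spec$t_bath_C, spec$t_initial_C)
    attr(out, "truncation_bound") <- 0
    return(out)
  }
  th_r <- theta_cylinder(r, t, spec$radius_m, spec$diffusivity_m2s, n_terms)
  th_z <- theta_slab(z, t, spec$height_m, spec$diffusivity_m2s, n_terms)
  out <- spec$t_bath_C + dT * th_r * th_z
  # first neglected modes, amplitude envelopes |coef| * exp(-lambda^2 Fo)
  lam_next <- (n_terms + 1 - 0.25) * pi
  m_next <- 2 * n_terms + 1
  b_r <- sqrt(2 * pi / lam_next) * 2 / lam_next *
    exp(-lam_next^2 * spec$diffusivity_m2s * t / spec$radius_m^2)
  b_z <- 4 / (pi * m_next) *
    exp(-(m_next * pi / spec$height_m)^2 * spec$diffusivity_m2s * t)
  attr(out, "truncation_bound") <- abs(dT) * (b_r + b_z)
  out
}

#' Volume fraction of the cylinder within a band of the bath temperature
#'
#' Evaluates the series solution on an `(r, z)` midpoint quadrature grid and
#' returns the r-weighted (cylindrical shell) volume fraction whose excess
#' temperature is at most `tol_fraction` of the imposed step.
#'
#' @param spec a [cylinder_spec()].
#' @param t time since the step, seconds.
#' @param tol_fraction band half-width as a fraction of the step, in
#'   `(0, 1)`; 0.05 means within 5% of the step (0.2 degrees C of a 4 degree
#'   step).
#' @param n_r,n_z quadrature points per axis.
#' @param n_terms series terms per factor.
#' @return fraction in `[0, 1]`.
#' @export
fraction_equilibrated <- function(spec, t, tol_fraction = 0.05,
                                  n_r = 96L, n_z = 96L, n_terms = 50L) {
  stopifnot(inherits(spec, "cylinder_spec"))
  if (tol_fraction <= 0 || tol_fraction >= 1)
    stop("tol_fraction must be in (0, 1)")
  if (t < 0) stop("t must be >= 0")
  if (t == 0) return(0)
  r_mid <- (seq_len(n_r) - 0.5) / n_r * spec$radius_m
  z_mid <- (seq_len(n_z) - 0.5) / n_z * spec$height_m
  th_r <- theta_cylinder(r_mid, t, spec$radius_m, spec$diffusivity_m2s, n_terms)
  th_z <- theta_slab(z_mid, t, spec$height_m, spec$diffusivity_m2s, n_terms)
  theta <- outer(th_r, th_z)  # excess / step
  inside <- abs(theta) <= tol_fraction
  w_r <- r_mid / sum(r_mid)  # shell weights: 2*pi*r*dr / volume
  sum(w_r * rowMeans(inside))
}

#' Time for a volume fraction of the gel to reach the bath band
#'
#' Smallest `t` (bisection to 0.1 s) at which
#' `fraction_equilibrated(spec, t, tol_fraction) >= frac`; well-defined
#' because every interior point's excess decays monotonically under a
#' uniform initial condition, so the equilibrated fraction is non-decreasing
#' in time.
#'
#' @param spec a [cylinder_spec()].
#' @param frac target volume fraction in `(0, 1)`, e.g. 0.95.
#' @param tol_fraction band half-width as a fraction of the step.
#' @param ... passed to [fraction_equilibrated()].
#' @return time in seconds.
#' @export
time_to_fraction <- function(spec, frac, tol_fraction = 0.05, ...) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  f <- function(t) fraction_equilibrated(spec, t, tol_fraction, ...)
  hi <- spec$height_m^2 / spec$diffusivity_m2s  # ~ slab diffusion time
  while (f(hi) < frac) hi <- hi * 2
  lo <- 0
  while (hi - lo > 0.1) {
    mid <- (lo + hi) / 2
    if (f(mid) >= frac) hi <- mid else lo <- mid
  }
  hi
}
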