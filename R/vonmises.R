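# von Mises utilities on the 360-degree response circle.
#
# Dispersion is reported as circular s.d. in degrees, related to the
# concentration kappa through the mean resultant length A1(kappa) =
# I1(kappa)/I0(kappa) and sd_rad = sqrt(-2 * log(A1(kappa))).

# Bessel-ratio A1 with exponential scaling for numerical range; large
# concentrations use the asymptotic expansion (besselI overflows there).
vm_A1 <- function(kappa) {
  if (kappa > 1e4) {
    return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3))
  }
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Convert between von Mises concentration and circular s.d. (degrees)
#'
#' @param sd_deg Circular standard deviation in degrees (> 0).
#' @param kappa Concentration parameter (>= 0).
#' @return `vm_kappa_from_sd()` returns kappa; `vm_sd_from_kappa()` the
#'   circular s.d. in degrees.
#' @export
vm_kappa_from_sd <- function(sd_deg) {
  if (sd_deg <= 0) abort("`sd_deg` must be > 0.")
  r_target <- exp(-deg2rad(sd_deg)^2 / 2)
  uniroot(function(k) vm_A1(k) - r_target,
          lower = 1e-8, upper = 1e7, tol = 1e-10)$root
}

#' @rdname vm_kappa_from_sd
#' @export
vm_sd_from_kappa <- function(kappa) {
  rad2deg(sqrt(-2 * log(vm_A1(kappa))))
}

# log density (per radian) of a von Mises at angular deviation x_deg (degrees)
vm_log_density <- function(x_deg, kappa) {
  log_i0_scaled <- if (kappa > 1e4) {
    # asymptotic: I0(k) ~ e^k / sqrt(2 pi k) * (1 + 1/(8k))
    -0.5 * log(2 * pi * kappa) + log1p(1 / (8 * kappa))
  } else {
    log(besselI(kappa, 0, expon.scaled = TRUE))
  }
  kappa * (cos(deg2rad(x_deg)) - 1) - log(2 * pi) - log_i0_scaled
}

#' Draw von Mises deviates (degrees)
#'
#' Best-Fisher rejection sampler for the von Mises distribution, returning
#' angular deviations in degrees centred on `mu`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0); `kappa = 0` is the circular uniform.
#' @return Angles in degrees, wrapped to `(-180, 180]` around 0.
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  if (kappa < 0) abort("`kappa` must be >= 0.")
  if (kappa == 0) {
    return(circ_diff(runif(n, 0, 360) + mu, 0))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3 - 0.5) * acos(f)
    out[need[ok]] <- theta[ok]
    need <- need[!ok]
  }
  circ_diff(rad2deg(out) + mu, 0)
}
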