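# Real regular solid harmonics as exact trivariate polynomials.
#
# A coil field term of order n, degree m is r^n P_n^m(cos theta) {cos,sin}(m phi),
# Schmidt semi-normalized, without the Condon-Shortley phase.  Every such term is a
# homogeneous polynomial of degree n in (x, y, z), so fields and their Jacobians can
# be evaluated exactly from a monomial table; no spherical-coordinate singularities.

# -- Legendre polynomial coefficients ------------------------------------------------

#' Coefficients of the Legendre polynomial P_n
#'
#' @param n order (non-negative integer).
#' @return numeric vector `c` with `P_n(u) = sum(c[j+1] * u^j)`.
#' @keywords internal
#' @noRd
legendre_coefs <- function(n) {
  if (n == 0) return(1)
  if (n == 1) return(c(0, 1))
  pkm1 <- 1
  pk <- c(0, 1)
  for (k in 1:(n - 1)) {
    up <- c(0, pk)                       # u * P_k
    pm <- c(pkm1, rep(0, length(up) - length(pkm1)))
    pk_next <- ((2 * k + 1) * up - k * pm) / (k + 1)
    pkm1 <- pk
    pk <- pk_next
  }
  pk
}

# m-fold derivative of a univariate polynomial given by its coefficient vector
poly1d_deriv <- function(coefs, m) {
  for (i in seq_len(m)) {
    if (length(coefs) <= 1) return(0)
    coefs <- coefs[-1] * seq_len(length(coefs) - 1)
  }
  coefs
}

# -- trivariate monomial polynomials -------------------------------------------------
# Representation: list(E = integer matrix (terms x 3) of exponents, c = coefficients)

tripoly <- function(E, c) {
  E <- matrix(as.numeric(E), ncol = 3)
  keep <- c != 0
  list(E = E[keep, , drop = FALSE], c = c[keep])
}

tripoly_zero <- function() tripoly(matrix(numeric(0), ncol = 3), numeric(0))

tripoly_simplify <- function(p) {
  if (length(p$c) == 0) return(p)
  key <- paste(p$E[, 1], p$E[, 2], p$E[, 3])
  cc <- tapply(p$c, key, sum)
  keys <- names(cc)
  parts <- do.call(rbind, lapply(strsplit(keys, " "), as.numeric))
  tripoly(parts, as.numeric(cc))
}

tripoly_add <- function(a, b) {
  tripoly_simplify(list(E = rbind(a$E, b$E), c = c(a$c, b$c)))
}

tripoly_scale <- function(p, s) list(E = p$E, c = p$c * s)

tripoly_mul <- function(a, b) {
  if (length(a$c) == 0 || length(b$c) == 0) return(tripoly_zero())
  E <- matrix(0, nrow = length(a$c) * length(b$c), ncol = 3)
  cc <- numeric(nrow(E))
  r <- 0L
  for (i in seq_along(a$c)) {
    for (j in seq_along(b$c)) {
      r <- r + 1L
      E[r, ] <- a$E[i, ] + b$E[j, ]
      cc[r] <- a$c[i] * b$c[j]
    }
  }
  tripoly_simplify(list(E = E, c = cc))
}

tripoly_pow <- function(p, k) {
  out <- tripoly(matrix(c(0, 0, 0), ncol = 3), 1)
  for (i in seq_len(k)) out <- tripoly_mul(out, p)
  out
}

# partial derivative along axis 1, 2 or 3
tripoly_deriv <- function(p, axis) {
  if (length(p$c) == 0) return(p)
  e <- p$E[, axis]
  keep <- e > 0
  if (!any(keep)) return(tripoly_zero())
  E <- p$E[keep, , drop = FALSE]
  cc <- p$c[keep] * E[, axis]
  E[, axis] <- E[, axis] - 1
  tripoly(E, cc)
}

# vectorized evaluation at points (x, y, z are equal-length vectors)
tripoly_eval <- function(p, x, y, z) {
  out <- numeric(length(x))
  for (i in seq_along(p$c)) {
    out <- out + p$c[i] * x^p$E[i, 1] * y^p$E[i, 2] * z^p$E[i, 3]
  }
  out
}

# -- solid harmonics -----------------------------------------------------------------

# Re[(x+iy)^m] or Im[(x+iy)^m] as a polynomial in x, y
angular_poly <- function(m, type) {
  if (m == 0) {
    if (type == "sin") return(tripoly_zero())
    return(tripoly(matrix(c(0, 0, 0), ncol = 3), 1))
  }
  t <- 0:m
  coef <- choose(m, t)
  if (type == "cos") {
    keep <- t %% 2 == 0
    sign <- (-1)^(t[keep] / 2)
  } else {
    keep <- t %% 2 == 1
    sign <- (-1)^((t[keep] - 1) / 2)
  }
  tt <- t[keep]
  tripoly(cbind(m - tt, tt, 0), coef[keep] * sign)
}

#' Solid harmonic term as a trivariate polynomial
#'
#' Builds `r^n P_n^m(cos theta) {cos,sin}(m phi)` (Schmidt semi-normalized associated
#' Legendre functions, no Condon-Shortley phase) as an exact polynomial in (x, y, z).
#' For n = 1 the three terms reduce to the coordinates themselves:
#' (1,0,cos) -> z, (1,1,cos) -> x, (1,1,sin) -> y.
#'
#' @param n order, `n >= 1`.
#' @param m degree, `0 <= m <= n`.
#' @param type `"cos"` or `"sin"` azimuthal dependence.
#' @return internal polynomial representation (exponent table + coefficients).
#' @keywords internal
#' @noRd
solid_harmonic_poly <- function(n, m, type = c("cos", "sin")) {
  type <- match.arg(type)
  stopifnot(n >= 1, m >= 0, m <= n)
  if (m == 0 && type == "sin") stop("sin terms with m = 0 are identically zero")
  q <- poly1d_deriv(legendre_coefs(n), m)   # d^m/du^m P_n(u)
  r2 <- tripoly(diag(2, 3, 3), c(1, 1, 1))  # x^2 + y^2 + z^2
  radial <- tripoly_zero()
  for (j in seq_along(q)) {
    jj <- j - 1L                            # power of u = z/r
    if (q[j] == 0) next
    k2 <- n - m - jj                        # leftover power of r
    if (k2 < 0 || k2 %% 2 != 0) next        # parity: only even leftovers survive
    term <- tripoly_mul(tripoly(matrix(c(0, 0, jj), ncol = 3), 1), tripoly_pow(r2, k2 / 2))
    radial <- tripoly_add(radial, tripoly_scale(term, q[j]))
  }
  schmidt <- if (m == 0) 1 else sqrt(2 * factorial(n - m) / factorial(n + m))
  tripoly_scale(tripoly_mul(angular_poly(m, type), radial), schmidt)
}
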