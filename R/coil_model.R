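# Gradient-coil field model: solid-harmonic expansion per coil axis, analytic
# Jacobian (the GNL tensor L), and the per-direction / trace b-value correctors.

#' Construct a gradient-coil nonlinearity model
#'
#' The normalized field of coil axis `a` is
#' `f_a(r) = sum_t coef_t * R0 * S_{n,m,type}(r / R0)`, where `S` is a real solid
#' harmonic (Schmidt semi-normalized, no Condon-Shortley phase).  Coordinates are in
#' mm in a right-handed magnet frame with the origin at isocenter (+x patient left,
#' +y posterior-to-anterior, +z superior).  The first-order part of each axis must
#' reproduce the nominal unit gradient, i.e. `grad f_a(0) = e_a`; a perfectly linear
#' coil is the single term (n = 1, coefficient 1) on its own axis.  Fields are
#' evaluated only within the validity radius `1.5 * R0`; points beyond it are flagged
#' (`NA`) rather than extrapolated.
#'
#' @param terms data.frame with columns `axis` ("x", "y" or "z"), `n` (order >= 1),
#'   `m` (degree, `0 <= m <= n`), `type` ("cos" or "sin") and `coef` (dimensionless).
#' @param R0 reference radius in mm (> 0).
#' @param name optional model name/version string.
#' @return an object of class `coil_model`.
#' @examples
#' lin <- linear_coil_model()
#' evaluate_field(lin, "z", cbind(0, 0, 100))  # 100: a linear coil returns the coordinate
#' @export
coil_model <- function(terms, R0, name = "custom") {
  stopifnot(is.data.frame(terms), is.numeric(R0), length(R0) == 1, R0 > 0)
  needed <- c("axis", "n", "m", "type", "coef")
  if (!all(needed %in% names(terms))) {
    stop("coil model terms need columns: ", paste(needed, collapse = ", "))
  }
  if (!all(terms$axis %in% c("x", "y", "z"))) stop("axis must be 'x', 'y' or 'z'")
  if (!all(terms$type %in% c("cos", "sin"))) stop("type must be 'cos' or 'sin'")
  if (!all(is.finite(terms$coef))) stop("non-finite coefficient: model rejected")
  if (!all(terms$n >= 1 & terms$m >= 0 & terms$m <= terms$n)) {
    stop("terms require n >= 1 and 0 <= m <= n")
  }

  fields <- list()
  for (ax in c("x", "y", "z")) {
    sub <- terms[terms$axis == ax, , drop = FALSE]
    p <- tripoly_zero()
    for (i in seq_len(nrow(sub))) {
      p <- tripoly_add(p, tripoly_scale(
        solid_harmonic_poly(sub$n[i], sub$m[i], sub$type[i]), sub$coef[i]))
    }
    fields[[ax]] <- list(
      f  = p,
      dx = tripoly_deriv(p, 1),
      dy = tripoly_deriv(p, 2),
      dz = tripoly_deriv(p, 3)
    )
  }

  model <- structure(
    list(terms = terms[, needed], R0 = R0, name = name, fields = fields),
    class = "coil_model")

  # normalization invariant: nominal unit gradient at isocenter
  J0 <- gnl_tensor_at(model, matrix(0, 1, 3))[1, , ]
  if (max(abs(J0 - diag(3))) > 1e-8) {
    stop("first-order terms must reproduce the nominal gradient: grad f_a(0) != e_a")
  }
  model
}

#' @export
print.coil_model <- function(x, ...) {
  cat("<coil_model> ", x$name, "\n", sep = "")
  cat("  R0:", x$R0, "mm; validity radius:", validity_radius(x), "mm\n")
  cat("  terms:", nrow(x$terms), "\n")
  invisible(x)
}

#' Radius within which the harmonic expansion is trusted
#'
#' @param model a [coil_model()].
#' @return validity radius in mm (`1.5 * R0`).
#' @export
validity_radius <- function(model) 1.5 * model$R0

#' Ideal (purely linear) gradient coil model
#'
#' @param R0 reference radius in mm.
#' @return a [coil_model()] whose normalized fields are the coordinates themselves,
#'   so the GNL tensor is the identity everywhere and all b-value bias vanishes.
#' @export
linear_coil_model <- function(R0 = 250) {
  coil_model(data.frame(
    axis = c("x", "y", "z"),
    n = 1, m = c(1, 1, 0),
    type = c("cos", "sin", "cos"),
    coef = 1), R0 = R0, name = "linear")
}

#' Representative whole-body gradient coil model
#'
#' Reads the coil configuration shipped with the package: a linear term plus odd
#' order-3 and order-5 harmonics per axis, calibrated so that the trace b-value bias
#' spans roughly -10% (at 200 mm superior-inferior offset) to +8% (at 200 mm
#' right-left offset), the bias regime typical of torso imaging on clinical 3T
#' systems.  The true vendor coefficients of any particular scanner are proprietary;
#' this synthetic model reproduces their qualitative spatial structure.
#'
#' @return a [coil_model()].
#' @export
default_coil_model <- function() {
  read_coil_model(system.file("extdata", "coil_default.yaml", package = "gncadc"))
}

#' Read / write a coil model configuration file
#'
#' The file is YAML with keys `name`, `R0_mm` and `terms`, the latter a list of
#' `{axis, n, m, type, coef}` records.  Writing then reading reproduces the model
#' losslessly (coefficients are stored at full precision).
#'
#' @param path file path.
#' @return [read_coil_model()] returns a [coil_model()]; [write_coil_model()] returns
#'   `path` invisibly.
#' @export
read_coil_model <- function(path) {
  if (!file.exists(path)) stop("coil model file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$R0_mm) || is.null(cfg$terms)) {
    stop("coil model file needs keys 'R0_mm' and 'terms'")
  }
  terms <- do.call(rbind, lapply(cfg$terms, function(t) {
    data.frame(axis = t$axis, n = t$n, m = t$m, type = t$type,
               coef = as.numeric(t$coef))
  }))
  coil_model(terms, R0 = cfg$R0_mm, name = cfg$name %||% basename(path))
}

#' @param model a [coil_model()].
#' @rdname read_coil_model
#' @export
write_coil_model <- function(model, path) {
  stopifnot(inherits(model, "coil_model"))
  cfg <- list(
    name = model$name,
    R0_mm = model$R0,
    terms = lapply(seq_len(nrow(model$terms)), function(i) {
      t <- model$terms[i, ]
      list(axis = t$axis, n = as.integer(t$n), m = as.integer(t$m),
           type = t$type, coef = format(t$coef, digits = 17))
    }))
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  points
}

#' Evaluate a normalized coil field
#'
#' @param model a [coil_model()].
#' @param axis coil axis, one of "x", "y", "z".
#' @param points n x 3 matrix of magnet-frame coordinates in mm.
#' @return numeric vector `f_a(r)` in mm; points beyond the validity radius return
#'   `NA` with a warning (flagged, never silently extrapolated).
#' @export
evaluate_field <- function(model, axis, points) {
  stopifnot(inherits(model, "coil_model"), axis %in% c("x", "y", "z"))
  points <- as_points(points)
  R0 <- model$R0
  out <- R0 * tripoly_eval(model$fields[[axis]]$f,
                           points[, 1] / R0, points[, 2] / R0, points[, 3] / R0)
  bad <- sqrt(rowSums(points^2)) > validity_radius(model)
  if (any(bad)) {
    out[bad] <- NA_real_
    warning(sum(bad), " point(s) beyond the validity radius (",
            validity_radius(model), " mm) flagged as NA")
  }
  out
}

# Jacobian of the normalized fields at arbitrary points: n x 3 x 3 array with
# [p, a, b] = d f_a / d x_b.  No validity check (internal).
gnl_tensor_at <- function(model, points) {
  points <- as_points(points)
  R0 <- model$R0
  X <- points[, 1] / R0; Y <- points[, 2] / R0; Z <- points[, 3] / R0
  L <- array(0, dim = c(nrow(points), 3, 3))
  axs <- c("x", "y", "z")
  ders <- c("dx", "dy", "dz")
  for (a in 1:3) {
    for (b in 1:3) {
      L[, a, b] <- tripoly_eval(model$fields[[axs[a]]][[ders[b]]], X, Y, Z)
    }
  }
  L
}

#' Gradient-nonlinearity tensor field on a grid
#'
#' Evaluates the GNL tensor `L(r)`, the Jacobian of the normalized coil fields
#' (`L[a, b] = d f_a / d x_b`), at every voxel center of a grid.  `L` maps nominal to
#' actual gradient vectors and is the identity at isocenter.
#'
#' @param model a [coil_model()].
#' @param geom grid geometry from [grid_geometry()].
#' @return object of class `gnl_tensor_field`: list with `geom` and `L`, an array of
#'   dimension `c(prod(dim), 3, 3)` in voxel-linear order.
#' @export
gnl_tensor <- function(model, geom) {
  stopifnot(inherits(model, "coil_model"))
  pts <- grid_points(geom)
  r <- sqrt(rowSums(pts^2))
  if (any(r > validity_radius(model))) {
    stop(sprintf(
      "grid extends to %.0f mm from isocenter, beyond the validity radius (%.0f mm)",
      max(r), validity_radius(model)))
  }
  structure(list(geom = geom, L = gnl_tensor_at(model, pts)),
            class = "gnl_tensor_field")
}

#' Orthonormal diffusion-gradient direction set
#'
#' @param u matrix with three rows, one unit vector per row.  Default: the laboratory
#'   axes.
#' @return a 3 x 3 matrix of class `direction_set`, validated pairwise orthonormal to
#'   1e-10.
#' @export
direction_set <- function(u = diag(3)) {
  u <- as.matrix(u)
  stopifnot(all(dim(u) == c(3, 3)))
  if (max(abs(u %*% t(u) - diag(3))) > 1e-10) {
    stop("direction set must be an orthonormal triad")
  }
  structure(u, class = c("direction_set", "matrix"))
}

#' Per-direction b-value corrector
#'
#' For a diffusion gradient applied along unit vector `u`, the actual b-value is
#' `c * b_nominal` with `c = u' (L'L) u`, the quadratic form of the GNL tensor.
#'
#' @param L 3 x 3 GNL tensor.
#' @param u unit direction vector (length 3).
#' @return scalar corrector `c > 0`.
#' @export
direction_corrector <- function(L, u) {
  L <- as.matrix(L)
  stopifnot(all(dim(L) == c(3, 3)), length(u) == 3)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("direction vector must be non-zero")
  if (abs(nu - 1) > 1e-8) stop("direction vector must have unit norm")
  as.numeric(crossprod(L %*% u))
}

#' Trace b-value corrector
#'
#' Trace DWI averages the log-signal over three orthogonal directions, so the
#' effective corrector is the mean of the per-direction correctors,
#' `cbar = mean_k u_k' (L'L) u_k = tr(L'L) / 3`, independent of which orthonormal
#' triad is used.
#'
#' @param L 3 x 3 GNL tensor.
#' @param dirs a [direction_set()].
#' @return scalar `cbar > 0`.
#' @export
trace_corrector <- function(L, dirs = direction_set()) {
  if (!inherits(dirs, "direction_set")) dirs <- direction_set(dirs)
  mean(vapply(1:3, function(k) direction_corrector(L, dirs[k, ]), numeric(1)))
}

# Fast trace corrector cbar = tr(L'L)/3 = sum_ab (dfa/dxb)^2 / 3 at many points.
cbar_at <- function(model, points) {
  points <- as_points(points)
  R0 <- model$R0
  X <- points[, 1] / R0; Y <- points[, 2] / R0; Z <- points[, 3] / R0
  acc <- numeric(nrow(points))
  for (ax in c("x", "y", "z")) {
    for (d in c("dx", "dy", "dz")) {
      acc <- acc + tripoly_eval(model$fields[[ax]][[d]], X, Y, Z)^2
    }
  }
  acc / 3
}

# Per-direction correctors at many points: n x 3 matrix with column k = u_k'L'Lu_k.
direction_correctors_at <- function(model, points, dirs = direction_set()) {
  if (!inherits(dirs, "direction_set")) dirs <- direction_set(dirs)
  L <- gnl_tensor_at(model, as_points(points))
  out <- matrix(0, nrow = dim(L)[1], ncol = 3)
  for (k in 1:3) {
    u <- dirs[k, ]
    for (a in 1:3) {
      Lu <- L[, a, 1] * u[1] + L[, a, 2] * u[2] + L[, a, 3] * u[3]
      out[, k] <- out[, k] + Lu^2
    }
  }
  out
}
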