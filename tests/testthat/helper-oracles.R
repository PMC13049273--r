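# Shared fixtures and independent oracles used across the suite.

# toy single-axis cubic model: f_z = z + eps * z^3 / R0^2 on the z axis
toy_cubic_model <- function(eps = 0.1, R0 = 250) {
  coil_model(rbind(
    data.frame(axis = "x", n = 1, m = 1, type = "cos", coef = 1),
    data.frame(axis = "y", n = 1, m = 1, type = "sin", coef = 1),
    data.frame(axis = "z", n = 1, m = 0, type = "cos", coef = 1),
    data.frame(axis = "z", n = 3, m = 0, type = "cos", coef = eps)),
    R0 = R0, name = "toy-cubic")
}

# random odd-order (3rd/5th) model with small coefficients
random_coil_model <- function(seed = 1, scale = 0.03) {
  set.seed(seed)
  extra <- do.call(rbind, lapply(c("x", "y", "z"), function(ax) {
    rows <- list()
    for (n in c(3, 5)) {
      for (m in 0:n) {
        for (ty in c("cos", "sin")) {
          if (m == 0 && ty == "sin") next
          if (stats::runif(1) < 0.4) {
            rows[[length(rows) + 1]] <- data.frame(
              axis = ax, n = n, m = m, type = ty,
              coef = stats::rnorm(1, 0, scale))
          }
        }
      }
    }
    do.call(rbind, rows)
  }))
  base <- rbind(
    data.frame(axis = "x", n = 1, m = 1, type = "cos", coef = 1),
    data.frame(axis = "y", n = 1, m = 1, type = "sin", coef = 1),
    data.frame(axis = "z", n = 1, m = 0, type = "cos", coef = 1))
  coil_model(rbind(base, extra), R0 = 250, name = "random-odd")
}

# random well-conditioned 3x3 tensor near identity
random_tensor <- function(seed = 1) {
  set.seed(seed)
  diag(3) + matrix(stats::rnorm(9, 0, 0.05), 3, 3)
}

# random orthonormal triad via QR
random_triad <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  direction_set(t(q))
}

# central finite-difference Jacobian of the normalized fields
fd_jacobian <- function(model, point, h = 0.01) {
  J <- matrix(0, 3, 3)
  axs <- c("x", "y", "z")
  for (a in 1:3) {
    for (b in 1:3) {
      pp <- pm <- point
      pp[b] <- pp[b] + h
      pm[b] <- pm[b] - h
      J[a, b] <- (evaluate_field(model, axs[a], matrix(pp, 1)) -
                    evaluate_field(model, axs[a], matrix(pm, 1))) / (2 * h)
    }
  }
  J
}

# brute-force quadratic form u' (L'L) u via explicit double loop
brute_corrector <- function(L, u) {
  G <- t(L) %*% L
  acc <- 0
  for (a in 1:3) for (b in 1:3) acc <- acc + u[a] * G[a, b] * u[b]
  acc
}

# sign-flip enumeration p-value for a paired t test (one-sided: mean > 0)
signflip_p <- function(d, two_sided = FALSE) {
  n <- length(d)
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(n))
  t_obs <- tstat(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  ts <- apply(signs, 1, function(s) tstat(s * abs(d)))
  if (two_sided) mean(abs(ts) >= abs(t_obs) - 1e-12) else mean(ts >= t_obs - 1e-12)
}

# small uniform-value test volume on a 2 mm grid
uniform_labelled_volume <- function(value = 0.5, n_voxels = 100, spacing = 2) {
  dims <- c(n_voxels, 1, 1)
  geom <- grid_geometry(dims, rep(spacing, 3))
  vol <- image_volume(array(value, dims), geom, "micron2/ms")
  labels <- image_volume(array(site_codes()[["L3"]], dims), geom, "label")
  list(vol = vol, labels = labels)
}
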