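# Internal ODE integrators. The deployment image carries no ODE solver
# package, so the two workhorses are implemented here: an adaptive
# Dormand-Prince 4(5) pair for non-stiff problems and a Rosenbrock
# ode23s-type method (L-stable, order 2 with 3rd-order error estimate) for
# the stiff syntrophic community model, where the dissolved-hydrogen pool
# relaxes on a timescale of seconds while the culture evolves over days.

# Dormand-Prince coefficients
.DP <- local({
  a <- matrix(0, 7, 7)
  a[2, 1] <- 1 / 5
  a[3, 1:2] <- c(3 / 40, 9 / 40)
  a[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
  a[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
  a[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656)
  a[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  list(
    a = a,
    c = c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1),
    b5 = c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0),
    b4 = c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
           187 / 2100, 1 / 40)
  )
})

# Adaptive explicit Runge-Kutta 4(5). f(t, y) -> dy/dt. Returns a matrix
# with one row per requested output time.
ode_rk45 <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                     h_init = NULL, max_steps = 5e6) {
  n <- length(y0)
  out <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- if (is.null(h_init)) (times[2] - times[1]) / 10 else h_init
  k <- matrix(0, 7, n)
  steps <- 0L
  for (i in seq_along(times)[-1]) {
    t_end <- times[i]
    while (t < t_end) {
      h <- min(h, t_end - t)
      k[1, ] <- f(t, y)
      for (s in 2:7) {
        k[s, ] <- f(t + .DP$c[s] * h,
                    y + h * drop(.DP$a[s, 1:(s - 1), drop = FALSE] %*%
                                   k[1:(s - 1), , drop = FALSE]))
      }
      y5 <- y + h * drop(.DP$b5 %*% k)
      y4 <- y + h * drop(.DP$b4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (is.na(err) || !is.finite(err)) err <- 2
      if (err <= 1) {
        t <- t + h
        y <- y5
      }
      h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-10))^(1 / 5)))
      steps <- steps + 1L
      if (steps > max_steps) stop("ode_rk45: step limit exceeded", call. = FALSE)
    }
    out[i, ] <- y
  }
  out
}

# Rosenbrock ode23s (Shampine & Reichelt) for autonomous systems, with a
# forward-difference Jacobian refreshed every step. L-stable; suitable for
# the stiff community model at modest accuracy cost.
ode_ros23 <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                      h_init = NULL, max_steps = 2e6) {
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  n <- length(y0)
  eye <- diag(n)
  out <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- if (is.null(h_init)) (times[2] - times[1]) / 10 else h_init
  steps <- 0L
  jac <- function(t, y, f0) {
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      dy <- max(1e-8, 1e-8 * abs(y[j]))
      yp <- y
      yp[j] <- yp[j] + dy
      J[, j] <- (f(t, yp) - f0) / dy
    }
    J
  }
  for (i in seq_along(times)[-1]) {
    t_end <- times[i]
    while (t < t_end) {
      h <- min(h, t_end - t)
      f0 <- f(t, y)
      J <- jac(t, y, f0)
      repeat {
        W <- eye - h * d * J
        LU <- tryCatch(solve(W), error = function(e) NULL)
        if (is.null(LU)) {
          h <- h / 2
          next
        }
        k1 <- drop(LU %*% f0)
        f1 <- f(t + h / 2, y + h / 2 * k1)
        k2 <- drop(LU %*% (f1 - k1)) + k1
        y1 <- y + h * k2
        f2 <- f(t + h, y1)
        k3 <- drop(LU %*% (f2 - e32 * (k2 - f1) - 2 * (k1 - f0)))
        errv <- (h / 6) * (k1 - 2 * k2 + k3)
        sc <- atol + rtol * pmax(abs(y), abs(y1))
        err <- sqrt(mean((errv / sc)^2))
        if (is.na(err) || !is.finite(err)) err <- 2
        if (err <= 1) {
          t <- t + h
          y <- y1
          h <- h * min(5, max(0.2, 0.8 * (1 / max(err, 1e-10))^(1 / 3)))
          break
        }
        h <- h * max(0.2, 0.8 * (1 / err)^(1 / 3))
        steps <- steps + 1L
        if (steps > max_steps) stop("ode_ros23: step limit exceeded", call. = FALSE)
      }
      steps <- steps + 1L
      if (steps > max_steps) stop("ode_ros23: step limit exceeded", call. = FALSE)
    }
    out[i, ] <- y
  }
  out
}
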