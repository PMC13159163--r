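# Moving-boundary diffusion model of a cooling condensate.
#
# A single spherical condensate of radius R(t) is cooled; the interface
# concentration is pinned to the dense binodal c*(T(t)) while the interior
# relaxes by diffusion,
#   dc/dt = D (1/r^2) d/dr ( r^2 dc/dr ),   c(R(t), t) = c*(T(t)),
# and the total solute mass integral(4 pi r^2 c dr) is conserved: as the
# condensate densifies it shrinks. Shrinkage follows a discrete rule on the
# fixed grid: whenever the solute mass on all but the outermost grid point
# exceeds the initial mass, the outermost point is removed.

#' Linear cooling protocol
#'
#' Temperature ramps from `T0` down to `T_end` at constant rate
#' \eqn{T(t) = T_0 - \alpha t}, then (optionally) holds at `T_end` until the
#' condensate has equilibrated.
#'
#' @param T0 initial temperature (K)
#' @param T_end final temperature (K), < `T0` (equal for an isothermal hold)
#' @param rate cooling rate \eqn{\alpha} (K/s), > 0
#' @param hold hold at `T_end` until equilibration (default TRUE)
#' @return an object of class `cooling_protocol`
#' @examples
#' cooling_protocol(celsius_to_kelvin(55), celsius_to_kelvin(36),
#'                  rate = 5 / 60)
#' @export
cooling_protocol <- function(T0, T_end, rate, hold = TRUE) {
  stopifnot(T0 >= T_end, rate > 0)
  structure(list(T0 = T0, T_end = T_end, rate = rate, hold = hold),
            class = "cooling_protocol")
}

protocol_temperature <- function(t, protocol) {
  pmax(protocol$T0 - protocol$rate * t, protocol$T_end)
}

#' Characteristic diffusive equilibration time
#'
#' \eqn{\tau = r^2 / (6 D)}: the timescale on which diffusion levels out
#' concentration gradients across a sphere of radius `r`.
#'
#' @param r sphere radius (m)
#' @param D diffusivity (m^2/s)
#' @return time (s), vectorised
#' @export
characteristic_time <- function(r, D) {
  stopifnot(all(r > 0), all(D > 0))
  r^2 / (6 * D)
}

# trapezoid mass integral(0..r_k) 4 pi r^2 c dr on the uniform grid,
# over the first `k` nodes of (r, conc)
shell_mass <- function(r, conc, k) {
  rr <- r[seq_len(k)]
  cc <- conc[seq_len(k)]
  w <- 4 * pi * rr^2 * cc
  sum((w[-1] + w[-k]) / 2) * (rr[2] - rr[1])
}

# Thomas algorithm for a tridiagonal system. `lower` and `upper` have
# length m - 1. Plain R loops; m is a few hundred so this is cheap.
thomas_solve <- function(lower, diag, upper, rhs) {
  m <- length(diag)
  cp <- numeric(m - 1)
  dp <- numeric(m)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:m) {
    denom <- diag[i] - lower[i - 1] * cp[i - 1]
    if (i < m) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
  }
  x <- numeric(m)
  x[m] <- dp[m]
  for (i in (m - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Simulate a cooling condensate
#'
#' Method-of-lines on a fixed radial grid with implicit (backward-Euler)
#' time stepping by default; an explicit option is provided (aborting with a
#' diagnostic when its stability limit is violated). The interface node is
#' pinned to the dense binodal concentration at the current temperature; a
#' zero-gradient condition holds at the centre. The run ends when the
#' maximum relative deviation of the profile from the final binodal value
#' drops below `eq_tol` (or at the end of cooling when `hold = FALSE`).
#'
#' @param R0 initial condensate radius (m)
#' @param protocol a [cooling_protocol()]
#' @param model a [phase_model()]
#' @param D dense-phase diffusivity (m^2/s)
#' @param c0 initial (uniform) concentration (kg/m^3); defaults to the dense
#'   binodal concentration at `protocol$T0`
#' @param n_grid number of grid intervals spanning `R0` (default 500; the
#'   discrete shrinkage rule bounds the mass drift by roughly one outer
#'   shell, ~3/n_grid, so the default keeps it below 1 percent)
#' @param dT_step temperature change per time step during cooling (K);
#'   sets the cooling-phase time step as `dT_step / rate`
#' @param dt_hold time step during the hold phase (s); default
#'   `tau / 400` with `tau` the characteristic time of the condensate
#' @param eq_tol relative equilibration tolerance ending the hold phase
#' @param save_every store every k-th time step in the trajectory
#' @param method `"implicit"` (default) or `"explicit"`
#' @param max_steps safety cap on the number of time steps
#' @return an object of class `condensate_trajectory`: list with `times`,
#'   `T` (K), `R` (m), `r` (grid, m), `conc` (time x radius matrix, NA
#'   outside the condensate), `n_valid` (grid points inside the condensate
#'   per saved time), `phi_minus`, `phi_plus`, `mass` (kg per saved time),
#'   `mass0`, and the simulation inputs
#' @examples
#' \donttest{
#' m <- fh_preset("m2000")
#' pr <- cooling_protocol(celsius_to_kelvin(55), celsius_to_kelvin(36), 5 / 60)
#' traj <- simulate_condensate(20e-6, pr, m, D = 1.3e-13)
#' }
#' @export
simulate_condensate <- function(R0, protocol, model, D, c0 = NULL,
                                n_grid = 500, dT_step = 0.05,
                                dt_hold = NULL, eq_tol = 1e-3,
                                save_every = 1L,
                                method = c("implicit", "explicit"),
                                max_steps = 2e5) {
  method <- match.arg(method)
  stopifnot(R0 > 0, D > 0, n_grid >= 10)
  dr <- R0 / n_grid
  r <- seq(0, R0, by = dr)
  np <- n_grid + 1L

  # binodal lookup over the protocol's temperature range (0.01 K table)
  Tlo <- protocol$T_end; Thi <- protocol$T0
  tab_T <- seq(Tlo - 1e-9, Thi + 1e-9, length.out = max(2L, ceiling((Thi - Tlo) / 0.01) + 1L))
  tab <- binodal_curve(tab_T, model)
  phi_minus_at <- stats::approxfun(tab$T, tab$phi_minus, rule = 2)
  phi_plus_at <- stats::approxfun(tab$T, tab$phi_plus, rule = 2)
  cstar <- function(TK) phi_plus_at(TK) * model$rho_solute

  if (is.null(c0)) c0 <- cstar(protocol$T0)
  conc <- rep(c0, np)
  n_val <- np # nodes currently inside the condensate
  conc[n_val] <- cstar(protocol$T0)
  mass0 <- shell_mass(r, conc, n_val)

  dt_cool <- dT_step / protocol$rate
  if (is.null(dt_hold)) dt_hold <- characteristic_time(R0, D) / 400
  t_cool <- (protocol$T0 - protocol$T_end) / protocol$rate
  c_end <- cstar(protocol$T_end)

  if (method == "explicit") {
    dt_stab <- dr^2 / (6 * D)
    if (min(dt_cool, dt_hold) > dt_stab) {
      stop(sprintf(paste0("explicit scheme unstable: time step %.3g s exceeds ",
                          "the stability limit dr^2/(6D) = %.3g s; refine the ",
                          "step or use method = 'implicit'"),
                   min(dt_cool, dt_hold), dt_stab))
    }
  }

  # one backward-Euler step on nodes 1..m (R indices) with Dirichlet at m+1
  step_implicit <- function(conc, m, dt, c_bnd) {
    idx <- seq_len(m) # unknowns: centre .. last interior node
    rr <- r[idx]
    rp <- rr + dr / 2; rm <- pmax(rr - dr / 2, 0)
    lam <- D * dt / dr^2
    ci <- ifelse(rr > 0, lam * rp^2 / rr^2, 6 * lam) # coupling to i+1
    ai <- ifelse(rr > 0, lam * rm^2 / rr^2, 0)       # coupling to i-1
    rhs <- conc[idx]
    rhs[m] <- rhs[m] + ci[m] * c_bnd
    thomas_solve(-ai[-1], 1 + ai + ci, -ci[-m], rhs)
  }
  step_explicit <- function(conc, m, dt, c_bnd) {
    idx <- seq_len(m)
    rr <- r[idx]
    rp <- rr + dr / 2; rm <- pmax(rr - dr / 2, 0)
    lam <- D * dt / dr^2
    cfull <- c(conc[idx], c_bnd)
    up <- cfull[idx + 1L] - cfull[idx]
    dn <- c(0, cfull[idx[-1]] - cfull[idx[-m]])
    flux <- ifelse(rr > 0, lam * (rp^2 * up - rm^2 * dn) / rr^2, 6 * lam * up)
    conc[idx] + flux
  }
  stepper <- if (method == "implicit") step_implicit else step_explicit

  # storage
  cap <- 4096L
  s_t <- numeric(cap); s_T <- numeric(cap); s_n <- integer(cap)
  s_c <- matrix(NA_real_, cap, np)
  nsave <- 0L
  push <- function(t, TK, conc, m) {
    nsave <<- nsave + 1L
    if (nsave > cap) {
      cap <<- cap * 2L
      s_t <<- c(s_t, numeric(cap / 2)); s_T <<- c(s_T, numeric(cap / 2))
      s_n <<- c(s_n, integer(cap / 2))
      s_c <<- rbind(s_c, matrix(NA_real_, cap / 2, np))
    }
    s_t[nsave] <<- t; s_T[nsave] <<- TK; s_n[nsave] <<- m
    s_c[nsave, seq_len(m)] <<- conc[seq_len(m)]
  }

  t <- 0
  TK <- protocol$T0
  push(t, TK, conc, n_val)
  step <- 0L
  equilibrated <- FALSE
  while (step < max_steps) {
    step <- step + 1L
    cooling <- t < t_cool - 1e-12
    dt <- if (cooling) min(dt_cool, t_cool - t) else dt_hold
    t_new <- t + dt
    T_new <- protocol_temperature(t_new, protocol)
    c_bnd <- cstar(T_new)

    m <- n_val - 1L # interior unknowns (boundary node is Dirichlet)
    conc[seq_len(m)] <- stepper(conc, m, dt, c_bnd)
    conc[n_val] <- c_bnd

    # discrete shrinkage: drop the outermost point while the mass on all
    # other points already exceeds the initial mass
    while (n_val > 3L && shell_mass(r, conc, n_val - 1L) > mass0) {
      n_val <- n_val - 1L
      conc[n_val] <- c_bnd
    }

    t <- t_new; TK <- T_new
    if (step %% save_every == 0L) push(t, TK, conc, n_val)

    if (!cooling) {
      if (!protocol$hold) break
      dev <- max(abs(conc[seq_len(n_val)] - c_end)) / c_end
      if (dev < eq_tol) { equilibrated <- TRUE; break }
    }
  }
  if (step %% save_every != 0L) push(t, TK, conc, n_val)
  if (!equilibrated && protocol$hold && step >= max_steps) {
    warning("simulation hit `max_steps` before equilibration")
  }

  keep <- seq_len(nsave)
  bin <- data.frame(T = s_T[keep])
  bin$phi_minus <- phi_minus_at(bin$T)
  bin$phi_plus <- phi_plus_at(bin$T)
  mass <- vapply(keep, function(i) shell_mass(r, s_c[i, ], s_n[i]), numeric(1))
  structure(list(
    times = s_t[keep], T = s_T[keep], R = r[s_n[keep]],
    r = r, conc = s_c[keep, , drop = FALSE], n_valid = s_n[keep],
    phi_minus = bin$phi_minus, phi_plus = bin$phi_plus,
    mass = mass, mass0 = mass0,
    R0 = R0, c0 = c0, D = D, protocol = protocol, model = model,
    equilibrated = equilibrated
  ), class = "condensate_trajectory")
}

#' @export
print.condensate_trajectory <- function(x, ...) {
  cat(sprintf(paste0("condensate trajectory: R0 = %.3g um, D = %.3g m^2/s, ",
                     "%.1f -> %.1f C at %.3g K/min\n"),
              x$R0 * 1e6, x$D, kelvin_to_celsius(x$protocol$T0),
              kelvin_to_celsius(x$protocol$T_end), x$protocol$rate * 60))
  cat(sprintf("  %d saved times over %.1f s; final R = %.3g um; mass drift %.3g%%\n",
              length(x$times), max(x$times), x$R[length(x$R)] * 1e6,
              100 * max(abs(x$mass / x$mass0 - 1))))
  invisible(x)
}

#' Saturation ratio field of a trajectory
#'
#' Ratio \eqn{c(r, t) / c^*_+(T(t))} between the local concentration and the
#' dense binodal concentration at the instantaneous temperature. Equal to 1
#' at the interface at all times (imposed boundary condition); drops below 1
#' in the core while cooling outpaces diffusion.
#'
#' @param traj a [simulate_condensate()] trajectory
#' @return matrix (time x radius) of saturation ratios, NA outside the
#'   condensate
#' @export
saturation_ratio <- function(traj) {
  cs <- traj$phi_plus * traj$model$rho_solute
  sweep(traj$conc, 1, cs, "/")
}
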