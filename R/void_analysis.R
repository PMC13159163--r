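# Void nucleation analysis: expected number of voids per condensate as the
# space-time integral of the void nucleation rate over a cooling trajectory,
# critical condensate sizes, the Poisson band, and fitting of the tension
# amplitude gamma0 and kinetic prefactor theta to void-count data.

# Poisson band on the expected number of voids for condensates classified as
# "exactly one void" (stochastic single-void size range).
POISSON_BAND_LOW <- 0.242
POISSON_BAND_HIGH <- 5.572

#' Poisson probability of observing n voids
#'
#' Nucleation is a Poisson process: given the expected number of voids `N`
#' from [expected_voids()], the probability of observing `n` voids is
#' \eqn{P(n) = N^n e^{-N} / n!}.
#'
#' @param N expected number of voids (>= 0)
#' @param n observed count (non-negative integer), vectorised
#' @return probability
#' @export
poisson_void_probability <- function(N, n) {
  stopifnot(all(N >= 0), all(n >= 0), all(n == round(n)))
  stats::dpois(n, N)
}

# Vectorised void driving force on a trajectory snapshot; phi at or outside
# the binodal interval (equilibrium, up to solver noise) maps to zero.
# Uses the stable tangent-excess evaluation (see delta_g_minus).
delta_g_minus_field <- function(phi, T, pm, pp, model) {
  delta_g_minus_core(pmin(pmax(phi, pm), pp), T, pm, pp, model)
}

# Precompute everything in the void-rate field that does not depend on
# (gamma0, theta): driving force, parent number concentration, molecular
# volume of the nucleating (dilute) phase, and the space-time quadrature
# weights. Layout: rows = radial nodes, cols = saved times.
void_field_context <- function(traj, Mw) {
  model <- traj$model
  nt <- length(traj$times)
  np <- length(traj$r)
  dr <- traj$r[2] - traj$r[1]
  conc <- t(traj$conc) # [np x nt]
  phi <- conc / model$rho_solute

  dg <- matrix(0, np, nt)
  for (i in seq_len(nt)) {
    k <- traj$n_valid[i]
    dg[seq_len(k), i] <- delta_g_minus_field(
      phi[seq_len(k), i], traj$T[i], traj$phi_minus[i], traj$phi_plus[i],
      model)
  }
  c_num <- conc * (N_AVOGADRO / Mw)
  # dilute (nucleating) phase molecular volume at each time
  vm_minus <- Mw / (N_AVOGADRO * traj$phi_minus * model$rho_solute)

  # radial trapezoid weights 4 pi r^2 dr, truncated at the moving boundary
  wr <- matrix(0, np, nt)
  base <- 4 * pi * traj$r^2 * dr
  for (i in seq_len(nt)) {
    k <- traj$n_valid[i]
    w <- base[seq_len(k)]
    w[1] <- w[1] / 2; w[k] <- w[k] / 2
    wr[seq_len(k), i] <- w
  }
  # temporal trapezoid weights
  wt <- numeric(nt)
  if (nt > 1) {
    dtv <- diff(traj$times)
    wt[1] <- dtv[1] / 2
    wt[nt] <- dtv[nt - 1] / 2
    if (nt > 2) wt[2:(nt - 1)] <- (dtv[-1] + dtv[-(nt - 1)]) / 2
  }
  # flattened supersaturated-node subset for fast repeated N evaluation:
  # everything except gamma(T) and theta is frozen here
  idx <- which(dg < 0)
  t_idx <- (idx - 1L) %/% np + 1L
  kbt_s <- KB * traj$T[t_idx]
  list(T = traj$T, phi_minus = traj$phi_minus, phi_plus = traj$phi_plus,
       dg = dg, c_num = c_num, vm_minus = vm_minus, wr = wr, wt = wt,
       times = traj$times,
       idx = idx, t_idx = t_idx, dg_s = dg[idx], kbt_s = kbt_s,
       vm_s = vm_minus[t_idx],
       ln_pref_s = log(c_num[idx] * abs(dg[idx])) - log(vm_minus[t_idx]),
       w_s = wr[idx] * wt[t_idx])
}

# N only, on the precomputed supersaturated subset (fast path used inside
# the fitting loops); identical to void_counts_on_context(...)$N
void_N_on_context <- function(ctx, tension, kin, Tc) {
  if (length(ctx$idx) == 0) return(0)
  gam <- gamma_on_context(ctx, tension, Tc)[ctx$t_idx]
  wc <- (16 * pi / 3) * gam^3 * ctx$vm_s^2 / ctx$dg_s^2
  lnJ <- log(kin$theta * kin$D_plus) + ctx$ln_pref_s -
    0.5 * log(gam * ctx$kbt_s) - wc / ctx$kbt_s
  sum(ifelse(lnJ < -700, 0, exp(lnJ)) * ctx$w_s)
}

# gamma(T) per saved time from stored binodal columns (no re-solve)
gamma_on_context <- function(ctx, tension, Tc) {
  switch(tension$form,
    constant = rep(tension$gamma0, length(ctx$T)),
    ising_T = tension$gamma0 *
      pmax((Tc - ctx$T) / Tc, 0)^tension$exponent,
    binodal_gap = tension$gamma0 *
      pmax(ctx$phi_plus - ctx$phi_minus, 0)^tension$exponent)
}

# K(t) and N for given (tension, theta) on a precomputed field context
void_counts_on_context <- function(ctx, tension, kin, Tc) {
  gam <- gamma_on_context(ctx, tension, Tc)
  nt <- length(ctx$T)
  np <- nrow(ctx$dg)
  kbt <- KB * ctx$T
  # per-time scalars expanded across rows (column-major recycling)
  gam_m <- matrix(gam, np, nt, byrow = TRUE)
  vm_m <- matrix(ctx$vm_minus, np, nt, byrow = TRUE)
  kbt_m <- matrix(kbt, np, nt, byrow = TRUE)
  dg <- ctx$dg
  J <- matrix(0, np, nt)
  ok <- dg < 0 & gam_m > 0
  if (any(ok)) {
    wc <- (16 * pi / 3) * gam_m[ok]^3 * vm_m[ok]^2 / dg[ok]^2
    lnJ <- log(kin$theta * kin$D_plus * ctx$c_num[ok] * abs(dg[ok])) -
      log(vm_m[ok]) - 0.5 * log(gam_m[ok] * kbt_m[ok]) - wc / kbt_m[ok]
    J[ok] <- ifelse(lnJ < -700, 0, exp(lnJ))
  }
  K <- colSums(J * ctx$wr)
  list(K = K, N = sum(K * ctx$wt))
}

#' Integrate an arbitrary rate field over a trajectory
#'
#' Space-time quadrature \eqn{N = \int K(t)\,dt} with
#' \eqn{K(t) = \int_0^{R(t)} 4\pi r^2 J\, dr} for a user-supplied rate
#' function; the physical void rate is the special case used by
#' [expected_voids()]. Useful for closed-form checks (e.g. a constant J over
#' a fixed sphere gives \eqn{N = J \cdot \frac{4}{3}\pi R^3 \cdot t}).
#'
#' @param traj a [simulate_condensate()] trajectory
#' @param rate_fn function `(conc, T, phi_minus, phi_plus) -> J` (m^-3 s^-1),
#'   vectorised over `conc`
#' @return list with `K` (per saved time, 1/s) and `N` (dimensionless)
#' @export
integrate_rate_field <- function(traj, rate_fn) {
  nt <- length(traj$times)
  dr <- traj$r[2] - traj$r[1]
  K <- numeric(nt)
  for (i in seq_len(nt)) {
    k <- traj$n_valid[i]
    J <- rate_fn(traj$conc[i, seq_len(k)], traj$T[i],
                 traj$phi_minus[i], traj$phi_plus[i])
    w <- 4 * pi * traj$r[seq_len(k)]^2 * dr
    w[1] <- w[1] / 2; w[k] <- w[k] / 2
    K[i] <- sum(w * J)
  }
  N <- if (nt > 1) sum((K[-1] + K[-nt]) / 2 * diff(traj$times)) else 0
  list(K = K, N = N)
}

#' Expected number of voids nucleating in a cooling condensate
#'
#' Integrates the void nucleation rate \eqn{J_{void}(c(r,t), T(t))} over the
#' shrinking condensate volume and the duration of the protocol:
#' \eqn{N = \int_{t_0}^{t_{end}} \int_0^{R(t)} 4\pi r^2 J\, dr\, dt}.
#'
#' @param traj a [simulate_condensate()] trajectory
#' @param tension a [tension_model()]
#' @param kin a [kinetic_params()]
#' @return expected number of voids (dimensionless, >= 0)
#' @export
expected_voids <- function(traj, tension, kin) {
  ctx <- void_field_context(traj, kin$Mw)
  Tc <- critical_point(traj$model)$T_c
  void_counts_on_context(ctx, tension, kin, Tc)$N
}

#' Void nucleation frequency over time
#'
#' \eqn{K(t) = \int_0^{R(t)} 4\pi r^2 J\, dr}: the expected number of voids
#' formed per unit time in the whole condensate. Its time integral equals
#' [expected_voids()]. For monotone cooling, K peaks at the end of the ramp,
#' where the core is furthest from equilibrium.
#'
#' @inheritParams expected_voids
#' @return data.frame with `time` (s) and `K` (1/s)
#' @export
nucleation_frequency <- function(traj, tension, kin) {
  ctx <- void_field_context(traj, kin$Mw)
  Tc <- critical_point(traj$model)$T_c
  data.frame(time = traj$times,
             K = void_counts_on_context(ctx, tension, kin, Tc)$K)
}

# simulate + count for a given diameter (helper for bisection / fitting)
expected_voids_at_diameter <- function(d, cooling_rate, model, tension, kin,
                                       T0, T_end, transport = list()) {
  args <- c(list(R0 = d / 2,
                 protocol = cooling_protocol(T0, T_end, cooling_rate),
                 model = model, D = kin$D_plus), transport)
  traj <- do.call(simulate_condensate, args)
  expected_voids(traj, tension, kin)
}

#' Critical condensate size for void nucleation
#'
#' Diameter at which, on average, `target_N` voids (default one) nucleate
#' during the cooling protocol, found by bisection between a small and a
#' large diameter (N increases monotonically with size). Optionally also the
#' stochastic single-void band: the diameters where N = 0.242 and N = 5.572.
#'
#' @param cooling_rate cooling rate (K/s)
#' @param model a [phase_model()]
#' @param tension a [tension_model()]
#' @param kin a [kinetic_params()]
#' @param T0,T_end protocol temperatures (K)
#' @param target_N target expected void count (default 1)
#' @param d_lo,d_hi bracketing diameters (m), default 10 and 100 um
#' @param tol_d bisection tolerance on the diameter (m), default 0.1 um
#' @param band also locate the Poisson band diameters (doubles the cost)
#' @param transport named list of extra arguments passed to
#'   [simulate_condensate()] (grid/step control)
#' @return list with `cooling_rate`, `d_crit` (m), `N_at_crit`, and if
#'   `band = TRUE` also `band_low`, `band_high` (m)
#' @export
critical_size <- function(cooling_rate, model, tension, kin, T0, T_end,
                          target_N = 1, d_lo = 10e-6, d_hi = 100e-6,
                          tol_d = 0.1e-6, band = FALSE, transport = list()) {
  Nfun <- function(d) expected_voids_at_diameter(d, cooling_rate, model,
                                                 tension, kin, T0, T_end,
                                                 transport)
  solve_one <- function(target, lo, hi) {
    N_lo <- Nfun(lo); N_hi <- Nfun(hi)
    tries <- 0
    while (N_lo > target && lo > 1e-6 && tries < 4) {
      lo <- lo / 2; N_lo <- Nfun(lo); tries <- tries + 1
    }
    tries <- 0
    while (N_hi < target && hi < 1e-3 && tries < 4) {
      hi <- hi * 2; N_hi <- Nfun(hi); tries <- tries + 1
    }
    if (N_lo > target || N_hi < target) {
      stop(sprintf(paste0("bisection bracket failure for N = %g: N(%.3g um) ",
                          "= %.3g, N(%.3g um) = %.3g"),
                   target, lo * 1e6, N_lo, hi * 1e6, N_hi))
    }
    N_mid <- NA_real_
    while (hi - lo > tol_d) {
      mid <- (lo + hi) / 2
      N_mid <- Nfun(mid)
      if (N_mid < target) lo <- mid else hi <- mid
    }
    list(d = (lo + hi) / 2, N = N_mid)
  }
  main <- solve_one(target_N, d_lo, d_hi)
  out <- list(cooling_rate = cooling_rate, d_crit = main$d, N_at_crit = main$N)
  if (band) {
    out$band_low <- solve_one(POISSON_BAND_LOW, d_lo, main$d)$d
    out$band_high <- solve_one(POISSON_BAND_HIGH, main$d, d_hi)$d
  }
  out
}

#' Read void-count experiments from CSV
#'
#' Expected columns: `cooling_rate_K_per_min`, `condensate_diameter_um`,
#' `n_voids`.
#'
#' @param path CSV file path
#' @return data.frame with `cooling_rate` (K/s), `diameter` (m), `n_voids`
#' @export
read_void_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cooling_rate_K_per_min", "condensate_diameter_um", "n_voids")
  if (!all(need %in% names(d))) {
    stop("void-count CSV must have columns: ", paste(need, collapse = ", "))
  }
  data.frame(cooling_rate = d$cooling_rate_K_per_min / 60,
             diameter = d$condensate_diameter_um * 1e-6,
             n_voids = d$n_voids)
}

#' Critical sizes from void-count records
#'
#' Per-rate estimate of the condensate diameter at which on average one void
#' forms. Two estimators:
#' \describe{
#'   \item{`single_void`}{the experimental convention: the arithmetic mean
#'     diameter of the condensates in which exactly one void formed.}
#'   \item{`poisson`}{maximum likelihood on the 0 / 1 / >=2 void-count
#'     categories of *all* condensates at that rate, under the Poisson model
#'     \eqn{P(0)=e^{-N}, P(1)=N e^{-N}, P(\ge 2)=1-(1+N)e^{-N}} with
#'     \eqn{\ln N = a + b \ln d} locally linear across the transition
#'     window; the critical size is \eqn{d = e^{-a/b}}. Statistically far
#'     more efficient than the single-void mean, because zero-void and
#'     multi-void condensates carry information too.}
#' }
#'
#' @param records data.frame with `cooling_rate` (K/s), `diameter` (m),
#'   `n_voids` (e.g. from [read_void_csv()] or [gen_void_experiment()])
#' @param method `"single_void"` (default, the experimental convention) or
#'   `"poisson"`
#' @return data.frame with `cooling_rate` (K/s), `diameter` (m) and, for
#'   `single_void`, `n_single` and `sd` (m)
#' @export
estimate_critical_sizes <- function(records,
                                    method = c("single_void", "poisson")) {
  method <- match.arg(method)
  stopifnot(all(c("cooling_rate", "diameter", "n_voids") %in% names(records)))
  if (method == "single_void") {
    one <- records[records$n_voids == 1, ]
    if (nrow(one) == 0) stop("no single-void condensates in the records")
    agg <- aggregate(one["diameter"], by = one["cooling_rate"], FUN = mean)
    agg$n_single <- aggregate(one["diameter"], by = one["cooling_rate"],
                              FUN = length)$diameter
    agg$sd <- aggregate(one["diameter"], by = one["cooling_rate"],
                        FUN = stats::sd)$diameter
    return(agg[order(agg$cooling_rate), ])
  }
  rates <- sort(unique(records$cooling_rate))
  d_crit <- vapply(rates, function(rk) {
    sub <- records[records$cooling_rate == rk, ]
    poisson_category_dcrit(sub$diameter, sub$n_voids)
  }, numeric(1))
  data.frame(cooling_rate = rates, diameter = d_crit)
}

# Per-rate Poisson-category MLE of the diameter where N = 1 (see
# estimate_critical_sizes). `n` may be exact counts or the category floor
# (0, 1, 2 meaning ">= 2").
poisson_category_dcrit <- function(d, n) {
  if (all(n == 0) || all(n >= 1)) {
    stop("cannot locate a critical size: all condensates in one category")
  }
  x <- log(d) - mean(log(d))
  cat3 <- pmin(n, 2L)
  nll <- function(par) {
    N <- exp(pmin(par[1] + par[2] * x, 300))
    ll <- ifelse(cat3 == 0L, -N,
                 ifelse(cat3 == 1L, log(N) - N,
                        log(pmax(1 - exp(-N) * (1 + N), 1e-300))))
    -sum(ll)
  }
  # initialise from the any-void indicator via the complementary log-log
  # link, which is exactly Poisson with log-linear N
  init <- tryCatch({
    g <- stats::glm((cat3 >= 1L) ~ x, family = stats::binomial("cloglog"))
    as.numeric(stats::coef(g))
  }, error = function(e) c(0, 10), warning = function(w) {
    g <- suppressWarnings(stats::glm((cat3 >= 1L) ~ x,
                                     family = stats::binomial("cloglog")))
    as.numeric(stats::coef(g))
  })
  if (!all(is.finite(init))) init <- c(0, 10)
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  if (fit$par[2] <= 0) stop("void counts do not increase with size")
  exp(-fit$par[1] / fit$par[2] + mean(log(d)))
}

#' Fit interfacial tension and kinetic prefactor to critical sizes
#'
#' Estimates \eqn{(\gamma_0, \vartheta)} by minimising
#' \eqn{\sum_k [\ln N(R_{0,k})]^2} over the per-rate critical sizes: at the
#' optimum every critically sized condensate is expected to form exactly one
#' void (\eqn{\ln 1 = 0}; the log weights under- and over-prediction
#' symmetrically). Nelder-Mead in log-parameter space from a log-spaced
#' multistart grid; the transport trajectory at each critical size is
#' simulated once and reused for every parameter evaluation (the field of
#' driving forces does not depend on \eqn{\gamma_0} or \eqn{\vartheta}).
#'
#' @param critical_sizes data.frame with `cooling_rate` (K/s) and `diameter`
#'   (m), one row per rate (e.g. from [estimate_critical_sizes()])
#' @param model a [phase_model()]
#' @param tension_form `"constant"`, `"ising_T"` or `"binodal_gap"`
#' @param kin a [kinetic_params()]; its `theta` is ignored (fitted)
#' @param T0,T_end protocol temperatures (K)
#' @param gamma0_range,theta_range multistart ranges (log-spaced)
#' @param n_starts multistart grid points per parameter (default 5)
#' @param transport named list of extra [simulate_condensate()] arguments
#' @return list with `gamma0` (J/m^2), `theta`, `objective`, `tension_form`,
#'   the fitted `tension` model, predicted `N` per rate at the optimum, and
#'   `starts` (per-start results)
#' @export
fit_void_parameters <- function(critical_sizes, model, tension_form, kin,
                                T0, T_end,
                                gamma0_range = c(1e-7, 1e-5),
                                theta_range = c(1e-13, 1e-6),
                                n_starts = 5, transport = list()) {
  stopifnot(nrow(critical_sizes) >= 2)
  Tc <- critical_point(model)$T_c
  ctxs <- lapply(seq_len(nrow(critical_sizes)), function(i) {
    args <- c(list(R0 = critical_sizes$diameter[i] / 2,
                   protocol = cooling_protocol(
                     T0, T_end, critical_sizes$cooling_rate[i]),
                   model = model, D = kin$D_plus), transport)
    void_field_context(do.call(simulate_condensate, args), kin$Mw)
  })
  Ns <- function(par) { # par = (log10 gamma0, log10 theta)
    tn <- tension_model(tension_form, gamma0 = 10^par[1], Tc = Tc)
    kn <- kinetic_params(theta = 10^par[2], D_plus = kin$D_plus,
                         D_minus = kin$D_minus, Mw = kin$Mw)
    vapply(ctxs, function(ctx)
      void_N_on_context(ctx, tn, kn, Tc), numeric(1))
  }
  objective <- function(par) {
    N <- Ns(par)
    if (any(!is.finite(N)) || any(N <= 0)) return(1e8)
    sum(log(N)^2)
  }
  starts <- expand.grid(
    g = seq(log10(gamma0_range[1]), log10(gamma0_range[2]),
            length.out = n_starts),
    t = seq(log10(theta_range[1]), log10(theta_range[2]),
            length.out = n_starts))
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(c(starts$g[i], starts$t[i]), objective,
                 method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10))
  })
  vals <- vapply(runs, function(f) f$value, numeric(1))
  if (all(vals >= 1e8)) {
    stop("all multistart fits failed: no parameter set yields finite void counts")
  }
  best <- runs[[which.min(vals)]]
  gamma0 <- 10^best$par[1]; theta <- 10^best$par[2]
  list(gamma0 = gamma0, theta = theta, objective = best$value,
       tension_form = tension_form,
       tension = tension_model(tension_form, gamma0 = gamma0, Tc = Tc),
       N = Ns(best$par),
       starts = data.frame(log10_gamma0 = starts$g, log10_theta = starts$t,
                           objective = vals))
}

#' Likelihood fit of tension and prefactor to raw void-count categories
#'
#' Extension of [fit_void_parameters()] that maximises the Poisson category
#' likelihood of *all* observed condensates instead of compressing each
#' cooling rate into a critical size: with expected count \eqn{N(d)} per
#' condensate, \eqn{P(0) = e^{-N}}, \eqn{P(1) = N e^{-N}},
#' \eqn{P(\ge 2) = 1 - (1 + N) e^{-N}}. Because the data then constrain the
#' absolute scale and the local steepness of \eqn{N(d)} per rate (rather
#' than only its unit crossing), the strong sampling correlation between
#' \eqn{\gamma_0} and \eqn{\vartheta} of the critical-size objective is
#' largely removed. \eqn{\ln N(d)} is evaluated exactly on a log-spaced
#' diameter grid per rate (one transport simulation per grid point, reused
#' across all parameter evaluations) and spline-interpolated in between.
#'
#' @param records data.frame with `cooling_rate` (K/s), `diameter` (m),
#'   `n_voids` (exact counts or the category floor 0/1/2)
#' @param model a [phase_model()]
#' @param tension_form `"constant"`, `"ising_T"` or `"binodal_gap"`
#' @param kin a [kinetic_params()]; its `theta` is ignored (fitted)
#' @param T0,T_end protocol temperatures (K)
#' @param n_interp simulated diameters per rate for the \eqn{\ln N(d)}
#'   interpolation
#' @param gamma0_range,theta_range,n_starts multistart grid (log-spaced)
#' @param transport named list of extra [simulate_condensate()] arguments
#' @return list with `gamma0`, `theta`, `logLik`, `tension_form`, `tension`
#' @export
fit_void_parameters_mle <- function(records, model, tension_form, kin,
                                    T0, T_end, n_interp = 12,
                                    gamma0_range = c(1e-7, 1e-5),
                                    theta_range = c(1e-13, 1e-6),
                                    n_starts = 3, transport = list()) {
  stopifnot(all(c("cooling_rate", "diameter", "n_voids") %in% names(records)))
  Tc <- critical_point(model)$T_c
  rates <- sort(unique(records$cooling_rate))
  per_rate <- lapply(rates, function(rk) {
    sub <- records[records$cooling_rate == rk, ]
    d_grid <- exp(seq(log(min(sub$diameter) * 0.98),
                      log(max(sub$diameter) * 1.02),
                      length.out = n_interp))
    ctxs <- lapply(d_grid, function(d) {
      args <- c(list(R0 = d / 2,
                     protocol = cooling_protocol(T0, T_end, rk),
                     model = model, D = kin$D_plus), transport)
      void_field_context(do.call(simulate_condensate, args), kin$Mw)
    })
    list(ctxs = ctxs, ld_grid = log(d_grid), ld = log(sub$diameter),
         cat = pmin(sub$n_voids, 2L))
  })
  negloglik <- function(par) {
    tn <- tension_model(tension_form, gamma0 = 10^par[1], Tc = Tc)
    kn <- kinetic_params(theta = 10^par[2], D_plus = kin$D_plus,
                         D_minus = kin$D_minus, Mw = kin$Mw)
    nll <- 0
    for (pr in per_rate) {
      lnN_grid <- log(pmax(vapply(pr$ctxs, function(ctx)
        void_N_on_context(ctx, tn, kn, Tc), numeric(1)), 1e-300))
      # ln N is monotone in ln d; the monotone (Hyman) spline avoids the
      # overshoot a natural spline produces across the steep transition
      lnN <- tryCatch(
        stats::splinefun(pr$ld_grid, lnN_grid, method = "hyman")(pr$ld),
        error = function(e)
          stats::approx(pr$ld_grid, lnN_grid, xout = pr$ld, rule = 2)$y)
      N <- exp(pmin(lnN, 300))
      ll <- ifelse(pr$cat == 0L, -N,
                   ifelse(pr$cat == 1L, lnN - N,
                          log(pmax(1 - exp(-N) * (1 + N), 1e-300))))
      nll <- nll - sum(ll)
    }
    if (!is.finite(nll)) 1e8 else nll
  }
  starts <- expand.grid(
    g = seq(log10(gamma0_range[1]), log10(gamma0_range[2]),
            length.out = n_starts),
    t = seq(log10(theta_range[1]), log10(theta_range[2]),
            length.out = n_starts))
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(c(starts$g[i], starts$t[i]), negloglik,
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
  })
  vals <- vapply(runs, function(f) f$value, numeric(1))
  if (all(vals >= 1e8)) stop("all multistart likelihood fits failed")
  best <- runs[[which.min(vals)]]
  # the likelihood surface has a long shallow (gamma0, theta) ridge along
  # which a single Nelder-Mead run stalls; restart from the incumbent until
  # the value stabilises
  repeat {
    again <- stats::optim(best$par, negloglik, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
    if (best$value - again$value < 1e-4) { best <- again; break }
    best <- again
  }
  gamma0 <- 10^best$par[1]; theta <- 10^best$par[2]
  list(gamma0 = gamma0, theta = theta, logLik = -best$value,
       tension_form = tension_form,
       tension = tension_model(tension_form, gamma0 = gamma0, Tc = Tc))
}
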