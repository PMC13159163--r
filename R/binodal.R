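# Binodal construction for the binary Flory-Huggins model.
#
# The coexisting compositions (phi_minus, phi_plus) at temperature T satisfy
# the common-tangent (equal chemical potential / equal osmotic pressure)
# conditions
#   f'(phi_minus) = f'(phi_plus)
#   f(phi_plus) - f(phi_minus) = f'(phi_minus) (phi_plus - phi_minus)
# They are located by the convex-hull construction of f(phi) on a composition
# grid (logarithmic near phi = 0, where the dilute branch sits for long
# chains) and then polished by a damped Newton iteration in logit space.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Lower convex hull (Andrew monotone chain) of points sorted by x.
# Returns indices of hull vertices.
lower_hull <- function(x, y) {
  n <- length(x)
  h <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      o <- h[k - 1L]; a <- h[k]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    h[k] <- i
  }
  h[seq_len(k)]
}

# Initial guess for the binodal from the convex hull of f(phi).
# Grid: log-spaced in phi down to 1e-12 below phi_c, linear above.
hull_guess <- function(chi, M, phi_c, n_log = 2200, n_lin = 2200) {
  phi <- c(10^seq(-12, log10(phi_c), length.out = n_log),
           seq(phi_c, 1 - 1e-9, length.out = n_lin + 1)[-1])
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  f <- xlx(phi) / M + xlx(1 - phi) + chi * phi * (1 - phi)
  h <- lower_hull(phi, f)
  gaps <- diff(phi[h])
  # prefer the hull facet that straddles the critical composition
  straddle <- which(phi[h][-length(h)] < phi_c & phi[h][-1] > phi_c)
  j <- if (length(straddle) > 0) straddle[which.max(gaps[straddle])] else which.max(gaps)
  c(phi[h][j], phi[h][j + 1])
}

# Damped Newton iteration on the common-tangent system, in logit(phi)
# coordinates so both branches stay in (0, 1).
newton_binodal <- function(phi_lo, phi_hi, chi, M,
                           tol = 1e-13, max_iter = 80) {
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  fval <- function(p) xlx(p) / M + xlx(1 - p) + chi * p * (1 - p)
  resid <- function(pl, ph) {
    c(fh_fprime(pl, chi, M) - fh_fprime(ph, chi, M),
      fval(ph) - fval(pl) - fh_fprime(pl, chi, M) * (ph - pl))
  }
  x <- c(logit(phi_lo), logit(phi_hi))
  Fv <- resid(inv_logit(x[1]), inv_logit(x[2]))
  for (it in seq_len(max_iter)) {
    if (max(abs(Fv)) < tol) break
    pl <- inv_logit(x[1]); ph <- inv_logit(x[2])
    wl <- pl * (1 - pl); wh <- ph * (1 - ph)
    J11 <- fh_fsecond(pl, chi, M) * wl
    J12 <- -fh_fsecond(ph, chi, M) * wh
    J21 <- -fh_fsecond(pl, chi, M) * (ph - pl) * wl
    J22 <- (fh_fprime(ph, chi, M) - fh_fprime(pl, chi, M)) * wh
    det <- J11 * J22 - J12 * J21
    if (!is.finite(det) || abs(det) < 1e-300) return(NULL)
    dx <- c(J22 * Fv[1] - J12 * Fv[2], -J21 * Fv[1] + J11 * Fv[2]) / det
    # damped update: halve the step until the residual decreases
    lambda <- 1
    repeat {
      xn <- x - lambda * dx
      Fn <- resid(inv_logit(xn[1]), inv_logit(xn[2]))
      if (all(is.finite(Fn)) && sum(abs(Fn)) <= sum(abs(Fv)) * (1 - 1e-4 * lambda) ||
          lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn
    Fv <- Fn
  }
  if (max(abs(Fv)) > 1e-9) return(NULL)
  out <- sort(inv_logit(x))
  if (out[2] - out[1] < 1e-12) return(NULL)
  out
}

#' Binodal compositions at a given temperature
#'
#' Computes the coexisting dilute and dense volume fractions
#' \eqn{(\phi_-, \phi_+)} of a [phase_model()] by the convex-hull
#' construction of the free energy, refined by Newton iteration on the
#' common-tangent conditions. At or above the critical temperature the
#' degenerate binodal \eqn{\phi_- = \phi_+ = \phi_c} is returned (so
#' temperature sweeps are loop-safe).
#'
#' @param T temperature (K), scalar
#' @param model a [phase_model()]
#' @return list with `T`, `phi_minus`, `phi_plus`
#' @examples
#' compute_binodal(309.15, fh_preset("m2000"))
#' @export
compute_binodal <- function(T, model) {
  stopifnot(length(T) == 1, T > 0)
  cp <- critical_point(model)
  chi <- chi_at(T, model)
  if (chi <= cp$chi_c || T >= cp$T_c) {
    return(list(T = T, phi_minus = cp$phi_c, phi_plus = cp$phi_c))
  }
  guess <- hull_guess(chi, model$M, cp$phi_c)
  sol <- newton_binodal(guess[1], guess[2], chi, model$M)
  if (is.null(sol)) {
    # indistinguishable from critical at hull-grid resolution
    return(list(T = T, phi_minus = cp$phi_c, phi_plus = cp$phi_c))
  }
  list(T = T, phi_minus = sol[1], phi_plus = sol[2])
}

#' Binodal curve over a temperature grid
#'
#' Marches the Newton solution of the common-tangent system across a
#' temperature grid, warm-starting each temperature from its neighbour
#' (one convex-hull initialisation at the coldest point). Much faster than
#' repeated [compute_binodal()] calls for fine sweeps.
#'
#' @param T vector of temperatures (K)
#' @param model a [phase_model()]
#' @return data.frame with columns `T`, `phi_minus`, `phi_plus`
#' @export
binodal_curve <- function(T, model) {
  stopifnot(all(T > 0))
  cp <- critical_point(model)
  ord <- order(T) # coldest first: widest gap, most robust hull init
  Ts <- T[ord]
  lo <- hi <- rep(cp$phi_c, length(Ts))
  prev <- NULL
  for (i in seq_along(Ts)) {
    chi <- chi_at(Ts[i], model)
    if (chi <= cp$chi_c || Ts[i] >= cp$T_c) {
      prev <- NULL
      next
    }
    init <- if (is.null(prev)) hull_guess(chi, model$M, cp$phi_c) else prev
    sol <- newton_binodal(init[1], init[2], chi, model$M)
    if (is.null(sol) && !is.null(prev)) {
      # warm start failed (e.g. large temperature jump): retry from the hull
      sol <- newton_binodal_from_hull(chi, model$M, cp$phi_c)
    }
    if (is.null(sol)) {
      prev <- NULL
      next
    }
    lo[i] <- sol[1]; hi[i] <- sol[2]
    prev <- sol
  }
  out <- data.frame(T = Ts, phi_minus = lo, phi_plus = hi)
  out <- out[order(ord), ] # restore the caller's temperature order
  rownames(out) <- NULL
  out
}

newton_binodal_from_hull <- function(chi, M, phi_c) {
  g <- hull_guess(chi, M, phi_c)
  newton_binodal(g[1], g[2], chi, M)
}

#' Read binodal measurements from CSV
#'
#' Expected columns: `temperature_C`, `phase` (`"dense"` or `"dilute"`),
#' `concentration_mg_per_ml`. Note 1 mg/mL = 1 kg/m^3.
#'
#' @param path CSV file path
#' @return data.frame with `T` (K), `phase`, `conc` (kg/m^3)
#' @export
read_binodal_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "phase", "concentration_mg_per_ml")
  if (!all(need %in% names(d))) {
    stop("binodal CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(d$phase %in% c("dense", "dilute"))) {
    stop("`phase` must be 'dense' or 'dilute'")
  }
  if (any(d$concentration_mg_per_ml <= 0)) stop("concentrations must be positive")
  data.frame(T = celsius_to_kelvin(d$temperature_C),
             phase = d$phase,
             conc = d$concentration_mg_per_ml) # mg/mL == kg/m^3
}

#' Fit the interaction parameter (A, B) to binodal measurements
#'
#' Least-squares fit of \eqn{\chi(T) = A + B/T} to measured coexistence
#' concentrations at fixed chain length `M`. By default dense and dilute
#' points are weighted equally; `weighting = "dense"` restricts the fit to
#' dense-phase points (the dense branch carries most of the information for
#' long chains, whose dilute branch is orders of magnitude lower).
#'
#' @param data data.frame with columns `T` (K), `phase`, `conc` (kg/m^3),
#'   e.g. from [read_binodal_csv()] or [gen_binodal_points()]
#' @param M effective chain length (fixed, not fitted)
#' @param rho_solute solute density (kg/m^3)
#' @param weighting `"both"` (default) or `"dense"`
#' @param init named vector of starting values `c(A=, B=)`
#' @return list with the fitted `model`, `A`, `B`, `T_c` (K), `sse`,
#'   and the `optim` convergence code
#' @export
fit_phase_model <- function(data, M, rho_solute = 1600,
                            weighting = c("both", "dense"),
                            init = c(A = 0.25, B = 90)) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("T", "phase", "conc") %in% names(data)))
  if (weighting == "dense") data <- data[data$phase == "dense", ]
  if (nrow(data) < 2) stop("need at least two measurements")
  temps <- sort(unique(data$T))
  objective <- function(par) {
    m <- tryCatch(phase_model(M = M, A = par[1], B = par[2],
                              rho_solute = rho_solute),
                  error = function(e) NULL)
    if (is.null(m)) return(1e12)
    tc <- tryCatch(critical_point(m)$T_c, error = function(e) NA_real_)
    if (!is.finite(tc)) return(1e12)
    bc <- binodal_curve(temps, m)
    pred <- ifelse(data$phase == "dense",
                   bc$phi_plus[match(data$T, bc$T)],
                   bc$phi_minus[match(data$T, bc$T)]) * rho_solute
    sum((pred - data$conc)^2)
  }
  fit <- stats::optim(init, objective, method = "Nelder-Mead",
                      control = list(parscale = c(0.05, 10),
                                     maxit = 500, reltol = 1e-12))
  par <- unname(fit$par)
  model <- phase_model(M = M, A = par[1], B = par[2],
                       rho_solute = rho_solute)
  list(model = model, A = par[1], B = par[2],
       T_c = critical_point(model)$T_c,
       sse = fit$value, convergence = fit$convergence)
}
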