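#' Interfacial tension models
#'
#' Three parameterisations of the dense-dilute interfacial tension
#' \eqn{\gamma(T)}:
#' \describe{
#'   \item{`constant`}{\eqn{\gamma(T) = \gamma_0}}
#'   \item{`ising_T`}{Ising critical temperature scaling
#'     \eqn{\gamma(T) = \gamma_0 ((T_c - T)/T_c)^{1.26}}}
#'   \item{`binodal_gap`}{binodal-width scaling
#'     \eqn{\gamma(T) = \gamma_0 (\phi_+(T) - \phi_-(T))^{3.9}}}
#' }
#' Both scaling forms vanish at the critical temperature. The exponents are
#' the 3D Ising surface-tension exponent \eqn{\mu \approx 1.26} and its
#' translation to the order-parameter gap \eqn{\mu/\beta \approx 3.9}.
#'
#' @param form one of `"constant"`, `"ising_T"`, `"binodal_gap"`
#' @param gamma0 tension amplitude (J/m^2), > 0
#' @param Tc critical temperature (K); required for `ising_T`, taken from
#'   the phase model at evaluation time when `NULL`
#' @param exponent scaling exponent; defaults to 1.26 (`ising_T`) or
#'   3.9 (`binodal_gap`)
#' @return an object of class `tension_model`
#' @examples
#' tension_model("ising_T", gamma0 = 1.8e-6, Tc = 337.65)
#' @export
tension_model <- function(form = c("constant", "ising_T", "binodal_gap"),
                          gamma0, Tc = NULL, exponent = NULL) {
  form <- match.arg(form)
  stopifnot(is.numeric(gamma0), length(gamma0) == 1, gamma0 >= 0)
  if (is.null(exponent)) {
    exponent <- switch(form, constant = NA_real_, ising_T = 1.26,
                       binodal_gap = 3.9)
  }
  structure(list(form = form, gamma0 = gamma0, Tc = Tc, exponent = exponent),
            class = "tension_model")
}

#' @export
print.tension_model <- function(x, ...) {
  cat(sprintf("tension model '%s': gamma0 = %g J/m^2%s\n", x$form, x$gamma0,
              if (x$form == "constant") "" else
                sprintf(", exponent = %g", x$exponent)))
  invisible(x)
}

#' Interfacial tension at temperature T
#'
#' Evaluates a [tension_model()]. The scaling forms require `T <= Tc`
#' (tension is only defined inside the two-phase region).
#'
#' @param T temperature (K), vectorised
#' @param tension a [tension_model()]
#' @param model a [phase_model()]; used for `Tc` (when not set on the
#'   tension model) and for the binodal gap
#' @param binodal optional data.frame with `phi_minus`, `phi_plus` matching
#'   `T` (avoids recomputing the binodal in sweeps); only used by the
#'   `binodal_gap` form
#' @return interfacial tension (J/m^2)
#' @export
gamma_at <- function(T, tension, model = NULL, binodal = NULL) {
  if (tension$form == "constant") {
    return(rep(tension$gamma0, length(T)))
  }
  Tc <- tension$Tc
  if (is.null(Tc)) {
    if (is.null(model)) stop("need `Tc` on the tension model or a phase model")
    Tc <- critical_point(model)$T_c
  }
  if (any(T > Tc + 1e-9)) {
    stop("scaling tension forms are undefined above the critical temperature")
  }
  if (tension$form == "ising_T") {
    return(tension$gamma0 * pmax((Tc - T) / Tc, 0)^tension$exponent)
  }
  # binodal_gap
  if (is.null(binodal)) {
    if (is.null(model)) stop("binodal_gap form needs a phase model or binodal")
    binodal <- binodal_curve(T, model)
  }
  gap <- pmax(binodal$phi_plus - binodal$phi_minus, 0)
  tension$gamma0 * gap^tension$exponent
}
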