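#' Parametric linear-viscoelastic sample model
#'
#' Constructs a sample model for the complex shear modulus `G*(omega)`.
#' Supported kinds:
#' \describe{
#'   \item{`elastic`}{`G* = G_e` (purely elastic).}
#'   \item{`kelvin_voigt`}{`G* = G_e + i omega eta`.}
#'   \item{`standard_linear_solid`}{`G* = G_e + G i omega tau / (1 + i omega tau)`
#'     with a single Maxwell branch (`G`, `tau` of length 1).}
#'   \item{`generalized_maxwell`}{`G* = G_e + sum_j G_j i omega tau_j / (1 + i omega tau_j)`
#'     (Prony series; zero branches degenerates to `elastic`).}
#'   \item{`springpot`}{`G* = c_alpha (i omega)^alpha`, `0 < alpha < 1`
#'     (frequency domain only; it has no finite-state time-domain update).}
#' }
#'
#' All moduli are SHEAR moduli in Pa; conversion to the indentation
#' (compression) modulus happens only in the contact-mechanics layer.
#'
#' @param kind model kind, one of the five above.
#' @param G_e equilibrium shear modulus (Pa, > 0), all kinds except springpot.
#' @param eta viscosity (Pa s, > 0), Kelvin-Voigt only.
#' @param G Maxwell branch moduli (Pa, > 0); length 1 for the SLS.
#' @param tau Maxwell branch relaxation times (s, > 0); same length as `G`.
#' @param c_alpha springpot scale (Pa s^alpha, > 0).
#' @param alpha springpot exponent, strictly inside (0, 1).
#' @return an object of class `rheology_model`.
#' @examples
#' sls <- rheology_model("standard_linear_solid", G_e = 2000, G = 4000, tau = 0.3)
#' complex_modulus(sls, c(0.05, 1, 10))
#' @export
rheology_model <- function(kind = c("elastic", "kelvin_voigt",
                                    "standard_linear_solid",
                                    "generalized_maxwell", "springpot"),
                           G_e = NULL, eta = NULL, G = NULL, tau = NULL,
                           c_alpha = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  pos <- function(x, nm, len = NULL) {
    if (is.null(x)) stop("rheology_model: parameter '", nm, "' is required for kind '",
                         kind, "'", call. = FALSE)
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0))
      stop("rheology_model: parameter '", nm, "' must be strictly positive and finite",
           call. = FALSE)
    if (!is.null(len) && length(x) != len)
      stop("rheology_model: parameter '", nm, "' must have length ", len, call. = FALSE)
    as.numeric(x)
  }
  m <- switch(kind,
    elastic = list(G_e = pos(G_e, "G_e", 1), eta = 0,
                   G = numeric(0), tau = numeric(0)),
    kelvin_voigt = list(G_e = pos(G_e, "G_e", 1), eta = pos(eta, "eta", 1),
                        G = numeric(0), tau = numeric(0)),
    standard_linear_solid = list(G_e = pos(G_e, "G_e", 1), eta = 0,
                                 G = pos(G, "G", 1), tau = pos(tau, "tau", 1)),
    generalized_maxwell = {
      G <- if (is.null(G)) numeric(0) else pos(G, "G")
      tau <- if (is.null(tau)) numeric(0) else pos(tau, "tau")
      if (length(G) != length(tau))
        stop("rheology_model: 'G' and 'tau' must have equal length", call. = FALSE)
      list(G_e = pos(G_e, "G_e", 1), eta = 0, G = G, tau = tau)
    },
    springpot = {
      a <- pos(alpha, "alpha", 1)
      if (a >= 1) stop("rheology_model: 'alpha' must lie strictly in (0, 1)",
                       call. = FALSE)
      list(G_e = 0, eta = 0, G = numeric(0), tau = numeric(0),
           c_alpha = pos(c_alpha, "c_alpha", 1), alpha = a)
    })
  m$kind <- kind
  class(m) <- "rheology_model"
  m
}

#' @export
print.rheology_model <- function(x, ...) {
  cat("<rheology_model>", x$kind, "\n")
  cat("  G_e =", x$G_e, "Pa")
  if (x$kind == "kelvin_voigt") cat(", eta =", x$eta, "Pa s")
  if (length(x$G))
    cat(", branches: G = [", paste(x$G, collapse = ", "),
        "] Pa, tau = [", paste(x$tau, collapse = ", "), "] s")
  if (x$kind == "springpot")
    cat("c_alpha =", x$c_alpha, "Pa s^alpha, alpha =", x$alpha)
  cat("\n")
  invisible(x)
}

# complex G*(omega) as a complex vector, omega = 2*pi*frequency
complex_modulus_value <- function(model, frequency) {
  stopifnot(inherits(model, "rheology_model"))
  w <- 2 * pi * frequency
  if (model$kind == "springpot")
    return(model$c_alpha * complex(real = 0, imaginary = w)^model$alpha)
  g <- complex(real = rep(model$G_e, length(w)), imaginary = model$eta * w)
  for (j in seq_along(model$G)) {
    iwt <- complex(real = 0, imaginary = w * model$tau[j])
    g <- g + model$G[j] * iwt / (1 + iwt)
  }
  g
}

#' Complex shear modulus of a sample model
#'
#' Evaluates the storage modulus `G'(omega)` and loss modulus `G''(omega)`
#' of a [rheology_model()] at given frequencies, with `omega = 2 pi f`.
#'
#' @param model a [rheology_model()].
#' @param frequency frequencies in Hz, all > 0.
#' @return data frame with columns `frequency`, `storage`, `loss` (Pa).
#' @export
complex_modulus <- function(model, frequency) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) || any(frequency <= 0))
    stop("complex_modulus: 'frequency' must be finite and > 0", call. = FALSE)
  g <- complex_modulus_value(model, frequency)
  data.frame(frequency = frequency, storage = Re(g), loss = Im(g))
}

#' Initial internal state for the time-domain memory kernel
#'
#' @param model a [rheology_model()] supported in the time domain.
#' @return list with current strain and per-branch stresses (all zero).
#' @export
memory_kernel_init <- function(model) {
  stopifnot(inherits(model, "rheology_model"))
  if (model$kind == "springpot")
    stop("memory_kernel_init: springpot has no finite-state time-domain update",
         call. = FALSE)
  list(strain = 0, branch_stress = numeric(length(model$G)))
}

#' One exact exponential-integrator step of the viscoelastic memory kernel
#'
#' Advances the internal branch stresses over `dt` under piecewise-linear
#' strain (constant strain rate `strain_increment / dt` within the step)
#' using the exact per-step solution of each Maxwell branch,
#' `sigma_j <- sigma_j e^{-dt/tau_j} + G_j r tau_j (1 - e^{-dt/tau_j})`,
#' which is unconditionally stable. The returned stress is
#' `G_e eps + sum_j sigma_j + eta r`. In sinusoidal steady state the
#' stress amplitude and phase agree with [complex_modulus()].
#'
#' @param model a [rheology_model()]; springpot is rejected.
#' @param state kernel state from [memory_kernel_init()] or a previous step.
#' @param strain_increment strain change over the step (dimensionless).
#' @param dt step duration in seconds, > 0.
#' @return list with elements `state` (updated) and `stress` (Pa).
#' @export
memory_kernel_step <- function(model, state, strain_increment, dt) {
  stopifnot(inherits(model, "rheology_model"))
  if (model$kind == "springpot")
    stop("memory_kernel_step: springpot has no finite-state time-domain update",
         call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("memory_kernel_step: 'dt' must be a single value > 0", call. = FALSE)
  rate <- strain_increment / dt
  eps <- state$strain + strain_increment
  sig <- state$branch_stress
  if (length(model$G)) {
    decay <- exp(-dt / model$tau)
    sig <- sig * decay + model$G * rate * model$tau * (1 - decay)
  }
  stress <- model$G_e * eps + sum(sig) + model$eta * rate
  list(state = list(strain = eps, branch_stress = sig), stress = stress)
}

#' Time-domain stress response to a strain history
#'
#' Convenience wrapper applying [memory_kernel_step()] along a sampled
#' strain history starting from the relaxed state.
#'
#' @param model a time-domain-capable [rheology_model()].
#' @param strain strain samples (the first sample is reached by a step
#'   from zero strain at rate `strain[1]/dt`).
#' @param dt uniform sampling interval (s).
#' @return numeric vector of stresses (Pa), same length as `strain`.
#' @export
simulate_stress <- function(model, strain, dt) {
  st <- memory_kernel_init(model)
  out <- numeric(length(strain))
  prev <- 0
  for (i in seq_along(strain)) {
    step <- memory_kernel_step(model, st, strain[i] - prev, dt)
    st <- step$state
    out[i] <- step$stress
    prev <- strain[i]
  }
  out
}

# equilibrium (long-time) shear modulus; used to predict the static depth
equilibrium_modulus <- function(model) {
  if (model$kind == "springpot")
    stop("springpot has no finite equilibrium modulus", call. = FALSE)
  model$G_e
}
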