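#' Construct two-tissue-compartment kinetic parameters
#'
#' @param K1 mL·cm^-3·min^-1, delivery rate from blood to tissue.
#' @param k2 min^-1, efflux rate back to blood.
#' @param k3,k4 min^-1, association/dissociation rates of specific binding;
#'   set `k3 = 0` for a one-tissue model. `k3 > 0` requires `k4 > 0`.
#' @param vB fractional blood volume in \[0, 1).
#' @return A [KineticParams-class].
#' @examples
#' KineticParams(K1 = 0.1, k2 = 0.2, k3 = 0.05, k4 = 0.05)
#' @export
KineticParams <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  new("KineticParams", K1 = as.numeric(K1), k2 = as.numeric(k2),
      k3 = as.numeric(k3), k4 = as.numeric(k4), vB = as.numeric(vB))
}

#' Construct tri-exponential whole-blood input-function parameters
#'
#' @param A1 kBq·cm^-3·min^-1; `A2`, `A3` kBq/cm^3; `l1 > l2 > l3 > 0`
#'   in min^-1.
#' @param A2,A3,l1,l2,l3 see `A1`.
#' @return An [InputFunctionParams-class].
#' @export
InputFunctionParams <- function(A1, A2, A3, l1, l2, l3) {
  new("InputFunctionParams", A1 = as.numeric(A1), A2 = as.numeric(A2),
      A3 = as.numeric(A3), l1 = as.numeric(l1), l2 = as.numeric(l2),
      l3 = as.numeric(l3))
}

#' Default whole-blood input-function parameters
#'
#' A bolus-shaped tri-exponential whole-blood curve with a sharp early peak
#' (around 15 s) and a slowly clearing tail, used as the simulator's blood
#' model. Amplitudes correspond to the reference injected dose of 169 kBq
#' per gram of body weight and are calibrated so the default phantom's
#' late-window pons SUV is about 0.33 in the sham condition;
#' [simulateStudy()] rescales them linearly with each subject's dose per
#' gram.
#'
#' @return An [InputFunctionParams-class].
#' @export
defaultInputFunctionParams <- function() {
  InputFunctionParams(A1 = 17022, A2 = 438, A3 = 416,
                      l1 = 4.13, l2 = 0.12, l3 = 0.01)
}

#' Evaluate the tri-exponential whole-blood model
#'
#' `Cb(t) = (A1*t - A2 - A3)*exp(-l1*t) + A2*exp(-l2*t) + A3*exp(-l3*t)`,
#' clipped at zero. By construction `Cb(0) = 0` and the curve decays to 0.
#'
#' @param params an [InputFunctionParams-class].
#' @param t numeric vector of times in minutes, >= 0.
#' @return Whole-blood activity concentration, kBq/cm^3 (vectorised).
#' @examples
#' fengInputFunction(defaultInputFunctionParams(), c(0, 0.25, 1, 30))
#' @export
fengInputFunction <- function(params, t) {
  stopifnot(is(params, "InputFunctionParams"))
  validObject(params)
  cb <- (params@A1 * t - params@A2 - params@A3) * exp(-params@l1 * t) +
    params@A2 * exp(-params@l2 * t) + params@A3 * exp(-params@l3 * t)
  pmax(cb, 0)
}

# Macro-rates and coefficients of the 2TCM impulse response
# IRF(t) = phi1*exp(-a1*t) + phi2*exp(-a2*t); 1TCM when k3 == 0.
irfCoefficients <- function(kp) {
  if (kp@k3 == 0) {
    list(alpha = kp@k2, phi = kp@K1)
  } else {
    b <- kp@k2 + kp@k3 + kp@k4
    disc <- sqrt(b^2 - 4 * kp@k2 * kp@k4)
    a1 <- (b + disc) / 2
    a2 <- (b - disc) / 2
    list(alpha = c(a1, a2),
         phi = kp@K1 / (a1 - a2) * c(a1 - kp@k3 - kp@k4, kp@k3 + kp@k4 - a2))
  }
}

# Convolve exp(-alpha*t) with a sampled curve cb on a uniform grid of step
# dt, treating cb as piecewise linear. The per-step integral has a closed
# form, so the update y[i] = E*y[i-1] + g[i-1] (a linear recurrence,
# evaluated in C by stats::filter) is exact for piecewise-linear input.
expConvolve <- function(alpha, cb, dt) {
  n <- length(cb)
  E <- exp(-alpha * dt)
  I1 <- (1 - E) / alpha
  I2 <- dt * I1 - (1 - E * (1 + alpha * dt)) / alpha^2  # int u*exp(-a(dt-u)) du
  c0 <- cb[-n]
  slope <- (cb[-1] - c0) / dt
  g <- c0 * I1 + slope * I2
  c(0, stats::filter(g, E, method = "recursive"))
}

# Fine uniform time grid (minutes) with 0.05-s resolution.
fineGrid <- function(tmaxMin, dtSec = 0.05) {
  dt <- dtSec / 60
  seq(0, tmaxMin + 1e-12, by = dt)
}

# Tissue curve on a fine grid for a callable or parametric blood model.
tissueCurveFine <- function(kp, input, tmaxMin, dtSec = 0.05) {
  tf <- fineGrid(tmaxMin, dtSec)
  cb <- if (is(input, "InputFunctionParams")) fengInputFunction(input, tf)
        else input(tf)
  dt <- tf[2] - tf[1]
  co <- irfCoefficients(kp)
  conv <- 0
  for (i in seq_along(co$alpha))
    conv <- conv + co$phi[i] * expConvolve(co$alpha[i], cb, dt)
  list(t = tf, values = (1 - kp@vB) * conv + kp@vB * cb, cb = cb)
}

#' Simulate a tissue time-activity curve from compartment kinetics
#'
#' Evaluates the reversible two-tissue-compartment model
#' `C_T(t) = (1 - vB) * (IRF %*% Cb)(t) + vB * Cb(t)`, where the impulse
#' response is the bi-exponential with macro-rates derived from
#' `(k2, k3, k4)` (mono-exponential one-tissue model when `k3 = 0`). The
#' convolution is evaluated on a uniform 0.05-s grid with an exact
#' piecewise-linear exponential update and linearly interpolated at `t`.
#'
#' @param kp a [KineticParams-class]; must describe a reversible model.
#' @param input an [InputFunctionParams-class] or a function of time
#'   (minutes) returning whole-blood concentration, defined on
#'   `[0, max(t)]`.
#' @param t numeric vector of evaluation times in minutes.
#' @return Tissue activity concentration at `t` (kBq/cm^3).
#' @examples
#' kp <- KineticParams(0.1, 0.2, 0.05, 0.05)
#' twoTissueTac(kp, defaultInputFunctionParams(), c(1, 10, 30, 60))
#' @export
twoTissueTac <- function(kp, input, t) {
  stopifnot(is(kp, "KineticParams"))
  validObject(kp)
  if (any(t < 0)) petStop("time", "evaluation times must be >= 0")
  fine <- tissueCurveFine(kp, input, max(t))
  stats::approx(fine$t, fine$values, xout = t)$y
}

#' Analytic total volume of distribution
#'
#' `V_T = (K1/k2) * (1 + k3/k4)` for a reversible two-tissue model and
#' `K1/k2` for a one-tissue model (`k3 = 0`). V_T is the equilibrium
#' tissue-to-blood concentration ratio; the fractional blood-volume term is
#' excluded (it is a measurement nuisance, not part of the tissue
#' distribution volume).
#'
#' @param kp a [KineticParams-class].
#' @return V_T in mL/cm^3.
#' @examples
#' analyticVt(KineticParams(0.1, 0.05))                 # 2.0
#' analyticVt(KineticParams(0.1, 0.2, 0.05, 0.05))      # 1.0
#' @export
analyticVt <- function(kp) {
  stopifnot(is(kp, "KineticParams"))
  validObject(kp)
  if (kp@k3 == 0) kp@K1 / kp@k2
  else kp@K1 / kp@k2 * (1 + kp@k3 / kp@k4)
}

#' Average a continuous curve over acquisition frames
#'
#' Models that each reconstructed frame reports the time-averaged
#' concentration over the frame:
#' `value_j = (1/duration_j) * integral of curve(t) dt` over frame j,
#' computed by trapezoidal quadrature on a fine uniform sub-grid.
#'
#' @param curve function of time in minutes returning concentration.
#' @param schedule a [FrameSchedule-class].
#' @param dtSec quadrature step in seconds (default 0.05).
#' @return Numeric vector of per-frame mean concentrations.
#' @examples
#' frameAverage(function(t) rep(2, length(t)), defaultFrameSchedule())
#' @export
frameAverage <- function(curve, schedule, dtSec = 0.05) {
  stopifnot(is(schedule, "FrameSchedule"))
  validObject(schedule)
  startsMin <- schedule@starts / 60
  dursMin <- schedule@durations / 60
  vapply(seq_along(startsMin), function(j) {
    nsub <- max(2L, ceiling(schedule@durations[j] / dtSec) + 1L)
    tt <- seq(startsMin[j], startsMin[j] + dursMin[j], length.out = nsub)
    y <- curve(tt)
    sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) / dursMin[j]
  }, numeric(1))
}
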