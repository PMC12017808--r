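# Scalar activation ingredients: force-stretch dependencies, tanh and
# twitch-superposition time activation, active nominal stress, and
# tabulated spatiotemporal scaling.

#' Hyperbolic-tangent time activation
#'
#' \eqn{f_t(t) = s \tanh(c (t - t_0))} for \eqn{t \ge t_0} and 0 before the
#' activation start time (the raw tanh is negative there and activation
#' cannot be negative).
#'
#' @param t Time in seconds (vectorized).
#' @param c Rise-rate parameter (1/s), > 0.
#' @param t0 Activation start time (s).
#' @param s Scaling factor in [0, 1].
#' @return Activation level(s) in [0, s].
#' @export
f_tanh <- function(t, c, t0 = 0, s = 1) {
  stopifnot(c > 0, s >= 0, s <= 1)
  pmax(0, s * tanh(c * (t - t0)))
}

#' Motor-unit twitch-train parameters
#'
#' Bundles the microstructural quantities of a recruitment of `nMU`
#' motor-unit types: fractions `rho` (summing to 1), peak twitch forces `Fi`
#' (N), twitch contraction times `Ti` (s, time to the twitch peak), and
#' interstimulus intervals `Ii` (s), plus the number of activated motor
#' units per unit reference cross-section area `Na` (1/mm^2).
#'
#' @param rho,Fi,Ti,Ii Numeric vectors of common length.
#' @param Na Activated motor units per reference area (1/mm^2).
#' @return An object of class `twitch_train`.
#' @export
twitch_train <- function(rho, Fi, Ti, Ii, Na = 1) {
  n <- length(rho)
  if (n == 0L) stop("motor-unit arrays must be nonempty", call. = FALSE)
  if (length(Fi) != n || length(Ti) != n || length(Ii) != n) {
    stop("rho, Fi, Ti, Ii must share the same length", call. = FALSE)
  }
  stopifnot(all(Fi > 0), all(Ti > 0), all(Ii > 0), Na > 0)
  if (abs(sum(rho) - 1) > 1e-8) {
    stop("motor-unit fractions rho must sum to 1", call. = FALSE)
  }
  structure(list(rho = rho, Fi = Fi, Ti = Ti, Ii = Ii, Na = Na, nMU = n),
            class = "twitch_train")
}

# unnormalized superposed train Na * sum_i rho_i F_i(t): single twitches of
# shape (dt/Ti) exp(1 - dt/Ti) fired every Ii and summed linearly
twitch_train_raw <- function(t, p) {
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    tot <- 0
    for (i in seq_len(p$nMU)) {
      nstim <- floor(tt / p$Ii[i])
      dt <- tt - (0:nstim) * p$Ii[i]
      u <- dt / p$Ti[i]
      tot <- tot + p$rho[i] * p$Fi[i] * sum(u * exp(1 - u))
    }
    p$Na * tot
  }, numeric(1))
}

# fused-tetanus plateau of the unnormalized train: mean over one
# interstimulus period of the steady-state superposition
twitch_train_plateau <- function(p) {
  t_ss <- 20 * max(p$Ti)
  ts <- seq(t_ss, t_ss + max(p$Ii), length.out = 201)
  mean(twitch_train_raw(ts, p))
}

#' Normalized twitch-superposition time activation
#'
#' Superposes single twitches of shape \eqn{(\Delta t / T_i)
#' \exp(1 - \Delta t / T_i)} fired every \eqn{I_i} per motor-unit type,
#' weighted by \eqn{\rho_i F_i} and scaled by `Na`, then normalized so the
#' fused-tetanus plateau equals 1.
#'
#' @param t Time in seconds (vectorized), >= 0.
#' @param params A [twitch_train()].
#' @return Normalized activation level(s); the plateau oscillates about 1.
#' @export
f_twitch <- function(t, params) {
  if (any(t < 0)) stop("time must be nonnegative", call. = FALSE)
  twitch_train_raw(t, params) / twitch_train_plateau(params)
}

#' Active force-stretch dependency (generalized active-strain family)
#'
#' \eqn{f_\xi(\lambda)} vanishes for \eqn{\lambda \le \lambda_{min}} (no
#' myofilament overlap), rises to its maximum 1 at the optimal fiber stretch
#' \eqn{\lambda_{opt}}, and decays to zero for large stretches:
#' \deqn{f_\xi = \frac{\lambda - \lambda_{min}}{\lambda_{opt} -
#' \lambda_{min}} \exp\!\left(\frac{(2\lambda_{min} - \lambda -
#' \lambda_{opt})(\lambda - \lambda_{opt})}{2 (\lambda_{min} -
#' \lambda_{opt})^2}\right)}
#'
#' @param lambda Fiber stretch (vectorized), > 0.
#' @param lambda_opt Optimal fiber stretch.
#' @param lambda_min Minimal active fiber stretch, 0 < lambda_min <
#'   lambda_opt.
#' @return Values in [0, 1], maximum 1 at `lambda_opt`.
#' @export
f_xi <- function(lambda, lambda_opt, lambda_min) {
  stopifnot(lambda_min > 0, lambda_min < lambda_opt)
  out <- numeric(length(lambda))
  up <- lambda > lambda_min
  l <- lambda[up]
  out[up] <- (l - lambda_min) / (lambda_opt - lambda_min) *
    exp((2 * lambda_min - l - lambda_opt) * (l - lambda_opt) /
          (2 * (lambda_min - lambda_opt)^2))
  out
}

#' Active force-stretch dependency (active-stress model)
#'
#' Three-branch parabolic description, continuous everywhere, equal to 1 at
#' the optimal stretch `lambda_opta` and symmetric about it; the outer
#' branches rise again for very small/large stretches (a known
#' non-physiological feature of this classical form).
#'
#' @param lambda_bar Isochoric fiber stretch (vectorized).
#' @param lambda_opta Optimal fiber stretch.
#' @return Nonnegative values, 1 at `lambda_opta`, 0.36 at the branch
#'   junctions `0.6 lambda_opta` and `1.4 lambda_opta`.
#' @export
f_xi_a <- function(lambda_bar, lambda_opta) {
  stopifnot(lambda_opta > 0)
  r <- lambda_bar / lambda_opta
  ifelse(r <= 0.6, 9 * (r - 0.4)^2,
         ifelse(r < 1.4, 1 - 4 * (1 - r)^2, 9 * (r - 1.6)^2))
}

#' Passive force-stretch dependency (active-stress model)
#'
#' Zero in compression (\eqn{\bar\lambda \le 1}), exponential for
#' \eqn{1 < \bar\lambda < \lambda^*}, and linear beyond the minimum linear
#' fiber stretch \eqn{\lambda^*}, with the linear coefficients chosen for
#' C1-continuity: \eqn{D_3 = D_1 D_2 e^{D_2 (\lambda^* - 1)}}, \eqn{D_4 =
#' D_1 (e^{D_2(\lambda^* - 1)} - 1) - \lambda^* D_3}.
#'
#' @param lambda_bar Isochoric fiber stretch (vectorized).
#' @param D1,D2 Passive fiber parameters (dimensionless).
#' @param lambda_star Minimum linear fiber stretch, > 1.
#' @return Nonnegative values; zero on (0, 1].
#' @export
f_xi_p <- function(lambda_bar, D1, D2, lambda_star) {
  stopifnot(D1 > 0, D2 > 0, lambda_star > 1)
  D3 <- D1 * D2 * exp(D2 * (lambda_star - 1))
  D4 <- D1 * (exp(D2 * (lambda_star - 1)) - 1) - lambda_star * D3
  ifelse(lambda_bar <= 1, 0,
         ifelse(lambda_bar < lambda_star,
                D1 * (exp(D2 * (lambda_bar - 1)) - 1),
                D3 * lambda_bar + D4))
}

#' Active nominal stress
#'
#' \eqn{P_a = P_{opt}\, f_t\, f_\xi(\lambda)\, f_v} with the force-velocity
#' dependency held at \eqn{f_v = 1} (quasi-static). Vanishes whenever the
#' time activation is zero or the fiber stretch is at or below
#' `lambda_min`.
#'
#' @param lambda Fiber stretch, > 0.
#' @param Popt Peak active nominal stress (kPa), >= 0.
#' @param ft Time-activation level in [0, 1] (e.g. from [f_tanh()] or
#'   [f_twitch()]; 1 at tetanus).
#' @param lambda_opt,lambda_min Force-stretch dependency parameters.
#' @return Active nominal stress in kPa.
#' @export
active_nominal_stress <- function(lambda, Popt, ft, lambda_opt, lambda_min) {
  if (Popt < 0) stop("Popt must be nonnegative", call. = FALSE)
  stopifnot(all(lambda > 0))
  Popt * ft * f_xi(lambda, lambda_opt, lambda_min)
}

#' Activation input for a constitutive evaluation
#'
#' Describes the activation state at a material point. `"passive"` means no
#' activation, `"tetanic"` the fused-tetanus plateau (time function 1), and
#' `"timed"` evaluates the model's native time function (tanh ramp for the
#' ASE and GASAM models, twitch superposition for GASA and ASA) at time
#' `t`. The scaling factor `scale` multiplies the time-function value and
#' implements spatiotemporally varying activation, where a driver assigns
#' one factor per material point and time step.
#'
#' @param state One of `"passive"`, `"tetanic"`, `"timed"`.
#' @param t Evaluation time in seconds (required for `"timed"`).
#' @param scale Scaling factor in [0, 1].
#' @return An object of class `muscle_activation`.
#' @export
muscle_activation <- function(state = c("tetanic", "passive", "timed"),
                              t = NULL, scale = 1) {
  state <- match.arg(state)
  stopifnot(scale >= 0, scale <= 1)
  if (state == "timed" && (is.null(t) || !is.finite(t))) {
    stop("timed activation requires a finite time t", call. = FALSE)
  }
  structure(list(state = state, t = t, scale = scale),
            class = "muscle_activation")
}

#' Read a tabulated activation schedule
#'
#' Reads a two-column whitespace- or tab-separated file (time in seconds,
#' scaling factor) and returns a step-interpolating function: the scaling
#' factor of the latest tabulated time not exceeding `t` (0 before the first
#' entry), mirroring a discrete per-time-step activation prescription.
#'
#' @param path Path to the tabular file.
#' @return A function `s(t)` vectorized in `t`.
#' @export
read_activation_schedule <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("time", "scale"))
  if (nrow(tab) < 1L) stop("empty activation schedule", call. = FALSE)
  if (is.unsorted(tab$time, strictly = TRUE)) {
    stop("schedule times must be strictly increasing", call. = FALSE)
  }
  if (any(tab$scale < 0 | tab$scale > 1)) {
    stop("scaling factors must lie in [0, 1]", call. = FALSE)
  }
  force(tab)
  function(t) {
    idx <- findInterval(t, tab$time)
    ifelse(idx >= 1L, tab$scale[pmax(idx, 1L)], 0)
  }
}
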