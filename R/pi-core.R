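#' PI controller gains
#'
#' Bundles the two controller gains with the target mean gray level and the
#' iteration budget used by [regulate_intensity()]. Values outside the
#' conventional tuning ranges (`kp` in \[0.1, 1\], `ki` in \[0.01, 1\]) are
#' accepted but flagged with a warning; `ki = 0` disables integral action and
#' is not flagged.
#'
#' @param kp proportional gain, dimensionless, must be positive.
#' @param ki integral gain, dimensionless, must be non-negative.
#' @param target_intensity desired mean gray level in \[0, 1\].
#' @param max_iterations positive integer budget for the closed-loop
#'   preprocessor.
#' @return an object of class `pi_gains`.
#' @examples
#' g <- pi_gains(kp = 0.6, ki = 0.05)
#' @export
pi_gains <- function(kp, ki, target_intensity = 0.5, max_iterations = 1L) {
  stopifnot(is.numeric(kp), length(kp) == 1, is.finite(kp),
            is.numeric(ki), length(ki) == 1, is.finite(ki))
  if (kp <= 0) stop("kp must be > 0")
  if (ki < 0) stop("ki must be >= 0")
  if (!is.numeric(target_intensity) || target_intensity < 0 ||
      target_intensity > 1) {
    stop("target_intensity must lie in [0, 1]")
  }
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    stop("max_iterations must be a positive integer")
  }
  if (kp < 0.1 || kp > 1) {
    warning(sprintf("kp = %g is outside the conventional tuning range [0.1, 1]", kp))
  }
  if (ki > 1 || (ki > 0 && ki < 0.01)) {
    warning(sprintf("ki = %g is outside the conventional tuning range [0.01, 1]", ki))
  }
  structure(list(kp = kp, ki = ki, target_intensity = target_intensity,
                 max_iterations = max_iterations),
            class = "pi_gains")
}

#' Fresh PI controller state
#'
#' @return a `pi_state` object with a zero integral accumulator and step 0.
#' @export
pi_state <- function() {
  structure(list(integral = 0, step = 0L), class = "pi_state")
}

#' One step of the discrete PI control law
#'
#' Updates the integral accumulator with the current error and returns the
#' control signal `kp * e + ki * sum(e_1..e_t)`. The accumulator is an exact
#' sum: no forgetting factor is applied, which distinguishes this law from
#' exponential-moving-average schemes.
#'
#' @param error scalar error signal (reference minus measurement).
#' @param state a [pi_state()] object.
#' @param gains a [pi_gains()] object.
#' @return list with elements `signal` and `state` (the advanced state).
#' @examples
#' st <- pi_state()
#' pi_control_signal(1, st, pi_gains(0.6, 0.05))$signal # 0.65
#' @export
pi_control_signal <- function(error, state, gains) {
  stopifnot(inherits(state, "pi_state"), inherits(gains, "pi_gains"))
  if (!is.numeric(error) || length(error) != 1 || !is.finite(error)) {
    stop(sprintf("non-finite error signal at step %d", state$step + 1L))
  }
  state$integral <- state$integral + error
  state$step <- state$step + 1L
  signal <- gains$kp * error + gains$ki * state$integral
  list(signal = signal, state = state)
}

validate_image_plane <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix of gray levels")
  }
  if (length(image) == 0) stop("image is empty")
  if (anyNA(image) || any(!is.finite(image))) stop("image contains NaN/NA pixels")
  if (min(image) < 0 || max(image) > 1) stop("pixel values must lie in [0, 1]")
  invisible(image)
}

#' Closed-loop mean-intensity regulation of an image
#'
#' Iteratively drives the mean gray level of an image toward
#' `gains$target_intensity`: in each loop the error `target - mean(image)` is
#' fed to the PI law, and the resulting scalar control signal is added
#' uniformly to every pixel, followed by clipping to \[0, 1\]. The loop stops
#' early once `|error| <= tolerance`; `tolerance = 0` always exhausts
#' `max_iterations` unless the error is exactly zero.
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param gains a [pi_gains()] object.
#' @param tolerance non-negative early-stopping tolerance on the absolute
#'   error (default `1e-3`).
#' @return list with elements `image` (the adjusted matrix) and `trace`, a
#'   data frame with one row per loop and columns `iteration`, `mean`,
#'   `error`, `integral`, `signal` (`signal` is `NA` on an early-stop row
#'   where no correction was applied).
#' @examples
#' out <- regulate_intensity(matrix(0, 8, 8), pi_gains(0.6, 0.05))
#' out$trace
#' @export
regulate_intensity <- function(image, gains, tolerance = 1e-3) {
  stopifnot(inherits(gains, "pi_gains"))
  validate_image_plane(image)
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0) {
    stop("tolerance must be a non-negative number")
  }
  state <- pi_state()
  rows <- vector("list", gains$max_iterations)
  for (it in seq_len(gains$max_iterations)) {
    m <- mean(image)
    e <- gains$target_intensity - m
    if (abs(e) <= tolerance) {
      rows[[it]] <- data.frame(iteration = it, mean = m, error = e,
                               integral = state$integral, signal = NA_real_)
      break
    }
    upd <- pi_control_signal(e, state, gains)
    state <- upd$state
    image <- clip01(image + upd$signal)
    rows[[it]] <- data.frame(iteration = it, mean = m, error = e,
                             integral = state$integral, signal = upd$signal)
  }
  list(image = image, trace = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
}

#' Analytic stability classification of the intensity loop
#'
#' The mean-intensity closed loop is (before clipping) a linear recurrence in
#' the deviation `x = mean - target` and the integral accumulator `I`:
#' `x' = (1 - kp - ki) x + ki I`, `I' = I - x`. The loop is classified by the
#' spectral radius of the companion matrix. When `ki = 0` the integral state
#' is disconnected from the mean dynamics (its unit eigenvalue is
#' unobservable), so the scalar factor `|1 - kp|` is used instead.
#'
#' @param gains a [pi_gains()] object, or any list with numeric `kp` and `ki`
#'   entries (accepted so degenerate gain combinations can be analysed).
#' @return list with `regime` (one of `"converging"`, `"marginal"`,
#'   `"diverging"`), `spectral_radius`, `eigenvalues`, and `oscillatory`
#'   (`TRUE` when the loop approaches its fixed point non-monotonically:
#'   complex or negative eigenvalues).
#' @examples
#' stability_margin(pi_gains(0.6, 0.05))$regime # "converging"
#' @export
stability_margin <- function(gains) {
  kp <- gains$kp
  ki <- gains$ki
  stopifnot(is.numeric(kp), is.numeric(ki), length(kp) == 1, length(ki) == 1)
  if (ki == 0) {
    ev <- complex(real = 1 - kp, imaginary = 0)
  } else {
    A <- matrix(c(1 - kp - ki, -1, ki, 1), 2, 2)
    ev <- eigen(A, only.values = TRUE)$values
    ev <- as.complex(ev)
  }
  rho <- max(Mod(ev))
  tol <- 1e-9
  regime <- if (rho < 1 - tol) "converging" else if (rho <= 1 + tol) "marginal" else "diverging"
  oscillatory <- any(abs(Im(ev)) > tol) || any(Re(ev) < -tol)
  list(regime = regime, spectral_radius = rho, eigenvalues = ev,
       oscillatory = oscillatory)
}
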