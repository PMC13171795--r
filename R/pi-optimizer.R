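# PI-controlled parameter updates: the loss gradient is treated as the
# control error; the proportional term is an instantaneous gradient step and
# the integral term is the exact, non-decaying sum of all past gradients.

#' State for the PI-controlled optimizer
#'
#' @param kp proportional step gain (> 0), playing the role of a learning
#'   rate for the instantaneous gradient.
#' @param ki integral step gain (>= 0) applied to the exact sum of all past
#'   gradients. With `ki = 0` the rule reduces elementwise to plain gradient
#'   descent with learning rate `kp`.
#' @param anti_windup optional positive clamp on the elementwise magnitude of
#'   the integral accumulator (default `NULL`: no clamping, the faithful
#'   exact-integrator rule).
#' @param eta_baseline learning rate used only by the SGD comparison mode of
#'   [compare_optimizers()]; stored for bookkeeping.
#' @return a `pi_optimizer_state` object with a zero integral accumulator.
#' @export
pi_optimizer_state <- function(kp, ki, anti_windup = NULL, eta_baseline = kp) {
  stopifnot(is.numeric(kp), kp > 0, is.numeric(ki), ki >= 0)
  if (!is.null(anti_windup)) stopifnot(is.numeric(anti_windup), anti_windup > 0)
  structure(list(integral = NULL, step = 0L, kp = kp, ki = ki,
                 anti_windup = anti_windup, eta_baseline = eta_baseline),
            class = "pi_optimizer_state")
}

# apply f elementwise over a parameter structure (array or nested named list)
param_map <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(j) {
      do.call(param_map, c(list(f), lapply(args, `[[`, j)))
    })
    names(out) <- names(args[[1]])
    out
  } else {
    do.call(f, args)
  }
}

check_grad_finite <- function(grads, path = "") {
  if (is.list(grads)) {
    nm <- names(grads) %||% as.character(seq_along(grads))
    for (j in seq_along(grads)) {
      check_grad_finite(grads[[j]], paste0(path, if (nzchar(path)) "$" else "", nm[j]))
    }
  } else if (any(!is.finite(grads))) {
    stop(sprintf("non-finite gradient entries in parameter '%s'", path))
  }
  invisible(NULL)
}

#' One PI-controlled parameter update
#'
#' Accumulates the current gradients into the exact integral (the sum
#' includes the current step) and applies
#' `theta' = theta - kp * g - ki * I`.
#'
#' @param parameters numeric array, or a (nested) named list of arrays.
#' @param gradients gradients with exactly the same structure.
#' @param state a [pi_optimizer_state()].
#' @return list with updated `parameters` and `state`.
#' @examples
#' st <- pi_optimizer_state(kp = 0.6, ki = 0.05)
#' pi_step(1, 1, st)$parameters # 0.35 for L = theta^2 / 2 at theta = 1
#' @export
pi_step <- function(parameters, gradients, state) {
  stopifnot(inherits(state, "pi_optimizer_state"))
  check_grad_finite(gradients)
  if (is.null(state$integral)) {
    state$integral <- param_map(function(g) g * 0, gradients)
  }
  state$integral <- param_map(`+`, state$integral, gradients)
  if (!is.null(state$anti_windup)) {
    cl <- state$anti_windup
    state$integral <- param_map(function(i) pmin(pmax(i, -cl), cl), state$integral)
  }
  kp <- state$kp
  ki <- state$ki
  parameters <- param_map(function(th, g, i) th - kp * g - ki * i,
                          parameters, gradients, state$integral)
  state$step <- state$step + 1L
  list(parameters = parameters, state = state)
}

#' Packaged toy optimization problems
#'
#' `"quadratic"` is the bowl `L = ||theta||^2 / 2`; `"biased_quadratic"` adds
#' a constant bias vector to every observed gradient (the reported loss stays
#' the unbiased bowl); `"logistic2d"` is full-batch logistic regression on a
#' seeded two-Gaussian point cloud, with the reference optimum taken from
#' `stats::glm`.
#'
#' @param name one of `"quadratic"`, `"biased_quadratic"`, `"logistic2d"`.
#' @param seed integer seed for the logistic cloud.
#' @return list with `init`, `loss`, `grad`, `theta_star`.
#' @export
toy_problem <- function(name = c("quadratic", "biased_quadratic", "logistic2d"),
                        seed = 1L) {
  name <- match.arg(name)
  if (name == "quadratic") {
    list(init = c(1, -1.5),
         loss = function(th) sum(th^2) / 2,
         grad = function(th) th,
         theta_star = c(0, 0))
  } else if (name == "biased_quadratic") {
    b <- c(0.3, -0.2)
    list(init = c(1, -1.5),
         loss = function(th) sum(th^2) / 2,
         grad = function(th) th + b,
         theta_star = c(0, 0),
         bias = b)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    n <- 30L
    X <- rbind(cbind(rnorm(n, -0.8, 1.2), rnorm(n, -0.4, 1.2)),
               cbind(rnorm(n, 0.8, 1.2), rnorm(n, 0.4, 1.2)))
    y <- rep(c(0, 1), each = n)
    fit <- stats::glm.fit(cbind(1, X), y, family = stats::binomial())
    list(init = c(0, 0, 0),
         loss = function(th) {
           z <- th[1] + X %*% th[-1]
           mean(log1p(exp(z)) - y * z)
         },
         grad = function(th) {
           z <- th[1] + X %*% th[-1]
           r <- 1 / (1 + exp(-z)) - y
           c(mean(r), colMeans(X * as.vector(r)))
         },
         theta_star = unname(fit$coefficients))
  }
}

#' Compare PI, SGD and momentum trajectories on a toy problem
#'
#' Runs the PI rule, plain gradient descent and momentum SGD from the same
#' start on one of the [toy_problem()] losses and tabulates per-step loss and
#' parameter-error norms. Everything is deterministic given `seed` (only the
#' logistic cloud is random).
#'
#' @param problem toy problem name, see [toy_problem()].
#' @param steps number of update steps.
#' @param kp,ki PI gains; `eta` is both the SGD learning rate and the
#'   momentum learning rate; `beta` the momentum decay.
#' @param seed seed forwarded to [toy_problem()].
#' @return data frame with columns `problem`, `optimizer`, `step`, `loss`,
#'   `param_error` (step 0 rows are the shared start).
#' @export
compare_optimizers <- function(problem = "quadratic", steps = 100L,
                               kp = 0.1, ki = 0.01, eta = 0.1, beta = 0.9,
                               seed = 1L) {
  tp <- toy_problem(problem, seed = seed)
  run <- function(optname) {
    th <- tp$init
    st_pi <- pi_optimizer_state(kp = kp, ki = ki, eta_baseline = eta)
    v <- th * 0
    out <- data.frame(problem = problem, optimizer = optname,
                      step = 0:steps, loss = NA_real_, param_error = NA_real_)
    out$loss[1] <- tp$loss(th)
    out$param_error[1] <- sqrt(sum((th - tp$theta_star)^2))
    for (t in seq_len(steps)) {
      g <- tp$grad(th)
      if (optname == "pi") {
        upd <- pi_step(th, g, st_pi)
        th <- upd$parameters
        st_pi <- upd$state
      } else if (optname == "sgd") {
        th <- th - eta * g
      } else {
        v <- beta * v + g
        th <- th - eta * v
      }
      out$loss[t + 1] <- tp$loss(th)
      out$param_error[t + 1] <- sqrt(sum((th - tp$theta_star)^2))
    }
    out
  }
  do.call(rbind, lapply(c("pi", "sgd", "momentum"), run))
}

#' Analytic stability classification of the PI rule on the scalar quadratic
#'
#' On `L = theta^2 / 2` the PI update is the linear 2-state recurrence
#' `theta' = (1 - kp - ki) theta - ki I`, `I' = I + theta`; the spectral
#' radius of its companion matrix classifies convergence (with `ki = 0` the
#' scalar factor `|1 - kp|` is used, as the integral state is disconnected).
#'
#' @param kp,ki PI step gains.
#' @return list with `regime`, `spectral_radius`, `eigenvalues`.
#' @export
pi_quadratic_stability <- function(kp, ki) {
  if (ki == 0) {
    ev <- complex(real = 1 - kp)
  } else {
    A <- matrix(c(1 - kp - ki, 1, -ki, 1), 2, 2)
    ev <- as.complex(eigen(A, only.values = TRUE)$values)
  }
  rho <- max(Mod(ev))
  tol <- 1e-9
  regime <- if (rho < 1 - tol) "converging" else if (rho <= 1 + tol) "marginal" else "diverging"
  list(regime = regime, spectral_radius = rho, eigenvalues = ev)
}
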