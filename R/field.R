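#' Parameters of the six-state spatial Epileptor model
#'
#' All constants of the neural-field model. The defaults are the calibrated
#' values used for coherent seizure propagation: `k = 0.636`,
#' `gamma11 = 0.34`, `gamma12 = 0.064`, `gamma22 = 0.032`, `gamma_glob = 1`,
#' `theta11 = -1`, `theta12 = -1`, `theta22 = -0.5`, `Iext = 3.1`,
#' `Iext2 = 0.45`, `tau0 = 2857`, `tau1 = 1`, `tau2 = 10`, `tt = 0.17`.
#' The excitability `x0` controls the equilibrium of each node: values
#' above roughly -2.06 permit autonomous seizures (epileptogenic zone,
#' `x0 = -1.6` in the study), values below give nodes that seize only when
#' recruited. `m` shapes the ictal branch of the fast subsystem (default 0).
#'
#' @param x0 excitability, scalar or per-node vector.
#' @param Iext,Iext2 constant bias currents of the fast-discharge and
#'   spike-and-wave (SWE) subsystems.
#' @param m ictal-dynamics (slope) parameter.
#' @param k global coupling scale.
#' @param gamma11,gamma12,gamma22 local coupling strengths (rapid
#'   discharge, integral and SWE terms).
#' @param gamma_glob multiplier on the global coupling.
#' @param theta11,theta12,theta22 Heaviside thresholds of the three local
#'   coupling terms.
#' @param tau0,tau1,tau2 time constants of the permittivity `z`, the fast
#'   recovery `y1` and the SWE recovery `y2`.
#' @param tt global time-scale multiplying all six derivatives.
#' @param a,b,c,d,aa,bb fixed polynomial coefficients of the Epileptor
#'   family (rarely changed).
#' @return an object of class `sem_parameters`.
#' @export
sem_parameters <- function(x0 = -2.2, Iext = 3.1, Iext2 = 0.45, m = 0,
                           k = 0.636, gamma11 = 0.34, gamma12 = 0.064,
                           gamma22 = 0.032, gamma_glob = 1,
                           theta11 = -1, theta12 = -1, theta22 = -0.5,
                           tau0 = 2857, tau1 = 1, tau2 = 10, tt = 0.17,
                           a = 1, b = 3, c = 1, d = 5, aa = 6, bb = 2) {
  stopifnot(tau0 > 0, tau1 > 0, tau2 > 0, tt > 0,
            gamma11 >= 0, gamma12 >= 0, gamma22 >= 0, gamma_glob >= 0,
            all(is.finite(x0)))
  structure(list(x0 = x0, Iext = Iext, Iext2 = Iext2, m = m, k = k,
                 gamma11 = gamma11, gamma12 = gamma12, gamma22 = gamma22,
                 gamma_glob = gamma_glob, theta11 = theta11,
                 theta12 = theta12, theta22 = theta22,
                 tau0 = tau0, tau1 = tau1, tau2 = tau2, tt = tt,
                 a = a, b = b, c = c, d = d, aa = aa, bb = bb),
            class = "sem_parameters")
}

#' @export
print.sem_parameters <- function(x, ...) {
  cat("<sem_parameters> x0 in [", min(x$x0), ", ", max(x$x0),
      "], k = ", x$k, ", tt = ", x$tt, "\n", sep = "")
  invisible(x)
}

# numeric parameter vector handed to the compiled core (order matters)
sem_par_vector <- function(p) {
  c(p$Iext, p$Iext2, p$m, p$k, p$gamma11, p$gamma12, p$gamma22,
    p$gamma_glob, p$theta11, p$theta12, p$theta22,
    p$tau0, p$tau1, p$tau2, p$tt, p$a, p$b, p$c, p$d, p$aa, p$bb)
}

# the printed rest and onset state vectors (x1, y1, z, x2, y2, g)
SEM_REST_STATE  <- c(x1 = -1.5, y1 = -11, z = 3, x2 = -0.9, y2 = 0.3, g = -0.1)
SEM_ONSET_STATE <- c(x1 = 0,    y1 = -5,  z = 3, x2 = 0,    y2 = 0,   g = 0)

#' Initialize the field state
#'
#' Every node starts at the interictal stable point
#' `(x1, y1, z, x2, y2, g) = (-1.5, -11, 3, -0.9, 0.3, -0.1)`; nodes in the
#' seizure-onset zone are overridden with the ictal state
#' `(0, -5, 3, 0, 0, 0)`, which triggers pathological propagation.
#'
#' @param n_nodes number of field nodes (>= 1).
#' @param onset_nodes integer vector of onset-zone node ids (may be empty).
#' @return an object of class `sem_state`: list of six per-node numeric
#'   vectors `x1, y1, z, x2, y2, g` plus `time` (ms).
#' @export
initialize_states <- function(n_nodes, onset_nodes = integer(0)) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L) stop("n_nodes must be >= 1")
  onset_nodes <- as.integer(onset_nodes)
  if (length(onset_nodes) &&
      (any(onset_nodes < 1L) || any(onset_nodes > n_nodes)))
    stop("onset_nodes out of range")
  s <- lapply(SEM_REST_STATE, rep, times = n_nodes)
  for (f in names(s)) s[[f]][onset_nodes] <- SEM_ONSET_STATE[[f]]
  s$time <- 0
  structure(s, class = "sem_state")
}

sem_state_matrix <- function(state) {
  rbind(state$x1, state$y1, state$z, state$x2, state$y2, state$g)
}

#' Ring-buffer history of past x1 values
#'
#' Holds the last `depth` per-node values of `x1` for delayed global
#' coupling. Implemented as an environment so writes mutate in place.
#' Reading at delay 0 returns the most recently written state; reads beyond
#' the buffer depth are an error.
#'
#' @param x1 initial per-node `x1` (the buffer is pre-filled with it, the
#'   usual convention for the pre-simulation past).
#' @param depth buffer depth in steps (>= 1).
#' @return an object of class `history_buffer`.
#' @export
history_buffer <- function(x1, depth) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("depth must be >= 1")
  h <- new.env(parent = emptyenv())
  h$buf <- matrix(x1, nrow = length(x1), ncol = depth)
  h$depth <- depth
  h$pos <- 1L  # column holding the newest write
  class(h) <- "history_buffer"
  h
}

#' @rdname history_buffer
#' @param h a `history_buffer`.
#' @param x1 per-node values to append as the newest entry.
#' @export
history_write <- function(h, x1) {
  h$pos <- if (h$pos == h$depth) 1L else h$pos + 1L
  h$buf[, h$pos] <- x1
  invisible(h)
}

#' @rdname history_buffer
#' @param node node index (1-based).
#' @param delay_steps nonnegative integer delay in steps; 0 returns the
#'   newest entry.
#' @export
history_read <- function(h, node, delay_steps) {
  if (any(delay_steps < 0L) || any(delay_steps > h$depth - 1L))
    stop("delay exceeds history buffer depth")
  col <- ((h$pos - 1L - delay_steps) %% h$depth) + 1L
  h$buf[cbind(node, col)]
}

#' Delayed global difference coupling on x1
#'
#' `input_i = k * gamma_glob * sum_j w_ij * (x1_j(t - d_ij) - x1_i(t))`.
#' The difference form vanishes at consensus, so the homogeneous stable
#' point remains a solution of the coupled system.
#'
#' @param history a `history_buffer` whose newest entry is `x1_now`.
#' @param conn a `sparse_connectome` (or `NULL` for no global coupling).
#' @param x1_now per-node current `x1`.
#' @param k global coupling scale (`k * gamma_glob` premultiplied by the
#'   caller if desired).
#' @param dt step size in ms, used to convert delays to steps (rounded to
#'   nearest, ties up).
#' @return per-node coupling input to the `x1` equation.
#' @export
compute_global_coupling <- function(history, conn, x1_now, k, dt = 0.1) {
  n <- length(x1_now)
  if (is.null(conn)) return(numeric(n))
  tw <- methods::as(conn$weights, "TsparseMatrix")
  i <- tw@i + 1L; j <- tw@j + 1L; w <- tw@x
  dsteps <- delay_steps(conn, dt)
  xd <- history_read(history, j, dsteps)
  acc <- numeric(n)
  contrib <- w * (xd - x1_now[i])
  agg <- rowsum(contrib, i)
  acc[as.integer(rownames(agg))] <- agg[, 1]
  k * acc
}

# integer step delays of a connectome (nearest, ties rounded up)
delay_steps <- function(conn, dt) {
  tw <- methods::as(conn$weights, "TsparseMatrix")
  d <- conn$delays[cbind(tw@i + 1L, tw@j + 1L)]
  as.integer(floor(d / dt + 0.5))
}

#' Heaviside-gated local coupling terms
#'
#' Three kernel-weighted neighbor sums gated by Heaviside steps:
#' `lc11_i = gamma11 * sum_j K_ij * H(x1_j - theta11)` (rapid discharge),
#' `lc12_i = gamma12 * sum_j K_ij * H(x1_j - theta12)` (integral term) and
#' `lc22_i = gamma22 * sum_j K_ij * H(x2_j - theta22)` (SWE term).
#' `H(u) = 1` for `u >= 0`, else 0.
#'
#' @param x1,x2 per-node state values.
#' @param kernel a `local_kernel` (or `NULL` for zero local coupling).
#' @param params a `sem_parameters`.
#' @return list with per-node vectors `lc11`, `lc12`, `lc22`.
#' @export
compute_local_coupling <- function(x1, x2, kernel, params) {
  n <- length(x1)
  if (length(x2) != n) stop("x1 and x2 must have equal length")
  if (is.null(kernel)) {
    z <- numeric(n)
    return(list(lc11 = z, lc12 = z, lc22 = z))
  }
  K <- kernel$K
  if (nrow(K) != n) stop("kernel size does not match node count")
  list(
    lc11 = params$gamma11 * as.numeric(K %*% as.numeric(x1 >= params$theta11)),
    lc12 = params$gamma12 * as.numeric(K %*% as.numeric(x1 >= params$theta12)),
    lc22 = params$gamma22 * as.numeric(K %*% as.numeric(x2 >= params$theta22))
  )
}

#' Right-hand side of the six-state spatial Epileptor
#'
#' The fast pair `(x1, y1)` produces rapid discharges, the slow pair
#' `(x2, y2)` the spike-and-wave (SWE) oscillation, `z` is the slow
#' permittivity controlling ictal transitions and `g` low-pass filters past
#' `x1` activity (temporal convolution), linking the two subsystems. Global
#' input and the rapid-discharge local term enter the `x1` equation, the
#' SWE local term enters `x2`, and the integral local term enters `g`. All
#' derivatives are scaled by the global time scale `tt`.
#'
#' @param state a `sem_state`.
#' @param params a `sem_parameters`.
#' @param glob per-node global coupling input (default 0).
#' @param lc list with `lc11`, `lc12`, `lc22` (default all 0).
#' @return list of six per-node derivative vectors.
#' @export
sem_derivatives <- function(state, params,
                            glob = 0, lc = list(lc11 = 0, lc12 = 0, lc22 = 0)) {
  x1 <- state$x1; y1 <- state$y1; z <- state$z
  x2 <- state$x2; y2 <- state$y2; g <- state$g
  if (!all(is.finite(c(x1, y1, z, x2, y2, g))))
    stop("non-finite state")
  p <- params
  f1 <- ifelse(x1 < 0,
               (p$a * x1 - p$b) * x1 * x1,
               (x2 - 0.6 * (z - 4)^2 - p$m) * x1)
  f2 <- ifelse(x2 < -0.25, 0, p$aa * (x2 + 0.25))
  list(
    x1 = p$tt * (y1 - f1 - z + p$Iext + glob + lc$lc11),
    y1 = p$tt * ((p$c - p$d * x1 * x1 - y1) / p$tau1),
    z  = p$tt * ((4 * (x1 - p$x0) - z) / p$tau0),
    x2 = p$tt * (-y2 + x2 - x2^3 + p$Iext2 + p$bb * g - 0.3 * (z - 3.5) + lc$lc22),
    y2 = p$tt * ((-y2 + f2) / p$tau2),
    g  = p$tt * (-0.01 * (g - 0.1 * x1) + lc$lc12)
  )
}

#' One deterministic Heun step of the field
#'
#' Predictor-corrector (Heun) update with the coupling inputs (global
#' delayed and local Heaviside terms) evaluated once per step from the
#' state at the beginning of the step, as in standard delayed neural-field
#' integrators. The history buffer, when given, is advanced once.
#'
#' @param state a `sem_state`.
#' @param params a `sem_parameters`.
#' @param conn a `sparse_connectome` or `NULL`.
#' @param kernel a `local_kernel` or `NULL`.
#' @param history a `history_buffer` or `NULL` (required when `conn` is
#'   given).
#' @param dt step size in ms (> 0).
#' @return the updated `sem_state`.
#' @export
heun_step <- function(state, params, conn = NULL, kernel = NULL,
                      history = NULL, dt = 0.1) {
  if (!(dt > 0)) stop("dt must be > 0")
  n <- length(state$x1)
  glob <- if (is.null(conn)) numeric(n) else {
    if (is.null(history)) stop("global coupling requires a history buffer")
    compute_global_coupling(history, conn, state$x1,
                            params$k * params$gamma_glob, dt)
  }
  lc <- compute_local_coupling(state$x1, state$x2, kernel, params)
  d1 <- sem_derivatives(state, params, glob, lc)
  pred <- state
  for (f in names(d1)) pred[[f]] <- state[[f]] + dt * d1[[f]]
  d2 <- sem_derivatives(pred, params, glob, lc)
  out <- state
  for (f in names(d1)) out[[f]] <- state[[f]] + dt * 0.5 * (d1[[f]] + d2[[f]])
  if (!all(is.finite(out$x1)))
    stop("integration diverged (non-finite state); reduce dt or coupling")
  out$time <- state$time + dt
  if (!is.null(history)) history_write(history, out$x1)
  out
}

#' Run the field simulation
#'
#' Integrates the spatial Epileptor over `duration` ms with the compiled
#' core (deterministic Heun at fixed `dt`), recording every
#' `monitor_stride` steps. The recording also tracks the full-resolution
#' per-node running maxima of `x1` and `x2`, used by the rate-conversion
#' calibration checks.
#'
#' @param params a `sem_parameters`; `x0` may be per-node.
#' @param n_nodes number of nodes (inferred from `x0`, `conn` or `kernel`
#'   when omitted).
#' @param conn a `sparse_connectome` or `NULL`.
#' @param kernel a `local_kernel` or `NULL`.
#' @param onset_nodes integer ids initialized in the ictal onset state.
#' @param duration simulated time in ms (>= 0).
#' @param dt step in ms (default 0.1).
#' @param monitor_stride record every this many steps (default 10).
#' @param init optional `sem_state` overriding [initialize_states()].
#' @return an object of class `field_recording`: list with `times` (ms),
#'   six n x T state matrices `x1 ... g`, `x1_max`, `x2_max` (per-node,
#'   full resolution), `dt`, `monitor_stride`, `final` (a `sem_state`).
#' @export
run_field <- function(params, n_nodes = NULL, conn = NULL, kernel = NULL,
                      onset_nodes = integer(0), duration = 1000, dt = 0.1,
                      monitor_stride = 10L, init = NULL) {
  stopifnot(inherits(params, "sem_parameters"), dt > 0, duration >= 0,
            monitor_stride >= 1)
  if (is.null(n_nodes)) {
    n_nodes <- if (!is.null(conn)) nrow(conn$weights)
    else if (!is.null(kernel)) nrow(kernel$K)
    else length(params$x0)
  }
  n_nodes <- as.integer(n_nodes)
  if (!is.null(conn) && nrow(conn$weights) != n_nodes)
    stop("connectome size does not match n_nodes")
  if (!is.null(kernel) && nrow(kernel$K) != n_nodes)
    stop("kernel size does not match n_nodes")
  x0 <- rep_len(params$x0, n_nodes)
  state <- if (is.null(init)) initialize_states(n_nodes, onset_nodes) else init

  if (is.null(conn)) {
    ei <- integer(0); ej <- integer(0); ew <- numeric(0); ed <- integer(0)
  } else {
    tw <- methods::as(conn$weights, "TsparseMatrix")
    ei <- tw@i; ej <- tw@j; ew <- tw@x
    ed <- delay_steps(conn, dt)
  }
  if (is.null(kernel)) {
    kp <- integer(1); ki <- integer(0); kx <- numeric(0)
  } else {
    K <- kernel$K
    kp <- K@p; ki <- K@i; kx <- K@x
  }
  n_steps <- as.integer(round(duration / dt))
  res <- sem_run_cpp(sem_state_matrix(state), x0, sem_par_vector(params),
                     ei, ej, ew, ed, kp, ki, kx,
                     dt, n_steps, as.integer(monitor_stride))
  final <- structure(list(x1 = res$final[1, ], y1 = res$final[2, ],
                          z = res$final[3, ], x2 = res$final[4, ],
                          y2 = res$final[5, ], g = res$final[6, ],
                          time = state$time + n_steps * dt),
                     class = "sem_state")
  structure(list(
    times = state$time + res$sample_steps * dt,
    x1 = res$x1, y1 = res$y1, z = res$z,
    x2 = res$x2, y2 = res$y2, g = res$g,
    x1_max = res$x1_max, x2_max = res$x2_max,
    dt = dt, monitor_stride = as.integer(monitor_stride),
    final = final
  ), class = "field_recording")
}

#' @export
print.field_recording <- function(x, ...) {
  cat("<field_recording> ", nrow(x$x1), " nodes x ", length(x$times),
      " samples (dt ", x$dt, " ms, stride ", x$monitor_stride, ")\n", sep = "")
  invisible(x)
}

#' Locate an uncoupled single-node equilibrium
#'
#' Damped Newton iteration (finite-difference Jacobian) on the six-state
#' right-hand side of one uncoupled node. The excitability `x0` selects the
#' equilibrium; for sufficiently negative `x0` (below about -2.06) the
#' located point is the interictal rest state.
#'
#' @param params a `sem_parameters`.
#' @param x0 scalar excitability for the node.
#' @param guess starting 6-vector `(x1, y1, z, x2, y2, g)`; defaults to the
#'   printed rest state.
#' @param tol residual norm tolerance (default 1e-12).
#' @param max_iter maximum Newton iterations.
#' @return named 6-vector at the root, with attribute `residual`.
#' @export
find_fixed_point <- function(params, x0, guess = SEM_REST_STATE,
                             tol = 1e-12, max_iter = 200L) {
  p <- params; p$x0 <- x0
  fn <- function(s) {
    st <- structure(list(x1 = s[1], y1 = s[2], z = s[3],
                         x2 = s[4], y2 = s[5], g = s[6]),
                    class = "sem_state")
    unlist(sem_derivatives(st, p), use.names = FALSE)
  }
  s <- as.numeric(guess)
  for (it in seq_len(max_iter)) {
    r <- fn(s)
    if (sqrt(sum(r^2)) < tol) break
    J <- matrix(0, 6, 6)
    hstep <- pmax(1e-7, abs(s) * 1e-7)
    for (j in 1:6) {
      sp <- s; sm <- s
      sp[j] <- sp[j] + hstep[j]; sm[j] <- sm[j] - hstep[j]
      J[, j] <- (fn(sp) - fn(sm)) / (2 * hstep[j])
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in fixed-point search")
    lambda <- 1
    repeat {
      s_new <- s - lambda * step
      if (sqrt(sum(fn(s_new)^2)) < sqrt(sum(r^2)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    s <- s_new
  }
  r <- fn(s)
  if (sqrt(sum(r^2)) >= 1e-10)
    stop("fixed-point search did not converge (residual ",
         format(sqrt(sum(r^2))), ")")
  names(s) <- c("x1", "y1", "z", "x2", "y2", "g")
  attr(s, "residual") <- sqrt(sum(r^2))
  s
}
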