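#' Calibrated field-to-rate conversion constants
#'
#' Offsets, gains and time step of the rectified linear transformation
#' that converts the Epileptor state variables into per-step Poisson spike
#' parameters. The defaults are the calibrated values
#' `o_x1 = 2`, `o_x2 = 0.5`, `g_x1 = 0.375`, `g_x2 = 1.25`, `dt = 0.1` ms,
#' chosen so that at least one spike is generated per spike-and-wave
#' complex and the rapid-discharge contribution peaks at about half the
#' SWE contribution.
#'
#' @param o_x1,o_x2 conversion offsets.
#' @param g_x1,g_x2 conversion gains (>= 0).
#' @param dt simulation step in ms (> 0), identical on both sides of the
#'   co-simulation.
#' @return an object of class `conversion_params`.
#' @export
conversion_params <- function(o_x1 = 2, o_x2 = 0.5,
                              g_x1 = 0.375, g_x2 = 1.25, dt = 0.1) {
  stopifnot(g_x1 >= 0, g_x2 >= 0, dt > 0)
  structure(list(o_x1 = o_x1, o_x2 = o_x2, g_x1 = g_x1, g_x2 = g_x2,
                 dt = dt), class = "conversion_params")
}

#' Rectified rate conversions of the fast and SWE variables
#'
#' `p_x1 = max(0, (x1 + o_x1) * g_x1 * dt)` and
#' `p_x2 = max(0, (x2 + o_x2) * g_x2 * dt)`: ReLU-like transformations
#' producing the per-step contributions of the rapid-discharge and
#' spike-and-wave components. At the interictal rest state
#' (`x1 = -1.5`, `x2 = -0.9`) the SWE contribution is exactly zero.
#'
#' @param x1,x2 state values (vectorized).
#' @param conv a `conversion_params`.
#' @return nonnegative per-step expected spike count(s).
#' @export
rate_from_x1 <- function(x1, conv = conversion_params()) {
  if (any(!is.finite(x1))) stop("x1 must be finite")
  pmax(0, (x1 + conv$o_x1) * conv$g_x1 * conv$dt)
}

#' @rdname rate_from_x1
#' @export
rate_from_x2 <- function(x2, conv = conversion_params()) {
  if (any(!is.finite(x2))) stop("x2 must be finite")
  pmax(0, (x2 + conv$o_x2) * conv$g_x2 * conv$dt)
}

#' Per-step Poisson spike parameter
#'
#' `lambda = p_x1 + p_x2`, the expected spike count of one step for one
#' device.
#'
#' @param p_x1,p_x2 nonnegative rectified contributions.
#' @return `lambda`, same length as the inputs.
#' @export
spike_parameter <- function(p_x1, p_x2) {
  if (any(p_x1 < 0) || any(p_x2 < 0))
    stop("rate contributions must be nonnegative")
  p_x1 + p_x2
}

#' Build the per-step rate message
#'
#' One Poisson parameter per CA1 vertex, computed from that vertex's `x1`
#' and `x2` and ordered by the device-creation order (ascending CA1 vertex
#' id), the ordering contract of the exchange.
#'
#' @param state a `sem_state` covering all mesh vertices.
#' @param dev_order integer vector of CA1 vertex ids (the device order).
#' @param conv a `conversion_params`.
#' @param step step index attached to the message.
#' @return an object of class `rate_message`: list with `step` and
#'   `lambda` (length `length(dev_order)`).
#' @export
make_rate_message <- function(state, dev_order, conv = conversion_params(),
                              step = 0L) {
  n <- length(state$x1)
  if (length(dev_order) == 0L) stop("empty device order")
  if (any(dev_order < 1L) || any(dev_order > n))
    stop("device order references vertices missing from the field state")
  lam <- spike_parameter(rate_from_x1(state$x1[dev_order], conv),
                         rate_from_x2(state$x2[dev_order], conv))
  structure(list(step = as.integer(step), lambda = lam),
            class = "rate_message")
}

# ---- transports -----------------------------------------------------------

#' Message transports for the lockstep exchange
#'
#' The exchange contract is transport-agnostic: the in-process transport
#' hands the numeric vector over unchanged, while the serialized transport
#' round-trips every message through its full-precision text encoding
#' (as a message-passing deployment would). Both must produce identical
#' results under the same seed.
#'
#' @return a transport object with a `send` function `function(lambda)`
#'   returning the delivered vector.
#' @export
transport_inprocess <- function() {
  structure(list(send = function(lambda) lambda,
                 name = "inprocess"), class = "cosim_transport")
}

#' @rdname transport_inprocess
#' @export
transport_serialized <- function() {
  structure(list(
    send = function(lambda) {
      as.numeric(strsplit(paste(sprintf("%.17g", lambda), collapse = ","),
                          ",", fixed = TRUE)[[1]])
    },
    name = "serialized"), class = "cosim_transport")
}

#' Run the one-directional lockstep co-simulation
#'
#' Both simulators advance with the same step `dt`. Per step: the field
#' advances one Heun step; a rate message (one Poisson parameter per CA1
#' vertex, device order) is produced and transported; the devices draw
#' Poisson counts; device spikes are relayed to their subpopulations
#' through static synapses and the spiking network advances one step;
#' the per-vertex spike counts are logged as the feedback message but, by
#' default, NOT fed back - the field influences CA1 spiking activity, not
#' vice versa. A feedback hook is present for future bidirectional use.
#'
#' @param params a `sem_parameters` for the field.
#' @param mesh a `surface_model` (defines the node set; CA1 vertices carry
#'   devices).
#' @param conn,kernel optional `sparse_connectome` / `local_kernel`.
#' @param onset_nodes onset-zone vertex ids.
#' @param net a `spiking_network`, or `NULL` to run the field side alone
#'   (the messages are still produced and logged).
#' @param assignment a `vertex_assignment` (required when `net` is given).
#' @param conv a `conversion_params`; its `dt` must equal `dt`.
#' @param duration simulated time (ms).
#' @param dt shared step (ms).
#' @param seed integer seed (device stream split off via [seed_stream()]).
#' @param monitor_stride field recording stride (steps).
#' @param relay_weight,relay_delay static relay synapse parameters.
#' @param connectivity logical; recurrent SNN connectivity on/off.
#' @param transport a transport from [transport_inprocess()] (default) or
#'   [transport_serialized()].
#' @param feedback_gain additive feedback of per-vertex spike counts onto
#'   the `x1` equation of the matching vertices; 0 (default) disables the
#'   channel, mirroring the one-directional design.
#' @return list with `field` (a `field_recording`), `spikes` (a
#'   `spike_record` or `NULL`), `rate_log` (`n_steps` x `n_dev`),
#'   `count_log` (`n_steps` x `n_dev`), `device_order`.
#' @export
run_cosimulation <- function(params, mesh, conn = NULL, kernel = NULL,
                             onset_nodes = integer(0), net = NULL,
                             assignment = NULL, conv = conversion_params(),
                             duration = 1000, dt = 0.1, seed = 1L,
                             monitor_stride = 10L, relay_weight = 20,
                             relay_delay = 1, connectivity = TRUE,
                             transport = transport_inprocess(),
                             feedback_gain = 0) {
  stopifnot(inherits(params, "sem_parameters"),
            inherits(mesh, "surface_model"),
            inherits(conv, "conversion_params"))
  if (abs(conv$dt - dt) > 1e-12)
    stop("conversion dt and simulation dt must be identical on both sides")
  n_nodes <- nrow(mesh$vertices)
  dev <- device_order(mesh)
  ndev <- length(dev)
  if (ndev == 0L) stop("mesh has no CA1 vertices to attach devices to")
  if (!is.null(net) && is.null(assignment))
    stop("an assignment is required to drive a spiking network")

  params$x0 <- rep_len(params$x0, n_nodes)
  state <- initialize_states(n_nodes, onset_nodes)
  max_delay <- if (is.null(conn)) 0L else max(delay_steps(conn, dt), 0L)
  hist <- history_buffer(state$x1, max_delay + 1L)

  n_steps <- as.integer(round(duration / dt))
  stride <- as.integer(monitor_stride)
  n_samples <- n_steps %/% stride + 1L
  rec <- list(times = numeric(n_samples),
              x1 = matrix(0, n_nodes, n_samples), y1 = matrix(0, n_nodes, n_samples),
              z = matrix(0, n_nodes, n_samples), x2 = matrix(0, n_nodes, n_samples),
              y2 = matrix(0, n_nodes, n_samples), g = matrix(0, n_nodes, n_samples))
  put <- function(i, s) {
    rec$times[i] <<- s$time
    rec$x1[, i] <<- s$x1; rec$y1[, i] <<- s$y1; rec$z[, i] <<- s$z
    rec$x2[, i] <<- s$x2; rec$y2[, i] <<- s$y2; rec$g[, i] <<- s$g
  }
  put(1L, state)
  x1max <- state$x1; x2max <- state$x2

  rate_log <- matrix(0, n_steps, ndev)
  count_log <- matrix(0L, n_steps, ndev)
  devcount_log <- matrix(0L, n_steps, ndev)

  eng <- NULL; subpops <- NULL; neuron_dev <- NULL; rsteps <- 0L
  ev_neuron <- vector("list", n_steps)
  if (!is.null(net)) {
    rsteps <- max(1L, as.integer(round(relay_delay / dt)))
    eng <- snn_engine(net, dt, connectivity, extra_delay_steps = rsteps)
    subpops <- assignment$vertex_to_neurons[dev]
    if (any(lengths(subpops) == 0L))
      stop("every device (CA1 vertex) needs a non-empty subpopulation; ",
           "run relabel_vertices() first")
    neuron_dev <- rep(NA_integer_, length(net$cloud$ids))
    for (k in seq_len(ndev)) neuron_dev[subpops[[k]]] <- k
  }
  set.seed(seed_stream(seed, 3))
  fb <- numeric(n_nodes)

  for (s in seq_len(n_steps)) {
    # field side (feedback input is zero unless the hook is enabled)
    glob <- if (is.null(conn)) numeric(n_nodes) else
      compute_global_coupling(hist, conn, state$x1,
                              params$k * params$gamma_glob, dt)
    if (feedback_gain != 0) glob <- glob + fb
    lc <- compute_local_coupling(state$x1, state$x2, kernel, params)
    d1 <- sem_derivatives(state, params, glob, lc)
    pred <- state
    for (f in names(d1)) pred[[f]] <- state[[f]] + dt * d1[[f]]
    d2 <- sem_derivatives(pred, params, glob, lc)
    for (f in names(d1)) state[[f]] <- state[[f]] + dt * 0.5 * (d1[[f]] + d2[[f]])
    state$time <- state$time + dt
    history_write(hist, state$x1)
    x1max <- pmax(x1max, state$x1); x2max <- pmax(x2max, state$x2)

    # rate message, transported to the spiking side
    msg <- make_rate_message(state, dev, conv, step = s)
    lam <- transport$send(msg$lambda)
    rate_log[s, ] <- lam

    if (!is.null(eng)) {
      cnt <- poisson_device_step(lam)
      devcount_log[s, ] <- cnt
      ext <- NULL
      hot <- which(cnt > 0L)
      if (length(hot)) {
        posts <- unlist(subpops[hot], use.names = FALSE)
        wts <- rep(relay_weight * cnt[hot], times = lengths(subpops[hot]))
        ext <- data.frame(neuron = posts, weight = wts, delay_steps = rsteps)
      }
      sp <- step_network(eng, external = ext)
      if (length(sp)) {
        ev_neuron[[s]] <- sp
        dv <- neuron_dev[sp]; dv <- dv[!is.na(dv)]
        if (length(dv)) count_log[s, ] <- count_log[s, ] +
            tabulate(dv, nbins = ndev)
      }
      # feedback message: logged, and applied only if the hook is enabled
      if (feedback_gain != 0) {
        fb[] <- 0
        fb[dev] <- feedback_gain * count_log[s, ]
      }
    }
    if (s %% stride == 0L) put(s %/% stride + 1L, state)
  }

  field <- structure(list(
    times = rec$times, x1 = rec$x1, y1 = rec$y1, z = rec$z,
    x2 = rec$x2, y2 = rec$y2, g = rec$g,
    x1_max = x1max, x2_max = x2max, dt = dt, monitor_stride = stride,
    final = state), class = "field_recording")

  spikes <- NULL
  if (!is.null(eng)) {
    lens <- lengths(ev_neuron)
    spikes <- structure(list(
      events = data.frame(neuron = as.integer(unlist(ev_neuron, use.names = FALSE)),
                          time = rep(seq_len(n_steps) * dt, lens)),
      counts = count_log, device_counts = devcount_log,
      device_order = dev, dt = dt, duration = n_steps * dt),
      class = "spike_record")
  }
  list(field = field, spikes = spikes, rate_log = rate_log,
       count_log = count_log, device_order = dev)
}
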