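#' Conductance-based bursting neuron parameters (Hill-Tononi style)
#'
#' Constants of the point-neuron model used for CA1 cells: a
#' conductance-based neuron with Na/K leaks, a dynamic firing threshold, a
#' depolarizing spike shape followed by a `tau_spike` repolarization, and
#' four intrinsic currents - persistent sodium (`I_NaP`),
#' sodium-activated potassium adaptation (`I_KNa`, spike-triggered),
#' low-threshold calcium (`I_T`) and hyperpolarization-activated cation
#' (`I_h`) - whose interplay produces the characteristic bursting of CA1
#' pyramidal cells. Synaptic input enters through a normalized
#' dual-exponential AMPA conductance. Voltages in mV, times in ms;
#' conductances are expressed relative to the membrane time constant as in
#' the Hill-Tononi formulation.
#'
#' @param E_Na,E_K,g_NaL,g_KL,tau_m leak reversal potentials, leak
#'   conductances and membrane time constant.
#' @param theta_eq,tau_theta equilibrium and relaxation time of the dynamic
#'   threshold.
#' @param tau_spike,t_ref spike repolarization time constant and absolute
#'   refractory period.
#' @param g_peak_AMPA,E_AMPA,tau_rise,tau_decay AMPA channel.
#' @param g_NaP persistent sodium peak conductance.
#' @param g_KNa,tau_D,D_influx,D_eq,D_half,D_exp adaptation current: the
#'   activity variable `D` jumps by `D_influx` at each spike and relaxes to
#'   `D_eq` with `tau_D`; activation is `D^D_exp / (D^D_exp + D_half^D_exp)`.
#' @param g_T,E_T low-threshold calcium current.
#' @param g_h,E_h anomalous rectifier.
#' @param V_init,theta_init initial membrane potential and threshold.
#' @return an object of class `ht_parameters`.
#' @export
ht_parameters <- function(E_Na = 30, E_K = -90, g_NaL = 0.2, g_KL = 1.0,
                          tau_m = 16, theta_eq = -51, tau_theta = 2,
                          tau_spike = 1.75, t_ref = 2,
                          g_peak_AMPA = 0.1, E_AMPA = 0,
                          tau_rise = 0.5, tau_decay = 2.4,
                          g_NaP = 1.0, g_KNa = 1.0, tau_D = 1250,
                          D_influx = 0.025, D_eq = 0.001, D_half = 0.25,
                          D_exp = 3.5, g_T = 1.0, E_T = 0,
                          g_h = 1.0, E_h = -40,
                          V_init = -70, theta_init = -51) {
  stopifnot(tau_m > 0, tau_theta > 0, tau_spike > 0, t_ref >= 0,
            tau_rise > 0, tau_decay > tau_rise, tau_D > 0)
  structure(as.list(environment()), class = "ht_parameters")
}

#' Short-term plasticity (Tsodyks-Markram) synapse parameters
#'
#' Each connection carries a utilization `U`, a recovery time constant
#' `tau_rec` (depression) and a facilitation time constant `tau_fac`
#' (0 disables facilitation). The effective weight of the k-th presynaptic
#' spike is `weight * u_k * x_k` with the standard resource/utilization
#' recursion.
#'
#' @param U release probability parameter, in (0, 1].
#' @param tau_rec,tau_fac recovery and facilitation time constants (ms).
#' @param weight absolute synaptic strength (AMPA conductance increment).
#' @param delay0 fixed synaptic latency (ms) added to the conduction term.
#' @param conduction axonal conduction speed (mm/ms) converting connection
#'   length into delay.
#' @return an object of class `tm_parameters`.
#' @export
tm_parameters <- function(U = 0.5, tau_rec = 800, tau_fac = 0,
                          weight = 8, delay0 = 1, conduction = 0.3) {
  stopifnot(U > 0, U <= 1, tau_rec >= 0, tau_fac >= 0, weight >= 0,
            delay0 >= 0, conduction > 0)
  structure(list(U = U, tau_rec = tau_rec, tau_fac = tau_fac,
                 weight = weight, delay0 = delay0, conduction = conduction),
            class = "tm_parameters")
}

#' Distance-dependent synthetic CA1 connectivity
#'
#' Emulates a morpho-anatomical connection strategy at test scale:
#' connection probability decays exponentially with 3D somatic distance,
#' normalized per source neuron so the expected out-degree equals
#' `mean_degree`. No self-connections.
#'
#' @param cloud a `neuron_cloud`.
#' @param mean_degree target mean out-degree (>= 0).
#' @param length_scale decay length of the connection probability (mm).
#' @param seed integer seed.
#' @param syn a `tm_parameters` applied to every connection.
#' @param neuron_params an `ht_parameters` shared by all neurons.
#' @return an object of class `spiking_network`: list with `cloud`,
#'   `neuron_params` and `connections` (data frame `pre`, `post`, `weight`,
#'   `U`, `tau_rec`, `tau_fac`, `delay`, `length`).
#' @export
build_synthetic_connectivity <- function(cloud, mean_degree = 20,
                                         length_scale = 1.5, seed = 1L,
                                         syn = tm_parameters(),
                                         neuron_params = ht_parameters()) {
  stopifnot(inherits(cloud, "neuron_cloud"), mean_degree >= 0,
            length_scale > 0)
  n <- length(cloud$ids)
  pos <- cloud$positions
  set.seed(as.integer(seed))
  pre <- list(); post <- list(); len <- list()
  chunk <- max(1L, min(n, as.integer(2^22 / n)))
  b <- 0L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- sqrt(outer(pos[s:e, 1], pos[, 1], "-")^2 +
              outer(pos[s:e, 2], pos[, 2], "-")^2 +
              outer(pos[s:e, 3], pos[, 3], "-")^2)
    kern <- exp(-d / length_scale)
    kern[cbind(seq_len(e - s + 1L), s:e)] <- 0  # no self-loops
    prob <- mean_degree * kern / pmax(rowSums(kern), .Machine$double.eps)
    prob <- pmin(prob, 1)
    hit <- which(matrix(runif(length(prob)) < prob, nrow(prob), ncol(prob)),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      b <- b + 1L
      pre[[b]] <- hit[, 1] + (s - 1L)
      post[[b]] <- hit[, 2]
      len[[b]] <- d[hit]
    }
  }
  pre <- as.integer(unlist(pre)); post <- as.integer(unlist(post))
  len <- as.numeric(unlist(len))
  o <- order(pre, post)
  k <- length(o)
  conns <- data.frame(pre = pre[o], post = post[o],
                      weight = rep(syn$weight, k),
                      U = rep(syn$U, k), tau_rec = rep(syn$tau_rec, k),
                      tau_fac = rep(syn$tau_fac, k),
                      delay = rep(syn$delay0, k) + len[o] / syn$conduction,
                      length = len[o])
  structure(list(cloud = cloud, neuron_params = neuron_params,
                 connections = conns),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat("<spiking_network> ", length(x$cloud$ids), " neurons, ",
      nrow(x$connections), " connections\n", sep = "")
  invisible(x)
}

#' Downscale a spiking network by random neuron sampling
#'
#' Uniformly samples `n_target` neurons without replacement and keeps
#' exactly the connections with both endpoints retained (the induced
#' subgraph). Ids are re-indexed by order-preserving compaction; the
#' old-to-new mapping is returned as the `mapping` element (and attribute).
#'
#' @param net a `spiking_network`.
#' @param n_target number of neurons to keep, in `[1, n]`.
#' @param seed integer seed.
#' @return the downscaled `spiking_network` with an integer `mapping`
#'   vector (`mapping[old_id] = new_id`, `NA` for dropped neurons).
#' @export
downscale <- function(net, n_target, seed = 1L) {
  stopifnot(inherits(net, "spiking_network"))
  n <- length(net$cloud$ids)
  n_target <- as.integer(n_target)
  if (is.na(n_target) || n_target < 1L || n_target > n)
    stop("n_target must be in [1, ", n, "]")
  set.seed(as.integer(seed))
  keep <- sort(sample.int(n, n_target))
  mapping <- rep(NA_integer_, n)
  mapping[keep] <- seq_len(n_target)

  cloud <- net$cloud
  cloud$positions <- cloud$positions[keep, , drop = FALSE]
  cloud$apd <- cloud$apd[keep, , drop = FALSE]
  cloud$ids <- seq_len(n_target)

  cc <- net$connections
  ok <- !is.na(mapping[cc$pre]) & !is.na(mapping[cc$post])
  cc <- cc[ok, , drop = FALSE]
  cc$pre <- mapping[cc$pre]
  cc$post <- mapping[cc$post]
  rownames(cc) <- NULL

  out <- structure(list(cloud = cloud, neuron_params = net$neuron_params,
                        connections = cc, mapping = mapping),
                   class = "spiking_network")
  attr(out, "mapping") <- mapping
  out
}

#' Integrity statistics of a spiking network
#'
#' The three distribution families used to assess a downscaled network
#' against its parent: neuronal density over spatial (AP-axis) bins, in-
#' and out-degree distributions, and the connection-length distribution.
#'
#' @param net a non-empty `spiking_network`.
#' @param ap_breaks,length_breaks number of bins (or break vectors) for the
#'   density and length histograms.
#' @return an object of class `network_stats`: list with `density`,
#'   `lengths` (both `hist` objects), `indegree`, `outdegree` (named count
#'   vectors over degrees 0..max) and `moments`.
#' @export
integrity_stats <- function(net, ap_breaks = 20, length_breaks = 20) {
  stopifnot(inherits(net, "spiking_network"))
  n <- length(net$cloud$ids)
  if (n == 0L) stop("empty network")
  cc <- net$connections
  dens <- hist(net$cloud$apd[, "ap"], breaks = ap_breaks, plot = FALSE)
  indeg <- tabulate(cc$post, nbins = n)
  outdeg <- tabulate(cc$pre, nbins = n)
  deg_tab <- function(d) {
    t <- table(factor(d, levels = 0:max(d, 0)))
    out <- as.integer(t); names(out) <- names(t); out
  }
  lens <- if (nrow(cc)) hist(cc$length, breaks = length_breaks, plot = FALSE)
          else NULL
  structure(list(
    density = dens,
    indegree = deg_tab(indeg),
    outdegree = deg_tab(outdeg),
    lengths = lens,
    moments = list(n_neurons = n, n_connections = nrow(cc),
                   mean_indegree = mean(indeg), mean_outdegree = mean(outdeg),
                   mean_length = if (nrow(cc)) mean(cc$length) else NA_real_)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  m <- x$moments
  cat("<network_stats> ", m$n_neurons, " neurons, ", m$n_connections,
      " connections, mean degree ", signif(m$mean_outdegree, 4), "\n", sep = "")
  invisible(x)
}

#' Per-step Poisson spike generation
#'
#' Draws the spike count of one step for each device from
#' `Poisson(p)`, `p` being the expected count for that step (the
#' rate-conversion output). Uses the current R random stream.
#'
#' @param p nonnegative expected count(s).
#' @return integer draw(s), same length as `p`.
#' @export
poisson_device_step <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("Poisson parameter must be finite and nonnegative (rectify first)")
  rpois(length(p), p)
}

#' Fan-out relay of device spikes to a subpopulation
#'
#' Every device spike is delivered identically to each neuron of the
#' device's subpopulation through a static (non-plastic) synapse with fixed
#' weight and delay.
#'
#' @param count nonnegative spike count emitted by the device this step.
#' @param subpop integer neuron ids of the subpopulation.
#' @param t device spike time (ms).
#' @param delay static synaptic delay (ms).
#' @param weight static synaptic weight.
#' @return data frame of synaptic events (`neuron`, `time`, `weight`);
#'   `count * length(subpop)` rows.
#' @export
relay_spikes <- function(count, subpop, t, delay = 1, weight = 1) {
  if (length(count) != 1L || !is.finite(count) || count < 0)
    stop("count must be a single nonnegative number")
  if (length(subpop) == 0L) stop("unknown or empty subpopulation")
  k <- as.integer(count)
  data.frame(neuron = rep(as.integer(subpop), times = k),
             time = rep(t + delay, length(subpop) * k),
             weight = rep(weight, length(subpop) * k))
}

# ---- simulation engine ----------------------------------------------------

# Mutable engine state for the spiking network (environment semantics so
# step_network() advances in place).
snn_engine <- function(net, dt = 0.1, connectivity = TRUE,
                       extra_delay_steps = 0L) {
  p <- net$neuron_params
  n <- length(net$cloud$ids)
  cc <- if (connectivity) net$connections else net$connections[0, ]
  dsteps <- if (nrow(cc)) as.integer(floor(cc$delay / dt + 0.5)) else integer(0)
  dsteps <- pmax(dsteps, 1L)  # events land at the next step at the earliest
  depth <- max(2L, if (length(dsteps)) max(dsteps) + 1L else 2L,
               as.integer(extra_delay_steps) + 1L)

  e <- new.env(parent = emptyenv())
  e$net <- net; e$p <- p; e$n <- n; e$dt <- dt
  e$V <- rep(p$V_init, n)
  e$theta <- rep(p$theta_init, n)
  e$ref <- integer(n)
  e$ref_steps <- max(1L, as.integer(round(p$t_ref / dt)))
  e$h_T <- 1 / (1 + exp((p$V_init + 83) / 4))
  e$m_h <- 1 / (1 + exp((p$V_init + 75) / 5.5))
  e$D <- rep(p$D_eq, n)
  e$gA_d <- numeric(n); e$gA_r <- numeric(n)
  tp <- (p$tau_decay * p$tau_rise / (p$tau_decay - p$tau_rise)) *
    log(p$tau_decay / p$tau_rise)
  e$syn_norm <- 1 / (exp(-tp / p$tau_decay) - exp(-tp / p$tau_rise))
  e$dec_d <- exp(-dt / p$tau_decay); e$dec_r <- exp(-dt / p$tau_rise)
  e$buf <- matrix(0, n, depth); e$depth <- depth; e$slot <- 1L
  e$step <- 0L
  # connection state (Tsodyks-Markram)
  e$cc <- cc
  e$dsteps <- dsteps
  e$adj <- if (nrow(cc)) split(seq_len(nrow(cc)), cc$pre) else list()
  e$tm_u <- cc$U                     # utilization just after last release
  e$tm_x <- rep(1, nrow(cc))         # resources just after last release
  e$tm_last <- rep(-Inf, nrow(cc))   # time of last presynaptic spike
  class(e) <- "snn_engine"
  e
}

# schedule conductance increments `w` onto neurons `post` after
# `delay_steps` (>= 1) steps
schedule_increments <- function(e, post, w, delay_steps) {
  if (length(post) == 0L) return(invisible(e))
  if (any(delay_steps < 1L) || any(delay_steps > e$depth - 1L))
    stop("synaptic delay outside buffer depth")
  slot <- ((e$slot - 1L + delay_steps) %% e$depth) + 1L
  key <- (slot - 1L) * e$n + post
  agg <- rowsum(w, key)
  keys <- as.integer(rownames(agg))
  e$buf[keys] <- e$buf[keys] + agg[, 1]
  invisible(e)
}

#' Advance the spiking network by one time step
#'
#' Explicit synchronous update at fixed `dt`: due synaptic events are
#' collected from the delivery buffer, membrane and intrinsic-current
#' states are advanced, threshold crossings emit spikes, and each emitted
#' spike updates the short-term-plasticity state of its outgoing
#' connections and schedules the depressed/facilitated increments at the
#' connection delays (rounded to steps, ties up, minimum one step).
#'
#' @param e an engine created by `snn_engine()` (internal; [run_snn()] is
#'   the high-level driver).
#' @param external optional data frame of external synaptic events to
#'   deliver, columns `neuron`, `weight`, `delay_steps`.
#' @param inj per-neuron injected current (normalized units), recycled.
#' @return integer ids of neurons that spiked during this step.
#' @export
step_network <- function(e, external = NULL, inj = 0) {
  p <- e$p; dt <- e$dt; n <- e$n
  if (!is.null(external) && nrow(external)) {
    if (any(external$neuron < 1L) || any(external$neuron > n))
      stop("unknown subpopulation neuron id in external events")
    schedule_increments(e, as.integer(external$neuron), external$weight,
                        as.integer(external$delay_steps))
  }
  # deliver due increments
  inc <- e$buf[, e$slot]
  if (any(inc != 0)) {
    e$buf[, e$slot] <- 0
    e$gA_d <- e$gA_d + inc * e$syn_norm
    e$gA_r <- e$gA_r + inc * e$syn_norm
  }
  # channel decays (exact exponentials)
  e$gA_d <- e$gA_d * e$dec_d
  e$gA_r <- e$gA_r * e$dec_r
  V <- e$V

  # intrinsic currents (normalized by tau_m as in the HT formulation)
  mNaP <- 1 / (1 + exp(-(V + 55.7) / 7.7))
  I_NaP <- -p$g_NaP * mNaP^3 * (V - p$E_Na)
  mKNa <- e$D^p$D_exp / (e$D^p$D_exp + p$D_half^p$D_exp)
  I_KNa <- -p$g_KNa * mKNa * (V - p$E_K)
  mT <- 1 / (1 + exp(-(V + 59) / 6.2))
  I_T <- -p$g_T * mT^2 * e$h_T * (V - p$E_T)
  I_h <- -p$g_h * e$m_h * (V - p$E_h)
  gA <- pmax(e$gA_d - e$gA_r, 0)
  I_syn <- -p$g_peak_AMPA * gA * (V - p$E_AMPA)

  dV <- (-p$g_NaL * (V - p$E_Na) - p$g_KL * (V - p$E_K) +
           I_NaP + I_KNa + I_T + I_h + I_syn + inj) / p$tau_m
  refr <- e$ref > 0L
  Vn <- V + dt * dV
  # spike shape: refractory cells repolarize toward E_K with tau_spike
  Vn[refr] <- V[refr] + dt * (-(V[refr] - p$E_K) / p$tau_spike)
  if (any(!is.finite(Vn))) stop("non-finite membrane state")

  # gating dynamics
  hinf <- 1 / (1 + exp((V + 83) / 4))
  tauh <- (30.8 + (211.4 + exp((V + 115.2) / 5)) /
             (1 + exp((V + 86) / 3.2))) / 3.74
  e$h_T <- e$h_T + dt * (hinf - e$h_T) / tauh
  minf_h <- 1 / (1 + exp((V + 75) / 5.5))
  tau_mh <- 1 / (exp(-14.59 - 0.086 * V) + exp(-1.87 + 0.0701 * V))
  e$m_h <- e$m_h + dt * (minf_h - e$m_h) / tau_mh
  e$D <- e$D + dt * (-(e$D - p$D_eq) / p$tau_D)
  e$theta <- e$theta + dt * (-(e$theta - p$theta_eq) / p$tau_theta)

  # threshold crossings
  sp <- which(!refr & Vn >= e$theta)
  if (length(sp)) {
    Vn[sp] <- p$E_Na             # spike peak
    e$theta[sp] <- p$E_Na        # relative refractoriness
    e$ref[sp] <- e$ref_steps
    e$D[sp] <- e$D[sp] + p$D_influx
    t_now <- e$step * dt
    for (i in sp) {
      ks <- e$adj[[as.character(i)]]
      if (is.null(ks)) next
      dtl <- t_now - e$tm_last[ks]
      u_prev <- e$tm_u[ks]; x_prev <- e$tm_x[ks]
      U <- e$cc$U[ks]
      fac <- ifelse(e$cc$tau_fac[ks] > 0, exp(-dtl / e$cc$tau_fac[ks]), 0)
      u_new <- U + u_prev * (1 - U) * fac
      x_rec <- 1 - (1 - x_prev) * exp(-dtl / pmax(e$cc$tau_rec[ks],
                                                  .Machine$double.eps))
      w_eff <- e$cc$weight[ks] * u_new * x_rec
      e$tm_u[ks] <- u_new
      e$tm_x[ks] <- x_rec * (1 - u_new)
      e$tm_last[ks] <- t_now
      schedule_increments(e, e$cc$post[ks], w_eff, e$dsteps[ks])
    }
  }
  e$ref[refr] <- e$ref[refr] - 1L
  e$V <- Vn
  e$slot <- if (e$slot == e$depth) 1L else e$slot + 1L
  e$step <- e$step + 1L
  sp
}

#' Run the spiking network driven by per-vertex rate streams
#'
#' Full simulation loop: at each step the per-vertex devices draw Poisson
#' spike counts from their rate stream, relay them to their subpopulations
#' through static synapses, the network advances one step, and spikes are
#' recorded and counted per vertex (in device order).
#'
#' @param net a `spiking_network`.
#' @param assignment a `vertex_assignment` (with `device_order`); `NULL`
#'   runs the network without devices.
#' @param rates `n_steps` x `n_devices` matrix of per-step Poisson
#'   parameters, columns ordered by `device_order` (or `NULL`).
#' @param duration simulated time (ms); defaults to `nrow(rates) * dt`.
#' @param dt step (ms), default 0.1.
#' @param seed integer seed for the device draws.
#' @param relay_weight,relay_delay static relay synapse weight and delay
#'   (ms).
#' @param connectivity logical; `FALSE` disables recurrent connections
#'   (devices only), the configuration used to verify rate/spike
#'   synchronization.
#' @param inj constant injected current per neuron (recycled).
#' @return an object of class `spike_record`: list with `events`
#'   (data frame `neuron`, `time`), `counts` and `device_counts`
#'   (`n_steps` x `n_devices`, device order), `device_order`, `dt`,
#'   `duration`.
#' @export
run_snn <- function(net, assignment = NULL, rates = NULL, duration = NULL,
                    dt = 0.1, seed = 1L, relay_weight = 20, relay_delay = 1,
                    connectivity = TRUE, inj = 0) {
  stopifnot(inherits(net, "spiking_network"))
  ndev <- 0L; subpops <- list(); neuron_dev <- integer(0)
  if (!is.null(assignment)) {
    dev <- assignment$device_order
    ndev <- length(dev)
    subpops <- assignment$vertex_to_neurons[dev]
    neuron_dev <- rep(NA_integer_, length(net$cloud$ids))
    for (k in seq_len(ndev)) neuron_dev[subpops[[k]]] <- k
  }
  if (!is.null(rates)) {
    rates <- as.matrix(rates)
    if (ncol(rates) != ndev)
      stop("rate stream count (", ncol(rates),
           ") does not match device count (", ndev, ")")
    if (any(!is.finite(rates)) || any(rates < 0))
      stop("rates must be finite and nonnegative")
  }
  n_steps <- if (!is.null(duration)) as.integer(round(duration / dt))
             else if (!is.null(rates)) nrow(rates)
             else stop("either duration or rates must be given")
  if (!is.null(rates) && nrow(rates) < n_steps)
    stop("rates has fewer steps than duration requires")

  rsteps <- max(1L, as.integer(round(relay_delay / dt)))
  e <- snn_engine(net, dt, connectivity, extra_delay_steps = rsteps)
  set.seed(as.integer(seed))

  counts <- matrix(0L, n_steps, ndev)
  devcounts <- matrix(0L, n_steps, ndev)
  ev_neuron <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    ext <- NULL
    if (ndev > 0L && !is.null(rates)) {
      cnt <- poisson_device_step(rates[s, ])
      devcounts[s, ] <- cnt
      hot <- which(cnt > 0L)
      if (length(hot)) {
        posts <- unlist(subpops[hot], use.names = FALSE)
        wts <- rep(relay_weight * cnt[hot],
                   times = lengths(subpops[hot]))
        ext <- data.frame(neuron = posts, weight = wts,
                          delay_steps = rsteps)
      }
    }
    sp <- step_network(e, external = ext, inj = inj)
    if (length(sp)) {
      ev_neuron[[s]] <- sp
      if (ndev > 0L) {
        dv <- neuron_dev[sp]
        dv <- dv[!is.na(dv)]
        if (length(dv)) {
          tb <- tabulate(dv, nbins = ndev)
          counts[s, ] <- counts[s, ] + tb
        }
      }
    }
  }
  lens <- lengths(ev_neuron)
  events <- data.frame(
    neuron = as.integer(unlist(ev_neuron, use.names = FALSE)),
    time = rep(seq_len(n_steps) * dt, lens)
  )
  structure(list(events = events, counts = counts,
                 device_counts = devcounts,
                 device_order = if (ndev) assignment$device_order else integer(0),
                 dt = dt, duration = n_steps * dt),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("<spike_record> ", nrow(x$events), " spikes over ", x$duration,
      " ms, ", ncol(x$counts), " devices\n", sep = "")
  invisible(x)
}
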