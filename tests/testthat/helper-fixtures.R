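# Shared fixtures and independent reference implementations (oracles).
# Oracles deliberately use different data structures and algorithms from
# the package paths they check.

# -- minimal hand-built spiking network ------------------------------------

make_point_net <- function(n = 1, conns = NULL, params = ht_parameters(),
                           positions = NULL) {
  if (is.null(positions)) positions <- matrix(0, n, 3)
  cloud <- structure(list(positions = positions,
                          apd = cbind(ap = positions[, 1], pd = positions[, 2]),
                          ids = seq_len(n)), class = "neuron_cloud")
  if (is.null(conns))
    conns <- data.frame(pre = integer(0), post = integer(0),
                        weight = numeric(0), U = numeric(0),
                        tau_rec = numeric(0), tau_fac = numeric(0),
                        delay = numeric(0), length = numeric(0))
  structure(list(cloud = cloud, neuron_params = params, connections = conns),
            class = "spiking_network")
}

# -- dense full-history field reference ------------------------------------

# Reference integrator: dense weight/delay matrices and a complete stored
# history of x1 (no ring buffer, no sparsity). Same model equations and
# frozen-coupling Heun convention, entirely different data structures.
dense_field_reference <- function(init, params, W, Dsteps, Kdense,
                                  dt, n_steps) {
  n <- length(init$x1)
  S <- rbind(init$x1, init$y1, init$z, init$x2, init$y2, init$g)
  hist_x1 <- matrix(init$x1, n, n_steps + 1)  # column t+1 = x1 at step t
  p <- params
  x0 <- rep_len(p$x0, n)
  deriv <- function(S, glob, lc11, lc12, lc22) {
    x1 <- S[1, ]; y1 <- S[2, ]; z <- S[3, ]
    x2 <- S[4, ]; y2 <- S[5, ]; g <- S[6, ]
    f1 <- ifelse(x1 < 0, (p$a * x1 - p$b) * x1 * x1,
                 (x2 - 0.6 * (z - 4)^2 - p$m) * x1)
    f2 <- ifelse(x2 < -0.25, 0, p$aa * (x2 + 0.25))
    rbind(p$tt * (y1 - f1 - z + p$Iext + glob + lc11),
          p$tt * ((p$c - p$d * x1^2 - y1) / p$tau1),
          p$tt * ((4 * (x1 - x0) - z) / p$tau0),
          p$tt * (-y2 + x2 - x2^3 + p$Iext2 + p$bb * g -
                    0.3 * (z - 3.5) + lc22),
          p$tt * ((-y2 + f2) / p$tau2),
          p$tt * (-0.01 * (g - 0.1 * x1) + lc12))
  }
  nz <- which(W != 0, arr.ind = TRUE)  # dense scan for nonzero pairs
  for (s in seq_len(n_steps)) {
    glob <- numeric(n)
    for (e in seq_len(nrow(nz))) {
      i <- nz[e, 1]; j <- nz[e, 2]
      past <- max(1L, s - Dsteps[i, j])  # history col for step s-1-d
      glob[i] <- glob[i] + W[i, j] * (hist_x1[j, past] - S[1, i])
    }
    glob <- p$k * p$gamma_glob * glob
    lc11 <- p$gamma11 * as.numeric(Kdense %*% as.numeric(S[1, ] >= p$theta11))
    lc12 <- p$gamma12 * as.numeric(Kdense %*% as.numeric(S[1, ] >= p$theta12))
    lc22 <- p$gamma22 * as.numeric(Kdense %*% as.numeric(S[4, ] >= p$theta22))
    d1 <- deriv(S, glob, lc11, lc12, lc22)
    d2 <- deriv(S + dt * d1, glob, lc11, lc12, lc22)
    S <- S + dt * 0.5 * (d1 + d2)
    hist_x1[, s + 1] <- S[1, ]
  }
  S
}

# -- all-pairs shortest path oracle (Floyd-Warshall) ------------------------

floyd_warshall <- function(edges, lengths, n) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    D[i, j] <- min(D[i, j], lengths[k])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# -- Tsodyks-Markram closed-form recursion ---------------------------------

tm_amplitudes <- function(spike_times, U, tau_rec, tau_fac) {
  u <- U; x <- 1; amps <- numeric(length(spike_times))
  last <- -Inf
  for (k in seq_along(spike_times)) {
    dt <- spike_times[k] - last
    fac <- if (tau_fac > 0) exp(-dt / tau_fac) else 0
    u_new <- U + u * (1 - U) * fac
    x_rec <- 1 - (1 - x) * exp(-dt / tau_rec)
    amps[k] <- u_new * x_rec
    x <- x_rec * (1 - u_new)
    u <- u_new
    last <- spike_times[k]
  }
  amps
}

# propagation fixture shared by field tests and acceptance
propagation_fixture <- function() {
  mesh <- generate_synthetic_hippocampus(20, 10)
  kern <- local_kernel(geodesic_distances(mesh, cutoff = 6),
                       sigma = 2, cutoff = 6)
  ca1 <- which(mesh$labels == "CA1")
  patch <- ca1[mesh$apd[ca1, "ap"] <= 2.2]
  x0 <- rep(-1.9, nrow(mesh$vertices))
  x0[patch] <- -1.6
  list(mesh = mesh, kernel = kern, patch = patch,
       params = sem_parameters(x0 = x0))
}

# small co-registered fixture for bridge/cosim tests
cosim_fixture <- function(n_neurons = 180, seed = 5) {
  geo <- build_geometry(n_ap = 12, n_pd = 6, n_neurons = n_neurons,
                        seed = seed)
  net <- build_synthetic_connectivity(geo$cloud, mean_degree = 8,
                                      seed = seed_stream(seed, 2))
  kern <- local_kernel(geodesic_distances(geo$mesh, cutoff = 6),
                       sigma = 2, cutoff = 6)
  c(geo, list(net = net, kernel = kern))
}
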