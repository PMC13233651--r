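test_that("state initialization places rest and onset nodes at the printed points", {
  s <- initialize_states(5)
  expect_equal(unique(s$x1), -1.5)
  expect_equal(unique(s$y1), -11)
  expect_equal(unique(s$z), 3)
  expect_equal(unique(s$x2), -0.9)
  expect_equal(unique(s$y2), 0.3)
  expect_equal(unique(s$g), -0.1)

  s3 <- initialize_states(5, onset_nodes = 3)
  expect_equal(s3$x1[3], 0); expect_equal(s3$y1[3], -5)
  expect_equal(s3$z[3], 3);  expect_equal(s3$x2[3], 0)
  expect_equal(s3$y2[3], 0); expect_equal(s3$g[3], 0)
  expect_equal(s3$x1[-3], rep(-1.5, 4))

  sall <- initialize_states(4, onset_nodes = 1:4)
  expect_equal(sall$x1, rep(0, 4))

  expect_error(initialize_states(0), "n_nodes")
  expect_error(initialize_states(3, onset_nodes = 5), "out of range")
})

test_that("derivatives scale linearly with tt and reject non-finite states", {
  p1 <- sem_parameters(x0 = -1.9)
  p2 <- sem_parameters(x0 = -1.9, tt = 2 * p1$tt)
  s <- initialize_states(3, onset_nodes = 2)
  d1 <- sem_derivatives(s, p1)
  d2 <- sem_derivatives(s, p2)
  for (f in names(d1)) expect_equal(d2[[f]], 2 * d1[[f]])

  s$x1[1] <- NaN
  expect_error(sem_derivatives(s, p1), "non-finite")
})

test_that("the printed rest point is quasi-stationary over 1000 ms without coupling", {
  # The printed initialization is a point on the slow interictal branch, not
  # an exact equilibrium: x1, z and g barely move, while the fast recovery
  # variable y1 relaxes onto its nullcline (1 - 5*x1^2, about -10.2) within
  # tens of ms. z drifts on the tau0 time scale.
  rec <- run_field(sem_parameters(x0 = -1.9), n_nodes = 1, duration = 1000,
                   monitor_stride = 1)
  dev <- function(f) max(abs(rec[[f]][1, ] - rec[[f]][1, 1]))
  expect_lt(dev("x1"), 0.3)
  expect_lt(dev("g"), 0.3)
  expect_lt(dev("x2"), 0.35)
  expect_lt(dev("y2"), 0.35)
  expect_lt(dev("y1"), 2.0)
  expect_lt(dev("z"), 2 * 1000 * 0.17 / 2857)  # bounded by the tau0 drift
})

test_that("fixed-point search locates a genuine equilibrium continuous in x0", {
  p <- sem_parameters()
  fp <- find_fixed_point(p, x0 = -1.9)
  expect_lt(attr(fp, "residual"), 1e-10)
  # all six derivative components vanish at the root
  st <- structure(as.list(fp), class = "sem_state")
  names(st) <- c("x1", "y1", "z", "x2", "y2", "g")
  p19 <- sem_parameters(x0 = -1.9)
  expect_lt(max(abs(unlist(sem_derivatives(st, p19)))), 1e-10)
  # near (but not at) the printed stable point
  expect_lt(abs(fp["x1"] - (-1.5)), 0.4)

  # continuity of the equilibrium branch as x0 sweeps -2.2 -> -1.9
  guess <- epicosim:::SEM_REST_STATE
  prev <- NULL
  for (x0 in seq(-2.2, -1.9, by = 0.01)) {
    f <- find_fixed_point(p, x0, guess = guess)
    if (!is.null(prev)) expect_lt(max(abs(f - prev)), 0.25)
    prev <- f; guess <- f
  }
})

test_that("history buffer honors the ring semantics and depth contract", {
  h <- history_buffer(c(1, 2), depth = 3)
  history_write(h, c(10, 20))
  expect_equal(history_read(h, 1:2, 0L), c(10, 20))  # delay 0 = newest
  expect_equal(history_read(h, 1:2, 1L), c(1, 2))
  history_write(h, c(100, 200))
  history_write(h, c(1000, 2000))
  expect_equal(history_read(h, 1:2, 2L), c(10, 20))
  expect_error(history_read(h, 1L, 3L), "depth")
})

test_that("global coupling vanishes for null weights and at consensus", {
  x1 <- c(-1.2, -1.4, -1.6)
  h <- history_buffer(x1, depth = 1)
  expect_equal(compute_global_coupling(h, NULL, x1, 0.636), rep(0, 3))

  # uniform state, zero delays: difference coupling vanishes
  W <- matrix(1, 3, 3); diag(W) <- 0
  conn <- sparse_connectome(W, W * 0, conduction_speed = 3)
  xu <- rep(-1.5, 3)
  hu <- history_buffer(xu, depth = 1)
  expect_equal(compute_global_coupling(hu, conn, xu, 0.636), rep(0, 3))
})

test_that("delayed coupling on a 3-node chain matches a dense-history evaluation", {
  # chain 1 <- 2 <- 3 with delays 0 and 2 steps, unit weights
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1; W[2, 3] <- 1
  L <- matrix(0, 3, 3)
  L[2, 3] <- 2 * 0.1 * 3  # 2 steps at speed 3 mm/ms, dt = 0.1
  conn <- sparse_connectome(W, L, conduction_speed = 3)
  # hand-built history: x1(t) = t + node/10
  h <- history_buffer(c(0.1, 0.2, 0.3), depth = 5)
  for (t in 1:4) history_write(h, t + c(0.1, 0.2, 0.3))
  x1_now <- 4 + c(0.1, 0.2, 0.3)
  got <- compute_global_coupling(h, conn, x1_now, k = 2, dt = 0.1)
  # node 1: w*(x1_2(t-0) - x1_1(t)) = (4.2 - 4.1); node 2: x1_3(t-2) - x1_2(t)
  expect_equal(got, 2 * c(4.2 - 4.1, 2.3 - 4.2, 0))
})

test_that("Heaviside local coupling obeys thresholds, hand values and gamma linearity", {
  p <- sem_parameters()
  n <- 3
  # kernel with a single entry K[1,2] = 0.5: geodesic distance sigma*log(2)
  g <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1),
                            x = rep(2 * log(2), 2), dims = c(3, 3))
  kern <- local_kernel(g, sigma = 2, cutoff = 6)
  expect_equal(kern$K[1, 2], 0.5)

  # everything below thresholds: all terms zero
  lc0 <- compute_local_coupling(rep(-2, n), rep(-2, n), kern, p)
  expect_equal(lc0$lc11, rep(0, n))
  expect_equal(lc0$lc22, rep(0, n))

  # single suprathreshold neighbor with K = 0.5: lc11 = 0.34 * 0.5
  x1 <- c(-2, 0, -2)  # node 2 above theta11 = -1
  lc <- compute_local_coupling(x1, rep(-2, n), kern, p)
  expect_equal(lc$lc11[1], 0.34 * 0.5)
  expect_equal(lc$lc12[1], 0.064 * 0.5)
  expect_equal(lc$lc22, rep(0, n))

  # linearity in the gammas
  p2 <- sem_parameters(gamma11 = 2 * 0.34, gamma12 = 2 * 0.064,
                       gamma22 = 2 * 0.032)
  lc2 <- compute_local_coupling(x1, rep(0, n), kern, p2)
  lc1 <- compute_local_coupling(x1, rep(0, n), kern, p)
  expect_equal(lc2$lc11, 2 * lc1$lc11)
  expect_equal(lc2$lc22, 2 * lc1$lc22)

  expect_error(compute_local_coupling(rep(0, 5), rep(0, 5), kern, p), "size")
})

test_that("Heun stepping fixes equilibria, converges at order dt^3 and is blockwise independent", {
  p <- sem_parameters(x0 = -2.2)
  fp <- find_fixed_point(p, x0 = -2.2)
  st <- structure(c(as.list(fp), list(time = 0)), class = "sem_state")
  names(st)[1:6] <- c("x1", "y1", "z", "x2", "y2", "g")
  out <- heun_step(st, p, dt = 0.1)
  expect_equal(unlist(out[1:6]), unlist(st[1:6]), tolerance = 1e-12)

  # Richardson: one-step local error shrinks ~8x when dt halves
  s0 <- initialize_states(1, onset_nodes = 1)
  step_to <- function(dt, t_end = 0.8) {
    s <- s0
    for (i in seq_len(round(t_end / dt))) s <- heun_step(s, p, dt = dt)
    unlist(s[1:6])
  }
  ref <- step_to(0.0005)
  e1 <- max(abs(step_to(0.2) - ref))
  e2 <- max(abs(step_to(0.1) - ref))
  e4 <- max(abs(step_to(0.05) - ref))
  expect_gt(e1 / e2, 3)   # global order ~2: factor ~4 per halving
  expect_gt(e2 / e4, 3)

  # decoupled nodes step independently
  p3 <- sem_parameters(x0 = c(-1.6, -1.9, -2.2))
  s3 <- initialize_states(3, onset_nodes = 1)
  joint <- heun_step(s3, p3, dt = 0.1)
  for (i in 1:3) {
    pi <- sem_parameters(x0 = p3$x0[i])
    si <- initialize_states(1, onset_nodes = if (i == 1) 1 else integer(0))
    oi <- heun_step(si, pi, dt = 0.1)
    expect_equal(joint$x1[i], oi$x1)
    expect_equal(joint$z[i], oi$z)
  }
})

test_that("run_field is deterministic, records as promised and matches R stepping", {
  p <- sem_parameters(x0 = rep(-1.6, 12))
  conn <- random_connectome(12, density = 0.3, seed = 3)
  mesh <- generate_synthetic_hippocampus(4, 4)
  kern <- local_kernel(geodesic_distances(mesh, 20)[1:12, 1:12], 2, 20)

  rec0 <- run_field(p, n_nodes = 12, duration = 0)
  expect_length(rec0$times, 1)
  expect_equal(rec0$x1[, 1], rep(-1.5, 12))

  recA <- run_field(p, n_nodes = 12, conn = conn, kernel = kern,
                    onset_nodes = 1:2, duration = 50, monitor_stride = 5)
  recB <- run_field(p, n_nodes = 12, conn = conn, kernel = kern,
                    onset_nodes = 1:2, duration = 50, monitor_stride = 5)
  expect_identical(recA, recB)
  expect_length(recA$times, 500 / 5 + 1)

  # compiled loop equals repeated R-level heun_step exactly
  st <- initialize_states(12, onset_nodes = 1:2)
  h <- history_buffer(st$x1, max(epicosim:::delay_steps(conn, 0.1)) + 1L)
  for (i in 1:500) st <- heun_step(st, p, conn = conn, kernel = kern,
                                   history = h, dt = 0.1)
  expect_equal(recA$final$x1, st$x1, tolerance = 1e-12)
  expect_equal(recA$final$g, st$g, tolerance = 1e-12)
})

test_that("sparse delayed simulation matches the dense full-history reference", {
  n <- 100
  conn <- random_connectome(n, density = 0.05, length_range = c(1, 30),
                            seed = 17)
  p <- sem_parameters(x0 = rep(-1.7, n))
  onset <- 1:5
  rec <- run_field(p, n_nodes = n, conn = conn, onset_nodes = onset,
                   duration = 100, monitor_stride = 1000)
  init <- initialize_states(n, onset)
  W <- as.matrix(conn$weights)
  Dsteps <- matrix(as.integer(floor(as.matrix(conn$delays) / 0.1 + 0.5)), n, n)
  ref <- dense_field_reference(init, p, W, Dsteps,
                               Kdense = matrix(0, n, n), dt = 0.1,
                               n_steps = 1000)
  expect_lt(max(abs(rec$final$x1 - ref[1, ])), 1e-10)
  expect_lt(max(abs(rec$final$z - ref[3, ])), 1e-10)
  expect_lt(max(abs(rec$final$g - ref[6, ])), 1e-10)
})

test_that("a single epileptogenic node seizes and returns toward rest; a propagation-zone node stays quiet over the study window", {
  p16 <- sem_parameters(x0 = -1.6)
  rec <- run_field(p16, n_nodes = 1, onset_nodes = 1, duration = 8000,
                   monitor_stride = 10)
  sig <- rec$x2[1, ] - rec$x1[1, ]
  on <- detect_seizures(sig, rec$times)
  expect_gt(length(on), 0)
  expect_gt(max(sig), 1)          # large-amplitude ictal oscillation
  expect_lt(min(sig), -2)
  # termination: the last second sits back near the interictal branch
  tail_idx <- rec$times > 7000
  expect_lt(max(abs(rec$x1[1, tail_idx] - (-1.5))), 0.5)

  p19 <- sem_parameters(x0 = -1.9)
  rec19 <- run_field(p19, n_nodes = 1, duration = 2000, monitor_stride = 10)
  expect_length(detect_seizures(rec19$x2[1, ] - rec19$x1[1, ], rec19$times), 0)
  # x1 hugs the interictal branch until the very end of the window, where
  # the slow permittivity drift starts releasing the fast subsystem
  early <- rec19$times <= 1800
  expect_lt(max(abs(rec19$x1[1, early] - (-1.5))), 0.5)
})

test_that("seizure recurrence period scales about linearly with tau0", {
  period_of <- function(tau0) {
    rec <- run_field(sem_parameters(x0 = -1.6, tau0 = tau0), n_nodes = 1,
                     onset_nodes = 1, duration = min(12 * tau0, 70000),
                     monitor_stride = 20)
    z <- rec$z[1, ]
    up <- which(z[-1] > 3.05 & z[-length(z)] <= 3.05)
    t_on <- rec$times[up + 1]
    expect_gte(length(t_on), 2)
    mean(diff(t_on))
  }
  taus <- c(1428, 2857, 5714)
  ratios <- vapply(taus, function(t) period_of(t) / t, numeric(1))
  # slope within +/-30%: all period/tau0 ratios agree to that factor
  expect_lt(max(ratios) / min(ratios), 1.3)
})

test_that("onset latency increases with geodesic distance from the onset patch", {
  fx <- propagation_fixture()
  rec <- run_field(fx$params, n_nodes = nrow(fx$mesh$vertices),
                   kernel = fx$kernel, onset_nodes = fx$patch,
                   duration = 1500, monitor_stride = 10)
  lat <- onset_latency_map(rec)
  D <- as.matrix(geodesic_distances(fx$mesh))
  dpatch <- apply(D[, fx$patch, drop = FALSE], 1, min)
  ok <- !is.na(lat)
  expect_gt(sum(ok), 150)
  rho <- cor(dpatch[ok], lat[ok], method = "spearman")
  expect_gt(rho, 0.8)
  # the onset patch itself has minimal latency
  expect_equal(unname(lat[fx$patch]), rep(min(lat, na.rm = TRUE),
                                          length(fx$patch)))
})
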