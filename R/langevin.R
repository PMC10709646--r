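## Langevin dynamics of the two proton coordinates: the package's
## synthetic-data generator. Emulates the statistical structure of QM/MM
## umbrella-sampling, steered-separation and unbiased decay trajectories
## on the calibrated model surfaces.

#' Simulation settings for Langevin dynamics
#'
#' @param temperature temperature, K (reference 310 K)
#' @param dt integration timestep, fs
#' @param friction Langevin friction, 1/ps; the free parameter setting the
#'   decay-time scale of unbiased runs (see the methods vignette)
#' @param mass effective mass per proton coordinate, amu
#' @param n_steps number of integration steps
#' @param burn_in steps discarded from the start (default 2 ps worth)
#' @param store_stride store every `store_stride`-th frame
#' @param seed RNG seed; recorded in every trajectory
#' @return object of class `dpt_sim_settings`
#' @export
simulation_settings <- function(temperature = 310, dt = 0.5, friction = 5,
                                mass = 1, n_steps = 16000,
                                burn_in = round(2000 / dt),
                                store_stride = 4L, seed = 1L) {
  stopifnot(dt > 0, temperature >= 0, friction > 0, mass > 0,
            n_steps >= 1, burn_in >= 0, burn_in < n_steps, store_stride >= 1)
  structure(list(temperature = temperature, dt = dt, friction = friction,
                 mass = mass, n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in),
                 store_stride = as.integer(store_stride),
                 seed = as.integer(seed)),
            class = "dpt_sim_settings")
}

#' Umbrella restraint window on the four hydrogen-bond distances
#'
#' The bias is (k/2) * sum_i (d_i - c_i)^2 over the four distance reaction
#' coordinates.
#'
#' @param centers restraint centers for d1..d4, Angstrom
#' @param k force constant in kJ/mol/nm^2 (per distance); the default is
#'   the conventional 20000
#' @param geom the [geometry_refs()] the distances refer to
#' @return object of class `dpt_umbrella_window`: centers, k (input units),
#'   `k_eV` (eV/A^2) and the effective 2D restraint centre (a, b)
#' @export
umbrella_window <- function(centers, k = 20000, geom = geometry_refs()) {
  stopifnot(length(centers) == 4, k > 0)
  structure(list(
    centers = as.numeric(centers), k = k, k_eV = bias_k_to_eV(k),
    a = (centers[1] + geom$R_NN - centers[2]) / 2,
    b = (centers[3] + geom$R_ON - centers[4]) / 2),
    class = "dpt_umbrella_window")
}

#' Restraint centers along a transfer path at a given collective coordinate
#'
#' Maps a window position lambda_c to proton-coordinate targets on the
#' asynchronous two-leg path (central proton first, via G-C+) or the
#' synchronous diagonal, then to the four distance centers.
#'
#' @param lambda_c collective-coordinate positions of the windows
#' @param path "asynchronous" or "synchronous"
#' @param geom a [geometry_refs()] object
#' @return matrix with one row per window: d1..d4 centers
#' @export
path_window_centers <- function(lambda_c,
                                path = c("asynchronous", "synchronous"),
                                geom = geometry_refs()) {
  path <- match.arg(path)
  u <- if (path == "synchronous") cbind(lambda_c, lambda_c)
  else {
    u1 <- ifelse(lambda_c <= 0.5, 2 * lambda_c, 1)
    u2 <- ifelse(lambda_c <= 0.5, 0, 2 * (lambda_c - 0.5))
    cbind(u1, u2)
  }
  r1 <- geom$r_cov + u[, 1] * (geom$R_NN - 2 * geom$r_cov)
  r2 <- geom$r_cov + u[, 2] * (geom$R_ON - 2 * geom$r_cov)
  cbind(d1 = r1, d2 = geom$R_NN - r1, d3 = r2, d4 = geom$R_ON - r2)
}

## shared driver around the C++ BAOAB core
.simulate_core <- function(params, settings, window = NULL, s = 0,
                           s_rate = 0, s_max = s, start = NULL,
                           stop_lambda = NULL) {
  stopifnot(inherits(params, "dpt_surface"),
            inherits(settings, "dpt_sim_settings"))
  geom <- params$geom
  tm <- surface_terms(params)
  if (is.null(start)) {
    sf <- as_surface_fun(params, s = s)
    start <- find_min_2d(sf, unlist(params$wells[params$wells$state == "GC",
                                                 c("x", "y")]))$pos
  }
  lam_a1 <- 0.5 / (geom$R_NN - 2 * geom$r_cov)
  lam_a2 <- 0.5 / (geom$R_ON - 2 * geom$r_cov)
  lam_b <- -geom$r_cov * (lam_a1 + lam_a2)
  set.seed(settings$seed)
  out <- langevin_core(
    gauss = tm$gauss, sep = tm$sep,
    conf = as.numeric(tm$conf), offset = tm$offset,
    wall = as.numeric(tm$wall),
    r0 = as.numeric(start),
    n_steps = settings$n_steps, dt = settings$dt,
    gamma_fs = settings$friction / 1000,
    mass = settings$mass * dpt_constants$amu,
    kT = dpt_constants$kB * settings$temperature,
    bias_center = if (is.null(window)) numeric(0) else c(window$a, window$b),
    bias_k = if (is.null(window)) 0 else window$k_eV,
    s0 = s, s_rate = s_rate, s_max = s_max,
    domain = geom$domain,
    store_stride = settings$store_stride, burn_in = settings$burn_in,
    lambda_coef = c(lam_a1, lam_a2, lam_b),
    stop_lambda = if (is.null(stop_lambda)) 0 else stop_lambda,
    stop_enabled = !is.null(stop_lambda))

  d <- cbind(d1 = out$r1, d2 = geom$R_NN - out$r1,
             d3 = out$r2, d4 = geom$R_ON - out$r2)
  traj <- data.frame(t_fs = out$t_fs, r1_A = out$r1, r2_A = out$r2,
                     d1_A = d[, 1], d2_A = d[, 2],
                     d3_A = d[, 3], d4_A = d[, 4],
                     lambda = lambda_of(out$r1, out$r2, geom),
                     E_eV = out$E_eV, s_A = out$s)
  n_kept <- settings$n_steps - settings$burn_in
  frac_reflect <- out$n_reflect / (2 * settings$n_steps)
  if (frac_reflect > 0.01)
    warning(sprintf("%.1f%% of steps hit the reflective domain boundary",
                    100 * frac_reflect))
  structure(traj, class = c("dpt_trajectory", "data.frame"),
            scenario = params$scenario, settings = settings,
            window = window, s = s, s_rate = s_rate,
            start = as.numeric(start),
            n_reflect = out$n_reflect,
            first_passage_fs = if (out$first_passage_step > 0)
              out$first_passage_step * settings$dt else NA_real_)
}

#' Simulate Langevin dynamics on a model surface
#'
#' Discretised underdamped Langevin dynamics (BAOAB splitting with exact
#' Ornstein-Uhlenbeck thermostat step) of the two proton coordinates on
#' `surface + umbrella bias`, with reflective boundaries at the domain
#' edges. Reproducible given the settings seed; burn-in frames are
#' discarded.
#'
#' @param params calibrated `dpt_surface`
#' @param settings [simulation_settings()]
#' @param window optional [umbrella_window()] restraint
#' @param s base-pair separation, Angstrom
#' @param start optional starting coordinates (default: the GC minimum)
#' @return a `dpt_trajectory`: data.frame with time (fs), proton
#'   coordinates, the four distances, lambda, instantaneous potential
#'   energy (eV) and separation; simulation metadata in attributes
#' @export
simulate_dpt <- function(params, settings, window = NULL, s = 0,
                         start = NULL) {
  .simulate_core(params, settings, window = window, s = s, start = start)
}

#' Run an umbrella-sampling window series along a transfer path
#'
#' Places `n_windows` restraint windows along the chosen path at evenly
#' spaced collective-coordinate values, runs `replicas` trajectories per
#' window, and checks histogram overlap between adjacent windows.
#' Replica 1 is seeded sequentially forward (each window starts from the
#' previous window's final frame), replica 2 sequentially backward from
#' the product side; further replicas start at their window centre.
#'
#' @param params calibrated `dpt_surface`
#' @param settings [simulation_settings()]; per-window seeds are derived
#'   from `settings$seed`
#' @param n_windows number of windows (>= 8)
#' @param lambda_range range of window centres in lambda
#' @param k umbrella force constant, kJ/mol/nm^2
#' @param replicas trajectories per window
#' @param path "asynchronous" (default) or "synchronous"
#' @param s base-pair separation
#' @param min_overlap minimum shared probability mass between adjacent
#'   windows' lambda histograms
#' @param start_mode how replica initial states are chosen:
#'   `"boltzmann"` (default) draws each replica's start from the restrained
#'   Boltzmann density by quadrature, emulating fully equilibrated umbrella
#'   replicas (restraint sub-basins populated with their equilibrium
#'   weights even when the in-window crossing time exceeds the sampling
#'   time); `"sweep"` seeds windows sequentially (replica 1 forward from
#'   the reactant side, replica 2 backward, others at window centres);
#'   `"center"` starts every replica at its window centre
#' @return list of `dpt_trajectory` (windows fastest-varying by replica),
#'   with the window list and overlap matrix as attributes
#' @export
run_umbrella_series <- function(params, settings, n_windows = 32,
                                lambda_range = c(-0.1, 1.1), k = 20000,
                                replicas = 3,
                                path = c("asynchronous", "synchronous"),
                                s = 0, min_overlap = 0.05,
                                start_mode = c("boltzmann", "sweep",
                                               "center")) {
  path <- match.arg(path)
  start_mode <- match.arg(start_mode)
  stopifnot(n_windows >= 8, replicas >= 1)
  geom <- params$geom
  lam_c <- seq(lambda_range[1], lambda_range[2], length.out = n_windows)
  centers <- path_window_centers(lam_c, path = path, geom = geom)
  windows <- lapply(seq_len(n_windows), function(i)
    umbrella_window(centers[i, ], k = k, geom = geom))

  starts <- NULL
  if (start_mode == "boltzmann") {
    h <- 0.01
    g <- seq(geom$domain[1], geom$domain[2], by = h)
    gr <- expand.grid(r1 = g, r2 = g)
    E0 <- surface_evaluate(params, gr$r1, gr$r2, s = s, check = FALSE)
    kT <- dpt_constants$kB * max(settings$temperature, 1)
    set.seed(settings$seed)
    starts <- lapply(windows, function(w) {
      B <- w$k_eV * ((gr$r1 - w$a)^2 + (gr$r2 - w$b)^2)
      lw <- -(E0 + B) / kT
      pr <- exp(lw - max(lw))
      idx <- sample.int(nrow(gr), replicas, replace = TRUE, prob = pr)
      cbind(gr$r1[idx], gr$r2[idx])
    })
  }

  trajs <- vector("list", n_windows * replicas)
  seed_of <- function(w, r) (settings$seed %% 100000L) * 10000L +
    (r - 1L) * 1000L + w
  for (rep_i in seq_len(replicas)) {
    order_w <- if (rep_i == 2) rev(seq_len(n_windows)) else seq_len(n_windows)
    prev_end <- NULL
    for (w in order_w) {
      st <- settings
      st$seed <- seed_of(w, rep_i)
      start <- switch(start_mode,
        boltzmann = starts[[w]][rep_i, ],
        sweep = if (rep_i <= 2 && !is.null(prev_end)) prev_end
                else c(windows[[w]]$a, windows[[w]]$b),
        center = c(windows[[w]]$a, windows[[w]]$b))
      start <- pmin(pmax(start, geom$domain[1]), geom$domain[2])
      tr <- .simulate_core(params, st, window = windows[[w]], s = s,
                           start = start)
      trajs[[(w - 1) * replicas + rep_i]] <- tr
      prev_end <- c(tail(tr$r1_A, 1), tail(tr$r2_A, 1))
    }
  }

  ov <- .window_overlaps(trajs, windows, n_windows, replicas)
  gaps <- which(ov$adjacent < min_overlap)
  if (length(gaps)) {
    if (!ov$connected)
      stop(sprintf(paste0("coverage error: lambda histograms of adjacent ",
                          "windows %s share < %.0f%% probability mass and the ",
                          "window graph is disconnected; add windows in ",
                          "lambda in [%.2f, %.2f]"),
                   paste(gaps, collapse = ", "), 100 * min_overlap,
                   min(lam_c[gaps]), max(lam_c[pmin(gaps + 1, n_windows)])))
    warning(sprintf(paste0("adjacent windows %s share < %.0f%% lambda ",
                           "histogram mass (bridged via non-adjacent ",
                           "overlap); consider more windows"),
                    paste(gaps, collapse = ", "), 100 * min_overlap))
  }
  structure(trajs, windows = windows, n_windows = n_windows,
            replicas = replicas, path = path, overlap = ov$adjacent)
}

## pooled per-window lambda histograms; adjacent shared mass and
## connectivity of the >=min_overlap overlap graph
.window_overlaps <- function(trajs, windows, n_windows, replicas,
                             nbin = 120, min_overlap = 0.05) {
  lam_all <- unlist(lapply(trajs, function(t) t$lambda))
  br <- seq(min(lam_all) - 1e-9, max(lam_all) + 1e-9, length.out = nbin + 1)
  H <- matrix(0, n_windows, nbin)
  for (w in seq_len(n_windows)) {
    lam <- unlist(lapply(seq_len(replicas), function(r)
      trajs[[(w - 1) * replicas + r]]$lambda))
    h <- hist(lam, breaks = br, plot = FALSE)$counts
    H[w, ] <- h / sum(h)
  }
  shared <- function(i, j) sum(pmin(H[i, ], H[j, ]))
  adjacent <- vapply(seq_len(n_windows - 1), function(i) shared(i, i + 1), 0)
  ## connectivity via union-find over all pairs with enough overlap
  parent <- seq_len(n_windows)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n_windows - 1)) for (j in (i + 1):n_windows)
    if (shared(i, j) >= min_overlap) parent[find(j)] <- find(i)
  connected <- length(unique(vapply(seq_len(n_windows), find, 0L))) == 1
  list(adjacent = adjacent, connected = connected)
}

#' Steered base-pair separation run
#'
#' Imposes a monotone separation schedule s(t) = min(rate * t, max_s) on
#' the surface's separation coupling while the protons evolve under
#' Langevin dynamics, emulating steered MD pulling of the base pair. In
#' `constant_force` mode the rate is force * mobility (overdamped pulling
#' of the slow opening coordinate).
#'
#' @param params calibrated `dpt_surface`
#' @param settings [simulation_settings()]
#' @param max_s final separation, Angstrom (<= 0.8)
#' @param pull_rate separation rate, Angstrom/ps (schedule mode)
#' @param mode "schedule" or "constant_force"
#' @param force separating force, in the conventional kJ/mol/nm quoting
#'   (default 500); used in constant_force mode
#' @param mobility mobility of the slow opening coordinate, A^2/(eV ps);
#'   the opening is overdamped, so s advances at force * mobility
#' @return a `dpt_trajectory` with the separation column `s_A` following
#'   the schedule
#' @export
steered_separation <- function(params, settings, max_s = 0.6,
                               pull_rate = 0.12,
                               mode = c("schedule", "constant_force"),
                               force = 500, mobility = 0.2) {
  mode <- match.arg(mode)
  stopifnot(max_s <= 0.8, max_s >= 0)
  rate_ps <- if (mode == "schedule") pull_rate
  else (force / dpt_constants$eV_per_kJmol / 10) * mobility  # eV/A * mobility
  if (max_s == 0 || rate_ps <= 0)
    return(.simulate_core(params, settings, s = 0))
  .simulate_core(params, settings, s = 0, s_rate = rate_ps / 1000,
                 s_max = max_s)
}

#' Unbiased decay runs from the tautomer
#'
#' Starts `n_replicas` unbiased trajectories at `start` (typically the
#' frozen-surface G*C* minimum) on a thermal surface and terminates each
#' when it enters the GC basin (lambda < `stop_lambda`) or at the cap.
#'
#' @param params_thermal calibrated thermal-scenario `dpt_surface`
#' @param start starting proton coordinates (G*C* product position)
#' @param settings [simulation_settings()]; `n_steps` acts as the cap
#'   (default 2 ps at dt = 0.5 fs), burn-in is ignored
#' @param n_replicas number of independent replicas
#' @param stop_lambda GC-basin threshold on lambda
#' @return list with `trajectories` and data.frame `first_passage`
#'   (replica, time_fs, decayed)
#' @export
decay_run <- function(params_thermal, start,
                      settings = simulation_settings(n_steps = 4000,
                                                     burn_in = 0,
                                                     store_stride = 1),
                      n_replicas = 20, stop_lambda = 0.15) {
  check_domain(start[1], start[2], params_thermal$geom)
  settings$burn_in <- 0L
  trajs <- vector("list", n_replicas)
  fpt <- data.frame(replica = seq_len(n_replicas), time_fs = NA_real_,
                    decayed = FALSE)
  for (i in seq_len(n_replicas)) {
    st <- settings
    st$seed <- (settings$seed %% 100000L) * 10000L + i
    tr <- .simulate_core(params_thermal, st, start = start,
                         stop_lambda = stop_lambda)
    trajs[[i]] <- tr
    fp <- attr(tr, "first_passage_fs")
    fpt$time_fs[i] <- fp
    fpt$decayed[i] <- is.finite(fp)
  }
  list(trajectories = trajs, first_passage = fpt)
}
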