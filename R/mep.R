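## The frozen ("instantaneous") potential-energy-surface workflow: energy
## grids over the two proton positions, smooth interpolation, local-minimum
## location, and nudged-elastic-band minimum energy paths.

#' Sample a model surface on a regular grid
#'
#' @param params calibrated `dpt_surface`
#' @param n_per_axis nodes per axis (default 33, i.e. 0.05 A spacing over
#'   the 0.9-2.5 A domain)
#' @param s base-pair separation
#' @return a `dpt_grid`: list with node vectors `r1`, `r2`, energy matrix
#'   `E` (r1 varies over rows), scenario id and separation. Grids coarser
#'   than 0.05 A spacing are flagged `too_coarse` for stationary analysis.
#' @export
sample_grid <- function(params, n_per_axis = 33, s = 0) {
  stopifnot(inherits(params, "dpt_surface"), n_per_axis >= 2)
  dom <- params$geom$domain
  g <- seq(dom[1], dom[2], length.out = n_per_axis)
  E <- outer(g, g, function(a, b) surface_evaluate(params, a, b, s = s,
                                                   check = FALSE))
  structure(list(r1 = g, r2 = g, E = E, scenario = params$scenario, s = s,
                 spacing = diff(g[1:2]),
                 too_coarse = diff(g[1:2]) > 0.05 + 1e-9),
            class = "dpt_grid")
}

#' Interpolate a surface grid to a smooth surface function
#'
#' Tensor-product natural cubic splines: C2-smooth along each axis,
#' reproduces the node energies exactly and linear data to rounding.
#' Queries are restricted to the grid hull.
#'
#' @param grid a `dpt_grid` (or compatible list with r1, r2, E)
#' @return a `dpt_interp` object usable wherever a surface is accepted
#'   (see [as_surface_fun()])
#' @export
interpolate_grid <- function(grid) {
  stopifnot(!is.null(grid$r1), !is.null(grid$r2), is.matrix(grid$E))
  if (any(!is.finite(grid$E))) stop("grid energies must be finite")
  if (is.unsorted(grid$r1) || is.unsorted(grid$r2))
    stop("grid axes must be sorted")
  row_spl <- lapply(seq_along(grid$r2), function(j)
    splinefun(grid$r1, grid$E[, j], method = "natural"))
  hull <- c(min(grid$r1), max(grid$r1), min(grid$r2), max(grid$r2))
  f1 <- function(x, y) {
    if (any(x < hull[1] - 1e-9 | x > hull[2] + 1e-9 |
            y < hull[3] - 1e-9 | y > hull[4] + 1e-9))
      stop("domain error: query outside the grid hull")
    vapply(seq_along(x), function(i) {
      col <- vapply(row_spl, function(sp) sp(x[i]), 0)
      splinefun(grid$r2, col, method = "natural")(y[i])
    }, 0)
  }
  structure(list(f = f1, hull = hull, grid = grid), class = "dpt_interp")
}

#' @export
as_surface_fun.dpt_interp <- function(x, s = 0) {
  h <- 1e-5
  hull <- x$hull
  fcl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  g <- function(r1, r2) {
    ## one-sided differences at the hull edge
    x1p <- fcl(r1 + h, hull[1], hull[2]); x1m <- fcl(r1 - h, hull[1], hull[2])
    y1p <- fcl(r2 + h, hull[3], hull[4]); y1m <- fcl(r2 - h, hull[3], hull[4])
    cbind((x$f(x1p, r2) - x$f(x1m, r2)) / (x1p - x1m),
          (x$f(r1, y1p) - x$f(r1, y1m)) / (y1p - y1m))
  }
  list(f = x$f, g = g, domain = c(hull[1], hull[2]))
}

## quadrant label relative to the bond midpoints
.quadrant_label <- function(r1, r2, geom) {
  t1 <- r1 > geom$R_NN / 2
  t2 <- r2 > geom$R_ON / 2
  ifelse(t1 & t2, "GstarCstar",
         ifelse(t1, "G_minus_C_plus",
                ifelse(t2, "G_plus_C_minus", "GC")))
}

#' Locate local minima of a surface by quasi-Newton descent
#'
#' Runs a damped-descent + BFGS minimisation from each start, merges
#' duplicates within `merge_tol`, and labels each minimum by which protons
#' have transferred (quadrant relative to the bond midpoints). Descents
#' that leave the hull are discarded with a message.
#'
#' @param surf a `dpt_surface`, `dpt_interp`, or surface-function list
#' @param starts matrix (or list) of starting coordinates; default: the
#'   four quadrant centres
#' @param merge_tol duplicate-merge distance, Angstrom
#' @param geom geometry for labelling
#' @param s separation (analytic surfaces)
#' @return data.frame (state, r1, r2, energy_eV, grad_norm), energies
#'   absolute (not shifted)
#' @export
find_minima <- function(surf, starts = NULL, merge_tol = 0.02,
                        geom = geometry_refs(), s = 0) {
  sf <- if (is.list(surf) && !is.null(surf$f) && is.null(attr(surf, "class")))
    surf else as_surface_fun(surf, s = s)
  if (inherits(surf, "dpt_grid"))
    stop("interpolate the grid first (interpolate_grid)")
  if (inherits(surf, "dpt_interp") && isTRUE(surf$grid$too_coarse))
    warning("grid spacing > 0.05 A: too coarse for stationary analysis")
  if (is.null(starts)) {
    q <- state_positions(geom)
    starts <- rbind(q$GC, q$G_minus_C_plus, q$G_plus_C_minus, q$GstarCstar)
  }
  starts <- rbind(starts)
  ## optimizer probes may step outside the hull: evaluate at the clamped
  ## point with a quadratic pull-back so descents stay well defined
  lo <- sf$domain[1]; hi <- sf$domain[2]
  safe <- list(
    f = function(x, y) {
      xc <- pmin(pmax(x, lo), hi); yc <- pmin(pmax(y, lo), hi)
      sf$f(xc, yc) + 1e3 * ((x - xc)^2 + (y - yc)^2)
    },
    g = function(x, y) {
      xc <- pmin(pmax(x, lo), hi); yc <- pmin(pmax(y, lo), hi)
      sf$g(xc, yc) + 2e3 * cbind(x - xc, y - yc)
    },
    domain = sf$domain)
  found <- list()
  for (i in seq_len(nrow(starts))) {
    m <- tryCatch(find_min_2d(safe, starts[i, ]), error = function(e) NULL)
    if (is.null(m)) {
      message(sprintf("descent from (%.2f, %.2f) left the hull; discarded",
                      starts[i, 1], starts[i, 2]))
      next
    }
    if (!m$converged) next
    dup <- FALSE
    for (f in found)
      if (sqrt(sum((f$pos - m$pos)^2)) < merge_tol) { dup <- TRUE; break }
    if (!dup) found[[length(found) + 1]] <- m
  }
  if (!length(found)) return(data.frame(state = character(0), r1 = numeric(0),
                                        r2 = numeric(0), energy_eV = numeric(0),
                                        grad_norm = numeric(0)))
  out <- data.frame(
    state = vapply(found, function(m) .quadrant_label(m$pos[1], m$pos[2], geom), ""),
    r1 = vapply(found, function(m) m$pos[1], 0),
    r2 = vapply(found, function(m) m$pos[2], 0),
    energy_eV = vapply(found, function(m) m$energy, 0),
    grad_norm = vapply(found, function(m) m$grad_norm, 0))
  out[order(out$energy_eV), ]
}

## generic saddle refinement on any surface function: eigenvector-following
## with finite-difference gradient/Hessian
.refine_saddle_fd <- function(sf, start, maxit = 200, h = 1e-4) {
  gfd <- function(p) drop(sf$g(p[1], p[2]))
  Hfd <- function(p) {
    g0x <- gfd(c(p[1] + h, p[2])); g1x <- gfd(c(p[1] - h, p[2]))
    g0y <- gfd(c(p[1], p[2] + h)); g1y <- gfd(c(p[1], p[2] - h))
    H <- rbind((g0x - g1x) / (2 * h), (g0y - g1y) / (2 * h))
    (H + t(H)) / 2
  }
  p <- start
  for (i in seq_len(maxit)) {
    g <- gfd(p)
    if (sqrt(sum(g^2)) < 1e-8) break
    e <- eigen(Hfd(p), symmetric = TRUE)
    gl <- drop(t(e$vectors) %*% g)
    step <- (-gl[1] / max(abs(e$values[1]), 0.3)) * e$vectors[, 1] +
            ( gl[2] / max(abs(e$values[2]), 0.3)) * e$vectors[, 2]
    n <- sqrt(sum(step^2))
    if (n > 0.05) step <- step * 0.05 / n
    p <- tryCatch({ sf$f(p[1] + step[1], p[2] + step[2]); p + step },
                  error = function(e) p)  # stay inside hull
  }
  g <- gfd(p)
  list(pos = p, energy = sf$f(p[1], p[2]), grad_norm = sqrt(sum(g^2)))
}

#' Nudged-elastic-band minimum energy path between two minima
#'
#' Chain-of-states optimisation with the improved tangent, spring forces
#' along the tangent, relaxed by damped projected descent to a
#' perpendicular-force tolerance, then a climbing step that converges the
#' highest image onto the exact saddle by eigenvector following. The initial
#' path runs through the requested zwitterion corner; with `via = "auto"`
#' both zwitterion initialisations are relaxed and the lower-barrier path
#' is returned.
#'
#' @param surf a `dpt_surface` or `dpt_interp`
#' @param from,to path endpoints (verified minima; see [find_minima()])
#' @param n_images number of images including endpoints
#' @param spring_k spring constant, eV/A^2
#' @param via initial-path routing: "auto", "G_minus_C_plus",
#'   "G_plus_C_minus" or "synchronous" (straight line)
#' @param tol force tolerance, eV/A
#' @param max_iter FIRE iteration cap
#' @param geom geometry for classification
#' @param s separation (analytic surfaces)
#' @return a `dpt_mep`: list with `images` (n x 2), `energy` along the
#'   path (eV), `arc` (cumulative arc length), `via` (traversed
#'   zwitterion), refined `saddles`, `converged`, `force_norms`
#' @export
neb_path <- function(surf, from, to, n_images = 32, spring_k = 1,
                     via = c("auto", "G_minus_C_plus", "G_plus_C_minus",
                             "synchronous"),
                     tol = 5e-3, max_iter = 20000, geom = geometry_refs(),
                     s = 0) {
  via <- match.arg(via)
  sf <- as_surface_fun(surf, s = s)
  if (via == "auto") {
    a <- neb_path(surf, from, to, n_images, spring_k, "G_minus_C_plus",
                  tol, max_iter, geom, s)
    b <- tryCatch(neb_path(surf, from, to, n_images, spring_k,
                           "G_plus_C_minus", tol, max_iter, geom, s),
                  error = function(e) NULL)
    if (is.null(b)) return(a)
    return(if (max(b$energy) < max(a$energy)) b else a)
  }
  pos <- state_positions(geom)
  mid <- switch(via,
                G_minus_C_plus = pos$G_minus_C_plus,
                G_plus_C_minus = pos$G_plus_C_minus,
                synchronous = (from + to) / 2)
  half <- ceiling(n_images / 2)
  path <- rbind(
    cbind(seq(from[1], mid[1], length.out = half),
          seq(from[2], mid[2], length.out = half)),
    cbind(seq(mid[1], to[1], length.out = n_images - half + 1),
          seq(mid[2], to[2], length.out = n_images - half + 1))[-1, ])
  ## keep images inside the physically relevant box: the compression walls
  ## start at R - 0.93, no stationary point lies beyond them
  lo <- sf$domain[1]
  hi1 <- min(sf$domain[2], geom$R_NN - 0.93 + 0.20)
  hi2 <- min(sf$domain[2], geom$R_ON - 0.93 + 0.20)
  clamp <- function(P) cbind(pmin(pmax(P[, 1], lo), hi1),
                             pmin(pmax(P[, 2], lo), hi2))
  path <- clamp(path)
  n <- nrow(path)

  energies <- function(P) sf$f(P[, 1], P[, 2])
  grads <- function(P) sf$g(P[, 1], P[, 2])

  neb_forces <- function(P, climb_at) {
    E <- energies(P)
    G <- grads(P)
    F <- matrix(0, n, 2)
    fmax <- 0
    for (i in 2:(n - 1)) {
      dp <- P[i + 1, ] - P[i, ]
      dm <- P[i, ] - P[i - 1, ]
      ## improved tangent (upwind in energy)
      tau <- if (E[i + 1] > E[i] && E[i] > E[i - 1]) dp
      else if (E[i + 1] < E[i] && E[i] < E[i - 1]) dm
      else {
        dEmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        dEmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        if (E[i + 1] > E[i - 1]) dp * dEmax + dm * dEmin
        else dp * dEmin + dm * dEmax
      }
      tn <- sqrt(sum(tau^2))
      if (tn < 1e-12) { tau <- dp + dm; tn <- sqrt(sum(tau^2)) }
      if (tn < 1e-12) { tau <- c(1, 0); tn <- 1 }
      tau <- tau / tn
      g <- G[i, ]
      if (!is.null(climb_at) && i == climb_at) {
        F[i, ] <- -g + 2 * sum(g * tau) * tau
      } else {
        f_perp <- -(g - sum(g * tau) * tau)
        f_spr <- spring_k * (sqrt(sum(dp^2)) - sqrt(sum(dm^2))) * tau
        F[i, ] <- f_perp + f_spr
      }
      fmax <- max(fmax, sqrt(sum(F[i, ]^2)))
    }
    list(F = F, fmax = fmax, E = E)
  }

  ## damped relaxation with a displacement cap and mild step adaptation:
  ## robust on stiff surfaces where more aggressive optimisers overshoot
  relax <- function(P, climb_at, iters, step = 2e-3, cap = 5e-3) {
    fmax <- Inf
    for (it in seq_len(iters)) {
      nf <- neb_forces(P, climb_at)
      fmax <- nf$fmax
      if (fmax < tol) break
      dP <- step * nf$F
      dn <- sqrt(rowSums(dP^2))
      over <- dn > cap
      if (any(over)) dP[over, ] <- dP[over, ] * (cap / dn[over])
      P <- clamp(P + dP)
    }
    list(P = P, fmax = fmax, iters = it)
  }

  ## phase 1: plain NEB to the force tolerance; a localized kink can
  ## flip-flop at the working step, so finish with a finer-step stage
  r1 <- relax(path, NULL, max_iter)
  if (r1$fmax >= tol) r1 <- relax(r1$P, NULL, max_iter, step = 4e-4,
                                  cap = 1e-3)
  P <- r1$P
  E <- energies(P)
  if (r1$fmax >= tol) {
    fn <- vapply(2:(n - 1), function(i)
      sqrt(sum(neb_forces(P, NULL)$F[i, ]^2)), 0)
    stop(sprintf(paste0("NEB non-convergence: max force %.2e eV/A after %d ",
                        "iterations; per-image force norms: %s"),
                 r1$fmax, r1$iters,
                 paste(sprintf("%.1e", fn), collapse = " ")))
  }

  ## climbing step: refine every interior energy maximum of the chain to a
  ## true saddle by eigenvector following, and move the highest image onto
  ## its saddle (the converged climbing image)
  locmax <- which(diff(sign(diff(E))) == -2) + 1
  ci <- which.max(E[2:(n - 1)]) + 1
  locmax <- union(locmax, ci)
  saddles <- lapply(sort(locmax), function(i)
    .refine_saddle_fd(sf, P[i, ]))
  top <- which.max(vapply(saddles, function(sd) sd$energy, 0))
  P[ci, ] <- saddles[[top]]$pos
  E <- energies(P)
  sads <- do.call(rbind, lapply(saddles, function(sd)
    data.frame(r1 = sd$pos[1], r2 = sd$pos[2], energy_eV = sd$energy,
               grad_norm = sd$grad_norm)))

  ## classify by the quadrant the path interior actually visits
  qi <- .quadrant_label(P[, 1], P[, 2], geom)
  via_found <- if (any(qi == "G_minus_C_plus")) "G_minus_C_plus"
  else if (any(qi == "G_plus_C_minus")) "G_plus_C_minus"
  else "synchronous"

  arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  structure(list(images = P, energy = E, arc = arc, via = via_found,
                 saddles = sads, converged = TRUE, fmax = r1$fmax,
                 climbing_image = ci, n_images = n, spring_k = spring_k,
                 endpoints = rbind(from, to), s = s),
            class = "dpt_mep")
}

#' @export
print.dpt_mep <- function(x, ...) {
  cat(sprintf("<dpt_mep> %d images via %s; barrier %.3f eV (rel. start)\n",
              x$n_images, x$via, max(x$energy) - x$energy[1]))
  if (nrow(x$saddles))
    cat(sprintf("  saddles at: %s eV (abs)\n",
                paste(sprintf("%.3f", x$saddles$energy_eV), collapse = ", ")))
  invisible(x)
}
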