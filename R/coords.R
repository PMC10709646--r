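## Proton coordinates, hydrogen-bond distances and the collective
## coordinate lambda.
##
## The two reaction coordinates are the donor-hydrogen distances of the two
## hydrogen bonds that carry the double proton transfer:
##   r1: N1(G)-H ... N3(C)   (the central bond; proton "1")
##   r2: N4(C)-H ... O6(G)   (the outer bond;  proton "2")
## Hydrogen bonds are treated as collinear, so each bond contributes two
## distances, donor-H and H-acceptor, which sum to the donor-acceptor
## length. The third (N2-O2) bond is a spectator and is not modelled.

#' Geometry references for the two reactive hydrogen bonds
#'
#' Defines the donor-acceptor lengths, the covalent donor-H distance, the
#' sampled domain of the proton coordinates, and the canonical (GC) and
#' tautomeric (G*C*) reference values of the four distance reaction
#' coordinates used to build the collective coordinate lambda.
#'
#' @param R_NN donor-acceptor length of the central N1-N3 bond, Angstrom
#' @param R_ON donor-acceptor length of the outer N4-O6 bond, Angstrom
#' @param r_cov covalent donor-H distance, Angstrom (same for both bonds)
#' @param domain sampled range of each proton coordinate, Angstrom
#' @param separation optional [separation_spec()]; its per-bond increments
#'   are added to `R_NN` and `R_ON`
#' @return an object of class `dpt_geometry`: a list with the bond lengths,
#'   domain, and the 4-vector distance references `d_GC` and `d_GstarCstar`
#'   (order: donor-H and H-acceptor of bond 1, then of bond 2)
#' @export
geometry_refs <- function(R_NN = 2.93, R_ON = 2.95, r_cov = 1.03,
                          domain = c(0.9, 2.5), separation = NULL) {
  if (!is.null(separation)) {
    stopifnot(inherits(separation, "dpt_separation"))
    R_NN <- R_NN + separation$increments[1]
    R_ON <- R_ON + separation$increments[2]
  }
  stopifnot(R_NN > 2 * r_cov * 0.9, R_ON > 2 * r_cov * 0.9,
            domain[1] < r_cov, domain[2] > max(R_NN, R_ON) - r_cov)
  g <- list(
    R_NN = R_NN, R_ON = R_ON, r_cov = r_cov, domain = domain,
    ## canonical: both protons on their donors; tautomeric: both transferred
    d_GC         = c(r_cov, R_NN - r_cov, r_cov, R_ON - r_cov),
    d_GstarCstar = c(R_NN - r_cov, r_cov, R_ON - r_cov, r_cov)
  )
  class(g) <- "dpt_geometry"
  g
}

#' Base-pair separation specification
#'
#' Describes a mechanical opening of the base pair by `s` Angstrom relative
#' to the canonical geometry. In the asymmetric mode (the behaviour seen
#' when the helicase pulls the pair apart, with the third hydrogen bond
#' staying near equilibrium) only the central bond opens; in the uniform
#' mode both reactive bonds share the increment.
#'
#' @param s separation relative to the canonical geometry, Angstrom (>= 0)
#' @param mode "asymmetric" (default; increments `c(s, 0)`) or "uniform"
#'   (increments `c(s, s)`)
#' @return object of class `dpt_separation`
#' @export
separation_spec <- function(s, mode = c("asymmetric", "uniform")) {
  mode <- match.arg(mode)
  if (s < 0) stop("separation s must be >= 0")
  inc <- if (mode == "asymmetric") c(s, 0) else c(s, s)
  structure(list(s = s, mode = mode, increments = inc),
            class = "dpt_separation")
}

#' Map proton coordinates to the four hydrogen-bond distances
#'
#' Under the collinear bond model the four distance reaction coordinates
#' are d1 = r1, d2 = R_NN - r1, d3 = r2, d4 = R_ON - r2.
#'
#' @param r1,r2 proton coordinates, Angstrom (vectors of equal length)
#' @param geom a [geometry_refs()] object
#' @return a matrix with columns d1..d4 (Angstrom)
#' @export
to_distances <- function(r1, r2, geom = geometry_refs()) {
  check_domain(r1, r2, geom)
  if (any(r1 >= geom$R_NN) || any(r2 >= geom$R_ON))
    stop("geometry error: proton coordinate beyond its donor-acceptor length")
  cbind(d1 = r1, d2 = geom$R_NN - r1, d3 = r2, d4 = geom$R_ON - r2)
}

#' Recover proton coordinates from the four distances
#'
#' Inverse of [to_distances()] on the collinear model (d1 and d3 are the
#' proton coordinates; d2 and d4 are checked for consistency).
#'
#' @param d matrix or 4-vector of distances as produced by [to_distances()]
#' @param geom a [geometry_refs()] object
#' @param tol consistency tolerance on d1+d2 and d3+d4, Angstrom
#' @return a two-column matrix (r1, r2)
#' @export
from_distances <- function(d, geom = geometry_refs(), tol = 1e-8) {
  d <- rbind(d)
  if (ncol(d) != 4) stop("expected four distances per row")
  if (any(abs(d[, 1] + d[, 2] - geom$R_NN) > tol) ||
      any(abs(d[, 3] + d[, 4] - geom$R_ON) > tol))
    stop("geometry error: distances inconsistent with collinear bond lengths")
  cbind(r1 = d[, 1], r2 = d[, 3])
}

#' Project the four distances onto the collective coordinate lambda
#'
#' lambda is the average relative change of the four distance reaction
#' coordinates from their canonical references:
#' lambda = mean_i (d_i - d_i^GC) / (d_i^G*C* - d_i^GC).
#' It equals 0 at the canonical GC references and 1 at the tautomeric
#' references, and is affine in each distance. Both single-transfer
#' zwitterions project to lambda = 1/2.
#'
#' @param d matrix of four distances (columns d1..d4) or a 4-vector
#' @param geom a [geometry_refs()] object
#' @return numeric vector of lambda values
#' @export
project_lambda <- function(d, geom = geometry_refs()) {
  d <- rbind(d)
  span <- geom$d_GstarCstar - geom$d_GC
  if (any(abs(span) <= 0.05))
    stop("configuration error: degenerate lambda references (|d_G*C* - d_GC| <= 0.05 A)")
  unname(rowMeans(sweep(sweep(d, 2, geom$d_GC), 2, span, "/")))
}

#' lambda directly from proton coordinates
#'
#' Convenience composition of [to_distances()] and [project_lambda()],
#' without the domain check (used on trajectory frames which may touch the
#' reflective boundaries).
#' @param r1,r2 proton coordinates, Angstrom
#' @param geom a [geometry_refs()] object
#' @return numeric vector of lambda values
#' @export
lambda_of <- function(r1, r2, geom = geometry_refs()) {
  u1 <- (r1 - geom$r_cov) / (geom$R_NN - 2 * geom$r_cov)
  u2 <- (r2 - geom$r_cov) / (geom$R_ON - 2 * geom$r_cov)
  (u1 + u2) / 2
}

## shared domain guard
check_domain <- function(r1, r2, geom) {
  lo <- geom$domain[1]; hi <- geom$domain[2]
  if (any(r1 < lo | r1 > hi | r2 < lo | r2 > hi))
    stop(sprintf("domain error: proton coordinates outside [%.2f, %.2f] A", lo, hi))
  invisible(TRUE)
}

## per-proton transfer progress (0 = on donor, 1 = transferred)
transfer_progress <- function(r1, r2, geom = geometry_refs()) {
  cbind(u1 = (r1 - geom$r_cov) / (geom$R_NN - 2 * geom$r_cov),
        u2 = (r2 - geom$r_cov) / (geom$R_ON - 2 * geom$r_cov))
}
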