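# Nudged elastic band path optimization on analytic potentials, with the
# simulated-annealing protocol used for partial NEB refinement of
# conformational transition paths: springs (k = 10 energy/length^2 analog)
# between neighboring replicas, a heat/hold/cool temperature schedule, and
# convergence when the band moves by less than delta-RMSD = 0.3 length
# units between annealing iterations.

#' Analytic test potentials
#'
#' `double_well`: V(x) = (x^2 - 1)^2 (1D, barrier top at x = 0).
#' `quadratic_bowl`: V(x) = 0.5 |x|^2 in any dimension.
#' `two_gaussian_wells`: 2D surface with two Gaussian wells and an off-axis
#' saddle between them.
#'
#' @param name potential name
#' @return object of class `helimsm_potential` with `energy(x)` and
#'   `gradient(x)`
#' @export
toy_potential <- function(name = c("double_well", "quadratic_bowl",
                                   "two_gaussian_wells")) {
  name <- match.arg(name)
  pot <- switch(name,
    double_well = list(
      energy = function(x) (x[1]^2 - 1)^2,
      gradient = function(x) c(4 * x[1] * (x[1]^2 - 1)),
      dim = 1L),
    quadratic_bowl = list(
      energy = function(x) 0.5 * sum(x^2),
      gradient = function(x) x,
      dim = NA_integer_),
    two_gaussian_wells = list(
      energy = function(x) {
        -exp(-((x[1] + 1)^2 + x[2]^2)) -
          exp(-((x[1] - 1)^2 + (x[2] - 0.8)^2)) +
          0.05 * (x[1]^2 + x[2]^2)
      },
      gradient = function(x) {
        g1 <- exp(-((x[1] + 1)^2 + x[2]^2))
        g2 <- exp(-((x[1] - 1)^2 + (x[2] - 0.8)^2))
        c(2 * (x[1] + 1) * g1 + 2 * (x[1] - 1) * g2 + 0.1 * x[1],
          2 * x[2] * g1 + 2 * (x[2] - 0.8) * g2 + 0.1 * x[2])
      },
      dim = 2L))
  structure(c(pot, list(name = name)), class = "helimsm_potential")
}

#' Construct a band of replicas
#'
#' @param start,end endpoint coordinates (D-vectors); endpoints stay fixed
#' @param n_replicas number of replicas including endpoints (default 60)
#' @return object of class `helimsm_band` (replicas x D matrix in `x`)
#' @export
new_band <- function(start, end, n_replicas = 60L) {
  if (n_replicas < 3) stop("need at least 3 replicas")
  D <- length(start)
  stopifnot(length(end) == D)
  w <- seq(0, 1, length.out = n_replicas)
  x <- outer(1 - w, start) + outer(w, end)
  structure(list(x = x, n = n_replicas, D = D,
                 start = start, end = end),
            class = "helimsm_band")
}

#' NEB parameters
#'
#' @param k_spring spring constant between neighboring replicas (default 10,
#'   the energy/length^2 analog of 10 kcal/mol/A^2)
#' @param delta_rmsd_tol convergence threshold on the band delta-RMSD
#'   between annealing iterations (default 0.3)
#' @param n_heat,n_hold,n_cool steps of the heat (0 -> T_max), hold and
#'   cool (T_max -> 0) phases of one annealing iteration
#' @param t_max peak dimensionless temperature
#' @param step_size damped-dynamics step size
#' @param max_anneal cap on annealing iterations
#' @param restrained optional index subset of coordinates the springs act on
#'   (the "partial" restraint scope); default all
#' @export
neb_params <- function(k_spring = 10, delta_rmsd_tol = 0.3, n_heat = 60L,
                       n_hold = 30L, n_cool = 150L, t_max = 0.05,
                       step_size = 0.02, max_anneal = 60L,
                       restrained = NULL) {
  stopifnot(k_spring > 0, delta_rmsd_tol > 0)
  list(k_spring = k_spring, delta_rmsd_tol = delta_rmsd_tol,
       n_heat = n_heat, n_hold = n_hold, n_cool = n_cool, t_max = t_max,
       step_size = step_size, max_anneal = max_anneal,
       restrained = restrained)
}

#' NEB force on every replica
#'
#' True force with its tangential component removed, plus a spring force
#' along the local tangent proportional to the difference of neighbor
#' spacings. Tangents are normalized central differences of the neighboring
#' replicas. Endpoint forces are zero.
#'
#' @param band `helimsm_band`
#' @param potential `helimsm_potential`
#' @param params from [neb_params()]
#' @return replicas x D force matrix
#' @export
neb_force <- function(band, potential, params = neb_params()) {
  x <- band$x
  n <- band$n; D <- band$D
  F <- matrix(0, n, D)
  rest <- if (is.null(params$restrained)) seq_len(D) else params$restrained
  for (i in 2:(n - 1)) {
    tang <- x[i + 1, ] - x[i - 1, ]
    tn <- sqrt(sum(tang^2))
    if (tn < 1e-12) stop("degenerate band: coincident neighbors at replica ", i)
    tang <- tang / tn
    g <- -potential$gradient(x[i, ])
    g_perp <- g - sum(g * tang) * tang
    d_fwd <- sqrt(sum((x[i + 1, ] - x[i, ])[rest]^2))
    d_bwd <- sqrt(sum((x[i, ] - x[i - 1, ])[rest]^2))
    f_spring <- params$k_spring * (d_fwd - d_bwd) * tang
    F[i, ] <- g_perp + f_spring
  }
  F
}

#' Delta-RMSD between two bands
#'
#' RMSD over all movable replica coordinates; replicas live in a shared
#' frame, so no superposition is applied.
#'
#' @param previous,current `helimsm_band` objects of the same shape
#' @return scalar RMSD
#' @export
band_delta_rmsd <- function(previous, current) {
  if (!all(dim(previous$x) == dim(current$x))) stop("band shape mismatch")
  mov <- 2:(previous$n - 1)
  d <- previous$x[mov, , drop = FALSE] - current$x[mov, , drop = FALSE]
  sqrt(mean(d^2))
}

#' Optimize a band with simulated annealing
#'
#' Repeats annealing iterations (heat 0 -> T_max, hold, cool -> 0; damped
#' dynamics on the NEB force with Gaussian kicks scaled by sqrt(T)) until
#' the band delta-RMSD between iterations drops below the threshold or the
#' iteration cap is reached. Endpoints never move.
#'
#' @param band `helimsm_band`
#' @param potential `helimsm_potential`
#' @param params from [neb_params()]
#' @param seed RNG seed for the thermal kicks
#' @return list with `band`, `converged`, `iterations`, `energy_profile`
#' @export
optimize_band <- function(band, potential, params = neb_params(), seed = 1L) {
  set.seed(seed)
  n <- band$n; D <- band$D
  mov <- 2:(n - 1)
  temps <- c(seq(0, params$t_max, length.out = params$n_heat),
             rep(params$t_max, params$n_hold),
             seq(params$t_max, 0, length.out = params$n_cool))
  converged <- FALSE
  iter <- 0L
  for (outer_it in seq_len(params$max_anneal)) {
    iter <- outer_it
    prev <- band
    for (temp in temps) {
      F <- neb_force(band, potential, params)
      kick <- if (temp > 0)
        matrix(rnorm(length(mov) * D, sd = sqrt(temp)), length(mov), D)
      else 0
      band$x[mov, ] <- band$x[mov, ] + params$step_size * F[mov, ] +
        sqrt(params$step_size) * kick
      if (!all(is.finite(band$x))) stop("non-finite coordinates during annealing")
      if (!all(is.finite(vapply(seq_len(n), function(i)
        potential$energy(band$x[i, ]), 0))))
        stop("non-finite energy during optimization")
    }
    if (band_delta_rmsd(prev, band) < params$delta_rmsd_tol) {
      converged <- TRUE
      break
    }
  }
  profile <- vapply(seq_len(n), function(i) potential$energy(band$x[i, ]), 0)
  list(band = band, converged = converged, iterations = iter,
       energy_profile = profile)
}
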