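#' Parameters of the reaction-diffusion relaxation oscillator
#'
#' A FitzHugh-Nagumo-type oscillator: a fast bistable activator `u` with
#' diffusion, and a slow recovery variable `w` whose rate `eps` sets the
#' period. With the recovery nullcline crossing the middle branch of the
#' cubic, every point oscillates autonomously; a pacemaker is a disk where
#' the slow drive `eps` is increased, shortening the local period so that
#' it entrains its surroundings through genuine trigger waves. This model
#' is the validation counterpart of the kinematic generator: waves here
#' emerge from the dynamics instead of being imposed.
#'
#' @param D_um2_per_min Activator diffusion coefficient.
#' @param k_fast Rate scale of the fast subsystem.
#' @param a,b Recovery nullcline offset and slope (`a = 0`, `b = 0.8` put
#'   the fixed point on the middle branch, i.e. oscillatory).
#' @param eps Baseline slow rate (1/min); the bulk period scales as `1/eps`.
#' @param eps_pacemaker_factor Multiplier of `eps` inside the pacemaker
#'   disk (> 1 shortens the local period).
#' @param pacemaker_xy_um,pacemaker_radius_um Pacemaker disk, or `NULL` for
#'   a homogeneous field.
#' @param dt_min Euler time step; must satisfy the diffusion stability bound
#'   `dt <= h^2 / (4 D)`.
#' @param save_interval_min Frame interval of the returned movie.
#' @param init_noise_sd SD of initial-condition noise on `u`.
#' @param init_excited_radius_um When > 0, the activator starts excited
#'   inside a central disk of this radius. Together with `eps = 0` (frozen
#'   recovery) this yields a pure bistable front whose speed scales as the
#'   square root of the diffusion coefficient -- the classical benchmark for
#'   the integrator.
#' @return A `pde_params` object.
#' @export
pde_params <- function(D_um2_per_min = 5, k_fast = 3, a = 0, b = 0.8,
                       eps = 0.2, eps_pacemaker_factor = 2,
                       pacemaker_xy_um = NULL, pacemaker_radius_um = 5,
                       dt_min = 0.02, save_interval_min = 0.5,
                       init_noise_sd = 0, init_excited_radius_um = 0) {
  structure(list(D_um2_per_min = D_um2_per_min, k_fast = k_fast, a = a, b = b,
                 eps = eps, eps_pacemaker_factor = eps_pacemaker_factor,
                 pacemaker_xy_um = pacemaker_xy_um,
                 pacemaker_radius_um = pacemaker_radius_um,
                 dt_min = dt_min, save_interval_min = save_interval_min,
                 init_noise_sd = init_noise_sd,
                 init_excited_radius_um = init_excited_radius_um),
            class = "pde_params")
}

#' Simulate the reaction-diffusion relaxation oscillator
#'
#' Explicit Euler integration of the two-variable oscillator of
#' [pde_params()] on the well grid, with zero-flux boundaries. The step
#' size is checked against the diffusion stability bound before
#' integrating. The activator field is returned as a movie so that fronts
#' can be analysed with [radial_kymograph()] and [fit_front_speed()]
#' (the activator rises at a front, so fit with `invert = TRUE`).
#'
#' @param params A [pde_params()].
#' @param geometry A [well_geometry()]; `pixel_size_um` is the grid spacing.
#' @param duration_min Simulated time.
#' @param seed RNG seed for initial-condition noise.
#' @return A [movie()] with channel `activator`.
#' @export
simulate_relaxation_oscillator_pde <- function(params, geometry, duration_min,
                                               seed = 1L) {
  stopifnot(inherits(params, "pde_params"), duration_min > 0)
  h <- geometry$pixel_size_um
  if (params$D_um2_per_min > 0 &&
      params$dt_min > h^2 / (4 * params$D_um2_per_min))
    stop(sprintf("unstable time step: dt must be <= h^2/(4D) = %.4g min",
                 h^2 / (4 * params$D_um2_per_min)))
  nr <- geometry$height_px; nc <- geometry$width_px
  eps <- matrix(params$eps, nr, nc)
  if (!is.null(params$pacemaker_xy_um)) {
    co <- pixel_coords_um(geometry)
    disk <- (co$x - params$pacemaker_xy_um[1])^2 +
      (co$y - params$pacemaker_xy_um[2])^2 <= params$pacemaker_radius_um^2
    eps[disk] <- params$eps * params$eps_pacemaker_factor
  }
  u0 <- matrix(-1.2, nr, nc)
  w0 <- matrix(-0.6, nr, nc)
  if (params$init_excited_radius_um > 0) {
    co <- pixel_coords_um(geometry)
    cx <- nc * h / 2; cy <- nr * h / 2
    u0[(co$x - cx)^2 + (co$y - cy)^2 <= params$init_excited_radius_um^2] <- 2
  }
  if (params$init_noise_sd > 0)
    u0 <- u0 + with_local_seed(seed, matrix(rnorm(nr * nc, sd = params$init_noise_sd), nr, nc))
  save_every <- max(1L, round(params$save_interval_min / params$dt_min))
  n_steps <- ceiling(duration_min / params$dt_min)
  n_steps <- (n_steps %/% save_every) * save_every
  u <- fhn_integrate_cpp(u0, w0, eps, geometry$mask, params$a, params$b,
                         params$k_fast, params$D_um2_per_min, h,
                         params$dt_min, n_steps, save_every)
  u <- array(u, c(nr, nc, n_steps / save_every + 1))
  for (f in seq_len(dim(u)[3])) u[, , f][!geometry$mask] <- 0
  movie(list(activator = u + 3),   # shift to keep intensities nonnegative
        pixel_size_um = h,
        frame_interval_min = save_every * params$dt_min)
}
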