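# Coarse-grained fast-pulling-of-ligand (FPL) engine.
#
# A single ligand bead moves by Langevin dynamics in a field of fixed
# Lennard-Jones + Coulomb sites (plain cutoff on both terms) while a
# harmonic spring whose anchor travels at constant speed along the pull
# axis drags it out of the pocket. Internal units are kJ/mol, nm, ps and
# amu; reported affinities are kcal/mol (1 kcal = 4.184 kJ).

#' Define a pull system (fixed sites + ligand bead)
#'
#' @param sites data.frame with columns `x`, `y`, `z` (nm), `eps` (kJ/mol),
#'   `sigma` (nm), `charge` (e); the sites are rigidly fixed, standing in
#'   for a restrained receptor.
#' @param ligand List with `mass` (amu), `charge` (e) and `position`
#'   (length-3, nm). The ligand is a single effective bead at the ligand
#'   centre of mass.
#' @param cutoff Nonbonded cutoff for both LJ and Coulomb terms, nm.
#' @param temperature Thermostat temperature, K.
#' @param friction Langevin friction, ps^-1.
#' @param dielectric Relative dielectric constant.
#' @return Object of class `"pull_system"`.
#' @export
pull_system <- function(sites, ligand = list(mass = 300, charge = 0,
                                             position = c(0, 0, 0)),
                        cutoff = 0.9, temperature = 300, friction = 10,
                        dielectric = 1) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("x", "y", "z", "eps", "sigma", "charge") %in% names(sites)),
            nrow(sites) >= 1, cutoff > 0, temperature >= 0, friction > 0,
            dielectric > 0, ligand$mass > 0, length(ligand$position) == 3)
  if (any(sites$sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(sites$eps < 0)) stop("epsilon must be non-negative", call. = FALSE)
  d <- sqrt(colSums((t(as.matrix(sites[, c("x", "y", "z")])) -
                       ligand$position)^2))
  if (min(d) > cutoff)
    stop("ligand must start inside the cutoff of at least one site",
         call. = FALSE)
  structure(list(sites = sites, ligand = ligand, cutoff = cutoff,
                 temperature = temperature, friction = friction,
                 dielectric = dielectric),
            class = "pull_system")
}

#' @export
print.pull_system <- function(x, ...) {
  cat(sprintf("Pull system: %d fixed site(s), ligand %g amu / %+g e\n",
              nrow(x$sites), x$ligand$mass, x$ligand$charge))
  cat(sprintf("  cutoff %g nm, T = %g K, friction %g ps^-1, dielectric %g\n",
              x$cutoff, x$temperature, x$friction, x$dielectric))
  invisible(x)
}

#' Define a pulling schedule
#'
#' Defaults follow the study's protocol: cantilever spring constant
#' k = 600 kJ/mol/nm^2, pulling speed v = 0.005 nm/ps, pulling force
#' recorded every 0.1 ps and other metrics every 10 ps, with a 100 ps
#' equilibration (stationary anchor) before the pull along +Z.
#'
#' @param k Spring constant, kJ/mol/nm^2.
#' @param v Pulling speed, nm/ps.
#' @param dt Integration timestep, ps (<= 0.005 recommended at the default
#'   friction).
#' @param duration Pulling time, ps; `duration * v` must span the channel.
#' @param equil Equilibration time before the anchor moves, ps (the
#'   bound-state averaging window).
#' @param force_every Force-recording interval, ps.
#' @param metric_every Energy/metric recording interval, ps.
#' @param axis Pull axis (normalised internally).
#' @return Object of class `"pull_schedule"`.
#' @export
pull_schedule <- function(k = 600, v = 0.005, dt = 0.002, duration = 600,
                          equil = 100, force_every = 0.1, metric_every = 10,
                          axis = c(0, 0, 1)) {
  stopifnot(k > 0, v > 0, dt > 0, duration > 0, equil >= 0,
            force_every >= dt, metric_every >= dt, length(axis) == 3,
            sum(axis^2) > 0)
  structure(list(k = k, v = v, dt = dt, duration = duration, equil = equil,
                 force_every = force_every, metric_every = metric_every,
                 axis = axis / sqrt(sum(axis^2))),
            class = "pull_schedule")
}

#' Ligand-receptor interaction energy at a position
#'
#' Pairwise 12-6 Lennard-Jones and Coulomb (1 / (4 pi eps0 dielectric r))
#' over all ligand-site pairs within the cutoff; both terms are exactly
#' zero beyond it.
#'
#' @param system A [pull_system()].
#' @param position Ligand position (length-3, nm); defaults to the system's
#'   initial position.
#' @return Named vector `c(E_cou, E_vdW)` in kJ/mol.
#' @export
interaction_energy <- function(system, position = system$ligand$position) {
  stopifnot(inherits(system, "pull_system"), length(position) == 3)
  .interaction_energy_cpp(as.matrix(system$sites[, c("x", "y", "z")]),
                          system$sites$eps, system$sites$sigma,
                          system$sites$charge, system$ligand$charge,
                          as.numeric(position), system$cutoff,
                          system$dielectric)
}

#' Run one fast-pulling-of-ligand trajectory
#'
#' Langevin (BAOAB) integration at the system temperature; the spring
#' anchor is stationary for `schedule$equil` ps (bound-state window), then
#' moves at `schedule$v` along the pull axis. The spring force
#' `k * (anchor - ligand projection)` is recorded every `force_every` ps
#' and the interaction-energy decomposition every `metric_every` ps.
#' Deterministic for a fixed seed.
#'
#' @param system A [pull_system()].
#' @param schedule A [pull_schedule()].
#' @param seed Integer seed.
#' @return Object of class `"pull_trajectory"`: time series of spring force
#'   (kJ/mol/nm), axial displacement (nm), `E_cou` / `E_vdW` (kJ/mol),
#'   cumulative work `work` (kJ/mol, trapezoidal integral of force times
#'   anchor speed), `F_max` (peak force during the pull), and
#'   `final_position`.
#' @export
run_pull <- function(system, schedule = pull_schedule(), seed = 1) {
  stopifnot(inherits(system, "pull_system"),
            inherits(schedule, "pull_schedule"))
  fe <- max(1L, as.integer(round(schedule$force_every / schedule$dt)))
  me <- max(1L, as.integer(round(schedule$metric_every / schedule$dt)))
  n_eq <- as.integer(round(schedule$equil / schedule$dt))
  n_pull <- as.integer(round(schedule$duration / schedule$dt))
  set.seed(seed)
  out <- .run_pull_cpp(as.matrix(system$sites[, c("x", "y", "z")]),
                       system$sites$eps, system$sites$sigma,
                       system$sites$charge, system$ligand$mass,
                       system$ligand$charge,
                       as.numeric(system$ligand$position), system$cutoff,
                       system$temperature, system$friction,
                       system$dielectric, schedule$k, schedule$v,
                       schedule$dt, n_eq, n_pull, fe, me, schedule$axis,
                       50)
  t_eq <- n_eq * schedule$dt
  v_anchor <- ifelse(out$t_force > t_eq, schedule$v, 0)
  # cumulative trapezoid of F(t) * v(t)
  integrand <- out$force * v_anchor
  dt_f <- diff(out$t_force)
  work <- c(0, cumsum(0.5 * (integrand[-1] + integrand[-length(integrand)]) *
                        dt_f))
  pulling <- out$t_force >= t_eq
  structure(list(time = out$t_force, force = out$force,
                 displacement = out$displacement, work = work,
                 t_metric = out$t_metric, E_cou = out$E_cou,
                 E_vdW = out$E_vdW,
                 F_max = max(out$force[pulling]),
                 final_position = out$final_position,
                 seed = seed, system = system, schedule = schedule),
            class = "pull_trajectory")
}

#' @export
print.pull_trajectory <- function(x, ...) {
  cat(sprintf("FPL trajectory (seed %d): %g ps equil + %g ps pull\n",
              x$seed, x$schedule$equil, x$schedule$duration))
  cat(sprintf("  F_max = %.1f kJ/mol/nm, total work = %.1f kJ/mol\n",
              x$F_max, x$work[length(x$work)]))
  invisible(x)
}

#' @export
plot.pull_trajectory <- function(x, ...) {
  graphics::plot(x$time, x$force, type = "l",
                 xlab = "time (ps)", ylab = "spring force (kJ/mol/nm)", ...)
  graphics::abline(v = x$schedule$equil, lty = 2, col = "grey50")
  invisible(x)
}

#' Pulling work of a trajectory
#'
#' Trapezoidal integral of the recorded spring force times the anchor speed
#' over the trajectory (the anchor is stationary during equilibration, so
#' only the pulling phase contributes).
#'
#' @param result A `"pull_trajectory"`.
#' @return Total work, kJ/mol.
#' @export
pull_work <- function(result) {
  stopifnot(inherits(result, "pull_trajectory"))
  if (!length(result$force)) stop("empty force series", call. = FALSE)
  result$work[length(result$work)]
}

#' Replica-averaged interaction-energy-difference estimate
#'
#' The study's binding estimator over independent pulling replicas: per
#' replica, the bound-state electrostatic and van der Waals interaction
#' energies are averaged over the pre-pull equilibration window and the
#' unbound state over the final 10 percent of the trajectory (where both
#' terms vanish by the cutoff once the ligand has cleared the pocket);
#' Delta E = Delta E_cou + Delta E_vdW = (E^bound - E^unbound) per term,
#' converted to kcal/mol and averaged over replicas (mean +/- SD). A
#' favorable pocket gives negative Delta E.
#'
#' @param results List of `"pull_trajectory"` replicas (the study uses 8).
#' @param unbound_frac Fraction of the trajectory tail used as the unbound
#'   window.
#' @return Object of class `"fpl_estimate"`: `per_replica` data.frame
#'   (`dE_cou`, `dE_vdW`, `dE_total`, kcal/mol), replica means and SDs, and
#'   `vdw_fraction` = |dE_vdW| / (|dE_vdW| + |dE_cou|).
#' @export
estimate_delta_e <- function(results, unbound_frac = 0.1) {
  stopifnot(length(results) >= 1, unbound_frac > 0, unbound_frac < 0.5)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "pull_trajectory"))
    d <- sqrt(colSums((t(as.matrix(r$system$sites[, c("x", "y", "z")])) -
                         r$final_position)^2))
    if (min(d) <= r$system$cutoff)
      stop(sprintf("replica %d ends inside the cutoff: incomplete unbinding",
                   i), call. = FALSE)
    t_eq <- r$schedule$equil
    bound <- r$t_metric <= t_eq
    if (!any(bound)) bound <- seq_along(r$t_metric) == 1
    n <- length(r$t_metric)
    unbound <- seq_len(n) > (1 - unbound_frac) * n
    dE_cou <- (mean(r$E_cou[bound]) - mean(r$E_cou[unbound])) / .KJ_PER_KCAL
    dE_vdW <- (mean(r$E_vdW[bound]) - mean(r$E_vdW[unbound])) / .KJ_PER_KCAL
    data.frame(replica = i, seed = r$seed, dE_cou = dE_cou, dE_vdW = dE_vdW,
               dE_total = dE_cou + dE_vdW)
  })
  per <- do.call(rbind, rows)
  mean_cou <- mean(per$dE_cou)
  mean_vdw <- mean(per$dE_vdW)
  denom <- abs(mean_vdw) + abs(mean_cou)
  structure(list(per_replica = per, n_replicas = nrow(per),
                 dE_cou = mean_cou, sd_cou = stats::sd(per$dE_cou),
                 dE_vdW = mean_vdw, sd_vdW = stats::sd(per$dE_vdW),
                 dE_total = mean(per$dE_total),
                 sd_total = stats::sd(per$dE_total),
                 vdw_fraction = if (denom > 0) abs(mean_vdw) / denom
                                else NA_real_),
            class = "fpl_estimate")
}

#' @export
print.fpl_estimate <- function(x, ...) {
  cat(sprintf("FPL interaction-energy estimate over %d replica(s):\n",
              x$n_replicas))
  fmt <- function(m, s) if (is.na(s)) sprintf("%.2f", m)
                        else sprintf("%.2f +/- %.2f", m, s)
  cat("  Delta E_cou   =", fmt(x$dE_cou, x$sd_cou), "kcal/mol\n")
  cat("  Delta E_vdW   =", fmt(x$dE_vdW, x$sd_vdW), "kcal/mol\n")
  cat("  Delta E_total =", fmt(x$dE_total, x$sd_total), "kcal/mol\n")
  if (!is.na(x$vdw_fraction))
    cat(sprintf("  vdW fraction  = %.0f%%\n", 100 * x$vdw_fraction))
  invisible(x)
}

#' Run replicas and estimate the interaction-energy difference
#'
#' Convenience wrapper: runs `n_replicas` independent trajectories (seeds
#' `seed`, `seed + 1`, ...) and applies [estimate_delta_e()].
#'
#' @param system A [pull_system()].
#' @param schedule A [pull_schedule()].
#' @param n_replicas Number of replicas (the study uses 8).
#' @param seed Base integer seed.
#' @return List with `estimate` (class `"fpl_estimate"`) and `replicas`.
#' @export
fpl_affinity <- function(system, schedule = pull_schedule(), n_replicas = 8,
                         seed = 1) {
  replicas <- lapply(seq_len(n_replicas) - 1L,
                     function(i) run_pull(system, schedule, seed = seed + i))
  list(estimate = estimate_delta_e(replicas), replicas = replicas)
}
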