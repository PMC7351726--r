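# The coarse-grained pulling engine and the interaction-energy estimator.

single_site <- function(eps = 20, sigma = 0.35, q_site = 0, q_lig = 0,
                        temperature = 300, at = NULL) {
  rmin <- 2^(1 / 6) * sigma
  pull_system(data.frame(x = 0, y = 0, z = -rmin, eps = eps, sigma = sigma,
                         charge = q_site),
              ligand = list(mass = 300, charge = q_lig,
                            position = at %||% c(0, 0, 0)),
              temperature = temperature)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("interaction energy obeys the LJ closed form and the cutoff", {
  sys <- single_site(eps = 20, sigma = 0.35)
  # ligand at the LJ minimum distance: E_vdW = -eps
  expect_equal(unname(interaction_energy(sys)["E_vdW"]), -20,
               tolerance = 1e-12)
  # at r = sigma the LJ energy crosses zero
  e <- interaction_energy(sys, c(0, 0, 0.35 - 2^(1 / 6) * 0.35))
  expect_equal(unname(e["E_vdW"]), 0, tolerance = 1e-10)
  # beyond the cutoff both terms vanish exactly
  e <- interaction_energy(sys, c(0, 0, 1.0))
  expect_identical(unname(e), c(0, 0))
  expect_error(interaction_energy(sys, c(0, 0, -2^(1 / 6) * 0.35)),
               "singularity")
})

test_that("interaction energy matches direct summation on random systems", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(5:100, 1)
    sites <- data.frame(x = stats::runif(n, -1, 1),
                        y = stats::runif(n, -1, 1),
                        z = stats::runif(n, -1, 1),
                        eps = stats::runif(n, 0, 30),
                        sigma = stats::runif(n, 0.2, 0.5),
                        charge = stats::runif(n, -0.5, 0.5))
    # keep at least one site within the cutoff of the origin
    sites$x[1] <- 0.3; sites$y[1] <- 0; sites$z[1] <- 0
    sys <- pull_system(sites, ligand = list(mass = 300, charge = 0.25,
                                            position = c(0, 0, 0)),
                       dielectric = 2)
    got <- interaction_energy(sys)
    want <- oracle_energy(sys)
    expect_equal(unname(got["E_cou"]), unname(want["E_cou"]),
                 tolerance = 1e-10)
    expect_equal(unname(got["E_vdW"]), unname(want["E_vdW"]),
                 tolerance = 1e-10)
  }
})

test_that("a force-free ligand at T = 0 tracks the anchor at friction lag", {
  sys <- single_site(eps = 0, sigma = 0.3, temperature = 0)
  sch <- pull_schedule(duration = 200, equil = 20)
  r <- run_pull(sys, sch, seed = 1)
  # overdamped steady state: spring force balances friction, F = gamma m v
  f_ss <- sys$friction * sys$ligand$mass * sch$v  # 15 kJ/mol/nm
  tail_f <- r$force[r$time > 150]
  expect_equal(mean(tail_f), f_ss, tolerance = 0.01)
  # work is friction work only: F_ss * v * duration
  expect_equal(pull_work(r), f_ss * sch$v * sch$duration, tolerance = 0.05)
  # displacement tracks the anchor travel
  expect_equal(max(r$displacement), sch$v * sch$duration, tolerance = 0.05)
})

test_that("trajectories are bitwise deterministic under a fixed seed", {
  sys <- synthetic_pocket(seed = 1, epsilon = 8, site_charges = 0.2,
                          ligand_charge = -0.2)
  sch <- pull_schedule(duration = 150, equil = 20)
  a <- run_pull(sys, sch, seed = 42)
  b <- run_pull(sys, sch, seed = 42)
  expect_identical(a$force, b$force)
  expect_identical(a$E_vdW, b$E_vdW)
  c <- run_pull(sys, sch, seed = 43)
  expect_false(identical(a$force, c$force))
})

test_that("recorded work equals the trapezoidal force integral", {
  sys <- synthetic_pocket(seed = 2, epsilon = 10)
  sch <- pull_schedule(duration = 150, equil = 20)
  r <- run_pull(sys, sch, seed = 7)
  v <- ifelse(r$time > sch$equil, sch$v, 0)
  integrand <- r$force * v
  w <- c(0, cumsum(0.5 * (integrand[-1] + integrand[-length(integrand)]) *
                     diff(r$time)))
  expect_equal(r$work, w, tolerance = 1e-9)
  expect_equal(pull_work(r), w[length(w)], tolerance = 1e-12)
})

test_that("deeper wells need larger rupture forces", {
  sch <- pull_schedule(duration = 400, equil = 50)
  fmax <- function(eps) {
    sys <- synthetic_pocket(seed = 1, epsilon = eps)
    mean(vapply(1:8, function(s)
      run_pull(sys, sch, seed = s)$F_max, 0))
  }
  expect_gt(fmax(40), fmax(5))
})

test_that("the energy decomposition identity holds per replica exactly", {
  sys <- synthetic_pocket(seed = 3, epsilon = 12,
                          site_charges = c(-0.3, 0.1, 0.1, 0.1),
                          ligand_charge = 0.25)
  out <- fpl_affinity(sys, pull_schedule(duration = 500, equil = 100),
                      n_replicas = 4, seed = 11)
  per <- out$estimate$per_replica
  expect_identical(per$dE_total, per$dE_cou + per$dE_vdW)
  expect_true(all(is.finite(per$dE_total)))
  expect_gte(out$estimate$sd_total, 0)
  # favorable pocket: bound state is attractive, Delta E negative
  expect_lt(out$estimate$dE_total, 0)
})

test_that("zero-charge pockets give exactly zero electrostatic change", {
  sys <- synthetic_pocket(seed = 4, epsilon = 10, site_charges = 0,
                          ligand_charge = 0)
  out <- fpl_affinity(sys, pull_schedule(duration = 500, equil = 100),
                      n_replicas = 3, seed = 5)
  expect_identical(out$estimate$per_replica$dE_cou, rep(0, 3))
  expect_equal(out$estimate$vdw_fraction, 1)
})

test_that("doubling the well depth doubles the vdW change within spread", {
  sch <- pull_schedule(duration = 500, equil = 100)
  e1 <- fpl_affinity(synthetic_pocket(seed = 1, epsilon = 10), sch,
                     n_replicas = 8, seed = 21)$estimate
  e2 <- fpl_affinity(synthetic_pocket(seed = 1, epsilon = 20), sch,
                     n_replicas = 8, seed = 21)$estimate
  ratio <- e2$dE_vdW / e1$dE_vdW
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("incomplete unbinding is reported as an error", {
  sys <- synthetic_pocket(seed = 1, epsilon = 10)
  short <- pull_schedule(duration = 40, equil = 20)  # never leaves the pocket
  r <- run_pull(sys, short, seed = 1)
  expect_error(estimate_delta_e(list(r)), "incomplete unbinding")
})

test_that("replica-mean affinity magnitude is monotone in well depth", {
  sch <- pull_schedule(duration = 400, equil = 60)
  depths <- c(5, 10, 20, 40)
  means <- vapply(depths, function(eps) {
    sys <- synthetic_pocket(seed = 1, epsilon = eps)
    est <- fpl_affinity(sys, sch, n_replicas = 8, seed = 31)$estimate
    abs(est$dE_total)
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_equal(stats::cor(depths, means, method = "spearman"), 1)
  # the correlation machinery recovers the planted monotone relation
  expect_gt(pearson_r(depths, means), 0.9)
})
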