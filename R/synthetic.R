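# Synthetic inputs with known ground truth: planted-interaction complexes,
# dock-score/IC50 datasets with controlled linear structure, and
# Lennard-Jones + Coulomb binding pockets for the pulling engine.
#
# All generators are deterministic under an explicit integer seed
# (R's default Mersenne-Twister stream, seeded per call).

# Octahedral direction budget for planted hydrogen bonds: 90 degree
# separations keep every non-partner donor/acceptor pair beyond the
# detection cutoff with a wide margin.
.HB_DIRECTIONS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

.unit <- function(v) v / sqrt(sum(v^2))

.pdb_line <- function(type, serial, name, resname, chain, resno, xyz,
                      element) {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Generate a protein-ligand complex with a planted fingerprint
#'
#' Builds a PDB-format complex around a small ligand at the origin:
#' `n_hbonds` hydrogen bonds planted on `n_hbond_residues` receptor
#' residues (ligand N-H donors aimed at carboxylate/backbone oxygens at
#' 2.75-3.05 A, collinear D-H...A), `n_contacts` further residues whose
#' nearest carbon sits 4.2-4.7 A from the ligand, and `n_decoys` residues
#' entirely beyond 6.2 A. All planted geometries satisfy the default
#' detection criteria with margin (>= 0.2 A, >= 10 degrees), and decoys
#' violate them with margin, so the detectors of [fingerprint()] recover
#' the ground truth exactly.
#'
#' @param seed Integer seed; the same seed yields byte-identical PDB text.
#' @param n_hbonds Number of planted hydrogen bonds (0-6).
#' @param n_hbond_residues Number of receptor residues carrying them
#'   (each takes 1 or 2 bonds); defaults to one residue per bond.
#' @param n_contacts Contact-shell residues beyond the H-bond set.
#' @param n_decoys Residues planted beyond the contact radius.
#' @param jitter Direction jitter amplitude, Angstrom-scale (kept small so
#'   planted margins survive).
#' @return Object of class `"synthetic_complex"`: list with `pdb`
#'   (character lines), `truth` (ligand id, n_hbonds, residue label sets)
#'   and `spec`.
#' @examples
#' sc <- synthetic_complex(seed = 1, n_hbonds = 3, n_contacts = 5)
#' fp <- fingerprint(parse_complex(sc$pdb, "LIG"))
#' identical(fp$n_hbonds, sc$truth$n_hbonds)
#' @export
synthetic_complex <- function(seed, n_hbonds = 3,
                              n_hbond_residues = min(n_hbonds, 6L),
                              n_contacts = 5, n_decoys = 4, jitter = 0.1) {
  stopifnot(n_hbonds >= 0, n_contacts >= 0, n_decoys >= 0, jitter >= 0,
            jitter <= 0.3)
  if (n_hbonds > 0) {
    if (n_hbond_residues < 1 || n_hbond_residues > n_hbonds ||
        n_hbonds > 2 * n_hbond_residues)
      stop("each H-bond residue must carry 1 or 2 planted bonds",
           call. = FALSE)
  } else n_hbond_residues <- 0L
  if (n_hbonds > nrow(.HB_DIRECTIONS) || n_contacts + n_decoys > 60)
    stop("infeasible geometry: interface overcrowded", call. = FALSE)
  set.seed(seed)

  lig <- list()  # each: list(name, element, xyz)
  add_lig <- function(name, element, xyz)
    lig[[length(lig) + 1]] <<- list(name = name, element = element, xyz = xyz)
  add_lig("C1", "C", c(0, 0, 0))
  add_lig("C2", "C", 1.45 * .unit(c(1, 1, 1)))
  add_lig("C3", "C", 1.45 * .unit(c(-1, -1, -1)))

  residues <- list()  # each: list(resname, resno, atoms=list(name, element, xyz))
  resno <- 100L

  # planted hydrogen bonds: ligand N-H ... O(receptor), collinear
  if (n_hbonds > 0) {
    owner <- rep(seq_len(n_hbond_residues), length.out = n_hbonds)
    acc <- vector("list", n_hbond_residues)
    for (j in seq_len(n_hbonds)) {
      u <- .HB_DIRECTIONS[j, ]
      w <- .unit(u + stats::runif(3, -1, 1) * 0.3 * jitter)
      d <- stats::runif(1, 2.75, 3.05)
      N <- 1.5 * w
      add_lig(paste0("N", j), "N", N)
      add_lig(paste0("H", j), "H", N + 1.0 * w)
      k <- owner[j]
      acc[[k]] <- c(acc[[k]], list(list(dir = w, pos = N + d * w)))
    }
    for (k in seq_len(n_hbond_residues)) {
      resno <- resno + 1L
      m <- .unit(Reduce(`+`, lapply(acc[[k]], `[[`, "dir")))
      centroid <- Reduce(`+`, lapply(acc[[k]], `[[`, "pos")) / length(acc[[k]])
      nm <- if (length(acc[[k]]) == 2) c("OD1", "OD2") else "OD1"
      atoms <- mapply(function(a, name) list(name = name, element = "O",
                                             xyz = a$pos),
                      acc[[k]], nm, SIMPLIFY = FALSE)
      cg <- centroid + 0.7 * m
      perp <- .unit(if (abs(m[1]) < 0.9) c(-m[2], m[1], 0) else c(0, -m[3], m[2]))
      atoms <- c(atoms, list(
        list(name = "CG", element = "C", xyz = cg),
        list(name = "CB", element = "C", xyz = cg + 1.5 * m),
        list(name = "CA", element = "C", xyz = cg + 3.0 * m),
        list(name = "N", element = "N", xyz = cg + 4.4 * m + 0.4 * perp),
        list(name = "C", element = "C", xyz = cg + 4.3 * m - 1.0 * perp),
        list(name = "O", element = "O", xyz = cg + 5.5 * m - 1.2 * perp)))
      residues[[length(residues) + 1]] <-
        list(resname = "ASP", resno = resno, atoms = atoms, kind = "hbond")
    }
  }

  rand_dir <- function() .unit(stats::rnorm(3))
  # contact residues: nearest atom is an apolar carbon inside the 5 A shell
  for (k in seq_len(n_contacts)) {
    resno <- resno + 1L
    v <- rand_dir()
    rc <- stats::runif(1, 4.2, 4.7)
    perp <- .unit(if (abs(v[1]) < 0.9) c(-v[2], v[1], 0) else c(0, -v[3], v[2]))
    atoms <- list(
      list(name = "CB", element = "C", xyz = rc * v),
      list(name = "CG", element = "C", xyz = (rc + 1.5) * v),
      list(name = "CD1", element = "C", xyz = (rc + 2.6) * v + 0.8 * perp),
      list(name = "CA", element = "C", xyz = (rc + 1.5) * v - 1.2 * perp),
      list(name = "N", element = "N", xyz = (rc + 2.9) * v - 1.6 * perp),
      list(name = "C", element = "C", xyz = (rc + 2.9) * v + 1.6 * perp),
      list(name = "O", element = "O", xyz = (rc + 4.1) * v + 1.8 * perp))
    residues[[length(residues) + 1]] <-
      list(resname = "LEU", resno = resno, atoms = atoms, kind = "contact")
  }
  # decoys: whole residue beyond 6.2 A of every ligand atom
  for (k in seq_len(n_decoys)) {
    resno <- resno + 1L
    v <- rand_dir()
    rd <- stats::runif(1, 7.8, 8.6)
    perp <- .unit(if (abs(v[1]) < 0.9) c(-v[2], v[1], 0) else c(0, -v[3], v[2]))
    atoms <- list(
      list(name = "CA", element = "C", xyz = rd * v),
      list(name = "N", element = "N", xyz = (rd + 1.4) * v + 0.5 * perp),
      list(name = "C", element = "C", xyz = (rd + 1.4) * v - 0.8 * perp),
      list(name = "O", element = "O", xyz = (rd + 2.6) * v - 1.0 * perp))
    residues[[length(residues) + 1]] <-
      list(resname = "GLY", resno = resno, atoms = atoms, kind = "decoy")
  }

  lines <- character()
  serial <- 0L
  for (res in residues) for (a in res$atoms) {
    serial <- serial + 1L
    lines <- c(lines, .pdb_line("ATOM", serial, a$name, res$resname, "A",
                                res$resno, a$xyz, a$element))
  }
  for (a in lig) {
    serial <- serial + 1L
    lines <- c(lines, .pdb_line("HETATM", serial, a$name, "LIG", "A", 900L,
                                a$xyz, a$element))
  }
  lines <- c(lines, "END")

  lab <- function(kind) {
    sel <- Filter(function(r) r$kind == kind, residues)
    vapply(sel, function(r) .residue_label(r$resname, r$resno), "")
  }
  hb_res <- lab("hbond")
  truth <- list(ligand_id = "LIG", n_hbonds = as.integer(n_hbonds),
                hbond_residues = hb_res,
                hydrophobic_residues = c(hb_res, lab("contact")),
                decoy_residues = lab("decoy"),
                n_ligand_atoms = length(lig), seed = seed)
  structure(list(pdb = lines, truth = truth,
                 spec = list(seed = seed, n_hbonds = n_hbonds,
                             n_hbond_residues = n_hbond_residues,
                             n_contacts = n_contacts, n_decoys = n_decoys,
                             jitter = jitter)),
            class = "synthetic_complex")
}

#' Noise level giving a target population correlation
#'
#' For dock scores uniform on `dock_range` and Delta G_exp generated as
#' `slope * dock + intercept + N(0, sd)`, returns the `sd` for which the
#' population Pearson correlation equals `r`.
#'
#' @param r Target correlation in (0, 1).
#' @param slope Linear slope (kcal/mol per kcal/mol).
#' @param dock_range Dock-score range, kcal/mol.
#' @return Noise standard deviation, kcal/mol.
#' @export
noise_sd_for_r <- function(r, slope, dock_range) {
  stopifnot(r > 0, r < 1)
  sd_x <- abs(diff(range(dock_range))) / sqrt(12)
  abs(slope) * sd_x * sqrt(1 / r^2 - 1)
}

#' Generate a dock-score / IC50 dataset with controlled linear structure
#'
#' Dock scores are drawn uniformly over `dock_range`; the experimental
#' binding free energy is `slope * dock + intercept` plus Gaussian noise in
#' Delta-G space (i.e. multiplicative on the concentration scale, matching
#' how assay error behaves on a log scale), then back-transformed to an
#' IC50 in uM through the inverse of [ic50_to_dg_exp()]. Defaults emulate
#' the study's series: 19 compounds, dock scores spanning roughly -14.5 to
#' -8.5 kcal/mol and an affinity trend of comparable shallowness.
#'
#' @param seed Integer seed.
#' @param n Number of compounds (>= 3).
#' @param slope,intercept Linear relation from dock score to Delta G_exp.
#' @param noise_sd Gaussian noise in Delta-G space, kcal/mol.
#' @param dock_range Dock-score range, kcal/mol.
#' @param constants [thermo_constants()].
#' @return List with `data` (data.frame `compound_id`, `dg_dock`,
#'   `ic50_uM`, `dg_exp`) and `true` (generating parameters).
#' @export
synthetic_affinity <- function(seed, n = 19, slope = 0.3, intercept = -4,
                               noise_sd = 0.3,
                               dock_range = c(-14.5, -8.5),
                               constants = thermo_constants()) {
  stopifnot(n >= 3, noise_sd >= 0)
  set.seed(seed)
  dock <- stats::runif(n, min(dock_range), max(dock_range))
  dg_exp <- slope * dock + intercept + stats::rnorm(n, 0, noise_sd)
  rt <- constants$R_kcal * constants$T_exp
  ic50_uM <- exp(dg_exp / rt) * 1e6
  data <- data.frame(compound_id = sprintf("S%02d", seq_len(n)),
                     dg_dock = dock, ic50_uM = ic50_uM, dg_exp = dg_exp,
                     stringsAsFactors = FALSE)
  list(data = data,
       true = list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                   dock_range = dock_range, seed = seed))
}

#' Generate a Lennard-Jones + Coulomb binding pocket
#'
#' Builds a [pull_system()] whose bound minimum sits near the origin with a
#' free exit along +Z: one anchor site directly below the ligand at its LJ
#' minimum distance and the remaining sites on a ring around the exit axis,
#' each at its own minimum distance from the origin. Site well depths,
#' radii and charges are controlled; with all charges zero the pocket's
#' Coulomb energy is identically zero.
#'
#' @param seed Integer seed (recorded; the construction is deterministic).
#' @param n_sites Number of fixed sites (>= 1).
#' @param epsilon LJ well depth per site, kJ/mol (scalar or length
#'   `n_sites`).
#' @param sigma LJ radius per site, nm (scalar or length `n_sites`).
#' @param site_charges Site charges, e (scalar or length `n_sites`).
#' @param ligand_charge Ligand charge, e.
#' @param ligand_mass Ligand mass, amu.
#' @param channel_length Unbinding channel length, nm: the pull must carry
#'   the ligand at least this far along +Z to clear the pocket.
#' @param ... Passed to [pull_system()] (cutoff, temperature, friction,
#'   dielectric).
#' @return A [pull_system()] with attribute `channel_length`.
#' @export
synthetic_pocket <- function(seed = 1, n_sites = 4, epsilon = 10,
                             sigma = 0.35, site_charges = 0,
                             ligand_charge = 0, ligand_mass = 300,
                             channel_length = 1.5, ...) {
  stopifnot(n_sites >= 1, channel_length > 0)
  epsilon <- rep_len(epsilon, n_sites)
  sigma <- rep_len(sigma, n_sites)
  site_charges <- rep_len(site_charges, n_sites)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(epsilon < 0)) stop("epsilon must be non-negative", call. = FALSE)
  rmin <- 2^(1 / 6) * sigma
  pos <- matrix(0, n_sites, 3)
  pos[1, ] <- c(0, 0, -rmin[1])
  if (n_sites > 1) {
    ang <- 2 * pi * (seq_len(n_sites - 1) - 1) / (n_sites - 1)
    for (i in seq_len(n_sites - 1))
      pos[i + 1, ] <- c(rmin[i + 1] * cos(ang[i]), rmin[i + 1] * sin(ang[i]), 0)
  }
  sites <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      eps = epsilon, sigma = sigma, charge = site_charges)
  sys <- pull_system(sites,
                     ligand = list(mass = ligand_mass, charge = ligand_charge,
                                   position = c(0, 0, 0)), ...)
  attr(sys, "channel_length") <- channel_length
  sys$seed <- seed
  sys
}
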