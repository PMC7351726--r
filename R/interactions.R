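# Protein-ligand interaction fingerprints: geometric hydrogen bonds and
# residues within a fixed contact radius of the ligand.
#
# H-bond criteria (the study's own criteria are unstated; these defaults
# are conventional geometric ones and are configurable everywhere):
# donor-acceptor heavy-atom distance <= 3.5 A and, when the donor carries
# explicit hydrogens, a D-H...A angle >= 120 degrees; distance-only when no
# hydrogens are present (the usual case for crystallographic receptors).

.WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD", "SOL")
.ION_RESIDUES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "BR", "IOD")

# Donor/acceptor rule table over the 20 standard residues (side chains);
# backbone N (except proline) donates, backbone O/OXT accepts.
.SC_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  TRP = "NE1", CYS = "SG"
)
.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

.residue_label <- function(resid, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste0(toupper(substring(resid, 1, 1)), tolower(substring(resid, 2)),
         resno, insert)
}

.guess_element <- function(elety) {
  e <- gsub("[0-9']", "", elety)
  two <- toupper(substring(e, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA"),
         paste0(substring(two, 1, 1), tolower(substring(two, 2, 2))),
         toupper(substring(e, 1, 1)))
}

#' Parse a protein-ligand complex from PDB text
#'
#' Reads a PDB file (via bio3d), resolves alternate locations (highest
#' occupancy wins, ties go to altloc "A"), drops waters and monoatomic ions,
#' and splits the structure into the polymer receptor (ATOM records) and a
#' single selected ligand (HETATM records).
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param ligand Ligand selector: a HETATM residue name (e.g. `"LIG"`), or a
#'   list with any of `resname`, `chain`, `resno`. Must match exactly one
#'   residue instance.
#' @return Object of class `"plcomplex"`: list with data.frames `receptor`
#'   and `ligand` (columns `elety`, `element`, `resid`, `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, coordinates in Angstrom) and `ligand_id`.
#' @export
parse_complex <- function(pdb, ligand) {
  path <- if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    pdb
  } else {
    tf <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), tf)
    tf
  }
  s <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                        rm.alt = FALSE))
  at <- s$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    .guess_element(at$elety[is.na(at$elesy) | at$elesy == ""])
  at$element <- gsub("\\s", "", at$elesy)
  at$o[is.na(at$o)] <- 1

  # altloc resolution per (chain, resno, insert, resid, atom name)
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      best <- idx[at$o[idx] == max(at$o[idx])]
      if (length(best) > 1) best <- best[order(at$alt[best])][1]
      best
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
    stop("non-finite coordinates in PDB", call. = FALSE)

  receptor <- at[at$type == "ATOM" & !(at$resid %in% .WATER_RESIDUES), ,
                 drop = FALSE]
  if (nrow(receptor) == 0)
    stop("format error: no polymer ATOM records", call. = FALSE)

  het <- at[at$type == "HETATM" &
              !(at$resid %in% c(.WATER_RESIDUES, .ION_RESIDUES)), ,
            drop = FALSE]
  sel <- if (is.character(ligand)) list(resname = ligand) else ligand
  keep <- rep(TRUE, nrow(het))
  if (!is.null(sel$resname)) keep <- keep & het$resid == sel$resname
  if (!is.null(sel$chain)) keep <- keep & het$chain == sel$chain
  if (!is.null(sel$resno)) keep <- keep & het$resno == sel$resno
  lig <- het[keep, , drop = FALSE]
  if (nrow(lig) == 0) stop("selection error: no ligand matches", call. = FALSE)
  inst <- unique(paste(lig$chain, lig$resno, lig$insert, lig$resid, sep = "|"))
  if (length(inst) > 1)
    stop("selection error: ligand selector matches ", length(inst),
         " residues", call. = FALSE)

  cols <- c("elety", "element", "resid", "chain", "resno", "insert",
            "x", "y", "z")
  structure(list(receptor = receptor[, cols], ligand = lig[, cols],
                 ligand_id = lig$resid[1]),
            class = "plcomplex")
}

#' @export
print.plcomplex <- function(x, ...) {
  cat(sprintf("Protein-ligand complex: ligand %s (%d atoms), receptor %d atoms, %d residues\n",
              x$ligand_id, nrow(x$ligand), nrow(x$receptor),
              length(unique(paste(x$receptor$chain, x$receptor$resno,
                                  x$receptor$insert)))))
  invisible(x)
}

.xyz <- function(df) as.matrix(df[, c("x", "y", "z")])

# Attach explicit hydrogens to their heavy atom (same residue instance,
# within 1.25 A). Returns, per heavy-atom row index, a list of H coordinates.
.attach_hydrogens <- function(df) {
  heavy <- which(df$element != "H")
  hs <- which(df$element == "H")
  out <- vector("list", nrow(df))
  if (!length(hs)) return(out)
  hv <- .xyz(df)
  for (h in hs) {
    same <- heavy[df$chain[heavy] == df$chain[h] &
                  df$resno[heavy] == df$resno[h] &
                  df$insert[heavy] == df$insert[h]]
    if (!length(same)) next
    d2 <- colSums((t(hv[same, , drop = FALSE]) - hv[h, ])^2)
    j <- same[which.min(d2)]
    if (min(d2) <= 1.25^2) out[[j]] <- c(out[[j]], list(hv[h, ]))
  }
  out
}

# Polar-atom inventory for one side of the interface.
# side = "receptor": rule-table typing; side = "ligand": element + bonded-H.
.polar_atoms <- function(df, side) {
  hyd <- .attach_hydrogens(df)
  heavy <- which(df$element != "H")
  rows <- lapply(heavy, function(i) {
    el <- df$element[i]
    if (!el %in% c("N", "O", "S")) return(NULL)
    name <- gsub("\\s", "", df$elety[i])
    resid <- df$resid[i]
    has_h <- length(hyd[[i]]) > 0
    if (side == "ligand") {
      donor <- el %in% c("N", "O") && has_h
      acceptor <- el %in% c("N", "O")
    } else {
      donor <- (name == "N" && resid != "PRO") ||
        name %in% (.SC_DONORS[[resid]] %||% character())
      acceptor <- name %in% c("O", "OXT") ||
        name %in% (.SC_ACCEPTORS[[resid]] %||% character())
      donor <- donor && el %in% c("N", "O")
      acceptor <- acceptor && el %in% c("N", "O")
    }
    if (!donor && !acceptor) return(NULL)
    list(row = i, donor = donor, acceptor = acceptor, hydrogens = hyd[[i]])
  })
  rows[!vapply(rows, is.null, TRUE)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dha_angle <- function(d, h, a) {
  v1 <- d - h
  v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect interface hydrogen bonds
#'
#' Enumerates donor/acceptor pairs across the protein-ligand interface
#' (N/O donors bearing hydrogens where present; N/O acceptors) and keeps
#' pairs with heavy-atom distance at most `d_max`. When the donor carries
#' explicit hydrogens the best D-H...A angle must reach `angle_min`;
#' without hydrogens the criterion is distance-only.
#'
#' @param complex A [parse_complex()] result.
#' @param d_max Heavy-atom donor-acceptor distance cutoff, Angstrom.
#' @param angle_min Minimum D-H...A angle, degrees.
#' @return data.frame sorted by distance: `direction` (`"ligand-donor"` or
#'   `"receptor-donor"`), `donor`, `acceptor` (atom names), `residue`
#'   (receptor residue label, e.g. `"Val135"`), `distance`, `angle` (`NA`
#'   without hydrogens).
#' @export
find_hbonds <- function(complex, d_max = 3.5, angle_min = 120) {
  stopifnot(inherits(complex, "plcomplex"), d_max > 0)
  lp <- .polar_atoms(complex$ligand, "ligand")
  rp <- .polar_atoms(complex$receptor, "receptor")
  lxyz <- .xyz(complex$ligand)
  rxyz <- .xyz(complex$receptor)

  res <- list()
  add <- function(direction, don_df, don, acc_df, acc, dxyz, axyz) {
    d <- sqrt(sum((dxyz[don$row, ] - axyz[acc$row, ])^2))
    if (d > d_max || d == 0) return()
    ang <- NA_real_
    if (length(don$hydrogens)) {
      angs <- vapply(don$hydrogens, function(h)
        .dha_angle(dxyz[don$row, ], h, axyz[acc$row, ]), 0)
      ang <- max(angs)
      if (ang < angle_min) return()
    }
    rec <- if (direction == "ligand-donor") acc_df[acc$row, ] else don_df[don$row, ]
    res[[length(res) + 1]] <<- data.frame(
      direction = direction,
      donor = gsub("\\s", "", don_df$elety[don$row]),
      acceptor = gsub("\\s", "", acc_df$elety[acc$row]),
      residue = .residue_label(rec$resid, rec$resno, rec$insert),
      distance = d, angle = ang, stringsAsFactors = FALSE)
  }
  for (don in lp) if (don$donor)
    for (acc in rp) if (acc$acceptor)
      add("ligand-donor", complex$ligand, don, complex$receptor, acc, lxyz, rxyz)
  for (don in rp) if (don$donor)
    for (acc in lp) if (acc$acceptor)
      add("receptor-donor", complex$receptor, don, complex$ligand, acc, rxyz, lxyz)

  if (!length(res))
    return(data.frame(direction = character(), donor = character(),
                      acceptor = character(), residue = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$distance), , drop = FALSE]
}

#' Receptor residues within a contact radius of the ligand
#'
#' A residue is in contact when at least one of its heavy atoms lies within
#' `radius` of any ligand heavy atom; hydrogens are ignored on both sides.
#'
#' @param complex A [parse_complex()] result.
#' @param radius Contact radius, Angstrom (the study uses 5).
#' @return Character vector of residue labels, ordered by residue number.
#' @export
contact_residues <- function(complex, radius = 5) {
  stopifnot(inherits(complex, "plcomplex"), radius > 0)
  lig <- complex$ligand[complex$ligand$element != "H", , drop = FALSE]
  rec <- complex$receptor[complex$receptor$element != "H", , drop = FALSE]
  if (nrow(lig) == 0 || nrow(rec) == 0) return(character())
  lx <- .xyz(lig)
  rx <- .xyz(rec)
  # min distance from each receptor atom to any ligand atom
  d2 <- apply(rx, 1, function(p) min(colSums((t(lx) - p)^2)))
  hit <- d2 <= radius^2
  if (!any(hit)) return(character())
  r <- rec[hit, , drop = FALSE]
  key <- paste(r$chain, r$resno, r$insert, r$resid, sep = "|")
  first <- !duplicated(key)
  r <- r[first, , drop = FALSE]
  r <- r[order(r$chain, r$resno, r$insert), , drop = FALSE]
  .residue_label(r$resid, r$resno, r$insert)
}

#' Interaction fingerprint of a complex
#'
#' Composes [find_hbonds()] and [contact_residues()] into the study's
#' per-ligand fingerprint: the number of interface hydrogen bonds, the
#' H-bonded residues, and the residues within the contact radius. By
#' default the contact (hydrophobic) set may overlap the H-bond set,
#' matching the study's separate listings; `mode = "exclusive-hydrophobic"`
#' removes H-bond partners from the contact set.
#'
#' @param complex A [parse_complex()] result.
#' @param d_max,angle_min H-bond criteria, see [find_hbonds()].
#' @param radius Contact radius, Angstrom.
#' @param mode `"overlap"` (default) or `"exclusive-hydrophobic"`.
#' @return Object of class `"contact_fingerprint"`: list with `ligand_id`,
#'   `n_hbonds`, `hbond_residues`, `hydrophobic_residues`, `hbonds` (the
#'   full bond table) and `params`.
#' @export
fingerprint <- function(complex, d_max = 3.5, angle_min = 120, radius = 5,
                        mode = c("overlap", "exclusive-hydrophobic")) {
  mode <- match.arg(mode)
  hb <- find_hbonds(complex, d_max = d_max, angle_min = angle_min)
  contacts <- contact_residues(complex, radius = radius)
  hb_res <- unique(hb$residue[order(suppressWarnings(
    as.integer(gsub("[^0-9]", "", hb$residue))))])
  hydro <- if (mode == "exclusive-hydrophobic") setdiff(contacts, hb_res)
           else contacts
  structure(list(ligand_id = complex$ligand_id, n_hbonds = nrow(hb),
                 hbond_residues = hb_res, hydrophobic_residues = hydro,
                 hbonds = hb,
                 params = list(d_max = d_max, angle_min = angle_min,
                               radius = radius, mode = mode)),
            class = "contact_fingerprint")
}

#' @export
print.contact_fingerprint <- function(x, ...) {
  cat(sprintf("Fingerprint for %s: %d H-bond(s)\n", x$ligand_id, x$n_hbonds))
  cat("  H-bond residues:   ",
      if (length(x$hbond_residues)) paste(x$hbond_residues, collapse = ", ")
      else "(none)", "\n")
  cat("  Contact residues:  ",
      if (length(x$hydrophobic_residues))
        paste(x$hydrophobic_residues, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' Jaccard index over the combined residue sets (H-bond union contact) of
#' two fingerprints; 1 for identical sets, 0 for disjoint, and defined as 1
#' when both are empty.
#'
#' @param a,b `"contact_fingerprint"` objects (or lists with
#'   `hbond_residues` / `hydrophobic_residues`).
#' @return Similarity in \[0, 1\].
#' @export
compare_fingerprints <- function(a, b) {
  sa <- union(a$hbond_residues, a$hydrophobic_residues)
  sb <- union(b$hbond_residues, b$hydrophobic_residues)
  if (!length(sa) && !length(sb)) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}
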