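# Independent brute-force oracles used to cross-check the implementation.

# Product-moment correlation written out longhand.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Normal-equation least squares plus RMS residual.
oracle_linfit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept, rmse = sqrt(mean(res^2)))
}

# Exhaustive O(n^2) interface hydrogen-bond count/set. Typing rules are
# re-derived here from the raw atom tables: ligand N/O with an attached H
# (<= 1.25 A, same residue) donate, all ligand N/O accept; receptor
# backbone N (non-PRO) and standard side-chain donors donate, backbone
# O/OXT and standard side-chain acceptors accept.
oracle_hbonds <- function(complex, d_max = 3.5, angle_min = 120) {
  don_tab <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                  GLN = "NE2", HIS = c("ND1", "NE2"), LYS = "NZ",
                  ARG = c("NE", "NH1", "NH2"), TRP = "NE1")
  acc_tab <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
                  GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
                  HIS = c("ND1", "NE2"))
  xyz <- function(df, i) as.numeric(df[i, c("x", "y", "z")])
  hydrogens_of <- function(df, i) {
    out <- list()
    for (h in seq_len(nrow(df))) {
      if (df$element[h] != "H") next
      if (df$resno[h] != df$resno[i] || df$chain[h] != df$chain[i]) next
      if (sqrt(sum((xyz(df, h) - xyz(df, i))^2)) <= 1.25)
        out <- c(out, list(xyz(df, h)))
    }
    out
  }
  angle <- function(d, h, a) {
    v1 <- d - h; v2 <- a - h
    acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  lig <- complex$ligand; rec <- complex$receptor
  bonds <- list()
  try_pair <- function(don_df, di, acc_df, ai, residue_df, ri) {
    d <- sqrt(sum((xyz(don_df, di) - xyz(acc_df, ai))^2))
    if (d > d_max) return()
    hs <- hydrogens_of(don_df, di)
    if (length(hs)) {
      best <- max(vapply(hs, function(h)
        angle(xyz(don_df, di), h, xyz(acc_df, ai)), 0))
      if (best < angle_min) return()
    }
    resid <- residue_df$resid[ri]
    lab <- paste0(toupper(substring(resid, 1, 1)),
                  tolower(substring(resid, 2)), residue_df$resno[ri])
    bonds[[length(bonds) + 1]] <<- lab
  }
  for (i in seq_len(nrow(lig))) {
    if (!lig$element[i] %in% c("N", "O")) next
    if (!length(hydrogens_of(lig, i))) next
    for (j in seq_len(nrow(rec))) {
      nm <- gsub("\\s", "", rec$elety[j])
      ok <- nm %in% c("O", "OXT") || nm %in% (acc_tab[[rec$resid[j]]])
      if (isTRUE(ok) && rec$element[j] %in% c("N", "O"))
        try_pair(lig, i, rec, j, rec, j)
    }
  }
  for (j in seq_len(nrow(rec))) {
    nm <- gsub("\\s", "", rec$elety[j])
    ok <- (nm == "N" && rec$resid[j] != "PRO") ||
      nm %in% (don_tab[[rec$resid[j]]])
    if (!isTRUE(ok) || !rec$element[j] %in% c("N", "O")) next
    for (i in seq_len(nrow(lig)))
      if (lig$element[i] %in% c("N", "O"))
        try_pair(rec, j, lig, i, rec, j)
  }
  as.character(unlist(bonds))
}

# Exhaustive O(n^2) contact-shell residue set.
oracle_contacts <- function(complex, radius = 5) {
  lig <- complex$ligand[complex$ligand$element != "H", ]
  rec <- complex$receptor[complex$receptor$element != "H", ]
  labs <- character()
  for (j in seq_len(nrow(rec))) {
    for (i in seq_len(nrow(lig))) {
      d <- sqrt(sum((as.numeric(rec[j, c("x", "y", "z")]) -
                       as.numeric(lig[i, c("x", "y", "z")]))^2))
      if (d <= radius) {
        labs <- c(labs, paste0(toupper(substring(rec$resid[j], 1, 1)),
                               tolower(substring(rec$resid[j], 2)),
                               rec$resno[j]))
        break
      }
    }
  }
  unique(labs)
}

# Direct-summation LJ + Coulomb oracle (kJ/mol; nm; e).
oracle_energy <- function(system, position = system$ligand$position) {
  e_cou <- 0; e_vdw <- 0
  for (i in seq_len(nrow(system$sites))) {
    r <- sqrt(sum((as.numeric(system$sites[i, c("x", "y", "z")]) -
                     position)^2))
    if (r > system$cutoff) next
    sr6 <- (system$sites$sigma[i] / r)^6
    e_vdw <- e_vdw + 4 * system$sites$eps[i] * (sr6^2 - sr6)
    e_cou <- e_cou + 138.935458 * system$sites$charge[i] *
      system$ligand$charge / (system$dielectric * r)
  }
  c(E_cou = e_cou, E_vdW = e_vdw)
}

# Random proper rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_complex <- function(complex, R, shift = c(0, 0, 0)) {
  tr <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- m[, 1] + shift[1]
    df$y <- m[, 2] + shift[2]
    df$z <- m[, 3] + shift[3]
    df
  }
  complex$receptor <- tr(complex$receptor)
  complex$ligand <- tr(complex$ligand)
  complex
}

# Minimal fixed-width PDB writer for hand-built test structures.
make_pdb_lines <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            df$type[i], i, df$name[i],
            if (!is.null(df$alt)) df$alt[i] else " ", df$resname[i],
            df$chain[i], df$resno[i], df$x[i], df$y[i], df$z[i],
            if (!is.null(df$occ)) df$occ[i] else 1, 0, df$element[i])
  }, "")
}
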