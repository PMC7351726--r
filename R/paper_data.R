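# Loaders and validators for the packaged study tables.
#
# The cytotoxicity, docking, interaction and descriptor tables of the study
# are shipped as TSV fixtures under inst/extdata, with the compound registry
# as JSON. Loaders normalise typography (Unicode minus, "> 20" censoring)
# and enforce the tables' invariants.

.CELL_LINES <- c("HepG2", "LU-1", "SW480", "HL-60", "HEK-293")

#' Path to a packaged data fixture
#'
#' @param ... Path components below `inst/extdata`.
#' @return Absolute path to the installed fixture.
#' @export
dp_fixture <- function(...) {
  p <- system.file("extdata", ..., package = "dockpull", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file.path(...), call. = FALSE)
  p
}

# Normalise typography found in the printed tables: Unicode minus signs and
# stray spacing around comparison signs and exponents.
.normalize_cell <- function(x) {
  x <- gsub("−|–", "-", x)
  gsub("\\s+", "", x)
}

#' Load the compound registry
#'
#' Identities and roles of every compound appearing in the study's tables:
#' the indirubin parent (1), the intermediates (2, 3, 4), the designed
#' conjugates (6a-6p), the reference kinase inhibitors (CHIR-98014,
#' Bio-acetoxime) and the reference cytotoxic drug (Ellipticine).
#'
#' @param path JSON fixture path; defaults to the packaged registry.
#' @return data.frame with columns `id`, `role`, `formula`, `graph_ref`
#'   (the latter two `NA` where the study deposits no certified structure).
#' @export
load_compounds <- function(path = dp_fixture("compounds.json")) {
  reg <- jsonlite::fromJSON(path)
  for (col in c("formula", "graph_ref"))
    if (is.null(reg[[col]])) reg[[col]] <- NA_character_
  roles <- c("parent", "intermediate", "designed",
             "reference-inhibitor", "reference-drug")
  if (anyDuplicated(reg$id))
    stop("compound registry ids are not unique", call. = FALSE)
  bad <- setdiff(unique(reg$role), roles)
  if (length(bad))
    stop("unknown compound role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  reg[, c("id", "role", "formula", "graph_ref")]
}

.assert_known_ids <- function(ids, registry, table) {
  if (is.null(registry)) return(invisible())
  unknown <- setdiff(unique(ids), registry$id)
  if (length(unknown))
    stop(sprintf("%s references compound ids absent from the registry: %s",
                 table, paste(unknown, collapse = ", ")), call. = FALSE)
  invisible()
}

#' Load the cytotoxicity table (IC50 with censoring)
#'
#' One row per compound x cell line. Cells printed "> 20" are right-censored
#' at 20 uM: `ic50_uM` is `NA`, `censored` is `TRUE` and `bound_uM` records
#' the censoring bound. Censored entries never carry a standard deviation.
#'
#' @param path TSV fixture path (columns `compound_id`, `cell_line`,
#'   `ic50_uM`, `sd_uM`); defaults to the packaged table.
#' @param registry Optional compound registry for id validation.
#' @return data.frame with columns `compound_id`, `cell_line`, `ic50_uM`,
#'   `sd_uM`, `censored`, `bound_uM`.
#' @examples
#' cyto <- load_cytotoxicity()
#' subset(cyto, compound_id == "6f" & cell_line == "HL-60")
#' @export
load_cytotoxicity <- function(path = dp_fixture("table1_cytotoxicity.tsv"),
                              registry = NULL) {
  raw <- utils::read.delim(path, colClasses = "character")
  need <- c("compound_id", "cell_line", "ic50_uM", "sd_uM")
  if (!all(need %in% names(raw)))
    stop("cytotoxicity table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ic <- .normalize_cell(raw$ic50_uM)
  censored <- grepl("^>", ic)
  bound <- ifelse(censored, suppressWarnings(as.numeric(sub("^>", "", ic))),
                  NA_real_)
  value <- ifelse(censored, NA_real_, suppressWarnings(as.numeric(ic)))
  sd <- suppressWarnings(as.numeric(.normalize_cell(raw$sd_uM)))

  bad <- which(!censored & (is.na(value) | value <= 0))
  if (length(bad))
    stop(sprintf("malformed IC50 value at line %d of %s: %s",
                 bad[1] + 1L, basename(path), raw$ic50_uM[bad[1]]),
         call. = FALSE)
  if (any(censored & !is.na(sd)))
    stop("censored IC50 entries must not carry a standard deviation",
         call. = FALSE)
  if (any(!is.na(sd) & sd < 0)) stop("negative sd_uM", call. = FALSE)
  unknown <- setdiff(unique(raw$cell_line), .CELL_LINES)
  if (length(unknown))
    stop("unknown cell line(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  .assert_known_ids(raw$compound_id, registry, "cytotoxicity table")

  data.frame(compound_id = raw$compound_id, cell_line = raw$cell_line,
             ic50_uM = value, sd_uM = sd, censored = censored,
             bound_uM = bound, stringsAsFactors = FALSE)
}

# Parse a printed K_i string such as "46.6E-12" (mol/L) to numeric.
.parse_ki <- function(x) {
  v <- suppressWarnings(as.numeric(.normalize_cell(x)))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop("malformed K_i value: ", x[bad], call. = FALSE)
  }
  v
}

#' Load the docking table (dock scores and predicted K_i)
#'
#' @param path TSV fixture path (columns `compound_id`, `dg_dock_kcal`,
#'   `ki_pred_M`, the latter in the table's scientific notation, e.g.
#'   `46.6E-12`); defaults to the packaged table.
#' @param registry Optional compound registry for id validation.
#' @return data.frame with columns `compound_id`, `dg_dock` (kcal/mol,
#'   negative) and `ki_pred` (mol/L, positive).
#' @examples
#' dock <- load_docking()
#' subset(dock, compound_id == "6f")
#' @export
load_docking <- function(path = dp_fixture("table2_docking.tsv"),
                         registry = NULL) {
  raw <- utils::read.delim(path, colClasses = "character")
  need <- c("compound_id", "dg_dock_kcal", "ki_pred_M")
  if (!all(need %in% names(raw)))
    stop("docking table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dg <- suppressWarnings(as.numeric(.normalize_cell(raw$dg_dock_kcal)))
  if (anyNA(dg))
    stop("malformed dock score at line ", which(is.na(dg))[1] + 1L,
         call. = FALSE)
  if (any(dg >= 0))
    stop("dock scores must be negative (kcal/mol); offending compound: ",
         raw$compound_id[which(dg >= 0)[1]], call. = FALSE)
  ki <- .parse_ki(raw$ki_pred_M)
  if (any(ki <= 0)) stop("K_i,pred must be positive", call. = FALSE)
  .assert_known_ids(raw$compound_id, registry, "docking table")
  data.frame(compound_id = raw$compound_id, dg_dock = dg, ki_pred = ki,
             stringsAsFactors = FALSE)
}

#' Load the published interaction table (H-bond counts and residues)
#'
#' Format/semantics reference only: the study's docked poses are not
#' deposited, so these counts are not recomputation targets.
#'
#' @param path TSV fixture path; defaults to the packaged table.
#' @param registry Optional compound registry for id validation.
#' @return data.frame with `compound_id`, `n_hbonds` and a list column
#'   `residues` of residue labels.
#' @export
load_interactions <- function(path = dp_fixture("table3_interactions.tsv"),
                              registry = NULL) {
  raw <- utils::read.delim(path, colClasses = "character")
  n <- suppressWarnings(as.integer(raw$n_hbonds))
  if (anyNA(n) || any(n < 0)) stop("malformed H-bond count", call. = FALSE)
  res <- lapply(strsplit(raw$residues, ","), trimws)
  if (any(n > 0 & lengths(res) == 0))
    stop("rows with H-bonds must list interacting residues", call. = FALSE)
  .assert_known_ids(raw$compound_id, registry, "interaction table")
  out <- data.frame(compound_id = raw$compound_id, n_hbonds = n,
                    stringsAsFactors = FALSE)
  out$residues <- res
  out
}

#' Load the published descriptor table (miLogP, TPSA, MW, predicted LD50)
#'
#' miLogP and the LD50/toxicity class come from third-party predictors and
#' are only ever loaded, never computed; TPSA and MW are recomputable from
#' the certified molecular graphs for compounds 1-4.
#'
#' @param path TSV fixture path; defaults to the packaged table.
#' @param registry Optional compound registry for id validation.
#' @return data.frame with columns `compound_id`, `milogp`, `tpsa`, `mw`,
#'   `ld50_pred`, `tox_class`.
#' @export
load_descriptors <- function(path = dp_fixture("table4_descriptors.tsv"),
                             registry = NULL) {
  raw <- utils::read.delim(path)
  out <- data.frame(compound_id = as.character(raw$compound_id),
                    milogp = as.numeric(raw$milogp),
                    tpsa = as.numeric(raw$tpsa_A2),
                    mw = as.numeric(raw$mw_gmol),
                    ld50_pred = as.numeric(raw$ld50_mgkg),
                    tox_class = as.integer(raw$tox_class),
                    stringsAsFactors = FALSE)
  if (any(out$tpsa < 0) || any(out$mw <= 0))
    stop("descriptor table violates TPSA >= 0 / MW > 0", call. = FALSE)
  if (any(out$tox_class < 1 | out$tox_class > 6))
    stop("toxicity class must lie in 1..6", call. = FALSE)
  .assert_known_ids(out$compound_id, registry, "descriptor table")
  out
}

#' Cross-check internal consistency of the docking table
#'
#' Back-converts each predicted inhibition constant to a binding free energy
#' at the docking temperature (`constants$T_dock`) and flags compounds whose
#' printed dock score disagrees by more than `rel_tol_dg` relative. With the
#' packaged table the sole anomaly is compound 6b, whose printed pair is
#' off by about 1.3 kcal/mol.
#'
#' @param records data.frame as returned by [load_docking()].
#' @param rel_tol_dg Relative tolerance on the dock score, in (0, 0.5).
#' @param constants [thermo_constants()].
#' @return data.frame of anomalies with columns `compound_id`, `dg_dock`,
#'   `dg_back` (back-converted, kcal/mol) and `rel_err`; zero rows when the
#'   table is consistent (or empty).
#' @examples
#' validate_dock_consistency(load_docking())
#' @export
validate_dock_consistency <- function(records, rel_tol_dg = 0.05,
                                      constants = thermo_constants()) {
  stopifnot(rel_tol_dg > 0, rel_tol_dg < 0.5)
  empty <- data.frame(compound_id = character(), dg_dock = numeric(),
                      dg_back = numeric(), rel_err = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0) return(empty)
  dg_back <- ki_to_dg(records$ki_pred, T = constants$T_dock,
                      R_kcal = constants$R_kcal)
  rel <- abs(dg_back - records$dg_dock) / abs(records$dg_dock)
  bad <- which(rel > rel_tol_dg)
  if (!length(bad)) return(empty)
  data.frame(compound_id = records$compound_id[bad],
             dg_dock = records$dg_dock[bad], dg_back = dg_back[bad],
             rel_err = rel[bad], stringsAsFactors = FALSE)
}
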