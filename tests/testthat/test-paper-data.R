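# Loading and validating the packaged study tables.

test_that("cytotoxicity loader parses the full table with censoring", {
  cyto <- load_cytotoxicity(registry = load_compounds())
  expect_equal(nrow(cyto), 100)  # 20 table rows x 5 cell lines
  expect_equal(sort(unique(cyto$cell_line)),
               sort(c("HepG2", "LU-1", "SW480", "HL-60", "HEK-293")))

  row <- cyto[cyto$compound_id == "6f" & cyto$cell_line == "HL-60", ]
  expect_false(row$censored)
  expect_equal(row$ic50_uM, 0.98)
  expect_equal(row$sd_uM, 0.12)

  row <- cyto[cyto$compound_id == "1" & cyto$cell_line == "HepG2", ]
  expect_true(row$censored)
  expect_true(is.na(row$ic50_uM))
  expect_true(is.na(row$sd_uM))
  expect_equal(row$bound_uM, 20)

  # censoring is total: never both a value and a flag
  expect_true(all(is.na(cyto$ic50_uM[cyto$censored])))
  expect_true(all(!is.na(cyto$ic50_uM[!cyto$censored])))
  expect_true(all(cyto$ic50_uM[!cyto$censored] > 0))
})

test_that("docking loader parses scientific-notation inhibition constants", {
  dock <- load_docking(registry = load_compounds())
  expect_equal(nrow(dock), 21)  # 19 series compounds + 2 reference inhibitors
  f6 <- dock[dock$compound_id == "6f", ]
  expect_equal(f6$dg_dock, -14.09)
  expect_equal(f6$ki_pred, 4.66e-11)
  bio <- dock[dock$compound_id == "Bio-acetoxime", ]
  expect_equal(bio$dg_dock, -10.69)
  expect_equal(bio$ki_pred, 1.406e-8)
  expect_true(all(dock$dg_dock < 0))
  expect_true(all(dock$ki_pred > 0))
})

test_that("loaders reject malformed and inconsistent rows", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tcell_line\tic50_uM\tsd_uM",
               "1\tHepG2\tnot-a-number\t0.1"), tf)
  expect_error(load_cytotoxicity(tf), "line 2")

  writeLines(c("compound_id\tcell_line\tic50_uM\tsd_uM",
               "1\tNIH-3T3\t1.0\t0.1"), tf)
  expect_error(load_cytotoxicity(tf), "cell line")

  writeLines(c("compound_id\tcell_line\tic50_uM\tsd_uM",
               "1\tHepG2\t>20\t0.1"), tf)
  expect_error(load_cytotoxicity(tf), "censored")

  writeLines(c("compound_id\tdg_dock_kcal\tki_pred_M",
               "1\t9.08\t222.71E-09"), tf)
  expect_error(load_docking(tf), "negative")
})

test_that("loaders accept Unicode minus typography", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tdg_dock_kcal\tki_pred_M",
               "1\t− 9.08\t222.71E−09"), tf)
  d <- load_docking(tf)
  expect_equal(d$dg_dock, -9.08)
  expect_equal(d$ki_pred, 2.2271e-7)
})

test_that("every table id resolves against the compound registry", {
  reg <- load_compounds()
  expect_no_error(load_cytotoxicity(registry = reg))
  expect_no_error(load_docking(registry = reg))
  expect_no_error(load_interactions(registry = reg))
  expect_no_error(load_descriptors(registry = reg))
  # Ellipticine is a reference drug with no dock score
  expect_false("Ellipticine" %in% load_docking()$compound_id)
  expect_true("Ellipticine" %in% reg$id)
})

test_that("cytotoxicity records round-trip through write and reload", {
  cyto <- load_cytotoxicity()
  tf <- tempfile(fileext = ".tsv")
  raw <- data.frame(compound_id = cyto$compound_id,
                    cell_line = cyto$cell_line,
                    ic50_uM = ifelse(cyto$censored,
                                     paste0(">", cyto$bound_uM),
                                     format(cyto$ic50_uM, trim = TRUE)),
                    sd_uM = ifelse(is.na(cyto$sd_uM), "",
                                   format(cyto$sd_uM, trim = TRUE)))
  utils::write.table(raw, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(load_cytotoxicity(tf), cyto)
})

test_that("docking-table consistency check flags only the discordant row", {
  dock <- load_docking()
  anom <- validate_dock_consistency(dock, rel_tol_dg = 0.05)
  expect_equal(anom$compound_id, "6b")
  expect_gt(abs(anom$dg_back - anom$dg_dock), 1.0)  # ~1.3 kcal/mol off

  expect_equal(nrow(validate_dock_consistency(dock[0, ])), 0)

  # identity case: K_i constructed exactly from the score never flags
  ident <- data.frame(compound_id = "X", dg_dock = -11.1,
                      ki_pred = dg_to_ki(-11.1, T = 298.15))
  expect_equal(nrow(validate_dock_consistency(ident)), 0)
})
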