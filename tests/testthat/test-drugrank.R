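two_by_three <- function() {
  bas_matrix(matrix(c(-8, -6, -7,
                      -9, -7, -5), nrow = 2, byrow = TRUE,
                    dimnames = list(c("R1", "R2"), c("L1", "L2", "L3"))))
}

test_that("ligands and receptors are ordered by mean binding affinity", {
  rk <- rank_bas_matrix(two_by_three())
  expect_equal(rk$ligands$ligand, c("L1", "L2", "L3"))
  expect_equal(rk$ligands$mean_bas, c(-8.5, -6.5, -6.0))
  expect_equal(rk$receptors$receptor, c("R1", "R2"))
  expect_equal(rk$receptors$mean_bas, c(-7.0, -7.0))

  single <- bas_matrix(matrix(-5, 1, 1, dimnames = list("R", "L")))
  expect_equal(rank_bas_matrix(single)$ligands$rank, 1L)
})

test_that("the ranking is invariant under row and column permutation", {
  m <- unclass(two_by_three())
  rk <- rank_bas_matrix(bas_matrix(m))
  rk_cols <- rank_bas_matrix(bas_matrix(m[, c(3, 1, 2)]))
  rk_rows <- rank_bas_matrix(bas_matrix(m[c(2, 1), ]))
  expect_equal(rk_cols$ligands, rk$ligands)
  expect_equal(rk_rows$ligands, rk$ligands)
  # adding a constant shifts means but keeps the order
  rk_shift <- rank_bas_matrix(bas_matrix(m + 2))
  expect_equal(rk_shift$ligands$ligand, rk$ligands$ligand)
  expect_equal(rk_shift$ligands$mean_bas, rk$ligands$mean_bas + 2)
})

test_that("coverage floor excludes sparse ligands and means use what exists", {
  m <- matrix(c(-8, NA, NA, -6,
                NA, -7, NA, -6,
                -7, NA, NA, -6), nrow = 3, byrow = TRUE,
              dimnames = list(c("R1", "R2", "R3"),
                              c("L1", "L2", "L3", "L4")))
  expect_warning(rk <- rank_bas_matrix(bas_matrix(m), min_coverage = 0.8),
                 "coverage")
  expect_setequal(rk$excluded, c("L1", "L2", "L3"))
  expect_equal(rk$ligands$ligand, "L4")
  expect_equal(rk$ligands$mean_bas, -6)
  expect_error(suppressWarnings(rank_bas_matrix(bas_matrix(m),
                                                min_coverage = 1.1)),
               class = "crossdx_data_error")
})

test_that("candidate selection applies the average and per-receptor cuts", {
  m <- matrix(c(-8.5, -7.8, -7.6,
                -8.5, -7.8, -7.6), nrow = 2, byrow = TRUE,
              dimnames = list(c("R1", "R2"), c("L1", "L2", "L3")))
  sel <- select_candidate_drugs(rank_bas_matrix(bas_matrix(m)),
                                avg_cut = -7.7)
  expect_equal(sel$ligand, c("L1", "L2"))

  # a weak entry on a selected ligand is reported receptor by receptor
  m2 <- matrix(c(-9, -6.9,
                 -9, -8.0), nrow = 2, byrow = TRUE,
               dimnames = list(c("R1", "R2"), c("L1", "L2")))
  sel2 <- select_candidate_drugs(rank_bas_matrix(bas_matrix(m2)),
                                 avg_cut = -7.0, per_receptor_cut = -7.0)
  row_l2 <- sel2[sel2$ligand == "L2", ]
  expect_equal(row_l2$n_weak, 1L)
  expect_equal(row_l2$weak_receptors, "R1")
  expect_equal(sel2[sel2$ligand == "L1", "n_weak"], 0L)

  expect_equal(nrow(select_candidate_drugs(rank_bas_matrix(bas_matrix(m)),
                                           avg_cut = -Inf)), 0L)

  # relaxing the average cut never removes a selected ligand
  rk <- rank_bas_matrix(generate_bas_matrix(seed = 3))
  strict <- select_candidate_drugs(rk, avg_cut = -8)$ligand
  relaxed <- select_candidate_drugs(rk, avg_cut = -7)$ligand
  expect_true(all(strict %in% relaxed))
})

test_that("rule-of-five violations follow the canonical bounds", {
  digoxin <- list(mw = 780, logp = 4.84, hba = 14, hbd = 6)
  v <- lipinski_violations(digoxin)
  expect_equal(v$count, 3)
  expect_setequal(v$violated, c("MW", "HBA", "HBD"))

  imatinib <- list(mw = 493, logp = 4.04, hba = 6, hbd = 2)
  expect_equal(lipinski_violations(imatinib)$count, 0)

  expect_equal(lipinski_violations(list(mw = 0.1, logp = 0, hba = 0,
                                        hbd = 0))$count, 0)
  expect_error(lipinski_violations(list(mw = 100, logp = 1, hba = 2)),
               class = "crossdx_data_error")

  # monotone: raising any descriptor never lowers the count
  set.seed(25)
  for (rep in 1:20) {
    d <- list(mw = runif(1, 100, 900), logp = runif(1, -2, 8),
              hba = sample(0:15, 1), hbd = sample(0:8, 1))
    base <- lipinski_violations(d)$count
    for (f in c("mw", "logp", "hba", "hbd")) {
      d2 <- d; d2[[f]] <- d2[[f]] + runif(1, 0, 400)
      expect_gte(lipinski_violations(d2)$count, base)
    }
  }
})

test_that("ADMET verdicts follow the printed threshold rules", {
  expect_equal(classify_admet(list(hia = 68.58, logbb = -1.39))$hia_verdict,
               "high")
  expect_equal(classify_admet(list(hia = 68.58, logbb = -1.39))$bbb_verdict,
               "poor")
  expect_equal(classify_admet(list(hia = 80, logbb = -0.71))$bbb_verdict,
               "intermediate")
  expect_equal(classify_admet(list(hia = 80, logbb = 0.5))$bbb_verdict,
               "permeant")
  expect_equal(classify_admet(list(hia = 20, logbb = 0))$hia_verdict, "low")
  # the HIA cut is configurable (some literature uses 50%)
  expect_equal(classify_admet(list(hia = 40, logbb = 0),
                              hia_cut = 50)$hia_verdict, "low")
  expect_error(classify_admet(list(hia = 120, logbb = 0)),
               class = "crossdx_data_error")
})

test_that("shipped candidate-drug tables screen as published", {
  desc <- read_molecule_table(system.file("extdata",
                                          "candidate_drug_descriptors.tsv",
                                          package = "crossdx"))
  scr <- lipinski_screen(desc)
  expect_equal(scr$violations[scr$compound == "Digoxin"], 3L)
  expect_equal(scr$violations[scr$compound == "Imatinib"], 0L)
  expect_equal(scr$violations[scr$compound == "Dovitinib"], 0L)

  adm <- read_molecule_table(system.file("extdata",
                                         "candidate_drug_admet.tsv",
                                         package = "crossdx"))
  verdicts <- admet_screen(adm)
  expect_true(all(verdicts$hia_verdict == "high"))
  expect_equal(verdicts$bbb_verdict[verdicts$compound == "Digoxin"], "poor")
  expect_equal(verdicts$bbb_verdict[verdicts$compound == "Dovitinib"],
               "intermediate")
})

test_that("BAS matrices survive a CSV round trip with missing cells", {
  m <- unclass(generate_bas_matrix(4, 5, 2, seed = 10))
  attr(m, "strong_ligands") <- NULL
  m[2, 3] <- NA
  path <- tempfile(fileext = ".csv")
  write_bas_csv(bas_matrix(m), path)
  back <- read_bas_csv(path)
  expect_equal(unclass(back), m, tolerance = 1e-12)
})
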