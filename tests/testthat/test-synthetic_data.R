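# Synthetic-cohort generator.

test_that("same seed gives byte-identical records and RNG state is restored", {
  set.seed(999)
  before <- .Random.seed
  a <- generate_trabecula("T01", "cTnC-C", seed = 17)
  expect_identical(before, .Random.seed)
  b <- generate_trabecula("T01", "cTnC-C", seed = 17)
  expect_identical(a, b)
  c2 <- generate_trabecula("T01", "cTnC-C", seed = 18)
  expect_false(identical(a$records, c2$records))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(a$records, f1, row.names = FALSE)
  write.csv(b$records, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noiseless pipeline closure recovers the generator truth exactly", {
  for (probe in c("cTnC-E", "cRLC-BC")) {
    sim <- generate_trabecula("T01", probe, noise = noise_free(), seed = 3)
    fits <- fit_records(invert_records(sim$records))
    key <- c("trabecula_id", "sl_um", "treatment", "response_kind")
    m <- merge(fits, sim$truth, by = key, suffixes = c("", ".true"))
    expect_equal(nrow(m), nrow(sim$truth))
    expect_equal(m$pca50, m$pca50.true, tolerance = 1e-6)
    expect_equal(m$n_h, m$n_h.true, tolerance = 1e-5)
    expect_equal(m$amplitude, m$amplitude.true, tolerance = 1e-5)
    expect_equal(m$delta, m$delta.true, tolerance = 1e-6)
  }
})

test_that("activation direction matches the probe: TnC down, RLC up", {
  simC <- generate_trabecula("T01", "cTnC-C", noise = noise_free(), seed = 5)
  simR <- generate_trabecula("T01", "cRLC-BC", noise = noise_free(), seed = 5)
  expect_true(all(simC$truth$delta[simC$truth$response_kind == "p2"] < 0))
  expect_true(all(simR$truth$delta[simR$truth$response_kind == "p2"] > 0))
  # SL 2.3 is better aligned: larger d2, higher relaxed <P2>
  tC <- simC$truth[simC$truth$response_kind == "p2", ]
  expect_lt(tC$d2[tC$sl_um == 1.9][1], tC$d2[tC$sl_um == 2.3][1])
})

test_that("blebbistatin arm suppresses force and shifts pCa50 down", {
  sim <- generate_trabecula("T01", "cTnC-C", noise = noise_free(), seed = 6,
                            sls = 1.9,
                            treatments = c("control", "blebbistatin"))
  tr <- sim$truth
  f_ctrl <- tr[tr$response_kind == "force" & tr$treatment == "control", ]
  f_bleb <- tr[tr$response_kind == "force" & tr$treatment == "blebbistatin", ]
  expect_equal(f_bleb$amplitude / f_ctrl$amplitude, 0.015)
  p_ctrl <- tr[tr$response_kind == "p2" & tr$treatment == "control", ]
  p_bleb <- tr[tr$response_kind == "p2" & tr$treatment == "blebbistatin", ]
  expect_equal(p_bleb$pca50 - p_ctrl$pca50, -0.08)
  expect_lt(p_bleb$n_h, p_ctrl$n_h)
})

test_that("cohort delta for the E helix stays within 2 SEM of its truth", {
  sim <- generate_cohort(10, probe = "cTnC-E", master_seed = 31,
                         sls = 1.9)
  fits <- fit_records(invert_records(sim$records))
  dd <- fits$delta[fits$response_kind == "p2"]
  truth_mean <- mean(sim$truth$delta[sim$truth$response_kind == "p2"])
  expect_lt(abs(mean(dd) - truth_mean), 2 * sem(dd) + 1e-6)
  expect_lt(abs(mean(dd) - (-0.101)), 0.01)  # near the table-scale change
})

test_that("cohort SEMs at the study's n are within 2x of table-scale SEMs", {
  sim <- generate_cohort(5, probe = "cTnC-C", master_seed = 41)
  fits <- fit_records(invert_records(sim$records))
  p2_19 <- fits[fits$response_kind == "p2" & fits$sl_um == 1.9, ]
  # printed-scale SEMs: pCa50 ~0.02-0.03, delta ~0.005, at pCa6 ~0.005
  expect_gt(sem(p2_19$pca50), 0.02 / 2)
  expect_lt(sem(p2_19$pca50), 0.03 * 2)
  expect_lt(sem(p2_19$delta), 0.005 * 2)
  expect_lt(sem(p2_19$resp_pca6), 0.005 * 2)
})

test_that("the SL effect is detected in most small cohorts (power)", {
  # power example scaled to 30 replicates to keep the suite fast; the
  # paired design makes the +0.11 pCa50 shift essentially always visible
  hits <- vapply(1:30, function(i) {
    sim <- generate_cohort(5, probe = "cTnC-C", master_seed = 1000 + i)
    fits <- fit_records(invert_records(sim$records))
    tbl <- build_summary_table(fits, layout = "table1")
    row <- tbl[tbl$response_kind == "p2" & tbl$quantity == "pca50" &
                 tbl$condition == "SL 2.3", ]
    isTRUE(row$star)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("generator validates inputs", {
  expect_error(generate_trabecula("T01", "cTnC-C"), "seed")
  expect_error(generate_cohort(1, master_seed = 1), "n >= 2")
  expect_error(generate_trabecula("T01", "unknown-probe", seed = 1),
               "unknown probe")
})
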