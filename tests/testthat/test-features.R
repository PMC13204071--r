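test_that("missing responses fill from the preceding, then following, wave", {
  p <- as_symptom_panel(rbind(
    long_records("A", "migraine", c(1L, NA, 0L)),
    long_records("A", "dizziness", c(NA, 1L, NA)),
    long_records("A", "faintness", c(NA, NA, NA)),
    long_records("A", "numbness", c(NA, NA, 1L))))
  filled <- impute_missing(p)
  expect_equal(unname(filled$responses["A", "migraine", ]), c(1L, 1L, 0L))
  expect_equal(unname(filled$responses["A", "dizziness", ]), c(1L, 1L, 1L))
  # missing at every wave: considered absent
  expect_equal(unname(filled$responses["A", "faintness", ]), c(0L, 0L, 0L))
  expect_equal(unname(filled$responses["A", "numbness", ]), c(1L, 1L, 1L))
  # untouched trajectories (defaulted absent) remain absent
  expect_true(all(filled$responses["A", "tinnitus", ] == 0L))
})

test_that("imputation is idempotent and leaves no missing values", {
  panel <- simulate_panel(simulation_config(150, missing_rate = 0.1,
                                            seed = 31))
  once <- impute_missing(panel)
  expect_false(anyNA(once$responses))
  expect_identical(impute_missing(once)$responses, once$responses)
})

test_that("ingestion rejects unknown items and wave labels with row context", {
  bad <- long_records("A", "migraine", c(0L, 1L, 0L))
  bad$item[2] <- "headache_misc"
  expect_error(as_symptom_panel(bad), "headache_misc")
  bad2 <- long_records("A", "migraine", c(0L, 1L, 0L))
  bad2$wave[3] <- "T4"
  expect_error(as_symptom_panel(bad2), "T4")
})

test_that("48 cross-sectional measures are produced per wave with exact counts", {
  panel <- simulate_panel(simulation_config(40, seed = 17))
  ms <- build_cross_sectional_measures(panel)
  expect_equal(dim(ms), c(40L, 48L, 3L))

  # an all-absent subject scores zero everywhere
  empty <- build_cross_sectional_measures(panel_with_trajectories(list()))
  expect_true(all(empty == 0))

  # exactly the six depression items present at T1
  dep_items <- symptom_items()$item[symptom_items()$domain == "depression"]
  p <- panel_with_trajectories(
    setNames(rep(list(c(1, 0, 0)), 6), dep_items))
  m <- build_cross_sectional_measures(p)
  expect_equal(unname(m[1L, "depression_summary", "T1"]), 6)
  expect_equal(unname(m[1L, "psychological_summary", "T1"]), 6)
  expect_equal(unname(m[1L, "physical_summary", "T1"]), 0)
  expect_equal(unname(m[1L, "overall_summary", "T1"]), 6)
  expect_equal(unname(m[1L, "overall_summary", "T2"]), 0)
})

test_that("item-level pattern codes follow the trajectory definitions", {
  p <- panel_with_trajectories(list(
    migraine = c(0, 1, 1),    # early escalation + late limited persistence
    dizziness = c(1, 1, 1),   # persistent presence
    faintness = c(0, 0, 0)))  # consistent absence
  pm <- derive_pattern_features(p)
  mig <- pm[1L, paste0("migraine__P", 1:10)]
  expect_equal(unname(mig), c(1, 0, 0, 0, 0, 0, 1, 0, 0, 0))
  diz <- pm[1L, paste0("dizziness__P", 1:10)]
  expect_equal(unname(diz), c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  fai <- pm[1L, paste0("faintness__P", 1:10)]
  expect_equal(unname(fai), c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0))
})

test_that("summary-level patterns follow the count/any-symptom coding", {
  # cardiac domain (3 items) with trajectories (0,1,1), (0,0,1), (1,0,0):
  # counts per wave are (1, 1, 2)
  p <- panel_with_trajectories(list(
    arrhythmia = c(0, 1, 1), angina_pectoris = c(0, 0, 1),
    chest_pain_with_exercise = c(1, 0, 0)))
  m <- build_cross_sectional_measures(p)
  expect_equal(unname(m[1L, "cardiac_summary", ]), c(1, 1, 2))
  pm <- derive_pattern_features(m)
  card <- pm[1L, paste0("cardiac_summary__P", 1:10)]
  # one member escalated early, one late; one resolved early; none late
  expect_equal(unname(card[1:4]), c(1, 1, 1, 0))
  # any-symptom indicator is (1,1,1): summary persistent presence
  expect_equal(unname(card[5:10]), c(1, 0, 0, 0, 0, 0))
})

test_that("pattern coding metadata distinguishes binary and count columns", {
  pm <- derive_pattern_features(
    simulate_panel(simulation_config(10, seed = 1)))
  info <- attr(pm, "pattern_info")
  expect_equal(nrow(info), 480L)
  expect_equal(sum(info$coding == "continuous_count"), 11L * 4L)
  bin <- info$column[info$coding == "binary"]
  expect_true(all(pm[, bin] %in% 0:1))
  cnt <- info[info$coding == "continuous_count", ]
  expect_true(all(pm[, cnt$column] <= rep(cnt$n_members,
                                          each = nrow(pm))))
})

test_that("pattern coding laws hold on a simulated cohort", {
  panel <- impute_missing(simulate_panel(
    simulation_config(300, missing_rate = 0.02, seed = 41)))
  m <- build_cross_sectional_measures(panel)
  pm <- derive_pattern_features(m)
  info <- attr(pm, "pattern_info")
  col <- function(meas, pat) pm[, paste0(meas, "__", pat)]

  # item-level escalation/resolution exclusions (summaries may mix member
  # escalations and resolutions, so the exclusion is an item-level law)
  for (it in symptom_items()$item) {
    expect_true(all(col(it, "P1") * col(it, "P3") == 0))
    expect_true(all(col(it, "P2") * col(it, "P4") == 0))
  }
  # conservation: count changes decompose into escalations and resolutions
  for (meas in attr(m, "measure_info")$measure) {
    expect_equal(m[, meas, "T2"], m[, meas, "T1"] +
                   col(meas, "P1") - col(meas, "P3"))
    expect_equal(m[, meas, "T3"], m[, meas, "T2"] +
                   col(meas, "P2") - col(meas, "P4"))
  }
  # item-level full trajectories partition: P5..P10 mutually exclusive and
  # exhaustive jointly with the two mixed trajectories (-,+,-) and (+,-,+)
  items <- symptom_items()$item
  per <- sapply(paste0("P", 5:10), function(p)
    rowSums(pm[, paste0(items, "__", p), drop = FALSE]))
  mixed <- rowSums(sapply(items, function(it)
    col(it, "P1") * col(it, "P4") + col(it, "P3") * col(it, "P2")))
  expect_true(all(rowSums(per) + mixed == 37))
  # aggregation consistency at every wave
  for (w in c("T1", "T2", "T3"))
    expect_equal(m[, "psychological_summary", w] + m[, "physical_summary", w],
                 m[, "overall_summary", w])
  # summary consistent absence implies no member activity at all
  for (meas in summary_measures()$measure) {
    p8 <- col(meas, "P8") == 1
    expect_true(all(col(meas, "P1")[p8] == 0 & col(meas, "P2")[p8] == 0 &
                      col(meas, "P3")[p8] == 0 & col(meas, "P4")[p8] == 0))
  }
})

test_that("design matrices carry 35 and 515 columns with aligned subjects", {
  ch <- cohort_preset("null", n_subjects = 25, seed = 6)
  pm <- derive_pattern_features(ch$panel)
  Xn <- assemble_design_matrix(pm, ch$covariates, "non_symptom")
  expect_equal(ncol(Xn), 35L)
  Xs <- assemble_design_matrix(pm, ch$covariates, "symptom_enhanced")
  expect_equal(ncol(Xs), 515L)
  expect_equal(rownames(Xs), ch$panel$subjects)
  info <- attr(Xs, "column_info")
  expect_equal(as.vector(table(info$source)[c("non_symptom", "pattern")]),
               c(35L, 480L))
  # misaligned covariate table names the offending subject
  expect_error(
    assemble_design_matrix(pm, ch$covariates[-3, ], "non_symptom"), "S3")
})

test_that("pattern matrices serialize with a machine-readable sidecar", {
  pm <- derive_pattern_features(
    simulate_panel(simulation_config(8, seed = 2)))
  d <- withr::local_tempdir()
  paths <- write_pattern_matrix(pm, file.path(d, "patterns.tsv"))
  tab <- utils::read.delim(paths[1L], check.names = FALSE)
  expect_equal(dim(tab), c(8L, 481L))
  meta <- jsonlite::read_json(paths[2L], simplifyVector = TRUE)
  expect_equal(nrow(meta), 480L)
  expect_setequal(unique(meta$coding), c("binary", "continuous_count"))
})
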