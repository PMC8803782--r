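test_that("region-node matching counts TP per node and FP per region", {
  geom <- volume3d(array(0, c(50, 50, 30)), c(1, 1, 1))
  reg_at <- function(lo, hi) mediastinet:::candidate_region(
    as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])), "p1")
  r_both <- reg_at(c(5, 5, 5), c(30, 30, 20))     # covers two nodes
  r_empty <- reg_at(c(40, 40, 25), c(45, 45, 28)) # covers none
  nodes <- nodes_df("p1", rbind(c(10, 10, 10), c(20, 20, 12)))
  counts <- match_detections(list(p1 = list(r_both, r_empty)),
                             list(p1 = nodes), list(p1 = geom))
  expect_equal(counts$tp, 2L)
  expect_equal(counts$fp, 1L)
  expect_equal(counts$fn, 0L)
  expect_equal(counts$n_nodes, 2L)

  # perfect prediction and no-prediction limits
  perfect <- match_detections(list(p1 = list(reg_at(c(8, 8, 8),
                                                    c(12, 12, 12)),
                                             reg_at(c(18, 18, 10),
                                                    c(22, 22, 14)))),
                              list(p1 = nodes), list(p1 = geom))
  expect_equal(c(perfect$tp, perfect$fp, perfect$fn), c(2L, 0L, 0L))
  none <- match_detections(list(p1 = list()), list(p1 = nodes),
                           list(p1 = geom))
  expect_equal(c(none$tp, none$fp, none$fn), c(0L, 0L, 2L))
  # region size statistics are reported for the localisation check
  expect_equal(unname(counts$region_extent_mm["max"]), 26)
  expect_error(match_detections(list(ghost = list()), list(p1 = nodes),
                                list(p1 = geom)), "unknown patient")
})

test_that("sensitivity and FPs/patient reproduce the published table rows", {
  c1 <- detection_counts(tp = 45, fp = 12, fn = 7, n_patients = 29)
  expect_equal(round_half_up(sensitivity(c1)), 0.87)
  expect_equal(round_half_up(fps_per_patient(c1)), 0.41)
  expect_equal(fps_per_patient(detection_counts(1, 0, 0, 5)), 0)
  expect_warning(s <- sensitivity(detection_counts(0, 3, 0, 5)),
                 "undefined")
  expect_true(is.nan(s))
})

test_that("kappa under the 8.3-nodes/patient convention reproduces the published value", {
  counts <- detection_counts(tp = 45, fp = 12, fn = 7, n_patients = 29)
  expect_equal(convention_tn(counts), 176.7)
  k <- cohen_kappa(counts)
  expect_equal(round_half_up(k$kappa), 0.77)
  expect_equal(k$band, "substantial")
  # perfect agreement
  expect_equal(cohen_kappa(tp = 10, fp = 0, fn = 0, tn = 30)$kappa, 1.0)
  # agreement with the textbook contingency-table oracle on random tables
  set.seed(19)
  for (rep in 1:20) {
    tab <- matrix(sample(1:60, 4, TRUE), 2)
    k1 <- cohen_kappa(tp = tab[1, 1], fn = tab[1, 2], fp = tab[2, 1],
                      tn = tab[2, 2])$kappa
    expect_equal(k1, oracle_kappa(tab), tolerance = 1e-12)
    # invariant under swapping the raters (transposing the table)
    k2 <- cohen_kappa(tp = tab[1, 1], fn = tab[2, 1], fp = tab[1, 2],
                      tn = tab[2, 2])$kappa
    expect_equal(k1, k2, tolerance = 1e-12)
  }
  expect_error(cohen_kappa(tp = 5, fp = 0, fn = 0, tn = 0), "degenerate")
  # landis-koch bands
  expect_equal(landis_koch_band(0.9), "almost perfect")
  expect_equal(landis_koch_band(0.77), "substantial")
  expect_equal(landis_koch_band(0.5), "moderate")
  expect_equal(landis_koch_band(0.3), "fair")
})

test_that("Clopper-Pearson equals binomial-tail inversion and paper CIs", {
  # boundary closed forms
  expect_equal(unname(clopper_pearson(0, 10)["lower"]), 0)
  expect_equal(unname(clopper_pearson(10, 10)["upper"]), 1)
  # published sensitivity intervals after 2-dp rounding
  expect_equal(unname(round_half_up(clopper_pearson(45, 52))), c(0.74, 0.94))
  expect_equal(unname(round_half_up(clopper_pearson(18, 34))), c(0.35, 0.70))
  expect_equal(unname(round_half_up(clopper_pearson(30, 34))), c(0.73, 0.97))
  # exact match with the bisection oracle over a grid of (x, n)
  set.seed(29)
  for (n in c(1, 7, 34, 52, 200)) {
    for (x in unique(c(0, 1, sample(0:n, min(5, n + 1)), n))) {
      expect_equal(clopper_pearson(x, n), oracle_clopper_pearson(x, n),
                   tolerance = 1e-9)
    }
  }
  # interval always contains the point estimate; width shrinks with n
  ci1 <- clopper_pearson(8, 10)
  expect_true(ci1["lower"] <= 0.8 && ci1["upper"] >= 0.8)
  ci2 <- clopper_pearson(80, 100)
  expect_lt(diff(ci2), diff(ci1))
  expect_error(clopper_pearson(5, 4), "successes")
  expect_error(clopper_pearson(-1, 4), "successes")
})

test_that("printed 2-dp rates invert to unique integer counts", {
  expect_equal(recover_count(0.87, 52), 45L)
  expect_equal(recover_count(0.41, 29), 12L)
  expect_equal(recover_count(0.50, 2), 1L)
  expect_equal(recover_count(0.53, 34), 18L)
  expect_equal(recover_count(0.88, 34), 30L)
  expect_equal(recover_count(0.69, 29), 20L)
  expect_equal(recover_count(0.24, 29), 7L)
  # ambiguity is surfaced, not resolved: with a large denominator many
  # integers print identically
  expect_error(recover_count(0.5, 1000), "ambiguous")
  expect_error(recover_count(0.07, 4), "no")
  expect_error(recover_count(0.5, 0), "denominator")
  # round trip: recover(sensitivity rounded) == tp for random counts
  set.seed(37)
  for (rep in 1:25) {
    tp <- sample(0:40, 1); fn <- sample(0:40, 1)
    if (tp + fn == 0 || tp + fn > 90) next
    rate <- round_half_up(tp / (tp + fn))
    hits <- tryCatch(recover_count(rate, tp + fn), error = function(e) NA)
    if (!is.na(hits)) expect_equal(hits, tp)
  }
})

test_that("cohort evaluation assembles the full published summary", {
  s1 <- evaluate_cohort(detection_counts(45, 12, 7, 29))
  expect_equal(round_half_up(s1$sensitivity), 0.87)
  expect_equal(unname(round_half_up(s1$sensitivity_ci)), c(0.74, 0.94))
  expect_equal(round_half_up(s1$fps_per_patient), 0.41)
  expect_equal(unname(round_half_up(s1$fps_per_patient_ci)), c(0.22, 0.71))
  expect_equal(round_half_up(s1$kappa), 0.77)
  expect_equal(s1$kappa_band, "substantial")

  s2 <- evaluate_cohort(detection_counts(18, 7, 16, 29))
  expect_equal(round_half_up(s2$sensitivity), 0.53)
  expect_equal(unname(round_half_up(s2$sensitivity_ci)), c(0.35, 0.70))
  expect_equal(unname(round_half_up(s2$fps_per_patient_ci)), c(0.10, 0.49))

  s3 <- evaluate_cohort(detection_counts(30, 20, 4, 29))
  expect_equal(round_half_up(s3$sensitivity), 0.88)
  expect_equal(unname(round_half_up(s3$sensitivity_ci)), c(0.73, 0.97))
  expect_equal(unname(round_half_up(s3$fps_per_patient_ci)), c(0.43, 1.04))

  # perfect phantom detector limit
  sp <- evaluate_cohort(detection_counts(10, 0, 0, 6))
  expect_equal(sp$sensitivity, 1.0)
  expect_equal(sp$fps_per_patient, 0.0)
  expect_equal(sp$kappa, 1.0)

  # JSON report round trip
  f <- tempfile(fileext = ".json")
  write_eval_summary(s1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$kappa, s1$kappa)
  expect_equal(back$counts$tp, 45L)
  expect_match(paste(as_report(s1), collapse = "\n"), "0.87")
})
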