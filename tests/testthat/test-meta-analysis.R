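lit_record <- function(study = "s1", label = "intact", top = 0, bottom = 10,
                       kind = "SOC", c_gkg = 50, n_gkg = 4, bd = 1.0,
                       region = "Nagqu") {
  data.frame(study_id = study, degradation_label = label,
             depth_top_cm = top, depth_bottom_cm = bottom,
             carbon_kind = kind, carbon_g_kg = c_gkg, n_g_kg = n_gkg,
             bd_g_cm3 = bd, region = region, year = 2015L,
             mapped_stage = NA_character_)
}

test_that("regroup_stage maps labels exactly and never guesses", {
  expect_equal(regroup_stage("non-degraded"), "S0")
  expect_equal(regroup_stage("  Bare Soil "), "S5")  # case/whitespace folded
  expect_error(regroup_stage("slight degradation of turf"),
               "unmapped degradation label", class = "data_error")
  expect_warning(
    out <- regroup_stage("mystery label", allow_drop = TRUE),
    "dropping")
  expect_true(is.na(out))
})

test_that("inclusion criteria reject with named reasons", {
  recs <- rbind(
    lit_record("s1", "intact"),
    lit_record("s1", "bare soil", c_gkg = 25),
    lit_record("s2", "severely degraded"),              # study without reference
    lit_record("s3", "intact"),
    lit_record("s3", "bare soil", top = 0, bottom = 20),  # wrong interval
    lit_record("s4", "intact"),
    lit_record("s4", "odd wording"),                    # unmapped label
    lit_record("s5", "intact", c_gkg = NA, n_gkg = NA, bd = NA))  # no data
  out <- apply_inclusion_criteria(recs)
  expect_equal(nrow(out$kept), 4)  # s1 both, s3 & s4 references
  reason_of <- function(study, label) {
    out$rejected$reject_reason[out$rejected$study_id == study &
                                 out$rejected$degradation_label == label]
  }
  expect_match(reason_of("s2", "severely degraded"), "no reference")
  expect_match(reason_of("s3", "bare soil"), "interval != 10 cm")
  expect_match(reason_of("s4", "odd wording"), "unclassified stage")
  expect_match(reason_of("s5", "intact"), "no SOC/N/BD data")
  expect_true(all(out$kept$mapped_stage %in% degradation_stages()))
})

test_that("a fully compliant study is kept in its entirety", {
  recs <- rbind(lit_record("s1", "intact"),
                lit_record("s1", "moderately degraded", c_gkg = 35),
                lit_record("s1", "bare soil", c_gkg = 25))
  out <- apply_inclusion_criteria(recs)
  expect_equal(nrow(out$kept), 3)
  expect_equal(nrow(out$rejected), 0)
})

test_that("record_stock harmonizes SOM and requires bulk density", {
  som <- lit_record(kind = "SOM", c_gkg = 40, bd = 1.0)
  expect_equal(record_stock(som, "C"), 20000)  # 20 g/kg * 1.0 * 10 cm * 100
  expect_equal(record_stock(lit_record(c_gkg = 0), "C"), 0)
  expect_error(record_stock(lit_record(bd = NA), "C"), "stock unavailable",
               class = "data_error")
})

test_that("effect_size follows 100*(D-R)/R and is scale-invariant", {
  expect_equal(effect_size(100, 100), 0)
  expect_equal(effect_size(58, 100), -42)
  expect_equal(effect_size(150, 100), 50)
  expect_error(effect_size(5, 0), "undefined effect size",
               class = "data_error")
  set.seed(31)
  D <- runif(50, 1, 100); R <- runif(50, 1, 100); k <- runif(50, 0.1, 10)
  expect_equal(effect_size(k * D, k * R), effect_size(D, R),
               tolerance = 1e-12)
})

test_that("aggregate_effects reports mean, SE and n per cell", {
  eff <- data.frame(study_id = c("a", "b", "c"), variable = "SOC",
                    basis = "stock", stage = c("S5", "S5", "S4"),
                    depth_top_cm = 0, depth_bottom_cm = 10,
                    effect_pct = c(-40, -44, 0))
  agg <- aggregate_effects(eff)
  s5 <- agg[agg$stage == "S5", ]
  expect_equal(s5$mean_pct, -42)
  expect_equal(s5$se_pct, 2)
  expect_equal(s5$n, 2L)
  s4 <- agg[agg$stage == "S4", ]
  expect_equal(s4$mean_pct, 0)
  expect_true(is.na(s4$se_pct))  # single observation: SE undefined
})

test_that("effect sizes fall back to contents when BD is missing", {
  corpus <- generate_literature_corpus(n_studies = 12, missing_bd_prob = 1,
                                       seed = 4)
  kept <- apply_inclusion_criteria(corpus)$kept
  eff <- compute_effect_sizes(kept)
  expect_true(nrow(eff) > 0)
  expect_false(any(eff$basis == "stock"))
  expect_true(all(eff$basis %in% c("content", "bd")))
})

test_that("a noise-free corpus returns the true effects exactly", {
  corpus <- generate_literature_corpus(n_studies = 15, between_study_sd = 0,
                                       missing_bd_prob = 0.3,
                                       som_report_prob = 0.5, seed = 8)
  kept <- apply_inclusion_criteria(corpus)$kept
  agg <- aggregate_effects(compute_effect_sizes(kept))
  soc <- agg[agg$variable == "SOC" & agg$stage == "S5" &
               agg$depth_top_cm == 0, ]
  # stock- and content-basis cells must both sit at the generative truth
  expect_equal(soc$mean_pct, rep(-42, nrow(soc)), tolerance = 1e-9)
})

test_that("the aggregated mean converges to the true effect with many studies", {
  corpus <- generate_literature_corpus(n_studies = 60, between_study_sd = 8,
                                       seed = 12)
  kept <- apply_inclusion_criteria(corpus)$kept
  agg <- aggregate_effects(compute_effect_sizes(kept))
  soc <- agg[agg$variable == "SOC" & agg$basis == "stock" &
               agg$stage == "S5" & agg$depth_top_cm == 0, ]
  expect_lt(abs(soc$mean_pct - (-42)), 2 * soc$se_pct)
})

test_that("per-study aggregation weights studies, not observations", {
  eff <- data.frame(study_id = c("a", "a", "a", "b"), variable = "SOC",
                    basis = "stock", stage = "S5",
                    depth_top_cm = 0, depth_bottom_cm = 10,
                    effect_pct = c(-10, -10, -10, -50))
  agg <- aggregate_effects(eff, per_study = TRUE)
  expect_equal(agg$mean_pct, -30)  # (-10 + -50)/2, not observation-weighted
  expect_equal(agg$n, 2L)
})
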