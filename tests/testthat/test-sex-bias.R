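test_that("sex ratios replace zero operands by the pseudocount", {
  expect_equal(log2_sex_ratio(8, 8), 0)
  expect_equal(log2_sex_ratio(8, 0), 3)    # zero ovary -> pseudocount 1
  expect_equal(log2_sex_ratio(1, 4), -2)
  expect_equal(log2_sex_ratio(0, 0), 0)    # both zero -> log2(1/1)
  expect_true(is.na(log2_sex_ratio(NA, NA)))  # absent in both tissues
  expect_equal(log2_sex_ratio(c(2, 0), c(1, 4), pseudocount = 2), c(1, -1))
  expect_error(log2_sex_ratio(-1, 2), ">= 0")

  # ratios are finite for any non-negative, not-both-absent inputs
  set.seed(81)
  t_ <- c(0, rexp(50, 1 / 10))
  o_ <- c(rexp(50, 1 / 10), 0)
  expect_true(all(is.finite(log2_sex_ratio(t_, o_))))
})

test_that("species bias classification uses inclusive boundaries", {
  expect_identical(classify_species_bias(-1.72), "female")
  expect_identical(classify_species_bias(0.5), "none")
  expect_identical(classify_species_bias(1.0), "male")
  expect_identical(classify_species_bias(-1.0), "female")
  expect_identical(classify_species_bias(c(-3, 0.2, 2, NA)),
                   c("female", "none", "male", NA))
})

test_that("bias tallies reproduce published worked examples", {
  expect_equal(tally_bias(c(-3.05, -2.81, -3.05, -2.5, -2.86, 1.15)),
               c(count_O = 5L, count_T = 1L))
  expect_equal(tally_bias(c(3.85, -1.98, 5.4, 1.83, 1.1, -3.12, 4.74)),
               c(count_O = 2L, count_T = 5L))
  expect_equal(tally_bias(numeric(0)), c(count_O = 0L, count_T = 0L))
})

test_that("the marker rule needs five biased species including the focal one", {
  cfg <- pipeline_config()
  # biased female in only four species -> none
  r4 <- ratio_row("m4", c(-2, -2, -2, -2, 0, 0, 0, 0, 0, 0))
  expect_identical(call_conserved_markers(r4, cfg)$call, "none")
  # five female species including dla -> female
  r5 <- ratio_row("m5", c(-2, -2, -2, -2, -1, 0, 0, 0, 0, 0))
  expect_identical(call_conserved_markers(r5, cfg)$call, "female")
  # six male species but a neutral focal ratio -> none
  rf <- ratio_row("mf", c(0.2, 2, 2, 2, 2, 2, 2, 0, 0, 0))
  expect_identical(call_conserved_markers(rf, cfg)$call, "none")
  # focal species without any ratio is never a marker
  rna <- ratio_row("mna", c(NA, -2, -2, -2, -2, -2, -2, NA, NA, NA))
  expect_identical(call_conserved_markers(rna, cfg)$call, "none")
})

test_that("swapping tissue labels maps female calls to male calls exactly", {
  set.seed(82)
  rows <- do.call(rbind, lapply(1:40, function(i) {
    ratio_row(sprintf("m%02d", i),
              round(runif(10, -4, 4) * sample(c(1, NA), 10, TRUE,
                                              c(0.8, 0.2)), 2))
  }))
  cfg <- pipeline_config()
  fwd <- call_conserved_markers(rows, cfg)
  flipped <- rows
  for (sp in FISH_SPECIES) flipped[[sp]] <- -flipped[[sp]]
  rev <- call_conserved_markers(flipped, cfg)
  rev <- rev[match(fwd$id, rev$id), ]
  expect_identical(rev$call[fwd$call == "female"],
                   rep("male", sum(fwd$call == "female")))
  expect_identical(rev$call[fwd$call == "male"],
                   rep("female", sum(fwd$call == "male")))
  expect_identical(rev$call[fwd$call == "none"],
                   rep("none", sum(fwd$call == "none")))
  expect_identical(rev$count_O, fwd$count_T)
  expect_identical(rev$count_T, fwd$count_O)
})

test_that("raising the bias threshold never increases tallies or marker counts", {
  set.seed(83)
  rows <- do.call(rbind, lapply(1:30, function(i) {
    ratio_row(sprintf("m%02d", i), round(runif(10, -4, 4), 2))
  }))
  thresholds <- c(0.5, 1, 1.5, 2.5)
  prev <- NULL
  for (thr in thresholds) {
    cfg <- pipeline_config(log2_bias_threshold = thr)
    mk <- call_conserved_markers(rows, cfg)
    mk <- mk[match(rows$id, mk$id), ]
    if (!is.null(prev)) {
      expect_true(all(mk$count_O <= prev$count_O))
      expect_true(all(mk$count_T <= prev$count_T))
      expect_lte(sum(mk$call != "none"), sum(prev$call != "none"))
    }
    prev <- mk
  }
})

test_that("marker output ordering is deterministic and diffable", {
  rows <- rbind(
    ratio_row("b-male", c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0)),
    ratio_row("a-fem", c(-2, -2, -2, -2, -2, -2, 0, 0, 0, 0)),
    ratio_row("c-none", c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)))
  mk <- call_conserved_markers(rows, pipeline_config())
  expect_identical(mk$id, c("a-fem", "b-male", "c-none"))
})

test_that("ratio tables respect annotation presence and aggregate by seed", {
  profs <- list(
    species_profile("dla", "ovary", c(m1 = 4, m2 = 8)),
    species_profile("dla", "testis", c(m1 = 16, m2 = 2)),
    species_profile("dre", "ovary", c(m1 = 10)),
    species_profile("dre", "testis", c(m1 = 10)))
  ann <- data.frame(
    name = c("m1", "m2", "m1"),
    species = c("dla", "dla", "dre"),
    mature_seq = c("ACGUACGUACGUACGUACGUAC", "AAGUACGUACGUACGUACGUAC",
                   "ACGUACGUACGUACGUACGUAC"),
    stringsAsFactors = FALSE)
  ann$seed <- extract_seed(ann$mature_seq)
  rt <- sex_ratio_table(profs, ann, level = "mature")
  expect_equal(rt$dla[rt$id == "m1"], 2)          # log2(16/4)
  expect_equal(rt$dre[rt$id == "m1"], 0)
  # m2 absent from dre's annotation: no ratio, not zero
  expect_true(is.na(rt$dre[rt$id == "m2"]))

  # seed level sums mature values sharing a seed
  ann2 <- ann
  ann2$seed[2] <- ann2$seed[1]  # m1 and m2 share a seed in dla
  rts <- sex_ratio_table(profs, ann2, level = "seed")
  expect_equal(rts$dla[rts$id == ann2$seed[1]], log2((16 + 2) / (4 + 8)))
})

test_that("planted panel sex bias is recovered and sparse bias is never called", {
  # strong female bias planted in six species including the focal one
  planted <- data.frame(
    id = sprintf("mir-sim-%d", 1:8), direction = "female", effect = 3,
    species = "dla,ola,aca,gac,dre,loc", stringsAsFactors = FALSE)
  sc <- simulation_config(n_mirnas = 150, core_seed_fraction = 1,
                          planted_sex_biased = planted, rng_seed = 19)
  panel <- simulate_species_panel(sc)
  rt <- sex_ratio_table(panel$profiles, panel$annotation)
  mk <- call_conserved_markers(rt, pipeline_config())
  calls <- mk$call[match(planted$id, mk$id)]
  expect_gte(mean(calls == "female"), 0.9)

  # the same bias planted in only three species is never a marker
  sparse <- planted
  sparse$species <- "dla,ola,aca"
  sc2 <- simulation_config(n_mirnas = 150, core_seed_fraction = 1,
                           planted_sex_biased = sparse, rng_seed = 23)
  panel2 <- simulate_species_panel(sc2)
  mk2 <- call_conserved_markers(sex_ratio_table(panel2$profiles,
                                                panel2$annotation),
                                pipeline_config())
  expect_identical(unique(mk2$call[match(sparse$id, mk2$id)]), "none")
})
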