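make_tbl_from_age_values <- function(values_by_age, medium = "grains") {
  # one-medium grid with prescribed per-age-group values, rest zero
  media <- media_roster()$medium
  vals <- rep(0, 110)
  idx <- which(media == medium)
  vals[(idx - 1) * 11 + seq_len(11)] <- values_by_age
  import_add_table(write_grid_csv(vals), "case")
}

test_that("time-weighted regrouping reproduces hand-computed lifestage doses", {
  # constant member doses pass through unchanged
  tbl <- make_tbl_from_age_values(c(12, 12, 12, 12, rep(0, 7)))
  ls <- regroup_lifestages(tbl)
  yi <- ls$doses[ls$doses$lifestage == "young_infant" & ls$doses$medium == "grains", ]
  expect_equal(yi$add, 12)

  # month weights 1, 2, 3, 6 over the four sub-year groups
  tbl2 <- make_tbl_from_age_values(c(1, 2, 3, 4, rep(0, 7)))
  ls2 <- regroup_lifestages(tbl2)
  yi2 <- ls2$doses[ls2$doses$lifestage == "young_infant" & ls2$doses$medium == "grains", ]
  expect_equal(yi2$add, 38 / 12) # (1*1 + 2*2 + 3*3 + 4*6) / 12
  expect_equal(yi2$add, 3.1667, tolerance = 1e-4)

  # single-member lifestage is an identity
  tbl3 <- make_tbl_from_age_values(c(rep(0, 6), 5.5, rep(0, 4)))
  ls3 <- regroup_lifestages(tbl3)
  yc <- ls3$doses[ls3$doses$lifestage == "young_child" & ls3$doses$medium == "grains", ]
  expect_equal(yc$add, 5.5)
})

test_that("each lifestage dose lies between its member extremes and preserves order", {
  tbl <- random_add_tbl(11)
  ls <- regroup_lifestages(tbl)
  map <- lifestage_map()
  for (st in lifestage_levels()) {
    members <- map$age_group[map$lifestage == st]
    for (m in c("soil", "breastmilk", "grains")) {
      mem_vals <- tbl$add[tbl$age_group %in% members & tbl$medium == m]
      got <- ls$doses$add[ls$doses$lifestage == st & ls$doses$medium == m]
      eps <- 1e-12 # weighted means may spill over the extremes by an ulp
      expect_gte(got, min(mem_vals) - eps)
      expect_lte(got, max(mem_vals) + eps)
    }
  }
  # strictly larger members give a strictly larger lifestage dose
  hi <- make_tbl_from_age_values(c(9, 8, 9, 10, 1, 2, rep(0, 5)))
  lsx <- regroup_lifestages(hi)
  d <- lsx$doses[lsx$doses$medium == "grains", ]
  expect_gt(
    d$add[d$lifestage == "young_infant"],
    d$add[d$lifestage == "infant"]
  )
})

test_that("regrouping agrees with a brute-force month-expansion oracle", {
  for (seed in c(1, 2, 3)) {
    tbl <- random_add_tbl(seed)
    ls <- regroup_lifestages(tbl)
    oracle <- month_expansion_oracle(tbl)
    for (m in names(oracle)) {
      got <- ls$doses[ls$doses$row_type == "lifestage" & ls$doses$medium == m, ]
      want <- oracle[[m]][as.character(got$lifestage)]
      expect_equal(got$add, as.numeric(want), tolerance = 1e-9)
    }
  }
})

test_that("LADD applies the lifestage-years over lifespan ratio", {
  tbl <- make_tbl_from_age_values(c(rep(0, 10), 1.0)) # adult only
  ls <- regroup_lifestages(tbl)
  adult <- ls$doses[ls$doses$lifestage == "adult" & ls$doses$medium == "grains", ]
  expect_equal(adult$ladd, 0.7) # 1.0 * 49 / 70

  tbl2 <- make_tbl_from_age_values(c(7, 7, 7, 7, rep(0, 7)))
  ls2 <- regroup_lifestages(tbl2)
  yi <- ls2$doses[ls2$doses$lifestage == "young_infant" & ls2$doses$medium == "grains", ]
  expect_equal(yi$ladd, 0.1) # 7.0 * 1 / 70
  # zero ADD stays zero
  expect_equal(ls2$doses$ladd[ls2$doses$add == 0], rep(0, sum(ls2$doses$add == 0)))
  # custom lifespan rescales
  ls35 <- compute_ladd(ls2, lifespan_years = 35)
  yi35 <- ls35$doses[ls35$doses$lifestage == "young_infant" & ls35$doses$medium == "grains", ]
  expect_equal(yi35$ladd, 0.2)
})

test_that("lifestage LADDs sum to the lifetime aggregate per medium", {
  tbl <- random_add_tbl(5)
  ls <- regroup_lifestages(tbl)
  stage <- ls$doses[ls$doses$row_type == "lifestage", ]
  lifetime <- ls$doses[ls$doses$lifestage == "lifetime", ]
  sums <- tapply(stage$ladd, as.character(stage$medium), sum)
  expect_equal(
    as.numeric(sums[as.character(lifetime$medium)]),
    lifetime$add,
    tolerance = 1e-12
  )
  # and the lifetime row equals sum_j ADD_j * Y_j / 70 algebraically
  alt <- tapply(stage$add * stage$years / 70, as.character(stage$medium), sum)
  expect_equal(as.numeric(alt[as.character(lifetime$medium)]), lifetime$add)
})

test_that("aggregate rows are time-weighted over childhood, adulthood and lifetime", {
  # constant dose collapses all aggregates to that constant
  tbl <- import_add_table(write_grid_csv(rep(3, 110)), "const")
  ag <- compute_aggregates(tbl)
  expect_equal(unique(ag$add), 3)

  # childhood 2, adult 0 -> lifetime 2 * 21/70
  vals <- c(rep(2, 10), 0)
  tbl2 <- make_tbl_from_age_values(vals)
  ag2 <- compute_aggregates(tbl2)
  g <- ag2[ag2$medium == "grains", ]
  expect_equal(g$add[g$lifestage == "childhood"], 2)
  expect_equal(g$add[g$lifestage == "adult_agg"], 0)
  expect_equal(g$add[g$lifestage == "lifetime"], 0.6)
  expect_equal(g$years, c(21, 49, 70))
})

test_that("percent contributions are ratios of lifestage doses", {
  # one nonzero medium takes 100%
  tbl <- make_tbl_from_age_values(rep(4, 11))
  pct <- percent_contributions(regroup_lifestages(tbl))
  expect_equal(pct$percent[pct$medium == "grains"], rep(100, 10))

  # two media at 1 and 3 split 25/75; equal media split 50/50
  media <- media_roster()$medium
  vals <- rep(0, 110)
  vals[(which(media == "meat") - 1) * 11 + seq_len(11)] <- 1
  vals[(which(media == "fish") - 1) * 11 + seq_len(11)] <- 3
  pct2 <- percent_contributions(regroup_lifestages(import_add_table(write_grid_csv(vals))))
  expect_equal(pct2$percent[pct2$medium == "meat"], rep(25, 10))
  expect_equal(pct2$percent[pct2$medium == "fish"], rep(75, 10))

  vals[vals == 3] <- 1
  pct3 <- percent_contributions(regroup_lifestages(import_add_table(write_grid_csv(vals))))
  expect_equal(pct3$percent[pct3$medium %in% c("meat", "fish")], rep(50, 20))

  # rows always total 100 unless flagged empty
  pct4 <- percent_contributions(regroup_lifestages(random_add_tbl(9)))
  totals <- tapply(pct4$percent, as.character(pct4$lifestage), sum)
  expect_equal(as.numeric(totals), rep(100, 10), tolerance = 1e-9)
})

test_that("zero-dose lifestages yield flagged all-zero percent rows, not NaN", {
  tbl <- import_add_table(write_grid_csv(rep(0, 110)), "empty")
  pct <- percent_contributions(regroup_lifestages(tbl))
  expect_true(all(pct$empty))
  expect_true(all(pct$percent == 0))
  expect_false(any(is.nan(pct$percent)))
})

test_that("tidy and glance expose the fitted dose table", {
  ls <- regroup_lifestages(random_add_tbl(3, "SynthX"))
  td <- tidy(ls)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 100) # (7 lifestages + 3 aggregates) x 10 media
  expect_named(
    td,
    c("row_type", "lifestage", "medium", "years", "add", "ladd", "percent", "empty")
  )
  expect_equal(nrow(tidy(ls, include_aggregates = FALSE)), 70)
  gl <- glance(ls)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$chemical, "SynthX")
  expect_equal(gl$n_lifestages, 7L)
})
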