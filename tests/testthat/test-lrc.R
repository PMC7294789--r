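# Scores are checked against hand evaluations of the weighted-proportion
# formula on pedigrees with known kinship weights, using flat-hazard tables
# whose percentile has the closed form 1 - exp(-h t).

# with h = 0.05, the top-10% age is -log(0.1)/0.05 = 46.05 years
LL_AGE <- 90   # comfortably top 10%
AVG_AGE <- 30  # comfortably below

test_that("worked examples reproduce the weighted-proportion formula", {
  tabs <- flat_tables(h = 0.05)

  # both parents long-lived, no other usable relatives
  ped <- pedigree(rbind(
    person_row("pa", sex = "male", birth_year = 1890, age_end = LL_AGE),
    person_row("mo", sex = "female", birth_year = 1895, age_end = LL_AGE),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  ))
  r <- lrc_score(ped, "focal", tabs)
  expect_equal(r$score, 1.0)
  expect_equal(r$weighted_total, 1.0)

  # one of two equally weighted relatives long-lived -> 0.5
  ped2 <- pedigree(rbind(
    person_row("pa", sex = "male", birth_year = 1890, age_end = LL_AGE),
    person_row("mo", sex = "female", birth_year = 1895, age_end = AVG_AGE),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  ))
  expect_equal(lrc_score(ped2, "focal", tabs)$score, 0.5)

  # 1 long-lived parent (0.5) + 1 average parent (0.5) + 4 average
  # grandparents (0.25 each): 0.5 / 2.0 = 0.25
  ped3 <- pedigree(rbind(
    person_row("gf1", sex = "male", birth_year = 1860, age_end = AVG_AGE),
    person_row("gm1", sex = "female", birth_year = 1862, age_end = AVG_AGE),
    person_row("gf2", sex = "male", birth_year = 1864, age_end = AVG_AGE),
    person_row("gm2", sex = "female", birth_year = 1866, age_end = AVG_AGE),
    person_row("pa", "gf1", "gm1", "male", 1890, LL_AGE),
    person_row("mo", "gf2", "gm2", "female", 1895, AVG_AGE),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  ))
  r3 <- lrc_score(ped3, "focal", tabs)
  expect_equal(r3$score, 0.25)
  expect_equal(r3$weighted_total, 2.0)
  expect_equal(r3$n_relatives_used, 6)
  # per-relative detail reproduces every term
  expect_equal(sum(r3$detail$weight[r3$detail$used & r3$detail$longlived]),
               r3$weighted_longlived)
})

test_that("inclusion rules handle missing ages and alive relatives", {
  tabs <- flat_tables(h = 0.05)
  ped <- pedigree(rbind(
    person_row("pa", sex = "male", birth_year = 1890, age_end = LL_AGE),
    person_row("mo", sex = "female", birth_year = 1895, age_end = NA,
               vital_status = "unknown"),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  ))
  r <- lrc_score(ped, "focal", tabs)
  expect_equal(r$score, 1.0)           # missing-age mother in neither sum
  expect_equal(r$weighted_total, 0.5)
  expect_equal(r$n_relatives_excluded, 1)

  alive <- pedigree(rbind(
    person_row("pa", sex = "male", birth_year = 1890, age_end = LL_AGE,
               vital_status = "alive"),
    person_row("mo", sex = "female", birth_year = 1895, age_end = AVG_AGE),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  ))
  # default: alive excluded entirely
  r1 <- lrc_score(alive, "focal", tabs)
  expect_equal(r1$score, 0)
  expect_equal(r1$weighted_total, 0.5)
  # alive_if_exceeds: father's current age already beats the threshold
  cfg <- lrc_config(alive_rule = "alive_if_exceeds")
  r2 <- lrc_score(alive, "focal", tabs, cfg)
  expect_equal(r2$score, 0.5)
  # but an alive relative below the threshold still drops out
  alive2 <- pedigree(rbind(
    person_row("pa", sex = "male", birth_year = 1890, age_end = AVG_AGE,
               vital_status = "alive"),
    person_row("mo", sex = "female", birth_year = 1895, age_end = AVG_AGE),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  ))
  expect_equal(lrc_score(alive2, "focal", tabs, cfg)$weighted_total, 0.5)
})

test_that("unscorable persons are flagged, never scored 0", {
  tabs <- flat_tables(h = 0.05)
  ped <- pedigree(rbind(
    person_row("pa", sex = "male", birth_year = 1890, age_end = NA,
               vital_status = "unknown"),
    person_row("mo", sex = "female", birth_year = 1895, age_end = NA,
               vital_status = "unknown"),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  ))
  r <- lrc_score(ped, "focal", tabs)
  expect_true(is.na(r$score))
  expect_identical(classify_lrc(r), "unscorable")
})

test_that("a missing life table names the offending relative", {
  tabs <- flat_tables(h = 0.05, years = 1900:1930)  # father's 1890 absent
  ped <- pedigree(rbind(
    person_row("pa", sex = "male", birth_year = 1890, age_end = LL_AGE),
    person_row("focal", "pa", NA, "female", 1920, 70)
  ))
  expect_error(lrc_score(ped, "focal", tabs), "relative 'pa'")
})

test_that("classification boundaries follow the printed cut-offs", {
  cfg <- lrc_config()
  expect_identical(classify_lrc(0, cfg), "family_control")
  expect_identical(classify_lrc(0.10, cfg), "unselected_low")
  expect_identical(classify_lrc(0.1999, cfg), "unselected_low")
  expect_identical(classify_lrc(0.20, cfg), "nonclassified")
  expect_identical(classify_lrc(0.25, cfg), "nonclassified")
  expect_identical(classify_lrc(0.2999, cfg), "nonclassified")
  expect_identical(classify_lrc(0.30, cfg), "family_case")  # boundary in
  expect_identical(classify_lrc(1, cfg), "family_case")
  expect_error(classify_lrc(1.2, cfg), "\\[0, 1\\]")
  expect_error(lrc_config(nonclassified_band = c(0.2, 0.25)), "abut")
})

test_that("the nine bins partition [0,1] with printed edges", {
  expect_identical(as.character(lrc_bins(c(0, 0.05, 0.95))),
                   c("g1", "g2", "g9"))
  edges <- c(0, 1e-9, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 1.0)
  expect_identical(as.character(lrc_bins(edges)),
                   c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8", "g9", "g9"))
  set.seed(99)
  x <- runif(10000)
  b <- lrc_bins(x)
  expect_false(anyNA(b))
  expect_identical(sum(table(b)), 10000L)  # exhaustive, mutually exclusive
  expect_error(lrc_bins(-0.1), "\\[0, 1\\]")
  expect_error(lrc_bins(1.1), "\\[0, 1\\]")
  expect_true(is.na(lrc_bins(NA)))
})

test_that("score matches brute-force re-evaluation on randomized pedigrees", {
  tabs <- flat_tables(h = 0.05)
  h <- 0.05
  set.seed(1234)
  for (i in 1:1000) {
    # random three-generation pedigree: 2 parents, 0-4 grandparents,
    # 0-3 aunts/uncles, random ages (some missing)
    n_gp <- sample(0:4, 1); n_au <- sample(0:3, 1)
    rows <- list(
      person_row("pa", if (n_gp >= 1) "gf1" else NA,
                 if (n_gp >= 2) "gm1" else NA, "male", 1890,
                 sample(c(NA, runif(1, 20, 100)), 1)),
      person_row("mo", if (n_gp >= 3) "gf2" else NA,
                 if (n_gp >= 4) "gm2" else NA, "female", 1895,
                 sample(c(NA, runif(1, 20, 100)), 1)),
      person_row("focal", "pa", "mo", "female", 1920, 70))
    if (n_gp >= 1) rows <- c(rows, list(person_row("gf1", sex = "male",
      birth_year = 1860, age_end = runif(1, 20, 100))))
    if (n_gp >= 2) rows <- c(rows, list(person_row("gm1", sex = "female",
      birth_year = 1861, age_end = runif(1, 20, 100))))
    if (n_gp >= 3) rows <- c(rows, list(person_row("gf2", sex = "male",
      birth_year = 1862, age_end = runif(1, 20, 100))))
    if (n_gp >= 4) rows <- c(rows, list(person_row("gm2", sex = "female",
      birth_year = 1863, age_end = runif(1, 20, 100))))
    if (n_gp >= 2 && n_au > 0) {
      for (j in seq_len(n_au)) rows <- c(rows, list(person_row(
        paste0("au", j), "gf1", "gm1", "female", 1890 + j,
        age_end = runif(1, 20, 100))))
    }
    df <- do.call(rbind, rows)
    ped <- pedigree(df)
    r <- lrc_score(ped, "focal", tabs)

    # oracle: explicit relative table, closed-form percentile, plain sums
    rel <- data.frame(
      id = setdiff(df$person_id, "focal"),
      stringsAsFactors = FALSE)
    rel$w <- ifelse(rel$id %in% c("pa", "mo"), 0.5, 0.25)
    rel$age <- df$age_end[match(rel$id, df$person_id)]
    rel <- rel[!is.na(rel$age), , drop = FALSE]
    rel$ll <- (1 - exp(-h * rel$age)) >= 0.9
    if (nrow(rel) == 0) {
      expect_true(is.na(r$score))
    } else {
      expect_equal(r$score, sum(rel$w * rel$ll) / sum(rel$w),
                   tolerance = 1e-12, info = paste("iteration", i))
    }
  }
})

test_that("score is permutation-invariant and weighted-mean monotone", {
  tabs <- flat_tables(h = 0.05)
  base <- rbind(
    person_row("gf1", sex = "male", birth_year = 1860, age_end = LL_AGE),
    person_row("gm1", sex = "female", birth_year = 1861, age_end = AVG_AGE),
    person_row("pa", "gf1", "gm1", "male", 1890, LL_AGE),
    person_row("mo", sex = "female", birth_year = 1895, age_end = AVG_AGE),
    person_row("focal", "pa", "mo", "female", 1920, 70)
  )
  s0 <- lrc_score(pedigree(base), "focal", tabs)$score
  set.seed(7)
  for (i in 1:10) {
    s <- lrc_score(pedigree(base[sample(nrow(base)), ]), "focal", tabs)$score
    expect_identical(s, s0)
  }
  # adding a non-long-lived aunt never increases the score
  with_avg_aunt <- rbind(base, person_row("au", "gf1", "gm1", "female",
                                          1892, AVG_AGE))
  expect_lte(lrc_score(pedigree(with_avg_aunt), "focal", tabs)$score, s0)
  # adding a long-lived aunt never decreases it
  with_ll_aunt <- rbind(base, person_row("au", "gf1", "gm1", "female",
                                         1892, LL_AGE))
  expect_gte(lrc_score(pedigree(with_ll_aunt), "focal", tabs)$score, s0)
})
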