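test_that("synthetic tables reproduce their generating laws", {
  # Makeham-only: flat hazards
  flat <- make_life_tables(1900, laws = list(
    female = list(a = 0.02, b = 0, c = 0.1),
    male = list(a = 0.02, b = 0, c = 0.1)), trend = 0)
  expect_true(all(get_life_table(flat, "female", 1900)$hazard == 0.02))

  # Gompertz: survival matches the closed form, hazards the law within
  # one discretization step
  b <- 1e-4; cc <- 0.09
  gomp <- make_life_tables(1900, laws = list(
    female = list(a = 0, b = b, c = cc),
    male = list(a = 0, b = b, c = cc)), trend = 0)
  tab <- get_life_table(gomp, "male", 1900)
  for (t in c(10, 50, 90)) {
    expect_equal(survival_probability(tab, t),
                 exp(-(b / cc) * (exp(cc * t) - 1)), tolerance = 1e-10)
  }
  x <- 0:99
  expect_equal(tab$hazard, b * exp(cc * x), tolerance = 0.05)

  # secular trend: every later-cohort hazard lower at every age
  tr <- make_life_tables(c(1900, 1950), trend = 0.01)
  expect_true(all(get_life_table(tr, "female", 1950)$hazard <
                    get_life_table(tr, "female", 1900)$hazard))
  # female tables dominate male under the default laws
  expect_true(all(get_life_table(tr, "female", 1900)$hazard <
                    get_life_table(tr, "male", 1900)$hazard))

  expect_error(make_life_tables(1900, laws = list(
    female = list(a = -1, b = 1e-4, c = 0.09),
    male = list(a = 0.01, b = 1e-4, c = 0.09))), "needs a >= 0")
})

test_that("cohorts are structurally valid and deterministic", {
  sc <- sim_scenario(n_families = 12, seed = 31)
  out <- simulate_cohort(sc)
  expect_length(out$pedigrees, 12)
  roles <- unlist(lapply(out$pedigrees, function(p) p$persons$role_tag))
  expect_setequal(intersect(unique(roles),
                            c("F1_ip", "F1_spouse", "F2_descendant",
                              "F2_spouse", "F3_descendant", "F3_spouse")),
                  unique(roles))

  # ascertainment: case IPs died 80+, control IPs 40-59 (truth record,
  # since the observed age may be blanked by missingness)
  tru <- merge(out$truth$persons[out$truth$persons$role_tag == "F1_ip", ],
               out$truth$families, by = "family_id")
  expect_true(all(tru$age_true[tru$arm == "case"] >= 80))
  expect_true(all(tru$age_true[tru$arm == "control"] >= 40 &
                    tru$age_true[tru$arm == "control"] < 60))

  # determinism: identical seed, byte-identical outputs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_output(out, d1)
  write_sim_output(simulate_cohort(sc), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }

  # truth percentiles recompute from the generating tables
  prs <- do.call(rbind, lapply(out$pedigrees, function(p) p$persons))
  tp <- out$truth$persons
  i <- match(tp$person_id, prs$person_id)
  for (j in sample(nrow(tp), 20)) {
    expect_equal(tp$percentile_true[j],
                 unname(survival_percentile(out$tables, prs$sex[i[j]],
                                            prs$birth_year[i[j]],
                                            tp$age_true[j])),
                 tolerance = 1e-12)
  }
})

test_that("theta = 0 gives exchangeable descendants with unit frailty", {
  out <- simulate_cohort(sim_scenario(n_families = 150, theta = 0, seed = 32))
  expect_true(all(out$truth$families$u == 1))
  si <- pedigree_smr_input(out$pedigrees)
  r <- smr_exact(si[si$role_tag == "F3_descendant", ], out$tables)
  expect_true(r$ci_low <= 1 && r$ci_high >= 1)
})

test_that("theta > 0 induces the familial longevity gradient", {
  out <- simulate_cohort(sim_scenario(n_families = 500, theta = 0.25,
                                      seed = 33))
  u <- out$truth$families$u
  arm <- out$truth$families$arm
  expect_lt(mean(u[arm == "case"]), mean(u[arm == "control"]))

  lrc <- lrc_table(out$pedigrees, out$tables)
  si <- pedigree_smr_input(out$pedigrees)
  m <- match(lrc$person_id, si$person_id)
  dat <- si[m[!is.na(m)], ]
  dat$group <- cut(lrc$score[!is.na(m)], c(-Inf, 0.2, Inf),
                   labels = c("low", "high"))
  g <- group_smr_table(dat, out$tables)
  expect_lt(g$smr[g$group == "high"], g$smr[g$group == "low"])
  expect_lt(g$ci_high[g$group == "high"], 1)
})

test_that("infeasible ascertainment errors out after bounded attempts", {
  sc <- sim_scenario(n_families = 2, case_age_min = 130, max_reject = 25,
                     seed = 34)
  expect_error(simulate_cohort(sc), "attempts")
})

test_that("missingness is role-targeted, reproducible and calibrated", {
  sc <- sim_scenario(n_families = 80, missing_rates = NULL, seed = 35)
  out <- simulate_cohort(sc)
  prs0 <- do.call(rbind, lapply(out$pedigrees, function(p) p$persons))
  expect_false(anyNA(prs0$age_end))

  # rate 0 is the identity
  same <- apply_missingness(out, c(F3_descendant = 0), seed = 1)
  expect_identical(do.call(rbind, lapply(same$pedigrees,
                                         function(p) p$persons))$age_end,
                   prs0$age_end)

  # rate 1 blanks every spouse
  allsp <- apply_missingness(out, c(F2_spouse = 1, F3_spouse = 1), seed = 1)
  prs1 <- do.call(rbind, lapply(allsp$pedigrees, function(p) p$persons))
  sp <- prs1$role_tag %in% c("F2_spouse", "F3_spouse")
  expect_true(all(is.na(prs1$age_end[sp])))
  expect_false(anyNA(prs1$age_end[!sp]))

  # realized fraction within a 99.9% binomial band of the target
  big <- simulate_cohort(sim_scenario(n_families = 700, missing_rates = NULL,
                                      seed = 36))
  miss <- apply_missingness(big, c(F3_descendant = 0.3), seed = 2)
  prs2 <- do.call(rbind, lapply(miss$pedigrees, function(p) p$persons))
  f3 <- prs2$role_tag == "F3_descendant"
  n <- sum(f3); k <- sum(is.na(prs2$age_end[f3]))
  expect_gt(n, 3000)
  expect_lt(abs(k / n - 0.3), 3.3 * sqrt(0.3 * 0.7 / n))
  expect_error(apply_missingness(out, c(F3_descendant = 1.5)), "\\[0, 1\\]")
})

test_that("proportional-mode frailty marginalizes to the Laplace form", {
  # population survival under gamma frailty: S_pop(t) = (1 + theta H(t))^(-1/theta)
  theta <- 0.5
  law <- list(a = 0.005, b = 1e-4, c = 0.09)
  rec <- simulate_survival_records(n_families = 4000, family_size = 5,
                                   hr_group = 1, theta = theta,
                                   hr_female = 1, law = law,
                                   censor_age = 200, seed = 37)
  haz <- lrckit:::gm_component_hazards(law, 1900, 0, 1900, 119)
  H <- function(t) law$a * t + (law$b / law$c) * (exp(law$c * t) - 1)
  for (t in c(20, 40, 60, 80)) {
    emp <- mean(rec$t > t)
    expect_equal(emp, (1 + theta * H(t))^(-1 / theta), tolerance = 0.02,
                 info = paste("age", t))
  }
})

test_that("zero-truncated Poisson counts are positive with the right mean", {
  set.seed(38)
  x <- lrckit:::rztpois(20000, 3)
  expect_true(all(x >= 1))
  expect_equal(mean(x), 3 / (1 - exp(-3)), tolerance = 0.02)
})
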