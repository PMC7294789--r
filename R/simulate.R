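# Synthetic multigenerational cohorts under Gompertz-Makeham mortality with
# shared family frailty. Stands in for restricted historical genealogies:
# F1 index couples ascertained as long-lived cases or mid-life-death
# controls, two descendant generations with married-in spouses, cohort life
# tables as the generating marginal law, right censoring at a calendar
# year, and role-specific missing-age rates.

# Yearly hazard increments of a Gompertz-Makeham law split into its
# background (Makeham, a) and senescent (Gompertz, b e^{cx}) components,
# with a log-linear secular decline in both by birth year. Increments are
# exact integrals H(x+1) - H(x), so the discretized table reproduces the
# continuous survival function exactly at integer ages.
gm_component_hazards <- function(law, birth_year, trend, ref_year, a_max) {
  m <- exp(-trend * (birth_year - ref_year))
  x <- 0:a_max
  bg <- rep(law$a * m, a_max + 1L)
  sen <- (law$b * m / law$c) * (exp(law$c * (x + 1)) - exp(law$c * x))
  list(bg = bg, sen = sen)
}

#' Build synthetic cohort life tables from a Gompertz-Makeham law
#'
#' Yearly hazards are the exact integral increments of the continuous
#' cumulative hazard `H(x) = a x + (b/c)(e^{cx} - 1)`, per sex, with an
#' optional log-linear secular decline of the whole hazard by birth year
#' (later cohorts have lower hazards at every age).
#'
#' @param birth_years Integer vector of birth years to tabulate.
#' @param laws Named list with elements `female` and `male`, each a list
#'   with Makeham background `a`, Gompertz level `b`, and slope `c` (all
#'   positive; `a` may be 0).
#' @param trend Proportional hazard decline per birth year (e.g. 0.01 =
#'   1% lower hazard per later birth year); 0 disables the trend.
#' @param ref_year Birth year at which the law applies unscaled; default
#'   the earliest of `birth_years`.
#' @param a_max Last tabulated age (>= 99).
#' @param tail_policy Passed to [life_table()].
#' @return A [life_table_collection()].
#' @export
make_life_tables <- function(birth_years,
                             laws = list(
                               female = list(a = 0.009, b = 0.85e-4, c = 0.09),
                               male = list(a = 0.011, b = 1.25e-4, c = 0.09)),
                             trend = 0.01, ref_year = min(birth_years),
                             a_max = 99,
                             tail_policy = c("hold_last", "error")) {
  tail_policy <- match.arg(tail_policy)
  for (s in c("female", "male")) {
    law <- laws[[s]]
    if (is.null(law)) stop("laws must have elements 'female' and 'male'")
    if (law$a < 0 || law$b < 0 || law$c <= 0 || law$a + law$b <= 0) {
      stop("mortality law needs a >= 0, b >= 0, c > 0 and a + b > 0")
    }
  }
  if (trend < 0) stop("trend must be non-negative")
  tabs <- list()
  for (s in c("female", "male")) {
    for (y in birth_years) {
      comp <- gm_component_hazards(laws[[s]], y, trend, ref_year, a_max)
      tabs[[length(tabs) + 1L]] <-
        life_table(s, y, comp$bg + comp$sen, tail_policy = tail_policy)
    }
  }
  life_table_collection(tabs, source = "synthetic Gompertz-Makeham")
}

# Invert a piecewise-linear cumulative hazard (yearly grid, last hazard
# held constant beyond the table) at exponential targets. Requires strictly
# positive hazards.
invert_cumhaz <- function(haz, targets) {
  if (any(haz <= 0)) stop("lifetime inversion needs strictly positive hazards")
  cum <- c(0, cumsum(haz))
  a_end <- length(haz)
  idx <- findInterval(targets, cum)
  over <- idx > a_end
  out <- numeric(length(targets))
  out[!over] <- (idx[!over] - 1) + (targets[!over] - cum[idx[!over]]) / haz[idx[!over]]
  out[over] <- a_end + (targets[over] - cum[a_end + 1L]) / haz[a_end]
  out
}

# Zero-truncated Poisson via the inverse-cdf trick.
rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

#' Scenario for the synthetic cohort generator
#'
#' Defaults describe the emulated world: 1,326 families ascertained 2:1
#' into a case arm (F1 index person died at 80+) and a control arm (died
#' 40-59), index persons born 1860-1875, roughly three children per
#' reproducing couple, censoring at calendar year 2019, role-specific
#' missing-age rates matching the historical source, and a shared
#' per-family gamma frailty (mean 1, variance `theta`) on the senescent
#' hazard component of blood descendants. Married-in spouses are always
#' frailty-free (`u = 1`): their survival mirrors the general population.
#'
#' @param n_families Number of families.
#' @param case_fraction Fraction of families in the case arm.
#' @param theta Variance of the gamma family frailty; 0 disables familial
#'   effects.
#' @param frailty_mode `"senescent"` (default) multiplies only the
#'   Gompertz component of the hazard by the family frailty, so mid-life
#'   background mortality stays non-familial; `"proportional"` multiplies
#'   the whole hazard, the textbook shared-frailty mechanism.
#' @param ip_birth_range Calendar years the F1 index persons are born in.
#' @param case_age_min Minimum age at death for the case arm.
#' @param control_age_range Age-at-death window for the control arm.
#' @param children_mean Mean of the zero-truncated Poisson number of
#'   children per reproducing couple.
#' @param p_children_f2 Probability an F2 descendant marries and has
#'   children (producing F3).
#' @param p_spouse_f3 Probability an F3 descendant has a recorded spouse.
#' @param child_offset_range Parent's age window at a child's birth.
#' @param spouse_age_gap_sd SD of the (integer) birth-year gap between
#'   spouses.
#' @param censoring_year Calendar year of end of follow-up.
#' @param missing_rates Named per-role probabilities that `age_end` is
#'   blanked; `NULL` keeps everything observed.
#' @param laws,trend,a_max Passed to [make_life_tables()].
#' @param max_reject Bound on ascertainment rejection attempts per family.
#' @param seed Integer seed; the run is reproducible bit-for-bit given it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_families = 1326, case_fraction = 884 / 1326,
                         theta = 0.25,
                         frailty_mode = c("senescent", "proportional"),
                         ip_birth_range = c(1860, 1875),
                         case_age_min = 80, control_age_range = c(40, 59),
                         children_mean = 3, p_children_f2 = 0.65,
                         p_spouse_f3 = 0.35,
                         child_offset_range = c(20, 40),
                         spouse_age_gap_sd = 3,
                         censoring_year = 2019,
                         missing_rates = c(F1_ip = 0, F1_spouse = 0,
                                           F2_descendant = 0.10,
                                           F2_spouse = 0.60,
                                           F3_descendant = 0.09,
                                           F3_spouse = 0.39),
                         laws = NULL, trend = 0.01, a_max = 99,
                         max_reject = 10000, seed = 1) {
  frailty_mode <- match.arg(frailty_mode)
  if (theta < 0) stop("theta must be non-negative")
  stopifnot(n_families >= 1, case_fraction >= 0, case_fraction <= 1)
  if (is.null(laws)) {
    laws <- list(female = list(a = 0.009, b = 0.85e-4, c = 0.09),
                 male = list(a = 0.011, b = 1.25e-4, c = 0.09))
  }
  structure(
    list(n_families = as.integer(n_families), case_fraction = case_fraction,
         theta = theta, frailty_mode = frailty_mode,
         ip_birth_range = ip_birth_range, case_age_min = case_age_min,
         control_age_range = control_age_range,
         children_mean = children_mean, p_children_f2 = p_children_f2,
         p_spouse_f3 = p_spouse_f3, child_offset_range = child_offset_range,
         spouse_age_gap_sd = spouse_age_gap_sd,
         censoring_year = censoring_year, missing_rates = missing_rates,
         laws = laws, trend = trend, a_max = a_max,
         max_reject = max_reject, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Simulate a multigenerational case/control cohort
#'
#' Generates, per family: an F1 index person rejection-sampled jointly with
#' the family frailty into the case (died at `case_age_min`+) or control
#' (died within `control_age_range`) arm, an F1 spouse, F2 children with
#' married-in spouses, and F3 grandchildren with spouses. Blood descendants
#' share the family frailty; spouses are frailty-free. Lifetimes are drawn
#' from the generating life tables by inversion of the piecewise-linear
#' cumulative hazard; follow-up is right-censored at `censoring_year`, and
#' role-specific missing-age rates are applied last (the truth record keeps
#' the uncensored values).
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `sim_output`: `pedigrees` (list of
#'   [pedigree()]), `tables` (the generating [life_table_collection()] —
#'   the exact marginal law of frailty-free individuals), `truth` (list
#'   with per-family `families$u` and per-person uncensored age and true
#'   survival percentile), and the `scenario`.
#' @export
simulate_cohort <- function(scenario = sim_scenario()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  set.seed(sc$seed)

  year_lo <- sc$ip_birth_range[1] - 15L
  year_hi <- sc$ip_birth_range[2] + 2L * (sc$child_offset_range[2] + 1L) +
    ceiling(4 * sc$spouse_age_gap_sd) + 15L
  years <- seq(year_lo, year_hi)
  tables <- make_life_tables(years, laws = sc$laws, trend = sc$trend,
                             ref_year = year_lo, a_max = sc$a_max)

  # per (sex, year) component hazards for lifetime draws
  comp <- list()
  for (s in c("female", "male")) {
    for (y in years) {
      comp[[lt_key(s, y)]] <-
        gm_component_hazards(sc$laws[[s]], y, sc$trend, year_lo, sc$a_max)
    }
  }
  draw_one <- function(sex, year, u) {
    cc <- comp[[lt_key(sex, year)]]
    if (sc$frailty_mode == "senescent") {
      min(invert_cumhaz(cc$bg, stats::rexp(1)),
          invert_cumhaz(cc$sen, stats::rexp(1) / u))
    } else {
      invert_cumhaz(cc$bg + cc$sen, stats::rexp(1) / u)
    }
  }
  clamp_year <- function(y) as.integer(pmin(pmax(y, year_lo), year_hi))

  n_case <- round(sc$n_families * sc$case_fraction)
  arms <- rep(c("case", "control"), c(n_case, sc$n_families - n_case))

  persons <- vector("list", sc$n_families)
  fam_u <- numeric(sc$n_families)
  truth_rows <- vector("list", sc$n_families)
  couple_rows <- vector("list", sc$n_families)

  for (f in seq_len(sc$n_families)) {
    fam <- paste0("fam", f)
    arm <- arms[f]

    # joint rejection on (u, T_ip): ascertainment by the index person's
    # death age selects the family frailty posterior for the arm
    ip_sex <- sample(c("female", "male"), 1L)
    ip_year <- sample(seq(sc$ip_birth_range[1], sc$ip_birth_range[2]), 1L)
    accepted <- FALSE
    for (try in seq_len(sc$max_reject)) {
      u <- if (sc$theta > 0) {
        stats::rgamma(1, shape = 1 / sc$theta, rate = 1 / sc$theta)
      } else 1
      t_ip <- draw_one(ip_sex, ip_year, u)
      ok <- if (arm == "case") t_ip >= sc$case_age_min else
        (t_ip >= sc$control_age_range[1] & t_ip < sc$control_age_range[2] + 1)
      if (ok) { accepted <- TRUE; break }
    }
    if (!accepted) {
      stop("ascertainment for the ", arm, " arm failed after ",
           sc$max_reject, " attempts; the scenario's mortality law may make ",
           "this arm unattainable")
    }
    fam_u[f] <- u

    acc <- new.env(parent = emptyenv())
    acc$id <- acc$fa <- acc$mo <- acc$sex <- acc$vs <- acc$role <- character(0)
    acc$year <- integer(0)
    acc$age <- acc$age_true <- acc$pct <- numeric(0)
    add <- function(id, father, mother, sex, year, role, uu) {
      t_raw <- if (role == "F1_ip") t_ip else draw_one(sex, year, uu)
      age_cens <- sc$censoring_year - year
      dead <- t_raw <= age_cens
      acc$id <- c(acc$id, id)
      acc$fa <- c(acc$fa, father); acc$mo <- c(acc$mo, mother)
      acc$sex <- c(acc$sex, sex); acc$year <- c(acc$year, year)
      acc$age <- c(acc$age, if (dead) t_raw else age_cens)
      acc$vs <- c(acc$vs, if (dead) "dead" else "alive")
      acc$role <- c(acc$role, role)
      acc$age_true <- c(acc$age_true, t_raw)
      acc$pct <- c(acc$pct, unname(survival_percentile(tables, sex, year, t_raw)))
    }

    acc$cp_a <- acc$cp_b <- character(0)
    note_couple <- function(a, b) {
      acc$cp_a <- c(acc$cp_a, a); acc$cp_b <- c(acc$cp_b, b)
    }

    ip_id <- paste0(fam, "_ip"); sp_id <- paste0(fam, "_f1sp")
    sp_sex <- if (ip_sex == "female") "male" else "female"
    sp_year <- clamp_year(ip_year + round(stats::rnorm(1, 0, sc$spouse_age_gap_sd)))
    add(ip_id, NA, NA, ip_sex, ip_year, "F1_ip", u)
    add(sp_id, NA, NA, sp_sex, sp_year, "F1_spouse", 1)
    note_couple(ip_id, sp_id)
    f1_father <- if (ip_sex == "male") ip_id else sp_id
    f1_mother <- if (ip_sex == "female") ip_id else sp_id

    n_f2 <- rztpois(1, sc$children_mean)
    for (j in seq_len(n_f2)) {
      f2_id <- paste0(fam, "_f2_", j)
      f2_sex <- sample(c("female", "male"), 1L)
      f2_year <- clamp_year(ip_year + 1L +
        floor(stats::runif(1, sc$child_offset_range[1], sc$child_offset_range[2])))
      add(f2_id, f1_father, f1_mother, f2_sex, f2_year, "F2_descendant", u)
      if (stats::runif(1) < sc$p_children_f2) {
        f2sp_id <- paste0(fam, "_f2sp_", j)
        f2sp_sex <- if (f2_sex == "female") "male" else "female"
        f2sp_year <- clamp_year(f2_year +
          round(stats::rnorm(1, 0, sc$spouse_age_gap_sd)))
        add(f2sp_id, NA, NA, f2sp_sex, f2sp_year, "F2_spouse", 1)
        note_couple(f2_id, f2sp_id)
        f2_father <- if (f2_sex == "male") f2_id else f2sp_id
        f2_mother <- if (f2_sex == "female") f2_id else f2sp_id
        n_f3 <- rztpois(1, sc$children_mean)
        for (k in seq_len(n_f3)) {
          f3_id <- paste0(fam, "_f3_", j, "_", k)
          f3_sex <- sample(c("female", "male"), 1L)
          f3_year <- clamp_year(f2_year + 1L +
            floor(stats::runif(1, sc$child_offset_range[1],
                               sc$child_offset_range[2])))
          add(f3_id, f2_father, f2_mother, f3_sex, f3_year, "F3_descendant", u)
          if (stats::runif(1) < sc$p_spouse_f3) {
            f3sp_id <- paste0(fam, "_f3sp_", j, "_", k)
            f3sp_sex <- if (f3_sex == "female") "male" else "female"
            f3sp_year <- clamp_year(f3_year +
              round(stats::rnorm(1, 0, sc$spouse_age_gap_sd)))
            add(f3sp_id, NA, NA, f3sp_sex, f3sp_year, "F3_spouse", 1)
            note_couple(f3_id, f3sp_id)
          }
        }
      }
    }
    persons[[f]] <- data.frame(
      person_id = acc$id, family_id = fam, father_id = acc$fa,
      mother_id = acc$mo, sex = acc$sex, birth_year = acc$year,
      age_end = acc$age, vital_status = acc$vs, role_tag = acc$role,
      stringsAsFactors = FALSE
    )
    truth_rows[[f]] <- data.frame(
      person_id = acc$id, family_id = fam, role_tag = acc$role,
      age_true = acc$age_true, percentile_true = acc$pct,
      stringsAsFactors = FALSE
    )
    couple_rows[[f]] <- data.frame(person_id = acc$cp_a, spouse_id = acc$cp_b,
                                   family_id = fam, stringsAsFactors = FALSE)
  }

  all_persons <- do.call(rbind, persons)
  out <- structure(
    list(
      pedigrees = lapply(split(all_persons, all_persons$family_id), pedigree),
      tables = tables,
      truth = list(
        families = data.frame(family_id = paste0("fam", seq_len(sc$n_families)),
                              arm = arms, u = fam_u,
                              stringsAsFactors = FALSE),
        persons = do.call(rbind, truth_rows),
        couples = do.call(rbind, couple_rows)
      ),
      scenario = sc
    ),
    class = "sim_output"
  )
  if (!is.null(sc$missing_rates) && any(sc$missing_rates > 0)) {
    out <- apply_missingness(out, sc$missing_rates)
  }
  out
}

#' @export
print.sim_output <- function(x, ...) {
  n <- sum(vapply(x$pedigrees, function(p) nrow(p$persons), integer(1)))
  cat(sprintf(
    "<sim_output> %d persons in %d families (theta = %g, %s frailty), seed %d\n",
    n, length(x$pedigrees), x$scenario$theta, x$scenario$frailty_mode,
    x$scenario$seed
  ))
  invisible(x)
}

#' Blank ages at death by role
#'
#' Emulates role-specific missing mortality information: each person's
#' `age_end` is set to missing with the probability given for their
#' `role_tag`. Vital status is untouched (one can know a person died
#' without knowing when), and the truth record keeps the original values.
#'
#' @param output A `sim_output`.
#' @param rates Named numeric vector of per-role missingness probabilities
#'   in \[0, 1\]; roles not listed keep their data.
#' @param seed Optional seed; by default the current RNG stream continues.
#' @return The modified `sim_output`.
#' @export
apply_missingness <- function(output, rates, seed = NULL) {
  stopifnot(inherits(output, "sim_output"))
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  output$pedigrees <- lapply(output$pedigrees, function(ped) {
    prs <- ped$persons
    m <- match(prs$role_tag, names(rates))
    p <- ifelse(is.na(m), 0, rates[m])
    blank <- stats::runif(nrow(prs)) < p
    prs$age_end[blank] <- NA_real_
    ped$persons <- prs
    ped
  })
  output
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `pedigree.tsv`, `life_tables.tsv`, `truth_families.tsv` and
#' `truth_persons.tsv` under `dir` in the dialects the package readers
#' accept. Byte-identical across runs with the same scenario seed.
#'
#' @param output A `sim_output`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_sim_output <- function(output, dir) {
  stopifnot(inherits(output, "sim_output"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.tsv"),
    life_tables = file.path(dir, "life_tables.tsv"),
    truth_families = file.path(dir, "truth_families.tsv"),
    truth_persons = file.path(dir, "truth_persons.tsv"),
    couples = file.path(dir, "couples.tsv")
  )
  write_pedigree(output$pedigrees, paths[["pedigree"]])
  write_life_tables(output$tables, paths[["life_tables"]])
  utils::write.table(output$truth$families, paths[["truth_families"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(output$truth$persons, paths[["truth_persons"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(output$truth$couples, paths[["couples"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Simulate flat survival records for frailty-model checks
#'
#' A direct generator for validating [fit_frailty_cox()]: families carry a
#' gamma frailty (mean 1, variance `theta`) and a family-level group label;
#' individual hazards are `u_i * exp(beta) * (a + b e^{cx})` for the case
#' group with `beta = log(hr_group)`, times a sex effect. Follow-up is
#' administratively censored at `censor_age`.
#'
#' @param n_families Number of families.
#' @param family_size Persons per family.
#' @param hr_group True hazard ratio of cases vs controls.
#' @param theta Frailty variance.
#' @param hr_female True female-vs-male hazard ratio.
#' @param p_case_family Probability a family is in the case group.
#' @param law Gompertz-Makeham baseline (list `a`, `b`, `c`).
#' @param censor_age Administrative censoring age.
#' @param birth_years Years to sample birth years from (covariate only).
#' @param seed Optional seed.
#' @return Data frame with `person_id`, `family_id`, `group`, `sex`,
#'   `birth_year`, `sibship`, `entry`, `t`, `event`, and the true `u` per
#'   row.
#' @export
simulate_survival_records <- function(n_families = 400, family_size = 5,
                                      hr_group = 0.75, theta = 0.2,
                                      hr_female = 0.75,
                                      p_case_family = 0.5,
                                      law = list(a = 0.005, b = 1e-4, c = 0.09),
                                      censor_age = 100,
                                      birth_years = 1900:1940, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  haz <- gm_component_hazards(law, birth_years[1], 0, birth_years[1], 119)
  haz <- haz$bg + haz$sen
  n <- n_families * family_size
  fam <- rep(seq_len(n_families), each = family_size)
  u_f <- if (theta > 0) {
    stats::rgamma(n_families, shape = 1 / theta, rate = 1 / theta)
  } else rep(1, n_families)
  grp <- ifelse(stats::runif(n_families) < p_case_family,
                "family_case", "family_control")
  sex <- sample(c("female", "male"), n, replace = TRUE)
  mult <- u_f[fam] * exp(log(hr_group) * (grp[fam] == "family_case") +
                         log(hr_female) * (sex == "female"))
  t_raw <- invert_cumhaz(haz, stats::rexp(n) / mult)
  event <- as.integer(t_raw <= censor_age)
  data.frame(
    person_id = paste0("p", seq_len(n)),
    family_id = paste0("fam", fam),
    group = factor(grp[fam], levels = c("family_control", "family_case")),
    sex = factor(sex, levels = c("male", "female")),
    birth_year = sample(birth_years, n, replace = TRUE),
    sibship = sibship_category(rep(family_size - 1L, n)),
    entry = 0,
    t = pmin(t_raw, censor_age), event = event,
    u = u_f[fam],
    stringsAsFactors = FALSE
  )
}
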