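#' Validate and normalize an SMR input table
#'
#' An SMR input is a data frame with one row per person and columns `sex`,
#' `birth_year`, `t` (age at death or last observation), `d` (1 = dead,
#' 0 = censored), and optionally `t0` (age of entry under left truncation,
#' default 0), `family_id`, and a grouping column. Rows with missing `t`
#' cannot contribute and are rejected here; exclude them upstream (and
#' count them — see [group_smr_table()]).
#'
#' @param data The data frame to check.
#' @return The data frame with `t0` filled in.
#' @keywords internal
as_smr_input <- function(data) {
  need <- c("sex", "birth_year", "t", "d")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("SMR input lacks column(s): ", paste(miss, collapse = ", "))
  if (!"t0" %in% names(data)) data$t0 <- 0
  data$t0[is.na(data$t0)] <- 0
  if (anyNA(data$t)) stop("SMR input has missing ages; exclude those rows upstream")
  if (!all(data$d %in% c(0, 1))) stop("d must be 0 (censored) or 1 (dead)")
  if (any(data$t0 > data$t)) stop("t0 must not exceed t")
  data
}

#' Expected number of deaths under reference life tables
#'
#' The sum of per-person conditional cumulative hazards
#' `sum_i H(t_i | t0_i)` from each person's sex- and birth-year-specific
#' table. Conditioning on the entry age `t0` corrects for left truncation:
#' a person only observable from age `t0` contributes hazard accrued after
#' `t0`. Censored persons contribute their hazard up to last observation
#' and no death.
#'
#' @param data An SMR input table (see [as_smr_input()]).
#' @param tables A [life_table_collection()].
#' @return Expected deaths (non-negative real).
#' @export
expected_deaths <- function(data, tables) {
  data <- as_smr_input(data)
  key <- paste(data$sex, data$birth_year, sep = "_")
  total <- 0
  for (k in unique(key)) {
    i <- which(key == k)
    tab <- get_life_table(tables, data$sex[i[1]], data$birth_year[i[1]])
    total <- total + sum(cumulative_hazard(tab, data$t[i], data$t0[i]))
  }
  total
}

smr_ci_exact <- function(d, e, alpha) {
  ll <- if (d == 0) 0 else stats::qchisq(alpha / 2, 2 * d) / (2 * e)
  ul <- stats::qchisq(1 - alpha / 2, 2 * (d + 1)) / (2 * e)
  c(ll, ul)
}

new_smr_result <- function(observed, expected, ci, alpha, method, n,
                           n_families = NA_integer_) {
  structure(
    list(observed = observed, expected = expected,
         smr = observed / expected, ci_low = ci[1], ci_high = ci[2],
         alpha = alpha, method = method, n = n, n_families = n_families),
    class = "smr_result"
  )
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf(
    "<smr_result> SMR %.4f (%d obs / %.2f exp), %d%% CI [%.4f, %.4f], %s, n = %d\n",
    x$smr, x$observed, x$expected, round(100 * (1 - x$alpha)),
    x$ci_low, x$ci_high, x$method, x$n
  ))
  invisible(x)
}

#' Standardized mortality ratio with exact confidence limits
#'
#' `SMR = d / e` with `d` the observed and `e` the expected deaths. The
#' exact limits treat `d` as Poisson and use the chi-square quantile form:
#' `LL = qchisq(alpha/2, 2d) / (2e)` (0 when `d = 0`) and
#' `UL = qchisq(1 - alpha/2, 2(d + 1)) / (2e)`. An SMR between 0 and 1
#' indicates excess survival relative to the reference population; above 1,
#' excess mortality.
#'
#' @inheritParams expected_deaths
#' @param alpha Significance level; default 0.05 for 95% limits.
#' @return An `smr_result`.
#' @export
smr_exact <- function(data, tables, alpha = 0.05) {
  data <- as_smr_input(data)
  e <- expected_deaths(data, tables)
  if (e <= 0) stop("expected deaths is zero; SMR undefined")
  d <- as.integer(sum(data$d))
  new_smr_result(d, e, smr_ci_exact(d, e, alpha), alpha, "exact", nrow(data),
                 if ("family_id" %in% names(data))
                   length(unique(data$family_id)) else NA_integer_)
}

#' SMR with family-resampling bootstrap confidence limits
#'
#' Families are the independent sampling units, so the bootstrap resamples
#' whole families with replacement `B` times, recomputes the SMR on each
#' resample, and reports percentile limits. Per-family observed and
#' expected totals are precomputed, so each replicate is a weighted sum.
#'
#' @inheritParams smr_exact
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Optional integer seed for reproducibility.
#' @return An `smr_result` with `method = "bootstrap"`.
#' @export
smr_bootstrap <- function(data, tables, B = 1000, seed = NULL, alpha = 0.05) {
  data <- as_smr_input(data)
  if (!"family_id" %in% names(data)) stop("bootstrap requires a family_id column")
  if (B < 200) stop("B must be at least 200")
  fams <- unique(data$family_id)
  if (length(fams) < 2L) stop("bootstrap requires at least 2 families")
  if (!is.null(seed)) set.seed(seed)

  key <- paste(data$sex, data$birth_year, sep = "_")
  h <- numeric(nrow(data))
  for (k in unique(key)) {
    i <- which(key == k)
    tab <- get_life_table(tables, data$sex[i[1]], data$birth_year[i[1]])
    h[i] <- cumulative_hazard(tab, data$t[i], data$t0[i])
  }
  obs_f <- vapply(split(data$d, data$family_id), sum, numeric(1))
  exp_f <- vapply(split(h, data$family_id), sum, numeric(1))
  e <- sum(exp_f)
  if (e <= 0) stop("expected deaths is zero; SMR undefined")
  d <- as.integer(sum(obs_f))

  nf <- length(obs_f)
  reps <- vapply(seq_len(B), function(b) {
    pick <- sample.int(nf, nf, replace = TRUE)
    sum(obs_f[pick]) / sum(exp_f[pick])
  }, numeric(1))
  ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  res <- new_smr_result(d, e, ci, alpha, "bootstrap", nrow(data), nf)
  res$replicates <- reps
  res
}

#' Per-group SMR table
#'
#' Splits a person table by a grouping column (for example the LRC bin or
#' the family case/control label) and estimates one exact SMR per group.
#' Persons with a missing age cannot enter an SMR; they are excluded here
#' and counted in `n_missing_age`, so the reported `n` reflects only those
#' with a known age at death or last observation. Empty groups yield a row
#' with `n = 0` and `NA` estimates.
#'
#' @param data A person table: SMR input columns plus `group` (or the
#'   column named by `group_col`). `t` may be `NA` here.
#' @param tables A [life_table_collection()].
#' @param group_col Name of the grouping column.
#' @param alpha Significance level for the exact limits.
#' @return Data frame with columns `group`, `n`, `n_missing_age`,
#'   `observed`, `expected`, `smr`, `ci_low`, `ci_high`.
#' @export
group_smr_table <- function(data, tables, group_col = "group", alpha = 0.05) {
  if (!group_col %in% names(data)) stop("no column '", group_col, "' in data")
  groups <- data[[group_col]]
  lev <- if (is.factor(groups)) levels(groups) else unique(groups)
  rows <- lapply(lev, function(g) {
    sub <- data[!is.na(groups) & groups == g, , drop = FALSE]
    n_miss <- sum(is.na(sub$t))
    sub <- sub[!is.na(sub$t), , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(group = g, n = 0L, n_missing_age = n_miss,
                        observed = NA_integer_, expected = NA_real_,
                        smr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE))
    }
    r <- smr_exact(sub, tables, alpha)
    data.frame(group = g, n = nrow(sub), n_missing_age = n_miss,
               observed = r$observed, expected = r$expected, smr = r$smr,
               ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten pedigrees into an SMR input table
#'
#' Extracts one row per person with a known age: the dead contribute
#' `d = 1` at their age at death, the alive contribute `d = 0` censored at
#' their age at last observation; persons with unknown vital status or
#' missing age are dropped (their count is retained as an attribute).
#' Entry ages can be set per role to encode truncation conditioning.
#'
#' @param pedigrees A `pedigree` or list of them.
#' @param t0_by_role Optional named numeric vector mapping `role_tag`
#'   values to entry ages (left truncation); unlisted roles enter at 0.
#'   Persons who died before their role's entry age are unobservable under
#'   that conditioning and are dropped.
#' @return Data frame with `person_id`, `family_id`, `role_tag`, `sex`,
#'   `birth_year`, `t0`, `t`, `d`; attribute `n_excluded` counts dropped
#'   rows.
#' @export
pedigree_smr_input <- function(pedigrees, t0_by_role = NULL) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  prs <- do.call(rbind, lapply(pedigrees, function(p) p$persons))
  keep <- !is.na(prs$age_end) & prs$vital_status %in% c("dead", "alive") &
    !is.na(prs$sex) & !is.na(prs$birth_year)
  out <- data.frame(
    person_id = prs$person_id[keep], family_id = prs$family_id[keep],
    role_tag = prs$role_tag[keep], sex = prs$sex[keep],
    birth_year = prs$birth_year[keep], t0 = 0,
    t = prs$age_end[keep], d = as.integer(prs$vital_status[keep] == "dead"),
    stringsAsFactors = FALSE
  )
  n_excluded <- sum(!keep)
  if (!is.null(t0_by_role)) {
    m <- match(out$role_tag, names(t0_by_role))
    out$t0 <- ifelse(is.na(m), 0, t0_by_role[m])
    unobservable <- out$t <= out$t0 & out$t0 > 0
    n_excluded <- n_excluded + sum(unobservable)
    out <- out[!unobservable, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
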