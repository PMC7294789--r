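#' Cohort life table
#'
#' A cohort life table holds, for one sex and one birth year, the yearly
#' hazard of dying between exact ages `x` and `x + 1` (`h_x`) for contiguous
#' ages starting at 0. Cumulative hazards, survival probabilities and
#' survival percentiles are derived from these hazards under a
#' piecewise-exponential convention: the hazard is constant within each year
#' of age, so the cumulative hazard is piecewise linear and survival is
#' continuous in age.
#'
#' @param sex `"female"` or `"male"`.
#' @param birth_year Integer calendar year of birth of the cohort.
#' @param hazard Numeric vector of yearly hazards for ages `0, 1, ...,
#'   length(hazard) - 1`. All values must be non-negative and finite.
#' @param tail_policy How to treat ages beyond the last tabulated year of
#'   age: `"hold_last"` (default) extends the table by holding the final
#'   hazard constant; `"error"` refuses.
#'
#' @return An object of class `cohort_life_table`.
#' @seealso [cumulative_hazard()], [survival_probability()],
#'   [survival_percentile()], [threshold_age()]
#' @export
life_table <- function(sex, birth_year, hazard,
                       tail_policy = c("hold_last", "error")) {
  sex <- match.arg(sex, c("female", "male"))
  tail_policy <- match.arg(tail_policy)
  birth_year <- as.integer(birth_year)
  hazard <- as.numeric(hazard)
  if (length(hazard) < 1L) {
    stop("life table for ", sex, " ", birth_year, " has no ages")
  }
  if (anyNA(hazard) || any(!is.finite(hazard))) {
    stop("life table for ", sex, " ", birth_year, " has missing or non-finite hazards")
  }
  if (any(hazard < 0)) {
    stop("life table for ", sex, " ", birth_year, " has negative hazards")
  }
  structure(
    list(
      sex = sex,
      birth_year = birth_year,
      ages = seq_along(hazard) - 1L,
      hazard = hazard,
      # cumhaz[k] = H(k - 1): cumulative hazard at the start of age k - 1
      cumhaz = c(0, cumsum(hazard)),
      tail_policy = tail_policy
    ),
    class = "cohort_life_table"
  )
}

#' @export
print.cohort_life_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_life_table> %s, born %d, ages 0-%d, tail: %s\n",
    x$sex, x$birth_year, max(x$ages), x$tail_policy
  ))
  invisible(x)
}

lt_key <- function(sex, birth_year) paste(sex, birth_year, sep = "_")

#' Collection of cohort life tables
#'
#' Bundles [life_table()] objects keyed by (sex, birth year). Lookup is by
#' exact key only; a missing (sex, birth year) combination is an error,
#' never a silent nearest-neighbour substitution, because borrowing an
#' adjacent cohort's mortality would bias survival percentiles.
#'
#' @param tables A list of `cohort_life_table` objects.
#' @param source Free-text label describing where the tables come from.
#' @return An object of class `life_table_collection`.
#' @export
life_table_collection <- function(tables, source = "unspecified") {
  if (!length(tables)) stop("empty life table collection")
  ok <- vapply(tables, inherits, logical(1), "cohort_life_table")
  if (!all(ok)) stop("all elements must be cohort_life_table objects")
  keys <- vapply(tables, function(t) lt_key(t$sex, t$birth_year), character(1))
  dup <- keys[duplicated(keys)]
  if (length(dup)) {
    stop("duplicate life table key(s): ", paste(unique(dup), collapse = ", "))
  }
  names(tables) <- keys
  yrs <- vapply(tables, function(t) t$birth_year, integer(1))
  structure(
    list(tables = tables, source = source, year_range = range(yrs)),
    class = "life_table_collection"
  )
}

#' @export
print.life_table_collection <- function(x, ...) {
  cat(sprintf(
    "<life_table_collection> %d tables, birth years %d-%d, source: %s\n",
    length(x$tables), x$year_range[1], x$year_range[2], x$source
  ))
  invisible(x)
}

#' Look up one table in a collection
#'
#' @param collection A [life_table_collection()].
#' @param sex,birth_year Exact key of the table wanted.
#' @return The matching `cohort_life_table`.
#' @export
get_life_table <- function(collection, sex, birth_year) {
  stopifnot(inherits(collection, "life_table_collection"))
  key <- lt_key(sex, as.integer(birth_year))
  tab <- collection$tables[[key]]
  if (is.null(tab)) {
    stop("no life table for key '", key, "' (exact-key lookup; no interpolation)")
  }
  tab
}

#' Read cohort life tables from a delimited text file
#'
#' Expects a header row and columns `sex`, `birth_year`, `age`, and either
#' `hazard` (yearly hazard `h_x`) or `qx` (yearly death probability, with
#' `convert_qx = TRUE`, converted as `h_x = -log(1 - q_x)`). The delimiter
#' is chosen from the file extension: `.csv` is comma-separated, anything
#' else tab-separated. Every (sex, birth_year) block must tabulate
#' contiguous ages starting at 0.
#'
#' @param path Path to the file.
#' @param convert_qx Set `TRUE` when the file carries `qx` instead of
#'   `hazard`.
#' @param tail_policy Passed to [life_table()].
#' @param source Label stored on the collection; defaults to the file name.
#' @return A [life_table_collection()].
#' @export
read_life_tables <- function(path, convert_qx = FALSE,
                             tail_policy = c("hold_last", "error"),
                             source = basename(path)) {
  tail_policy <- match.arg(tail_policy)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  value_col <- if (convert_qx) "qx" else "hazard"
  need <- c("sex", "birth_year", "age", value_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("life table file lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (convert_qx) {
    if (any(df$qx < 0 | df$qx >= 1)) stop("qx values must lie in [0, 1)")
    df$hazard <- -log(1 - df$qx)
  }
  key <- lt_key(df$sex, df$birth_year)
  if (anyDuplicated(paste(key, df$age))) {
    bad <- unique(key[duplicated(paste(key, df$age))])
    stop("duplicate (sex, birth_year, age) rows for key(s): ",
         paste(bad, collapse = ", "))
  }
  tabs <- lapply(split(df, key), function(block) {
    block <- block[order(block$age), , drop = FALSE]
    if (!identical(as.integer(block$age), seq_len(nrow(block)) - 1L)) {
      stop("non-contiguous ages for key '",
           lt_key(block$sex[1], block$birth_year[1]),
           "': ages must run 0, 1, 2, ... without gaps")
    }
    life_table(block$sex[1], block$birth_year[1], block$hazard,
               tail_policy = tail_policy)
  })
  life_table_collection(unname(tabs), source = source)
}

#' Write a life table collection to a delimited text file
#'
#' Emits the same dialect [read_life_tables()] accepts (columns
#' `sex,birth_year,age,hazard`).
#'
#' @param collection A [life_table_collection()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_life_tables <- function(collection, path) {
  stopifnot(inherits(collection, "life_table_collection"))
  rows <- do.call(rbind, lapply(collection$tables, function(t) {
    data.frame(sex = t$sex, birth_year = t$birth_year, age = t$ages,
               hazard = t$hazard, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# H(t) from age 0, vectorized over t; piecewise-linear in t with slope h_x
# inside year x. Beyond the tabulated range the behaviour follows the
# table's tail policy.
lt_cumhaz_at <- function(table, t) {
  a_end <- length(table$hazard)          # table covers [0, a_end)
  h_last <- table$hazard[a_end]
  out <- numeric(length(t))
  over <- t > a_end
  if (any(over)) {
    if (table$tail_policy == "error") {
      stop("age ", max(t), " beyond table maximum ", a_end,
           " (tail_policy = 'error'; use 'hold_last' to extend)")
    }
    out[over] <- table$cumhaz[a_end + 1L] + (t[over] - a_end) * h_last
  }
  inr <- !over
  if (any(inr)) {
    x <- pmin(floor(t[inr]), a_end - 1L)  # t == a_end folds into last year
    out[inr] <- table$cumhaz[x + 1L] + (t[inr] - x) * table$hazard[x + 1L]
  }
  out
}

#' Conditional cumulative hazard from a cohort life table
#'
#' `H(t | t0) = H(t) - H(t0)` with `H(t) = sum_{x < floor(t)} h_x +
#' (t - floor(t)) h_floor(t)` (constant hazard within each year of age).
#' `H` is additive over adjacent intervals.
#'
#' @param table A [life_table()].
#' @param t Age(s) in years; fractional allowed; vectorized.
#' @param t0 Conditioning (left-truncation) age, scalar or vector matching
#'   `t`; default 0.
#' @return Non-negative cumulative hazard(s).
#' @export
cumulative_hazard <- function(table, t, t0 = 0) {
  stopifnot(inherits(table, "cohort_life_table"))
  if (anyNA(t) || anyNA(t0)) stop("ages must not be missing")
  if (any(t < 0) || any(t0 < 0)) stop("ages must be non-negative")
  if (any(t0 > t)) stop("t0 must not exceed t")
  lt_cumhaz_at(table, t) - lt_cumhaz_at(table, t0)
}

#' Conditional survival probability from a cohort life table
#'
#' `S(t | t0) = exp(-H(t | t0))`; equals 1 at `t = t0` and is
#' non-increasing in `t`.
#'
#' @inheritParams cumulative_hazard
#' @return Survival probability(ies) in (0, 1].
#' @export
survival_probability <- function(table, t, t0 = 0) {
  exp(-cumulative_hazard(table, t, t0))
}

#' Sex- and birth-cohort-specific survival percentile
#'
#' The percentile of an age at death within the person's own birth cohort
#' and sex: `P = 1 - S(age_at_death)`. A person with `P >= 0.9` belongs to
#' the top 10% survivors of their cohort (the inclusive `>=` convention is
#' used for the top-fraction indicator throughout the package).
#'
#' @param tables A [life_table_collection()].
#' @param sex,birth_year Key of the person's cohort table (exact lookup).
#' @param age_at_death Age(s) at death in years; fractional allowed.
#' @return Percentile(s) in \[0, 1).
#' @export
survival_percentile <- function(tables, sex, birth_year, age_at_death) {
  tab <- get_life_table(tables, sex, birth_year)
  1 - survival_probability(tab, age_at_death)
}

#' Age at death marking the top fraction of a birth cohort
#'
#' The smallest age `a` (linearly interpolated within the year under the
#' piecewise-exponential convention) at which the table's survival drops to
#' `S(a) <= z`, i.e. the age one must outlive to enter the top `z` fraction
#' of survivors. Monotone in `z`: the top-1% age is at least the top-10%
#' age.
#'
#' @param table A [life_table()].
#' @param top_fraction `z` in (0, 1).
#' @return Age in years.
#' @export
threshold_age <- function(table, top_fraction) {
  stopifnot(inherits(table, "cohort_life_table"))
  z <- top_fraction
  if (!is.numeric(z) || length(z) != 1L || z <= 0 || z >= 1) {
    stop("top_fraction must be a single number in (0, 1)")
  }
  target <- -log(z)                       # need H(a) >= target
  cum <- table$cumhaz
  a_end <- length(table$hazard)
  if (cum[a_end + 1L] >= target) {
    x <- which(cum[-1L] >= target)[1L]    # crossing happens within year x - 1
    h <- table$hazard[x]
    if (h <= 0) return(as.numeric(x - 1L))  # flat year: crossing at its start
    return((x - 1L) + (target - cum[x]) / h)
  }
  if (table$tail_policy == "error" || table$hazard[a_end] <= 0) {
    stop("survival never reaches ", z, " within the table range; ",
         "extend the table or use tail_policy = 'hold_last'")
  }
  a_end + (target - cum[a_end + 1L]) / table$hazard[a_end]
}
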