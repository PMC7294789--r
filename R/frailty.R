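#' Shared gamma-frailty proportional-hazards fit
#'
#' Fits the Cox-type random effects model
#' `lambda(t_ij) = u_i lambda_0(t_ij) exp(beta' Z_ij + gamma' X_ij)` where
#' `u_i` is a per-family multiplicative frailty with a mean-1 gamma
#' distribution and variance `theta`, and the baseline hazard is left
#' unspecified. Estimation is penalized partial likelihood
#' (`survival::coxph` with a `frailty` term). Left truncation is handled
#' through the `entry` column (counting-process form); right censoring
#' through `event`.
#'
#' @param records Data frame with columns `family_id`, `t` (age at death or
#'   censoring), `event` (1 = death, 0 = censored), optional `entry`
#'   (left-truncation age, default 0), and the covariate columns named in
#'   `covariates`.
#' @param covariates Character vector of covariate column names (right-hand
#'   side of the model). Character columns are converted to factors; set
#'   the reference level upstream when it matters.
#' @param theta `NULL` (default) estimates the frailty variance; a fixed
#'   non-negative number constrains it. At `theta = 0` the model is, by
#'   definition, an ordinary Cox partial-likelihood fit (all frailties 1).
#' @param eps Convergence tolerance on the outer (theta) iteration.
#' @param max_iter Maximum outer iterations before a non-convergence error.
#' @return An object of class `frailty_fit`: `coefficients` data frame
#'   (`term`, `coef`, `hr`, `ci_low`, `ci_high`, `se`, `p`), `theta`,
#'   `n`, `n_families`, `n_events`, `iter`, `converged`, and the underlying
#'   `coxph` fit as `fit`.
#' @export
fit_frailty_cox <- function(records, covariates, theta = NULL,
                            eps = 1e-6, max_iter = 100) {
  need <- c("family_id", "t", "event", covariates)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (!"entry" %in% names(records)) records$entry <- 0
  records$entry[is.na(records$entry)] <- 0
  bad <- records$entry >= records$t
  if (any(bad)) stop(sum(bad), " record(s) with entry >= t; ",
                     "left-truncated rows must survive past their entry age")
  for (cv in covariates) {
    if (anyNA(records[[cv]])) stop("missing values in covariate '", cv, "'")
    if (is.character(records[[cv]])) records[[cv]] <- factor(records[[cv]])
    if (is.factor(records[[cv]])) {
      records[[cv]] <- droplevels(records[[cv]])
      if (nlevels(records[[cv]]) < 2L) {
        # constant in these data: nothing to adjust for
        covariates <- setdiff(covariates, cv)
      }
    }
  }
  if (!length(covariates)) stop("no non-constant covariates left to fit")
  if (sum(records$event) == 0) stop("all records are censored; nothing to fit")
  n_fam <- length(unique(records$family_id))
  if (n_fam < 2L) {
    stop("frailty variance is unidentifiable with a single family")
  }

  use_entry <- any(records$entry > 0)
  surv <- if (use_entry) "survival::Surv(entry, t, event)" else "survival::Surv(t, event)"
  fixed_theta0 <- !is.null(theta) && theta == 0
  ftrm <- if (fixed_theta0) {
    NULL  # theta = 0: frailties are all 1; the model is plain Cox
  } else if (is.null(theta)) {
    "survival::frailty(family_id, distribution = 'gamma', eps = eps)"
  } else {
    "survival::frailty(family_id, distribution = 'gamma', theta = theta, eps = eps)"
  }
  rhs <- paste(c(covariates, ftrm), collapse = " + ")
  fml <- stats::as.formula(paste(surv, "~", rhs))
  env <- new.env(parent = environment())
  env$records <- records; env$theta <- theta; env$eps <- eps
  environment(fml) <- env
  fit <- tryCatch(
    survival::coxph(fml, data = records,
                    control = survival::coxph.control(
                      eps = eps, outer.max = max_iter, iter.max = 200)),
    error = function(e) stop("frailty fit failed: ", conditionMessage(e)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(fml, data = records,
                        control = survival::coxph.control(
                          eps = eps, outer.max = max_iter, iter.max = 200)))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    })

  est_theta <- if (fixed_theta0) {
    0
  } else if (length(fit$history)) {
    fit$history[[1]]$theta
  } else {
    NA_real_
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))[seq_along(cf)]
  zq <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = names(cf), coef = unname(cf), hr = exp(unname(cf)),
    ci_low = exp(unname(cf) - zq * se), ci_high = exp(unname(cf) + zq * se),
    se = se, p = 2 * stats::pnorm(-abs(unname(cf) / se)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  converged <- is.null(attr(fit, "fit_warning")) &&
    (is.null(fit$iter) || max(fit$iter) < 200)
  if (!converged && !is.null(attr(fit, "fit_warning"))) {
    warning("frailty fit flagged: ", attr(fit, "fit_warning"))
  }
  structure(
    list(coefficients = coefs, theta = est_theta, n = nrow(records),
         n_families = n_fam, n_events = sum(records$event),
         iter = fit$iter, converged = converged, fit = fit),
    class = "frailty_fit"
  )
}

#' @export
print.frailty_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<frailty_fit> %d persons in %d families, %d events; theta = %s\n",
              x$n, x$n_families, x$n_events,
              if (is.na(x$theta)) "NA" else format(round(x$theta, digits))))
  df <- x$coefficients
  df[, c("coef", "hr", "ci_low", "ci_high", "se")] <-
    round(df[, c("coef", "hr", "ci_low", "ci_high", "se")], digits)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Sibship-size category
#'
#' Bins a number of siblings into the standard categories: single child (0
#' sibs), small (1-2, the reference level), medium (3-5), large (6-8),
#' exceptional (9 or more).
#'
#' @param n_sibs Integer number of siblings (not counting the person).
#' @return Factor with reference level `"small_1_2"`.
#' @export
sibship_category <- function(n_sibs) {
  lab <- cut(n_sibs, breaks = c(-1, 0, 2, 5, 8, Inf),
             labels = c("single_0", "small_1_2", "medium_3_5",
                        "large_6_8", "exceptional_9plus"))
  stats::relevel(lab, ref = "small_1_2")
}

#' Family case vs control survival contrast
#'
#' Fits the shared-frailty Cox contrast between family cases and family
#' controls. Two schemes are supported:
#'
#' * Scheme `"A"`: cases vs controls, adjusted for sibship-size category,
#'   birth year and sex.
#' * Scheme `"B"`: adds the spouses of cases and of controls as two extra
#'   groups. Spouses enter the risk set at a delayed entry age (left
#'   truncation) because they are only observable once married into the
#'   family; by default the entry age of each spouse group is its first
#'   observed death age. Scheme B adjusts for birth year and sex (spouses
#'   have no sibship within the family).
#'
#' @param records Data frame with columns `family_id`, `t`, `event`,
#'   `group` (values among `family_case`, `family_control`,
#'   `spouse_of_case`, `spouse_of_control`), `birth_year`, `sex`, and for
#'   scheme A `sibship` (a factor from [sibship_category()]). Rows with
#'   other group values are dropped.
#' @param scheme `"A"` or `"B"`.
#' @param spouse_entry Named numeric vector giving the entry age of
#'   `spouse_of_case` and `spouse_of_control` rows; `NULL` (default) uses
#'   each spouse group's first observed death age. Spouse rows censored at
#'   or before their entry age are unobservable and are dropped (counted in
#'   the result).
#' @param theta Passed to [fit_frailty_cox()].
#' @return A `frailty_fit` with extra fields `scheme`, `spouse_entry`, and
#'   `n_dropped_spouses`.
#' @export
case_control_contrast <- function(records, scheme = c("A", "B"),
                                  spouse_entry = NULL, theta = NULL) {
  scheme <- match.arg(scheme)
  groups <- if (scheme == "A") {
    c("family_control", "family_case")
  } else {
    c("family_control", "family_case", "spouse_of_case", "spouse_of_control")
  }
  records <- records[records$group %in% groups, , drop = FALSE]
  records$group <- factor(records$group, levels = groups)
  if (!"entry" %in% names(records)) records$entry <- 0
  n_dropped <- 0L
  if (scheme == "B") {
    if (is.null(spouse_entry)) {
      spouse_entry <- vapply(c("spouse_of_case", "spouse_of_control"),
                             function(g) {
        dt <- records$t[records$group == g & records$event == 1]
        if (!length(dt)) stop("no observed deaths among ", g,
                              "; supply spouse_entry explicitly")
        min(dt)
      }, numeric(1))
    }
    m <- match(as.character(records$group), names(spouse_entry))
    records$entry <- pmax(records$entry, ifelse(is.na(m), 0, spouse_entry[m]))
    if (any(records$event == 1 & records$t < records$entry)) {
      stop("spouse death(s) before the configured entry age: ",
           "left truncation makes these unobservable; check spouse_entry")
    }
    # the first observed death defines the entry age and must stay at risk
    at_edge <- records$event == 1 & records$t == records$entry
    records$entry[at_edge] <- records$t[at_edge] - 1e-6
    drop <- records$event == 0 & records$t <= records$entry
    n_dropped <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  covs <- if (scheme == "A") c("group", "sibship", "birth_year", "sex")
          else c("group", "birth_year", "sex")
  fit <- fit_frailty_cox(records, covariates = covs, theta = theta)
  fit$scheme <- scheme
  fit$spouse_entry <- if (scheme == "B") spouse_entry else NULL
  fit$n_dropped_spouses <- n_dropped
  fit
}
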