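#' Configuration of the LRC score and family classification
#'
#' @param top_fraction `Z`: the fraction of a birth cohort that counts as
#'   long-lived; a relative is long-lived when their survival percentile
#'   `P >= 1 - Z`. Default 0.10 (top 10% survivors), the threshold at which
#'   longevity has been shown to be heritable.
#' @param case_cutoff LRC score at or above which a person is a family
#'   case; default 0.30.
#' @param nonclassified_band Half-open interval `[lo, hi)` of scores
#'   treated as nonclassified; its upper edge must meet `case_cutoff`.
#'   Default `c(0.20, 0.30)`. Scores in `(0, lo)` are labelled
#'   `unselected_low` (positive score but no demonstrated excess survival).
#' @param alive_rule How relatives who are still alive enter the score:
#'   `"exclude"` (default) drops them from numerator and denominator;
#'   `"alive_if_exceeds"` counts an alive relative as long-lived when their
#'   current age already puts them at `P >= 1 - Z` (the percentile can only
#'   rise), still excluding alive relatives below the threshold.
#' @return An object of class `lrc_config`.
#' @export
lrc_config <- function(top_fraction = 0.10, case_cutoff = 0.30,
                       nonclassified_band = c(0.20, 0.30),
                       alive_rule = c("exclude", "alive_if_exceeds")) {
  alive_rule <- match.arg(alive_rule)
  stopifnot(top_fraction > 0, top_fraction < 1,
            length(nonclassified_band) == 2L,
            nonclassified_band[1] < nonclassified_band[2])
  if (!isTRUE(all.equal(nonclassified_band[2], case_cutoff))) {
    stop("nonclassified_band must abut case_cutoff")
  }
  structure(
    list(top_fraction = top_fraction, case_cutoff = case_cutoff,
         nonclassified_band = nonclassified_band, alive_rule = alive_rule),
    class = "lrc_config"
  )
}

#' Longevity Relatives Count score
#'
#' The LRC score of person `i` is the kinship-weighted proportion of their
#' ancestral blood relatives who became long-lived:
#' \deqn{LRC_i = \frac{\sum_k w_k \, I(P_k \ge 1 - Z)}{\sum_k w_k}}
#' where `w_k` is the relationship coefficient between `i` and relative
#' `k`, `P_k` is relative `k`'s sex- and birth-cohort-specific survival
#' percentile, and `Z` is the long-lived top fraction (default 10%). A
#' score of 0.5 means half of a person's relatives, weighted by genetic
#' distance, were long-lived.
#'
#' Relatives with an unknown age at death contribute to neither sum: an
#' unknown lifespan is evidence for neither class. Alive relatives follow
#' `config$alive_rule`. A person whose usable weighted total is 0 is
#' "unscorable" (`score = NA`), never silently 0.
#'
#' @param ped A [pedigree()].
#' @param focal Person id to score.
#' @param tables A [life_table_collection()] supplying percentiles.
#' @param config An [lrc_config()].
#' @param relatives Optionally a precomputed [ancestral_relatives()] set;
#'   by default the parents + grandparents + aunts/uncles of `focal`.
#' @return An object of class `lrc_result`: list with `focal`, `score`
#'   (`NA` if unscorable), `weighted_longlived`, `weighted_total`,
#'   `n_relatives_used`, `n_relatives_excluded`, and a per-relative
#'   `detail` data frame reproducing every term (id, relation, weight, age,
#'   percentile, long-lived indicator, used flag).
#' @export
lrc_score <- function(ped, focal, tables, config = lrc_config(),
                      relatives = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "lrc_config"))
  if (is.null(relatives)) relatives <- ancestral_relatives(ped, focal)
  prs <- ped$persons
  det <- as.data.frame(relatives)
  n <- nrow(det)
  det$age_end <- prs$age_end[ped$index[det$relative_id]]
  det$vital_status <- prs$vital_status[ped$index[det$relative_id]]
  det$percentile <- NA_real_
  det$longlived <- NA
  det$used <- FALSE

  thr <- 1 - config$top_fraction
  ridx <- ped$index[det$relative_id]
  sex <- prs$sex[ridx]; by <- prs$birth_year[ridx]
  ok <- !is.na(det$age_end) & !is.na(sex) & !is.na(by)
  if (any(ok)) {
    key <- paste(sex, by)
    for (k in unique(key[ok])) {
      j <- which(ok & key == k)
      tab <- tryCatch(get_life_table(tables, sex[j[1]], by[j[1]]),
                      error = function(e) {
                        stop("relative '", det$relative_id[j[1]], "': ",
                             conditionMessage(e))
                      })
      det$percentile[j] <- 1 - exp(-lt_cumhaz_at(tab, det$age_end[j]))
    }
    dead <- ok & det$vital_status == "dead"
    det$longlived[dead] <- det$percentile[dead] >= thr
    det$used[dead] <- TRUE
    if (config$alive_rule == "alive_if_exceeds") {
      al <- ok & det$vital_status == "alive" & det$percentile >= thr
      det$longlived[al] <- TRUE
      det$used[al] <- TRUE
    }
  }

  w_tot <- sum(det$weight[det$used])
  w_ll <- sum(det$weight[det$used & det$longlived])
  structure(
    list(
      focal = attr(relatives, "focal") %||% focal,
      score = if (w_tot > 0) w_ll / w_tot else NA_real_,
      weighted_longlived = w_ll,
      weighted_total = w_tot,
      n_relatives_used = sum(det$used),
      n_relatives_excluded = n - sum(det$used),
      config = config,
      detail = det
    ),
    class = "lrc_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lrc_result <- function(x, ...) {
  cat(sprintf(
    "<lrc_result> %s: score %s (%g / %g over %d relatives, %d excluded)\n",
    x$focal,
    if (is.na(x$score)) "unscorable" else format(round(x$score, 4)),
    x$weighted_longlived, x$weighted_total,
    x$n_relatives_used, x$n_relatives_excluded
  ))
  invisible(x)
}

#' Family case/control classification of an LRC result
#'
#' * score `NA` (no usable relatives) -> `"unscorable"`
#' * score 0 -> `"family_control"` (no long-lived ancestors)
#' * `0 < score < 0.20` -> `"unselected_low"` (no demonstrated excess
#'   survival)
#' * `0.20 <= score < 0.30` -> `"nonclassified"`
#' * `score >= 0.30` -> `"family_case"` (boundary included)
#'
#' Cut points come from `config`.
#'
#' @param result An [lrc_result()], or a bare numeric vector of scores.
#' @param config The [lrc_config()] the scores were computed with.
#' @return Character label(s).
#' @export
classify_lrc <- function(result, config = lrc_config()) {
  score <- if (inherits(result, "lrc_result")) result$score else as.numeric(result)
  lo <- config$nonclassified_band[1]
  hi <- config$case_cutoff
  out <- character(length(score))
  out[is.na(score)] <- "unscorable"
  ok <- !is.na(score)
  if (any(ok & (score < 0 | score > 1))) stop("LRC scores must lie in [0, 1]")
  out[ok & score == 0] <- "family_control"
  out[ok & score > 0 & score < lo] <- "unselected_low"
  out[ok & score >= lo & score < hi] <- "nonclassified"
  out[ok & score >= hi] <- "family_case"
  out
}

#' Nine-group LRC binning
#'
#' Assigns scores to the nine mutually exclusive, exhaustive groups
#' `g1 = {0}`, `g2 = (0, 0.1)`, `g3 = [0.1, 0.2)`, `g4 = [0.2, 0.3)`,
#' `g5 = [0.3, 0.4)`, `g6 = [0.4, 0.5)`, `g7 = [0.5, 0.6)`,
#' `g8 = [0.6, 0.7)`, `g9 = [0.7, 1.0]`. Edges are left-closed except g1,
#' which is exactly zero, and g9, which includes 1.
#'
#' @param scores Numeric scores in \[0, 1\]; `NA` (unscorable) stays `NA`.
#' @return Factor with levels `g1`..`g9`.
#' @export
lrc_bins <- function(scores) {
  scores <- as.numeric(scores)
  ok <- !is.na(scores)
  if (any(ok & (scores < 0 | scores > 1))) stop("LRC scores must lie in [0, 1]")
  lev <- paste0("g", 1:9)
  out <- factor(rep(NA_character_, length(scores)), levels = lev)
  breaks <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  idx <- findInterval(scores[ok], breaks, left.open = FALSE) + 1L
  idx[scores[ok] == 0] <- 1L       # g1 is exactly zero, not [0, 0.1)
  idx[idx > 9L] <- 9L              # score 1.0 belongs to g9
  out[ok] <- lev[idx]
  out
}

#' Score every focal person in a set of pedigrees
#'
#' Convenience wrapper running [lrc_score()], [classify_lrc()] and
#' [lrc_bins()] over all persons carrying `focal_role` (or an explicit id
#' list), across a list of pedigrees.
#'
#' @param pedigrees A `pedigree` or list of them.
#' @param tables A [life_table_collection()].
#' @param config An [lrc_config()].
#' @param focal_role `role_tag` value selecting the persons to score
#'   (default `"F3_descendant"`); ignored when `focal_ids` is given.
#' @param focal_ids Optional explicit person ids to score.
#' @return Data frame with one row per focal person: `person_id`,
#'   `family_id`, `score`, `weighted_longlived`, `weighted_total`,
#'   `n_used`, `n_excluded`, `label`, `bin`.
#' @export
lrc_table <- function(pedigrees, tables, config = lrc_config(),
                      focal_role = "F3_descendant", focal_ids = NULL) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  rows <- lapply(pedigrees, function(ped) {
    ids <- if (is.null(focal_ids)) {
      ped$persons$person_id[!is.na(ped$persons$role_tag) &
                            ped$persons$role_tag == focal_role]
    } else {
      intersect(focal_ids, ped$persons$person_id)
    }
    if (!length(ids)) return(NULL)
    rs <- lapply(ids, function(id) lrc_score(ped, id, tables, config))
    data.frame(
      person_id = ids, family_id = ped$family_id,
      score = vapply(rs, `[[`, numeric(1), "score"),
      weighted_longlived = vapply(rs, `[[`, numeric(1), "weighted_longlived"),
      weighted_total = vapply(rs, `[[`, numeric(1), "weighted_total"),
      n_used = vapply(rs, `[[`, integer(1), "n_relatives_used"),
      n_excluded = vapply(rs, `[[`, integer(1), "n_relatives_excluded"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no focal persons matched")
  rownames(out) <- NULL
  out$label <- classify_lrc(out$score, config)
  out$bin <- lrc_bins(out$score)
  out
}
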