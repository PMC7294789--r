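#' Derive co-parent couples from pedigrees
#'
#' Two persons form a couple when they appear together as father and
#' mother of at least one child. This recovers spouse links for anyone
#' with recorded children; childless couples need an explicit couples
#' table.
#'
#' @param pedigrees A `pedigree` or list of them.
#' @return Data frame with columns `person_id`, `spouse_id`, `family_id`
#'   (both orientations are included).
#' @export
derive_couples <- function(pedigrees) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  rows <- lapply(pedigrees, function(ped) {
    prs <- ped$persons
    ok <- !is.na(prs$father_id) & !is.na(prs$mother_id)
    if (!any(ok)) return(NULL)
    pair <- unique(data.frame(a = prs$father_id[ok], b = prs$mother_id[ok],
                              stringsAsFactors = FALSE))
    data.frame(person_id = c(pair$a, pair$b), spouse_id = c(pair$b, pair$a),
               family_id = ped$family_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(person_id = character(0), spouse_id = character(0),
                      family_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Sibship size (number of siblings sharing >= 1 parent) for a set of ids.
sibship_sizes <- function(pedigrees, ids) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  out <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (ped in pedigrees) {
    here <- intersect(ids, ped$persons$person_id)
    for (id in here) out[[id]] <- length(ped_siblings_of(ped, id))
  }
  out
}

#' Survival records for the case/control contrast
#'
#' Assembles the flat record table [case_control_contrast()] consumes from
#' scored pedigrees: one row per classified focal person (group =
#' `family_case` / `family_control`) plus, when `couples` are supplied,
#' their spouses (group = `spouse_of_case` / `spouse_of_control`). Rows
#' need a known age; sibship size is computed from the pedigree.
#'
#' @param pedigrees A `pedigree` or list of them.
#' @param lrc A scored table from [lrc_table()].
#' @param couples Optional couples table (see [derive_couples()]); enables
#'   the spouse groups.
#' @return Data frame with `person_id`, `family_id`, `group`, `t`,
#'   `event`, `entry`, `birth_year`, `sex`, `sibship`.
#' @export
contrast_records <- function(pedigrees, lrc, couples = NULL) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  prs <- do.call(rbind, lapply(pedigrees, function(p) p$persons))
  rownames(prs) <- NULL
  take <- function(ids, group) {
    i <- match(ids, prs$person_id)
    i <- i[!is.na(i)]
    i <- i[!is.na(prs$age_end[i]) & prs$vital_status[i] %in% c("dead", "alive")]
    if (!length(i)) return(NULL)
    data.frame(
      person_id = prs$person_id[i], family_id = prs$family_id[i],
      group = group, t = prs$age_end[i],
      event = as.integer(prs$vital_status[i] == "dead"),
      entry = 0, birth_year = prs$birth_year[i], sex = prs$sex[i],
      stringsAsFactors = FALSE
    )
  }
  cases <- lrc$person_id[lrc$label == "family_case"]
  controls <- lrc$person_id[lrc$label == "family_control"]
  rows <- list(take(cases, "family_case"), take(controls, "family_control"))
  if (!is.null(couples)) {
    sp_case <- couples$spouse_id[couples$person_id %in% cases]
    sp_ctrl <- couples$spouse_id[couples$person_id %in% controls]
    rows <- c(rows, list(take(setdiff(sp_case, c(cases, controls)), "spouse_of_case"),
                         take(setdiff(sp_ctrl, c(cases, controls)), "spouse_of_control")))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable records for the contrast")
  focal <- out$group %in% c("family_case", "family_control")
  sib <- sibship_sizes(pedigrees, unique(out$person_id[focal]))
  out$sibship <- sibship_category(
    ifelse(focal, sib[out$person_id], 0L))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates percentiles -> LRC scores -> classification -> per-bin
#' SMRs -> frailty contrast over one set of pedigrees and reference life
#' tables, writing tab-separated tables and a JSON run manifest to
#' `out_dir`. Inputs may be in-memory objects or file paths (read with the
#' package readers). Each stage logs one line with row counts.
#'
#' @param pedigrees List of [pedigree()] objects, or path to a pedigree
#'   file.
#' @param tables A [life_table_collection()], or path to a life-table
#'   file.
#' @param out_dir Output directory.
#' @param config An [lrc_config()].
#' @param alpha Significance level for SMR limits.
#' @param scheme Contrast scheme, `"A"` or `"B"` (see
#'   [case_control_contrast()]).
#' @param couples Optional couples table for scheme B; when `NULL` it is
#'   derived from co-parenthood.
#' @param focal_role `role_tag` selecting the persons to score.
#' @param seed Seed recorded in the manifest and applied before any
#'   stochastic stage.
#' @return Invisibly, a list with the computed tables (`lrc`,
#'   `classification`, `bin_smr`, `contrast`, `theta`) and the manifest.
#' @export
run_pipeline <- function(pedigrees, tables, out_dir,
                         config = lrc_config(), alpha = 0.05,
                         scheme = c("A", "B"), couples = NULL,
                         focal_role = "F3_descendant", seed = 1) {
  scheme <- match.arg(scheme)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  input_files <- character(0)
  if (is.character(pedigrees)) {
    input_files <- c(input_files, pedigree = pedigrees)
    pedigrees <- read_pedigree(pedigrees)
  }
  if (is.character(tables)) {
    input_files <- c(input_files, tables = tables)
    tables <- read_life_tables(tables)
  }
  stage <- function(name, rows_in, rows_out) {
    message(sprintf("stage=%s rows_in=%d rows_out=%d", name, rows_in, rows_out))
  }
  tsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  n_persons <- sum(vapply(pedigrees, function(p) nrow(p$persons), integer(1)))
  lrc <- lrc_table(pedigrees, tables, config, focal_role = focal_role)
  stage("lrc_score", n_persons, nrow(lrc))
  tsv(lrc, "lrc_scores.tsv")

  cls <- as.data.frame(table(label = lrc$label), stringsAsFactors = FALSE)
  names(cls) <- c("label", "n")
  stage("classify", nrow(lrc), nrow(cls))
  tsv(cls, "classification_counts.tsv")

  smr_in <- pedigree_smr_input(pedigrees)
  smr_in <- smr_in[match(lrc$person_id, smr_in$person_id), , drop = FALSE]
  smr_in$group <- lrc$bin
  smr_in$t[is.na(smr_in$person_id)] <- NA  # scored but unusable rows
  bin_smr <- group_smr_table(smr_in, tables, alpha = alpha)
  stage("bin_smr", nrow(lrc), nrow(bin_smr))
  tsv(bin_smr, "bin_smr.tsv")

  if (scheme == "B" && is.null(couples)) couples <- derive_couples(pedigrees)
  rec <- contrast_records(pedigrees, lrc, couples = couples)
  fit <- case_control_contrast(rec, scheme = scheme)
  stage("contrast", nrow(rec), nrow(fit$coefficients))
  tsv(fit$coefficients, "contrast_coefficients.tsv")

  manifest <- list(
    package = "lrckit",
    version = as.character(utils::packageVersion("lrckit")),
    seed = seed,
    alpha = alpha,
    scheme = scheme,
    lrc_config = unclass(config),
    inputs = if (length(input_files)) {
      lapply(input_files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f))))
    } else "in-memory",
    counts = list(persons = n_persons, scored = nrow(lrc),
                  classification = as.list(stats::setNames(cls$n, cls$label))),
    bin_smr_covers_1 = stats::setNames(
      as.list(!is.na(bin_smr$smr) & bin_smr$ci_low <= 1 & bin_smr$ci_high >= 1),
      bin_smr$group),
    theta = fit$theta
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(lrc = lrc, classification = cls, bin_smr = bin_smr,
                 contrast = fit$coefficients, theta = fit$theta,
                 manifest = manifest))
}

#' Singleton vs family selection report
#'
#' Cross-tabulates the "at least one top-10% parent" singleton selection
#' against LRC bands and reports each band's SMR: of the focal persons
#' with a long-lived parent, how many carry little other familial
#' longevity (LRC < 0.20, phenocopy parents as a group) versus a
#' family-level enrichment (LRC >= 0.30)?
#'
#' @param pedigrees A `pedigree` or list of them.
#' @param tables A [life_table_collection()].
#' @param lrc A scored table from [lrc_table()]; computed when `NULL`.
#' @param config An [lrc_config()].
#' @param alpha Significance level for SMR limits.
#' @return Data frame with one row per LRC band (`(0,0.2)`, `[0.2,0.3)`,
#'   `[0.3,1]`) within the selected group: `n`, `observed`, `expected`,
#'   `smr`, `ci_low`, `ci_high`; attribute `n_selected` gives the size of
#'   the "at least one long-lived parent" group.
#' @export
singleton_vs_family_report <- function(pedigrees, tables, lrc = NULL,
                                       config = lrc_config(), alpha = 0.05) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  if (is.null(lrc)) lrc <- lrc_table(pedigrees, tables, config)
  prs <- do.call(rbind, lapply(pedigrees, function(p) p$persons))
  idx <- stats::setNames(seq_len(nrow(prs)), prs$person_id)
  thr <- 1 - config$top_fraction

  has_ll_parent <- vapply(lrc$person_id, function(id) {
    i <- idx[[id]]
    parents <- c(prs$father_id[i], prs$mother_id[i])
    parents <- parents[!is.na(parents)]
    any(vapply(parents, function(p) {
      j <- idx[[p]]
      if (is.na(prs$age_end[j]) || prs$vital_status[j] != "dead" ||
          is.na(prs$sex[j]) || is.na(prs$birth_year[j])) return(FALSE)
      survival_percentile(tables, prs$sex[j], prs$birth_year[j],
                          prs$age_end[j]) >= thr
    }, logical(1)))
  }, logical(1))

  sel <- lrc[has_ll_parent & !is.na(lrc$score), , drop = FALSE]
  band <- cut(sel$score, breaks = c(0, 0.2, 0.3, 1),
              labels = c("(0,0.2)", "[0.2,0.3)", "[0.3,1]"),
              right = FALSE, include.lowest = TRUE)
  smr_in <- pedigree_smr_input(pedigrees)
  m <- match(sel$person_id, smr_in$person_id)
  dat <- data.frame(
    sex = smr_in$sex[m], birth_year = smr_in$birth_year[m],
    t0 = 0, t = smr_in$t[m], d = smr_in$d[m],  # NA rows: focal age unknown
    group = band, stringsAsFactors = FALSE
  )
  out <- group_smr_table(dat, tables, alpha = alpha)
  attr(out, "n_selected") <- nrow(sel)
  out
}
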