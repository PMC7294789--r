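#' Pedigree of one family
#'
#' Wraps a person table (one row per individual) and validates the family
#' structure: parent links must be acyclic, parents must be present in the
#' table, a parent's birth year must precede the child's when both are
#' known, and the father/mother slots must be male/female when the parent's
#' sex is recorded. Parent links are taken to be biological; the
#' relationship machinery only ever follows them.
#'
#' @param persons A data frame with columns `person_id`, `family_id`,
#'   `father_id`, `mother_id` (`NA`, `""` or `"0"` for unknown), `sex`
#'   (`"female"`, `"male"` or `NA`), `birth_year`, `age_end` (years at death
#'   or at last observation; `NA` when unknown), `vital_status` (`"dead"`,
#'   `"alive"` or `"unknown"`), and optionally `role_tag`.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(persons) {
  need <- c("person_id", "family_id", "father_id", "mother_id", "sex",
            "birth_year", "age_end", "vital_status")
  miss <- setdiff(need, names(persons))
  if (length(miss)) stop("pedigree lacks column(s): ", paste(miss, collapse = ", "))
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  if (!"role_tag" %in% names(persons)) persons$role_tag <- NA_character_
  persons$person_id <- as.character(persons$person_id)
  for (col in c("father_id", "mother_id")) {
    v <- as.character(persons[[col]])
    v[!is.na(v) & v %in% c("", "0")] <- NA_character_
    persons[[col]] <- v
  }
  if (anyDuplicated(persons$person_id)) {
    stop("duplicate person_id(s): ",
         paste(unique(persons$person_id[duplicated(persons$person_id)]),
               collapse = ", "))
  }
  fam <- unique(persons$family_id)
  if (length(fam) != 1L) {
    stop("a pedigree holds exactly one family; got family_id(s): ",
         paste(fam, collapse = ", "))
  }
  bad_sex <- !is.na(persons$sex) & !persons$sex %in% c("female", "male")
  if (any(bad_sex)) stop("invalid sex for: ",
                         paste(persons$person_id[bad_sex], collapse = ", "))
  bad_vs <- !persons$vital_status %in% c("dead", "alive", "unknown")
  if (any(bad_vs)) stop("invalid vital_status for: ",
                        paste(persons$person_id[bad_vs], collapse = ", "))

  idx <- seq_len(nrow(persons))
  names(idx) <- persons$person_id
  for (col in c("father_id", "mother_id")) {
    ref <- persons[[col]]
    unknown <- !is.na(ref) & !(ref %in% persons$person_id)
    if (any(unknown)) {
      stop("person(s) referenced as ", sub("_id", "", col),
           " but absent from the pedigree: ",
           paste(unique(ref[unknown]), collapse = ", "))
    }
  }
  fa <- idx[persons$father_id]; mo <- idx[persons$mother_id]
  fsex <- persons$sex[fa]
  if (any(!is.na(fsex) & fsex != "male")) {
    stop("father is not male for child(ren): ",
         paste(persons$person_id[!is.na(fsex) & fsex != "male"], collapse = ", "))
  }
  msex <- persons$sex[mo]
  if (any(!is.na(msex) & msex != "female")) {
    stop("mother is not female for child(ren): ",
         paste(persons$person_id[!is.na(msex) & msex != "female"], collapse = ", "))
  }
  for (p in list(fa, mo)) {
    both <- !is.na(p) & !is.na(persons$birth_year) & !is.na(persons$birth_year[p])
    bad <- both & persons$birth_year[p] >= persons$birth_year
    if (any(bad)) {
      stop("parent born in or after child's birth year for child(ren): ",
           paste(persons$person_id[bad], collapse = ", "))
    }
  }

  depth <- ped_depths(persons, idx)   # errors on cycles
  structure(
    list(persons = persons, family_id = fam, index = idx, depth = depth),
    class = "pedigree"
  )
}

# Generation depth per person (founders 0); detects cycles in parent links.
ped_depths <- function(persons, idx) {
  n <- nrow(persons)
  fa <- unname(idx[persons$father_id]); mo <- unname(idx[persons$mother_id])
  depth <- rep(NA_integer_, n)
  state <- integer(n)  # 0 unvisited, 1 in progress, 2 done
  visit <- function(i) {
    stack <- i
    while (length(stack)) {
      j <- stack[length(stack)]
      if (state[j] == 2L) { stack <- stack[-length(stack)]; next }
      ps <- c(fa[j], mo[j]); ps <- ps[!is.na(ps)]
      if (state[j] == 0L) {
        state[j] <<- 1L
        pending <- ps[state[ps] != 2L]
        if (any(state[pending] == 1L)) {
          stop("cycle in parent links involving person '",
               persons$person_id[j], "'")
        }
        if (length(pending)) { stack <- c(stack, pending); next }
      }
      depth[j] <<- if (length(ps)) max(depth[ps]) + 1L else 0L
      state[j] <<- 2L
      stack <- stack[-length(stack)]
    }
  }
  for (i in seq_len(n)) if (state[i] == 0L) visit(i)
  names(depth) <- persons$person_id
  depth
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> family %s: %d persons, %d generations\n",
              x$family_id, nrow(x$persons), max(x$depth) + 1L))
  invisible(x)
}

#' Read pedigrees from a delimited text file
#'
#' One person per row, PED-like columns `family_id`, `person_id`,
#' `father_id`, `mother_id`, `sex`, `birth_year`, `age_end`,
#' `vital_status`, optional `role_tag`; `0` or empty marks an unknown
#' parent. `.csv` is comma-separated, anything else tab-separated. Returns
#' one validated [pedigree()] per `family_id`.
#'
#' @param path Path to the file.
#' @return A named list of `pedigree` objects (names = family ids).
#' @export
read_pedigree <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = "character", na.strings = c("NA", ""))
  df$birth_year <- as.integer(df$birth_year)
  df$age_end <- as.numeric(df$age_end)
  lapply(split(df, df$family_id), pedigree)
}

#' Write pedigrees to a delimited text file
#'
#' Emits the dialect [read_pedigree()] accepts; unknown parents are written
#' as `0`, missing values as empty fields.
#'
#' @param pedigrees A `pedigree` or list of them.
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigrees, path) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  rows <- do.call(rbind, lapply(pedigrees, function(p) p$persons))
  for (col in c("father_id", "mother_id")) {
    rows[[col]][is.na(rows[[col]])] <- "0"
  }
  cols <- c("family_id", "person_id", "father_id", "mother_id", "sex",
            "birth_year", "age_end", "vital_status", "role_tag")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows[, cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Kinship coefficient between two pedigree members
#'
#' The probability that one allele drawn at random from `a` and one from
#' `b` are identical by descent, computed by the standard recursion on the
#' pedigree as given: founders are unrelated and non-inbred, and
#' `phi(a, a) = 1/2 (1 + phi(father_a, mother_a))`. For distinct persons
#' the recursion descends through the parents of whichever argument sits in
#' the later generation, which guarantees termination on the acyclic graph.
#'
#' @param ped A [pedigree()].
#' @param a,b Person ids.
#' @return Kinship coefficient in \[0, 1\].
#' @export
kinship_coefficient <- function(ped, a, b) {
  stopifnot(inherits(ped, "pedigree"))
  for (id in c(a, b)) {
    if (!id %in% ped$persons$person_id) stop("unknown person id '", id, "'")
  }
  memo <- new.env(parent = emptyenv())
  ped_phi(ped, a, b, memo)
}

ped_phi <- function(ped, a, b, memo) {
  if (is.na(a) || is.na(b)) return(0)
  key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  prs <- ped$persons
  ia <- ped$index[[a]]; ib <- ped$index[[b]]
  val <- if (a == b) {
    0.5 * (1 + ped_phi(ped, prs$father_id[ia], prs$mother_id[ia], memo))
  } else {
    # recurse through the deeper individual: it cannot be an ancestor of
    # the other, so the recursion strictly reduces total depth
    if (ped$depth[[a]] < ped$depth[[b]]) { tmp <- a; a <- b; b <- tmp; ia <- ib }
    0.5 * (ped_phi(ped, prs$father_id[ia], b, memo) +
           ped_phi(ped, prs$mother_id[ia], b, memo))
  }
  memo[[key]] <- val
  val
}

#' Relationship coefficient (expected genome sharing)
#'
#' Twice the kinship coefficient: the expected fraction of nuclear DNA two
#' relatives share. Parent-child and full siblings give 0.5; grandparents,
#' aunts and uncles 0.25; first cousins 0.125. These are the weights `w_k`
#' the LRC score puts on each relative.
#'
#' @inheritParams kinship_coefficient
#' @return Relationship coefficient in \[0, 1\].
#' @export
relationship_coefficient <- function(ped, a, b) {
  if (identical(a, b)) stop("relationship coefficient requires two distinct persons")
  2 * kinship_coefficient(ped, a, b)
}

ped_children_of <- function(ped, parent_id) {
  prs <- ped$persons
  prs$person_id[(!is.na(prs$father_id) & prs$father_id == parent_id) |
                (!is.na(prs$mother_id) & prs$mother_id == parent_id)]
}

ped_siblings_of <- function(ped, id) {
  prs <- ped$persons
  i <- ped$index[[id]]
  sibs <- character(0)
  for (p in c(prs$father_id[i], prs$mother_id[i])) {
    if (!is.na(p)) sibs <- c(sibs, ped_children_of(ped, p))
  }
  setdiff(unique(sibs), id)
}

#' Ancestral blood relatives of a focal person
#'
#' Enumerates the relative set the LRC score is computed over: by default
#' the focal person's parents, grandparents, and aunts/uncles (full or half
#' siblings of a parent) — the two ascending generations of blood
#' relatives. Siblings of the focal person can be added via
#' `include_siblings` but are off by default, matching a score built from
#' ancestors only. Married-in spouses never appear: only parent links are
#' followed.
#'
#' @param ped A [pedigree()].
#' @param focal Person id of the individual being scored.
#' @param relations Relationship classes to include; any subset of
#'   `c("parents", "grandparents", "aunts_uncles")`.
#' @param include_siblings Also include full/half siblings of the focal
#'   person.
#' @return An object of class `relative_set`: a data frame with columns
#'   `relative_id`, `relation`, `weight` (the relationship coefficient) and
#'   attribute `focal`.
#' @export
ancestral_relatives <- function(ped, focal,
                                relations = c("parents", "grandparents",
                                              "aunts_uncles"),
                                include_siblings = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  if (!focal %in% ped$persons$person_id) stop("unknown focal id '", focal, "'")
  relations <- match.arg(relations, several.ok = TRUE)
  prs <- ped$persons
  i <- ped$index[[focal]]
  parents <- c(prs$father_id[i], prs$mother_id[i])
  parents <- parents[!is.na(parents)]

  out <- list()
  add <- function(ids, label) {
    ids <- setdiff(unique(ids), focal)
    if (length(ids)) {
      out[[length(out) + 1L]] <<- data.frame(
        relative_id = ids, relation = label, stringsAsFactors = FALSE)
    }
  }
  if ("parents" %in% relations) add(parents, "parent")
  if ("grandparents" %in% relations) {
    gps <- unlist(lapply(parents, function(p) {
      j <- ped$index[[p]]
      c(prs$father_id[j], prs$mother_id[j])
    }))
    add(gps[!is.na(gps)], "grandparent")
  }
  if ("aunts_uncles" %in% relations) {
    au <- unlist(lapply(parents, function(p) ped_siblings_of(ped, p)))
    add(setdiff(au, parents), "aunt_uncle")
  }
  if (include_siblings) add(ped_siblings_of(ped, focal), "sibling")

  if (!length(out)) {
    res <- data.frame(relative_id = character(0), relation = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[!duplicated(res$relative_id), , drop = FALSE]
    memo <- new.env(parent = emptyenv())
    res$weight <- vapply(res$relative_id,
                         function(r) 2 * ped_phi(ped, focal, r, memo),
                         numeric(1))
    res <- res[res$weight > 0, , drop = FALSE]  # blood relatives only
    rownames(res) <- NULL
  }
  attr(res, "focal") <- focal
  class(res) <- c("relative_set", class(res))
  res
}
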