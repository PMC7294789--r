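# Fixtures are built in code: small pedigrees with known kinship structure,
# constant-hazard life tables with closed-form survival, and a brute-force
# path-counting oracle for relationship coefficients.

person_row <- function(id, father = NA, mother = NA, sex = NA,
                       birth_year = NA, age_end = NA,
                       vital_status = "dead", family_id = "famA",
                       role_tag = NA) {
  data.frame(person_id = id, family_id = family_id,
             father_id = as.character(father), mother_id = as.character(mother),
             sex = as.character(sex), birth_year = as.integer(birth_year),
             age_end = as.numeric(age_end), vital_status = vital_status,
             role_tag = as.character(role_tag), stringsAsFactors = FALSE)
}

# Three generations: grandparents gf/gm -> parents pa (their child) and
# aunt/uncle au1..au3 (pa's full siblings); married-in parent mo (founder);
# focal + sibling are children of pa x mo. An aunt's spouse (non-blood)
# is present to exercise exclusion.
toy_pedigree_3gen <- function(ages = NULL) {
  df <- rbind(
    person_row("gf", sex = "male", birth_year = 1860, age_end = 70),
    person_row("gm", sex = "female", birth_year = 1862, age_end = 85),
    person_row("gf2", sex = "male", birth_year = 1861, age_end = 60),
    person_row("gm2", sex = "female", birth_year = 1863, age_end = 65),
    person_row("pa", "gf", "gm", "male", 1890, 90),
    person_row("au1", "gf", "gm", "female", 1892, 50),
    person_row("au2", "gf", "gm", "male", 1894, 55),
    person_row("au3", "gf", "gm", "female", 1896, 88),
    person_row("au1_sp", sex = "male", birth_year = 1891, age_end = 77),
    person_row("mo", "gf2", "gm2", "female", 1895, 82),
    person_row("focal", "pa", "mo", "female", 1920, 70, role_tag = "F3_descendant"),
    person_row("sib", "pa", "mo", "male", 1922, 60)
  )
  if (!is.null(ages)) df$age_end[match(names(ages), df$person_id)] <- ages
  pedigree(df)
}

# Classic 8-person first-cousin pedigree: two sibs (p1, p2) married to
# founders; c1 and c2 are first cousins.
cousin_pedigree <- function() {
  pedigree(rbind(
    person_row("g1", sex = "male", birth_year = 1850, age_end = 70),
    person_row("g2", sex = "female", birth_year = 1852, age_end = 75),
    person_row("p1", "g1", "g2", "male", 1880, 70),
    person_row("p2", "g1", "g2", "female", 1882, 70),
    person_row("s1", sex = "female", birth_year = 1881, age_end = 70),
    person_row("s2", sex = "male", birth_year = 1880, age_end = 70),
    person_row("c1", "p1", "s1", "male", 1910, 70),
    person_row("c2", "s2", "p2", "female", 1912, 70)
  ))
}

# Flat-hazard tables: S(t) = exp(-h t), percentile closed form 1 - exp(-h t).
flat_tables <- function(h = 0.05, years = 1850:1930, a_max = 99) {
  life_table_collection(
    unlist(lapply(c("female", "male"), function(s) {
      lapply(years, function(y) life_table(s, y, rep(h, a_max + 1)))
    }), recursive = FALSE),
    source = "flat test tables"
  )
}

# Brute-force path-counting oracle for the relationship coefficient:
# 2 * sum over common ancestors C and pairs of ancestral paths (a -> C,
# b -> C) meeting only at C of (1/2)^(len_a + len_b + 1). Valid for
# non-inbred pedigrees (all test pedigrees are).
oracle_relationship <- function(ped, a, b) {
  prs <- ped$persons
  parents_of <- function(id) {
    i <- which(prs$person_id == id)
    p <- c(prs$father_id[i], prs$mother_id[i])
    p[!is.na(p)]
  }
  # all ancestral paths from id upward (including the trivial path {id})
  paths_up <- function(id) {
    out <- list(id)
    for (p in parents_of(id)) {
      out <- c(out, lapply(paths_up(p), function(pp) c(id, pp)))
    }
    out
  }
  pa <- paths_up(a); pb <- paths_up(b)
  total <- 0
  for (x in pa) for (y in pb) {
    cx <- x[length(x)]; cy <- y[length(y)]
    if (cx != cy) next
    # paths must share only the common ancestor endpoint
    if (length(intersect(x[-length(x)], y[-length(y)])) > 0) next
    total <- total + 0.5^(length(x) - 1 + length(y) - 1 + 1)
  }
  2 * total
}

# Random non-inbred pedigree of <= 12 persons: founders plus children of
# random founder/member couples (never creating loops: mates are founders).
random_small_pedigree <- function(seed) {
  set.seed(seed)
  n_founder_pairs <- sample(2:3, 1)
  rows <- list()
  founders <- character(0)
  k <- 0
  for (i in seq_len(n_founder_pairs)) {
    k <- k + 1; fa <- paste0("f", k)
    k <- k + 1; mo <- paste0("f", k)
    rows <- c(rows, list(
      person_row(fa, sex = "male", birth_year = 1850 + i, age_end = 70),
      person_row(mo, sex = "female", birth_year = 1850 + i, age_end = 70)))
    founders <- c(founders, fa, mo)
  }
  gen1 <- character(0)
  males <- founders[seq(1, length(founders), 2)]
  females <- founders[seq(2, length(founders), 2)]
  for (j in seq_len(sample(2:4, 1))) {
    id <- paste0("c", j)
    rows <- c(rows, list(person_row(id, sample(males, 1), sample(females, 1),
                                    sample(c("male", "female"), 1), 1880 + j, 70)))
    gen1 <- c(gen1, id)
  }
  # one extra generation off a random couple of gen1 members
  g1m <- gen1[vapply(rows[match(gen1, vapply(rows, function(r) r$person_id, ""))],
                     function(r) r$sex == "male", logical(1))]
  g1f <- setdiff(gen1, g1m)
  if (length(g1m) && length(g1f)) {
    fa <- sample(g1m, 1); mo <- sample(g1f, 1)
    if (!share_parent(rows, fa, mo)) {
      for (j in seq_len(sample(1:2, 1))) {
        rows <- c(rows, list(person_row(paste0("d", j), fa, mo,
                                        sample(c("male", "female"), 1),
                                        1910 + j, 70)))
      }
    }
  }
  pedigree(do.call(rbind, rows))
}

share_parent <- function(rows, a, b) {
  get <- function(id) {
    r <- rows[[which(vapply(rows, function(r) r$person_id, "") == id)]]
    c(r$father_id, r$mother_id)
  }
  length(intersect(stats::na.omit(get(a)), stats::na.omit(get(b)))) > 0
}
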