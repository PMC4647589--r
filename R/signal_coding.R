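# Name dictionary for compounds whose class is not recoverable from the
# name grammar alone (mostly terpenoids, whose -ol/-al/-ene suffixes would
# otherwise be misread as plain alcohols/aldehydes/alkenes).
.compound_dictionary <- c(
  "9-oda" = "keto acid",
  "9-oxo-decenoic acid" = "keto acid",
  "9-oxo-2-decenoic acid" = "keto acid",
  "9-oxodecenoic acid" = "keto acid",
  "squalene" = "terpene",
  "farnesene" = "terpene",
  "alpha-farnesene" = "terpene",
  "beta-farnesene" = "terpene",
  "limonene" = "terpene",
  "myrcene" = "terpene",
  "ocimene" = "terpene",
  "beta-ocimene" = "terpene",
  "geranial" = "terpene",
  "neral" = "terpene",
  "citral" = "terpene",
  "geraniol" = "terpene alcohol",
  "nerol" = "terpene alcohol",
  "farnesol" = "terpene alcohol",
  "linalool" = "terpene alcohol",
  "citronellol" = "terpene alcohol",
  "nerolidol" = "terpene alcohol",
  "geranylgeraniol" = "terpene alcohol"
)

#' Describe a compound by structural hints
#'
#' A fallback description for compounds whose name is unknown to the
#' classifier: chain length, saturation, functional-group tag and
#' methyl-branch count. When the functional-group tag and hydrocarbon
#' features conflict, the functional group wins (an unsaturated acid is a
#' fatty acid, not an alkene) because the classes mirror biosynthetic
#' end-group chemistry; a methyl-branched alkene is an alkene.
#'
#' @param name Compound name (optional if a descriptor is given).
#' @param chain_length Carbon chain length (optional, `> 0`).
#' @param saturation `"none"`, `"ene"` or `"diene"`.
#' @param functional_group One of `"hydrocarbon"`, `"acid"`, `"keto-acid"`,
#'   `"ester"`, `"aldehyde"`, `"alcohol"`, `"terpene"`, `"terpene-alcohol"`,
#'   `"lactone"`, or `NA`.
#' @param methyl_branches Number of methyl branches (default 0).
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(name = NA_character_, chain_length = NA_integer_,
                            saturation = c("none", "ene", "diene"),
                            functional_group = NA_character_,
                            methyl_branches = 0L) {
  saturation <- match.arg(saturation)
  if ((is.na(name) || !nzchar(name)) && is.na(functional_group))
    stop("a compound record needs a name or a functional-group descriptor")
  if (!is.na(chain_length) && chain_length <= 0)
    stop("chain_length must be positive")
  valid_fg <- c("hydrocarbon", "acid", "keto-acid", "ester", "aldehyde",
                "alcohol", "terpene", "terpene-alcohol", "lactone")
  if (!is.na(functional_group) && !(functional_group %in% valid_fg))
    stop("unknown functional group tag: ", functional_group)
  structure(list(name = name, chain_length = chain_length,
                 saturation = saturation,
                 functional_group = functional_group,
                 methyl_branches = as.integer(methyl_branches)),
            class = "compound_record")
}

#' Classify a compound into one of the twelve biosynthetic classes
#'
#' Deterministic classification into [compound_classes()]: an exact
#' dictionary of special names is consulted first, then a name grammar
#' (suffix and keyword rules on the systematic name), then the descriptor
#' rules of a [compound_record()]. Compounds that cannot be classified are
#' returned as `"unknown"` -- never silently dropped -- and a message lists
#' them.
#'
#' @param x Character vector of compound names, or a single
#'   [compound_record()].
#' @param quiet Suppress the message listing unknowns.
#' @return Character vector of class names (`"unknown"` where
#'   unclassifiable).
#' @examples
#' classify_compound(c("pentacosane", "9-ODA", "decyl decanoate"))
#' @export
classify_compound <- function(x, quiet = FALSE) {
  if (inherits(x, "compound_record")) {
    cls <- NA_character_
    if (!is.na(x$name) && nzchar(x$name)) cls <- .classify_name(x$name)
    if (is.na(cls) || cls == "unknown") cls <- .classify_descriptor(x)
    if (cls == "unknown" && !quiet)
      message("unclassifiable compound record: ",
              if (is.na(x$name)) "<unnamed>" else x$name)
    return(cls)
  }
  if (!is.character(x)) stop("'x' must be compound names or a compound_record")
  out <- vapply(x, .classify_name, character(1), USE.NAMES = FALSE)
  if (any(out == "unknown") && !quiet)
    message("unclassifiable compounds: ",
            paste(unique(x[out == "unknown"]), collapse = ", "))
  out
}

.classify_name <- function(name) {
  if (is.na(name) || !nzchar(name)) return("unknown")
  s <- tolower(trimws(name))
  hit <- .compound_dictionary[s]
  if (!is.na(hit)) return(unname(hit))
  # last alphabetic token carries the suffix chemistry
  tokens <- regmatches(s, gregexpr("[a-z]+", s))[[1]]
  last <- if (length(tokens)) tokens[length(tokens)] else ""
  if (grepl("lactone", s) || grepl("olide$", last)) return("lactone")
  if (grepl("oxo", s) && grepl("acid", s)) return("keto acid")
  if (grepl("oate$", last) || grepl("\\bester\\b", s)) return("ester")
  if (grepl("\\bacid\\b", s)) return("fatty acid")
  if (grepl("(an|en|dien)al$", last)) return("aldehyde")
  if (grepl("(an|en|dien)ol$", last)) return("alcohol")
  if (grepl("dien", s)) return("alkadiene")
  if (grepl("ene$", last) || grepl("ene\\b", s)) return("alkene")
  if (grepl("ane$", last)) {
    if (grepl("methyl", s)) return("branched alkane")
    return("linear alkane")
  }
  "unknown"
}

.classify_descriptor <- function(rec) {
  fg <- rec$functional_group
  if (is.na(fg)) return("unknown")
  switch(fg,
    "acid" = "fatty acid",
    "keto-acid" = "keto acid",
    "ester" = "ester",
    "aldehyde" = "aldehyde",
    "alcohol" = "alcohol",
    "terpene" = "terpene",
    "terpene-alcohol" = "terpene alcohol",
    "lactone" = "lactone",
    "hydrocarbon" = switch(rec$saturation,
      diene = "alkadiene",
      ene = "alkene",
      none = if (isTRUE(rec$methyl_branches > 0)) "branched alkane"
             else "linear alkane"
    ),
    "unknown"
  )
}

#' Default criterion for calling a compound fertility-linked
#'
#' Differences between castes can be qualitative (present in the fertile
#' caste, absent in the other) or quantitative (overproduced). The
#' quantitative rule is a one-sided Wilcoxon rank-sum comparison (fertile
#' above non-fertile) at level `alpha` combined with a minimum arithmetic
#' fold-change of group means; both are configurable stand-ins for whatever
#' statistical definition of "overproduced" a given dataset used.
#'
#' @param alpha Significance level of the rank-sum test (default 0.05).
#' @param fold_min Minimum fertile/non-fertile mean ratio (default 2).
#' @param detect_prop Minimum fraction of fertile-group individuals in which
#'   the compound must be detected for the qualitative rule (default 0.5).
#' @return A `fertility_criterion` list.
#' @export
fertility_criterion <- function(alpha = 0.05, fold_min = 2, detect_prop = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (fold_min < 1) stop("'fold_min' must be >= 1")
  if (detect_prop <= 0 || detect_prop > 1) stop("'detect_prop' must be in (0, 1]")
  structure(list(alpha = alpha, fold_min = fold_min, detect_prop = detect_prop),
            class = "fertility_criterion")
}

.fertile_groups <- c("queen", "mature_female")
.nonfertile_groups <- c("worker", "virgin_female")

#' Is a compound fertility-linked in one species' profile?
#'
#' Applies the qualitative rule (detected in the fertile caste, abundance
#' zero in every non-fertile individual) OR the quantitative rule of the
#' [fertility_criterion()]. The decision is invariant to a global rescaling
#' of abundances (ranks and fold-changes are unit-free). With fewer than two
#' individuals in either group only the qualitative rule is applied, with a
#' warning; a compound detected in neither group returns `FALSE` with a
#' warning.
#'
#' @param profile Long-format data frame for one species with columns
#'   `group` (queen/worker or mature_female/virgin_female),
#'   `individual_id`, `compound`, `abundance` (`>= 0`). Individuals without
#'   a row for the compound count as abundance 0.
#' @param compound Compound name to test.
#' @param criterion A [fertility_criterion()].
#' @return Logical.
#' @export
call_fertility_linked <- function(profile, compound,
                                  criterion = fertility_criterion()) {
  stopifnot(is.data.frame(profile))
  need <- c("group", "individual_id", "compound", "abundance")
  if (!all(need %in% colnames(profile)))
    stop("profile needs columns: ", paste(need, collapse = ", "))
  if (any(profile$abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  groups <- unique(profile$group)
  fg <- intersect(groups, .fertile_groups)
  ng <- intersect(groups, .nonfertile_groups)
  if (length(fg) != 1L || length(ng) != 1L)
    stop("profile must contain one fertile (queen/mature_female) and one ",
         "non-fertile (worker/virgin_female) group; found: ",
         paste(groups, collapse = ", "))
  per_indiv <- function(grp) {
    ids <- unique(profile$individual_id[profile$group == grp])
    sel <- profile$group == grp & profile$compound == compound
    ab <- stats::setNames(rep(0, length(ids)), ids)
    if (any(sel)) {
      agg <- tapply(profile$abundance[sel], profile$individual_id[sel], sum)
      ab[names(agg)] <- agg
    }
    ab
  }
  f <- per_indiv(fg)
  n <- per_indiv(ng)
  if (all(f == 0) && all(n == 0)) {
    warning("compound '", compound, "' not detected in either group")
    return(FALSE)
  }
  qualitative <- all(n == 0) && mean(f > 0) >= criterion$detect_prop
  if (qualitative) return(TRUE)
  if (length(f) < 2L || length(n) < 2L) {
    warning("single-individual group for compound '", compound,
            "': qualitative rule only")
    return(FALSE)
  }
  if (mean(n) == 0) return(FALSE) # detected but below the qualitative bar
  p <- suppressWarnings(
    stats::wilcox.test(f, n, alternative = "greater", exact = NULL)$p.value)
  fold <- mean(f) / mean(n)
  isTRUE(p < criterion$alpha && fold >= criterion$fold_min)
}

#' Read a per-individual compound abundance table
#'
#' @param path TSV with columns `species`, `sociality`, `group`,
#'   `individual_id`, `compound`, `abundance`.
#' @return A validated data frame.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(abundance = "numeric"))
  validate_profiles(df)
}

#' Validate a long-format chemical profile table
#'
#' @param profiles Data frame with columns `species`, `sociality`, `group`,
#'   `individual_id`, `compound`, `abundance`.
#' @return The data frame, after checking group labels are consistent with
#'   sociality (queen/worker for eusocial, mature/virgin female for
#'   solitary) and abundances are non-negative.
#' @export
validate_profiles <- function(profiles) {
  need <- c("species", "sociality", "group", "individual_id",
            "compound", "abundance")
  miss <- setdiff(need, colnames(profiles))
  if (length(miss)) stop("profile table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(profiles$sociality %in% c("eusocial", "solitary")))
    stop("sociality must be 'eusocial' or 'solitary'")
  bad_eu <- profiles$sociality == "eusocial" &
    !(profiles$group %in% c("queen", "worker"))
  bad_sol <- profiles$sociality == "solitary" &
    !(profiles$group %in% c("mature_female", "virgin_female"))
  if (any(bad_eu | bad_sol))
    stop("group labels inconsistent with sociality for species: ",
         paste(unique(profiles$species[bad_eu | bad_sol]), collapse = ", "))
  soc <- tapply(profiles$sociality, profiles$species,
                function(x) length(unique(x)))
  if (any(soc > 1))
    stop("species with conflicting sociality: ",
         paste(names(soc)[soc > 1], collapse = ", "))
  if (any(profiles$abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  profiles
}

#' Code chemical profiles into the binary character matrix
#'
#' For each species and compound class, the cell is 1 if at least one
#' compound of that class is fertility-linked under the criterion, 0 if
#' compounds of the class were assayed but none is fertility-linked, and
#' `?` (`NA`) if no compound of the class was measured in that species.
#' Compounds the classifier cannot place are excluded from the class cells
#' and surfaced in the `unknown_compounds` attribute (with a warning).
#'
#' @param profiles Long-format profile table (see [validate_profiles()]).
#' @param criterion A [fertility_criterion()].
#' @param classes Character classes to code; default [compound_classes()].
#' @return A character matrix (species x classes) with attribute
#'   `unknown_compounds`.
#' @export
build_character_matrix <- function(profiles,
                                   criterion = fertility_criterion(),
                                   classes = compound_classes()) {
  if (nrow(profiles) == 0L) {
    out <- matrix(numeric(0), 0, length(classes),
                  dimnames = list(NULL, classes))
    return(structure(validate_character_matrix(out),
                     unknown_compounds = character(0)))
  }
  profiles <- validate_profiles(profiles)
  species <- unique(profiles$species)
  mat <- matrix(NA_real_, length(species), length(classes),
                dimnames = list(species, classes))
  unknown <- character(0)
  for (sp in species) {
    prof <- profiles[profiles$species == sp, , drop = FALSE]
    comps <- unique(prof$compound)
    if (length(comps) == 0L || all(is.na(prof$abundance))) {
      warning("species '", sp, "' has no usable compounds; coded as all-?")
      next
    }
    cls <- classify_compound(comps, quiet = TRUE)
    if (any(cls == "unknown"))
      unknown <- union(unknown, comps[cls == "unknown"])
    for (cl in intersect(unique(cls), classes)) {
      members <- comps[cls == cl]
      linked <- vapply(members, function(cm)
        suppressWarnings(call_fertility_linked(prof, cm, criterion)),
        logical(1))
      mat[sp, cl] <- as.numeric(any(linked))
    }
  }
  if (length(unknown))
    warning("unclassifiable compounds excluded from coding: ",
            paste(unknown, collapse = ", "))
  structure(validate_character_matrix(mat), unknown_compounds = unknown)
}
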