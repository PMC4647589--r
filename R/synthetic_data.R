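#' Configuration for the synthetic-data generators
#'
#' Bundles the study-level conditions the simulators emulate: tree size and
#' birth rate for Yule (pure-birth) topologies, the true symmetric
#' transition rate of the binary characters, and the chemical-profile
#' parameters (individuals per caste group, queen/mature-female
#' overproduction fold, lognormal noise). Defaults mirror the study design:
#' 16 species, 12 compound-class characters, 8 individuals per group, a
#' 4-fold queen excess for fertility-linked compounds, and lognormal
#' abundance noise with sigma 0.75 on the log scale (peak-area coefficients
#' of variation of roughly 50-100%).
#'
#' @param n_tips Number of species (`>= 2`).
#' @param birth Yule birth rate (`> 0`).
#' @param q_true True transition rate per unit branch (`>= 0`).
#' @param n_characters Number of binary characters (`>= 1`).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_individuals Individuals per caste group (`>= 1`).
#' @param fold_change Fertile/non-fertile abundance ratio for
#'   fertility-linked compounds; `Inf` makes the difference qualitative
#'   (non-fertile abundance exactly 0).
#' @param sigma_log Lognormal sd on the log scale (`> 0`).
#' @param base_abundance Median abundance of a compound (arbitrary units).
#' @param compounds_per_class Compounds assayed per class (`>= 1`).
#' @param prop_eusocial Fraction of species that are eusocial.
#' @param p_linked Probability a species-class cell is truly
#'   fertility-linked when no truth matrix is supplied.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_tips = 16L, birth = 1, q_true = 0.1,
                              n_characters = 12L, seed = 1L,
                              n_individuals = 8L, fold_change = 4,
                              sigma_log = 0.75, base_abundance = 100,
                              compounds_per_class = 2L,
                              prop_eusocial = 11 / 16, p_linked = 0.5) {
  stopifnot(n_tips >= 2, birth > 0, q_true >= 0, n_characters >= 1,
            n_individuals >= 1, fold_change >= 1 || is.infinite(fold_change),
            sigma_log > 0, base_abundance > 0, compounds_per_class >= 1,
            prop_eusocial >= 0, prop_eusocial <= 1,
            p_linked >= 0, p_linked <= 1)
  structure(list(n_tips = as.integer(n_tips), birth = birth, q_true = q_true,
                 n_characters = as.integer(n_characters),
                 seed = as.integer(seed),
                 n_individuals = as.integer(n_individuals),
                 fold_change = fold_change, sigma_log = sigma_log,
                 base_abundance = base_abundance,
                 compounds_per_class = as.integer(compounds_per_class),
                 prop_eusocial = prop_eusocial, p_linked = p_linked),
            class = "sim_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Rooted binary topology with labeled tips `sp01, sp02, ...`; branch
#' lengths come from the pure-birth process and are typically overwritten
#' with [set_unit_branch_lengths()] downstream. Yule shapes are used because
#' the reconstruction is conditional on a fixed tree, so the generator only
#' needs plausible topologies.
#'
#' @param n_tips Number of tips (`>= 2`).
#' @param birth Birth rate.
#' @param seed Optional integer seed for reproducibility.
#' @return A `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips = 16L, birth = 1, seed = NULL) {
  if (n_tips < 2) stop("'n_tips' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  validate_tree(tr)
}

#' Simulate a binary character along a tree under Mk1
#'
#' Forward simulation of the same process the reconstruction assumes: the
#' root state is drawn from the prior, then each edge switches state with
#' probability `(1 - exp(-2*q*t))/2`. Returns the tip states together with
#' the true internal states so reconstructions can be scored against the
#' truth.
#'
#' @param tree A `phylo` with branch lengths (use
#'   [set_unit_branch_lengths()] for the unit-length convention).
#' @param q_true Transition rate (`>= 0`).
#' @param seed Optional integer seed.
#' @param pi Root state prior, default flat.
#' @return List with `tip_states` (named 0/1 vector), `node_states`
#'   (internal nodes, named by ape node id) and `root_state`.
#' @export
simulate_character <- function(tree, q_true, seed = NULL, pi = c(0.5, 0.5)) {
  validate_tree(tree)
  if (q_true < 0) stop("'q_true' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  po <- ape::reorder.phylo(tree, "postorder")
  elen <- po$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(po$edge))
  n <- ape::Ntip(po)
  N <- n + po$Nnode
  states <- rep(NA_integer_, N)
  root <- n + 1L
  states[root] <- stats::rbinom(1, 1, pi[2])
  # reverse postorder visits each edge parent-first
  for (i in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    sw <- (1 - exp(-2 * q_true * elen[i])) / 2
    flip <- stats::runif(1) < sw
    states[ch] <- if (flip) 1L - states[p] else states[p]
  }
  list(
    tip_states = stats::setNames(states[seq_len(n)], po$tip.label),
    node_states = stats::setNames(states[(n + 1L):N], (n + 1L):N),
    root_state = states[root]
  )
}

# Compound roster: `compounds_per_class` named compounds per class, all
# classifiable by classify_compound(), so coding recovers the truth.
.default_roster <- function(compounds_per_class = 2L) {
  roster <- list(
    "linear alkane" = c("tricosane", "pentacosane", "heptacosane",
                        "nonacosane"),
    "branched alkane" = c("3-methylpentacosane", "11-methylheptacosane",
                          "13-methylnonacosane", "5-methyltricosane"),
    "alkene" = c("(Z)-9-tricosene", "9-pentacosene", "7-heptacosene",
                 "9-hentriacontene"),
    "alkadiene" = c("6,9-tricosadiene", "8,11-pentacosadiene",
                    "6,9-heptacosadiene", "8,11-nonacosadiene"),
    "aldehyde" = c("hexadecanal", "octadecanal", "eicosanal", "docosanal"),
    "alcohol" = c("hexacosanol", "docosanol", "tetracosanol", "octacosanol"),
    "fatty acid" = c("hexadecanoic acid", "(Z)-9-octadecenoic acid",
                     "octadecanoic acid", "tetradecanoic acid"),
    "keto acid" = c("9-oxo-2-decenoic acid", "10-oxodecanoic acid",
                    "8-oxooctanoic acid", "9-oxononanoic acid"),
    "ester" = c("decyl decanoate", "hexadecanoic acid methyl ester",
                "octadecenoic acid methyl ester", "dodecyl acetate"),
    "terpene" = c("squalene", "beta-farnesene", "limonene", "myrcene"),
    "terpene alcohol" = c("geraniol", "farnesol", "nerolidol", "linalool"),
    "lactone" = c("hexadecanolide", "octadecanolide", "tetradecanolide",
                  "dodecanolide")
  )
  lapply(roster, utils::head, compounds_per_class)
}

#' Simulate caste chemical profiles with known coding ground truth
#'
#' Per species, generates queen/worker (eusocial) or mature/virgin-female
#' (solitary) per-individual abundance tables. Designated fertility-linked
#' compounds (one per truly-linked species-class cell) have the configured
#' fold excess in the fertile group; abundances carry multiplicative
#' lognormal noise (peak areas are positive and right-skewed). With
#' `fold_change = Inf` the non-fertile group's abundance is exactly zero
#' (a qualitative difference). Returns the ground-truth binary matrix the
#' coding stage should recover.
#'
#' @param config A [simulation_config()].
#' @param truth Optional species x class 0/1 matrix to use as ground truth;
#'   by default cells are Bernoulli(`p_linked`).
#' @return List with `profiles` (long data frame) and `truth` (binary
#'   matrix).
#' @export
simulate_chem_profiles <- function(config = simulation_config(),
                                   truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- compound_classes()
  species <- sprintf("sp%02d", seq_len(config$n_tips))
  n_eu <- round(config$prop_eusocial * config$n_tips)
  sociality <- stats::setNames(
    rep(c("eusocial", "solitary"), c(n_eu, config$n_tips - n_eu)), species)
  if (is.null(truth)) {
    truth <- matrix(stats::rbinom(length(species) * length(classes), 1,
                                  config$p_linked),
                    length(species), length(classes),
                    dimnames = list(species, classes))
  } else {
    truth <- validate_character_matrix(truth)
    stopifnot(setequal(rownames(truth), species),
              setequal(colnames(truth), classes))
    truth <- truth[species, classes]
  }
  roster <- .default_roster(config$compounds_per_class)
  rows <- vector("list", 0)
  for (sp in species) {
    eu <- sociality[sp] == "eusocial"
    groups <- if (eu) c("queen", "worker") else c("mature_female", "virgin_female")
    for (cl in classes) {
      comps <- roster[[cl]]
      linked <- truth[sp, cl] == 1
      for (ci in seq_along(comps)) {
        is_signal <- linked && ci == 1L # one linked compound per linked class
        # In the purely qualitative regime (fold = Inf) caste-invariant
        # compounds get identical caste profiles: the regime isolates the
        # presence/absence logic, so coding recovers the truth exactly;
        # the statistical criterion is exercised by the finite-fold regimes.
        shared <- if (is.infinite(config$fold_change) && !is_signal)
          stats::rlnorm(config$n_individuals,
                        meanlog = log(config$base_abundance),
                        sdlog = config$sigma_log)
        for (g in groups) {
          fertile <- g %in% .fertile_groups
          mu <- config$base_abundance
          ab <- if (is_signal && !fertile && is.infinite(config$fold_change)) {
            rep(0, config$n_individuals)
          } else if (!is.null(shared)) {
            shared
          } else {
            if (is_signal && fertile && !is.infinite(config$fold_change))
              mu <- mu * config$fold_change
            stats::rlnorm(config$n_individuals, meanlog = log(mu),
                          sdlog = config$sigma_log)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, sociality = unname(sociality[sp]), group = g,
            individual_id = sprintf("%s_%s_%02d", sp, g,
                                    seq_len(config$n_individuals)),
            compound = comps[ci], abundance = ab
          )
        }
      }
    }
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  list(profiles = validate_profiles(profiles), truth = truth)
}

#' Write a full synthetic study directory
#'
#' Materializes every input the pipeline reads: a Yule tree
#' (`tree.nwk`, unit branch lengths), a simulated binary character matrix
#' (`matrix.tsv`, one Mk1 character per compound class at `q_true`), the
#' true internal node states (`node_states.tsv`), caste chemical profiles
#' (`profiles.tsv`) with their coding ground truth (`truth_matrix.tsv`),
#' and nested clade definitions (`clades.yml`).
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_fixture_dir <- function(config = simulation_config(), dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- set_unit_branch_lengths(
    simulate_yule_tree(config$n_tips, config$birth, seed = config$seed))
  classes <- compound_classes()
  ncls <- min(config$n_characters, length(classes))
  char_names <- c(classes[seq_len(ncls)],
                  if (config$n_characters > ncls)
                    sprintf("char%02d", seq_len(config$n_characters - ncls)))
  mat <- matrix(NA_real_, config$n_tips, config$n_characters,
                dimnames = list(tree$tip.label, char_names))
  nodes <- matrix(NA_integer_, tree$Nnode, config$n_characters,
                  dimnames = list(ape::Ntip(tree) + seq_len(tree$Nnode),
                                  char_names))
  for (j in seq_len(config$n_characters)) {
    sim <- simulate_character(tree, config$q_true,
                              seed = config$seed + 1000L + j)
    mat[, j] <- sim$tip_states[tree$tip.label]
    nodes[, j] <- sim$node_states
  }
  chem <- simulate_chem_profiles(config)
  # clades: every internal node's subtree, most inclusive first
  subt <- ape::prop.part(tree)
  clades <- lapply(seq_along(subt), function(i) tree$tip.label[subt[[i]]])
  names(clades) <- sprintf("clade%02d", seq_along(clades))
  keep <- vapply(clades, length, integer(1)) >= 2
  clades <- clades[keep]
  paths <- list(
    tree = file.path(dir, "tree.nwk"),
    matrix = file.path(dir, "matrix.tsv"),
    node_states = file.path(dir, "node_states.tsv"),
    profiles = file.path(dir, "profiles.tsv"),
    truth_matrix = file.path(dir, "truth_matrix.tsv"),
    clades = file.path(dir, "clades.yml")
  )
  write_newick(tree, paths$tree)
  write_character_matrix(mat, paths$matrix)
  utils::write.table(data.frame(node = rownames(nodes), nodes,
                                check.names = FALSE),
                     paths$node_states, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(chem$profiles, paths$profiles, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_character_matrix(chem$truth, paths$truth_matrix)
  yaml::write_yaml(clades, paths$clades)
  invisible(paths)
}
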