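# Independent oracles and small generators shared across tests.

# Brute-force MRCA: intersect root-to-tip paths; the common node farthest
# from the root is the MRCA.
bf_mrca <- function(tree, tips) {
  parent_of <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  path_to_root <- function(node) {
    p <- node
    while (node != root) {
      node <- parent_of[node]
      p <- c(p, node)
    }
    p
  }
  paths <- lapply(match(tips, tree$tip.label), path_to_root)
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(nd) length(path_to_root(nd)), integer(1))
  common[which.max(depth)] # deepest shared node = MRCA
}

# Topology + branch-length isomorphism via ape's comparator.
trees_isomorphic <- function(a, b) {
  use_len <- !is.null(a$edge.length) && !is.null(b$edge.length)
  isTRUE(ape::all.equal.phylo(a, b, use.edge.length = use_len))
}

# Random multifurcating tree: collapse random internal edges of a Yule tree.
random_polytomy_tree <- function(n_tips, seed) {
  tr <- simulate_yule_tree(n_tips, seed = seed)
  internal <- which(tr$edge[, 2] > ape::Ntip(tr))
  if (length(internal) > 1) {
    drop <- sample(internal, max(1, length(internal) %/% 3))
    tr$edge.length[drop] <- 0
    tr <- ape::di2multi(tr, tol = 1e-12)
  }
  set_unit_branch_lengths(tr)
}

# All rooted binary topologies on n labeled tips.
all_topologies <- function(n) {
  phangorn::allTrees(n, rooted = TRUE, tip.label = paste0("t", seq_len(n)))
}

# One species' long-format profile from per-individual abundance vectors.
make_profile <- function(species = "sp", sociality = "eusocial",
                         fertile, nonfertile, compound = "pentacosane") {
  groups <- if (sociality == "eusocial") c("queen", "worker")
            else c("mature_female", "virgin_female")
  rbind(
    data.frame(species = species, sociality = sociality, group = groups[1],
               individual_id = sprintf("f%02d", seq_along(fertile)),
               compound = compound, abundance = fertile),
    data.frame(species = species, sociality = sociality, group = groups[2],
               individual_id = sprintf("n%02d", seq_along(nonfertile)),
               compound = compound, abundance = nonfertile)
  )
}
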