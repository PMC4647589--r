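#' Parse a rooted Newick tree
#'
#' Reads a Newick string under the rooted interpretation (the outermost
#' clade is the root). Single-quoted labels (needed for species names with
#' spaces, e.g. `'Centris analis'`) are supported and stored unquoted;
#' doubled quotes inside a quoted label are unescaped. Internal node labels
#' are preserved. Missing branch lengths are legal and stored as `NA`
#' (the analysis overwrites them with [set_unit_branch_lengths()]).
#' Multifurcations, including a basal polytomy, are retained.
#'
#' @param text A single Newick string, semicolon-terminated.
#' @return An object of class `phylo` (see \pkg{ape}).
#' @seealso [write_newick()], [set_unit_branch_lengths()]
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:1);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single Newick string")
  text <- trimws(text)
  if (grepl("\\[&U\\]", text, ignore.case = TRUE))
    stop("unrooted tree marker [&U] found: a rooted tree is required")
  text <- gsub("\\[&R\\]", "", text, ignore.case = TRUE)
  masked <- .mask_quoted_labels(text)
  .check_newick_syntax(masked$text)
  tr <- tryCatch(
    ape::read.tree(text = masked$text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error: input could not be read as a tree")
  tr$tip.label <- .unmask_labels(tr$tip.label, masked$labels)
  if (!is.null(tr$node.label))
    tr$node.label <- .unmask_labels(tr$node.label, masked$labels)
  validate_tree(tr)
  tr
}

#' Read a rooted Newick tree from a file
#'
#' @param path Path to a Newick file (first tree taken).
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

# Replace 'quoted labels' by safe placeholders so ape's reader never sees
# spaces or punctuation; returns the masked string and the label table.
.mask_quoted_labels <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- character(0)
  labels <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "'") {
      j <- i + 1L
      lab <- character(0)
      repeat {
        if (j > n) stop("Newick parse error: unterminated quote at character ", i)
        if (chars[j] == "'") {
          if (j < n && chars[j + 1L] == "'") { # escaped quote
            lab <- c(lab, "'"); j <- j + 2L
          } else break
        } else {
          lab <- c(lab, chars[j]); j <- j + 1L
        }
      }
      labels <- c(labels, paste(lab, collapse = ""))
      out <- c(out, sprintf("fertsigQLAB%04d", length(labels)))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  list(text = paste(out, collapse = ""), labels = labels)
}

.unmask_labels <- function(x, labels) {
  if (length(labels) == 0L || is.null(x)) return(x)
  m <- regmatches(x, regexpr("^fertsigQLAB[0-9]{4}$", x))
  idx <- grepl("^fertsigQLAB[0-9]{4}$", x)
  x[idx] <- labels[as.integer(sub("fertsigQLAB", "", x[idx]))]
  x
}

# Cheap syntax scan so malformed input fails with a character offset
# instead of an opaque ape error.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  if (!grepl(";\\s*$", paste(chars, collapse = "")))
    stop("Newick parse error: missing terminating ';'")
  invisible(TRUE)
}

#' Write a tree as a Newick string
#'
#' Labels containing spaces, quotes or Newick metacharacters are
#' single-quoted (internal quotes doubled), so [parse_newick()] round-trips
#' them. Trees without branch lengths are written without `:len` fields.
#'
#' @param tree A `phylo` object.
#' @param path Optional file to write to; the string is returned invisibly.
#' @return The Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_tree(tree)
  tr <- tree
  needs_quote <- function(x) grepl("[^A-Za-z0-9_.+|/-]", x)
  labs <- c(tr$tip.label, tr$node.label)
  quoted <- character(0)
  mask <- function(x) {
    idx <- needs_quote(x)
    if (any(idx)) {
      start <- length(quoted)
      quoted <<- c(quoted, x[idx])
      x[idx] <- sprintf("fertsigQLAB%04d", start + seq_len(sum(idx)))
    }
    x
  }
  tr$tip.label <- mask(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- mask(tr$node.label)
  s <- ape::write.tree(tr)
  if (length(quoted)) {
    for (k in seq_along(quoted)) {
      q <- paste0("'", gsub("'", "''", quoted[k]), "'")
      s <- sub(sprintf("fertsigQLAB%04d", k), q, s, fixed = TRUE)
    }
  }
  if (!is.null(path)) writeLines(s, path)
  s
}

#' Validate a phylogeny for use in the analysis
#'
#' Checks the invariants the reconstruction relies on: a single root,
#' at least two uniquely and non-emptily labeled tips, and non-negative
#' (or missing) edge lengths. Multifurcations are allowed.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly; errors otherwise.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(!nzchar(tree$tip.label)) || anyNA(tree$tip.label))
    stop("empty tip labels are not allowed")
  if (!is.null(tree$edge.length)) {
    bad <- which(!is.na(tree$edge.length) & tree$edge.length < 0)
    if (length(bad)) stop("negative edge lengths at edges: ", paste(bad, collapse = ", "))
  }
  # exactly one root: one node that never appears as a child
  parents <- unique(tree$edge[, 1])
  children <- tree$edge[, 2]
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

#' Set every branch length to one
#'
#' Unit branch lengths model a punctuational mode of change: one expected
#' opportunity for change per cladogenetic event rather than per unit time.
#' Missing lengths are replaced like any others; the operation is idempotent
#' and leaves the topology untouched.
#'
#' @param tree A `phylo` object.
#' @return The tree with all edge lengths equal to 1.
#' @export
set_unit_branch_lengths <- function(tree) {
  validate_tree(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (non-empty subset of the
#'   tree's tips). A single tip is its own MRCA.
#' @return The node id (ape numbering: tips `1..Ntip`, root `Ntip+1`).
#' @export
mrca_node <- function(tree, tips) {
  validate_tree(tree)
  tips <- unique(as.character(tips))
  if (length(tips) == 0L) stop("'tips' must be non-empty")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Graft a subtree onto a backbone tree
#'
#' Attaches the subtree's root as a new child of the given backbone node,
#' the operation used to assemble a composite supertree from separately
#' published phylogenies. Tip labels must be disjoint.
#'
#' @param backbone A `phylo` object.
#' @param subtree A `phylo` object, or a single tip label (character) to add.
#' @param attach_at Node id in the backbone at which to attach.
#' @return The grafted `phylo` tree.
#' @export
graft <- function(backbone, subtree, attach_at) {
  validate_tree(backbone)
  if (is.character(subtree) && length(subtree) == 1L) {
    # ape cannot represent a 1-tip phylo; splice a single tip directly
    lab <- subtree
    if (lab %in% backbone$tip.label) stop("label collision: ", lab)
    n <- ape::Ntip(backbone)
    if (!(attach_at %in% seq_len(n + backbone$Nnode)))
      stop("attach_at node ", attach_at, " not in backbone")
    if (attach_at <= n) stop("cannot attach at a tip; choose an internal node")
    new <- backbone
    new$edge[new$edge > n] <- new$edge[new$edge > n] + 1L # shift internals
    att <- if (attach_at > n) attach_at + 1L else attach_at
    new$edge <- rbind(new$edge, c(att, n + 1L))
    # renumber: new tip gets id n+1; old tip ids unchanged
    new$edge.length <- if (!is.null(new$edge.length)) c(new$edge.length, 1) else NULL
    new$tip.label <- c(new$tip.label, lab)
    storage.mode(new$edge) <- "integer"
    attr(new, "order") <- NULL
    out <- parse_newick(write_newick(new)) # renormalize node ordering

    validate_tree(out)
    return(out)
  }
  validate_tree(subtree)
  clash <- intersect(backbone$tip.label, subtree$tip.label)
  if (length(clash))
    stop("label collision between backbone and subtree: ",
         paste(clash, collapse = ", "))
  n <- ape::Ntip(backbone)
  if (!(attach_at %in% seq_len(n + backbone$Nnode)))
    stop("attach_at node ", attach_at, " not in backbone")
  sub <- subtree
  sub$root.edge <- if (is.null(sub$root.edge)) 1 else sub$root.edge
  out <- ape::bind.tree(backbone, sub, where = attach_at, position = 0)
  validate_tree(out)
  out
}

#' Define a named clade by its member tips
#'
#' A clade is located in a tree as the MRCA of its member tips, the way
#' reported clades (e.g. "Meliponini", "Corbiculate bees") are defined by
#' their member taxa.
#'
#' @param name Clade name.
#' @param tips Character vector of tip labels.
#' @return An object of class `clade_definition`.
#' @export
clade_definition <- function(name, tips) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("clade name must be a non-empty string")
  tips <- unique(as.character(tips))
  if (length(tips) == 0L) stop("clade '", name, "' has no tips")
  structure(list(name = name, tips = tips), class = "clade_definition")
}

#' Read clade definitions from a YAML or JSON file
#'
#' The file maps clade names to tip-label lists.
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A named list of [clade_definition()] objects.
#' @export
read_clade_definitions <- function(path) {
  if (!file.exists(path)) stop("clade definition file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported clade definition format: .", ext)
  )
  if (!length(raw) || is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("clade definitions must be a named mapping of clade -> tips")
  if (anyDuplicated(names(raw)))
    stop("duplicate clade names in ", path)
  out <- lapply(names(raw), function(nm) clade_definition(nm, unlist(raw[[nm]])))
  names(out) <- names(raw)
  out
}

# Check clade definitions against a tree; returns named list of tip vectors.
.resolve_clades <- function(tree, clades) {
  if (inherits(clades, "clade_definition")) clades <- list(clades)
  tipsets <- lapply(clades, function(cl) {
    if (inherits(cl, "clade_definition")) cl$tips else unique(as.character(cl))
  })
  nms <- if (!is.null(names(clades)) && all(nzchar(names(clades)))) names(clades)
         else vapply(clades, function(cl) cl$name, character(1))
  names(tipsets) <- nms
  for (nm in nms) {
    missing <- setdiff(tipsets[[nm]], tree$tip.label)
    if (length(missing))
      stop("clade '", nm, "' names tips absent from the tree: ",
           paste(missing, collapse = ", "))
  }
  tipsets
}
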