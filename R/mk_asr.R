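#' Transition probability matrix of the two-state symmetric Markov model
#'
#' For the Mk1 model with a single rate `q` for gains (0 to 1) and losses
#' (1 to 0), the probability of staying in a state over a branch of length
#' `t` is `(1 + exp(-2*q*t))/2` and of switching `(1 - exp(-2*q*t))/2`,
#' the closed form of `expm(Q t)` for the rate matrix with off-diagonal `q`.
#'
#' @param q Transition rate, `>= 0`, per unit branch length.
#' @param t Branch length, `>= 0`.
#' @return A 2x2 row-stochastic, symmetric matrix with dimnames
#'   `c("0","1")` (absent, present).
#' @examples
#' transition_matrix(0.5, 1)
#' @export
transition_matrix <- function(q, t) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("'q' must be a single non-negative number")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single non-negative number")
  e <- exp(-2 * q * t)
  stay <- (1 + e) / 2
  sw <- (1 - e) / 2
  matrix(c(stay, sw, sw, stay), 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Construct an Mk1 model object
#'
#' @param q Symmetric transition rate (`>= 0`).
#' @param logL Maximized log-likelihood, if fitted.
#' @param bounds Rate bounds used in fitting.
#' @param boundary Logical: did the estimate hit a bound?
#' @param pi Root prior over (absent, present). The flat prior equals the
#'   stationary distribution of the symmetric chain, so it is inert here,
#'   but it is kept explicit and configurable.
#' @return An object of class `mk_model`.
#' @export
mk_model <- function(q, logL = NA_real_, bounds = c(1e-8, 1e3),
                     boundary = FALSE, pi = c(0.5, 0.5)) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("'q' must be a single non-negative number")
  if (length(pi) != 2L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("'pi' must be two non-negative probabilities summing to 1")
  structure(
    list(q = q, k = 2L, logL = logL, bounds = bounds,
         boundary = boundary, pi = pi),
    class = "mk_model"
  )
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk1 model (2 states, symmetric gains/losses)\n")
  cat(sprintf("  rate q = %.6g per unit branch length\n", x$q))
  if (is.finite(x$logL)) cat(sprintf("  log-likelihood = %.6f\n", x$logL))
  if (isTRUE(x$boundary))
    cat("  note: estimate at the bound of [",
        format(x$bounds[1]), ", ", format(x$bounds[2]), "]\n", sep = "")
  invisible(x)
}

# ---- internal pruning machinery -------------------------------------------

# Postorder representation reused across likelihood evaluations.
.mk_prep <- function(tree) {
  validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  elen <- po$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(po$edge))
  if (anyNA(elen))
    stop("tree has missing branch lengths; call set_unit_branch_lengths() first")
  list(edge = po$edge, elen = elen, ntip = ape::Ntip(po),
       nnode = po$Nnode, root = ape::Ntip(po) + 1L, labels = po$tip.label,
       tree = po)
}

# Normalize tip states into an (Ntip + Nnode) x 2 conditional-likelihood
# matrix. Accepts 0/1/NA, "0"/"1"/"?" in a named vector covering every tip.
.mk_tip_matrix <- function(prep, tip_states) {
  n <- prep$ntip
  if (is.null(names(tip_states)))
    stop("'tip_states' must be named by tip label")
  missing_tips <- setdiff(prep$labels, names(tip_states))
  if (length(missing_tips))
    stop("no state given for tips: ", paste(missing_tips, collapse = ", "))
  x <- tip_states[prep$labels]
  if (is.character(x)) {
    x[x == "?"] <- NA
    x <- suppressWarnings(as.integer(x))
  }
  x <- as.numeric(x)
  if (any(!is.na(x) & !(x %in% c(0, 1))))
    stop("tip states must be 0, 1 or ?/NA")
  L <- matrix(1, n + prep$nnode, 2)
  known <- !is.na(x)
  L[seq_len(n)[known], 1] <- as.numeric(x[known] == 0)
  L[seq_len(n)[known], 2] <- as.numeric(x[known] == 1)
  L
}

# Felsenstein pruning with optional per-node rescaling and optional
# clamping of one node to one state. Returns the log-likelihood.
.mk_loglik <- function(prep, tipL, q, pi = c(0.5, 0.5), scale = TRUE,
                       clamp_node = NA_integer_, clamp_state = NA_integer_) {
  L <- tipL
  edge <- prep$edge
  elen <- prep$elen
  logscale <- 0
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    e <- exp(-2 * q * elen[i])
    stay <- (1 + e) / 2; sw <- (1 - e) / 2
    l0 <- L[ch, 1L]; l1 <- L[ch, 2L]
    if (!is.na(clamp_node) && ch == clamp_node) {
      if (clamp_state == 0L) l1 <- 0 else l0 <- 0
    }
    if (scale) {
      s <- l0 + l1
      if (s <= 0) return(-Inf)
      l0 <- l0 / s; l1 <- l1 / s
      logscale <- logscale + log(s)
    }
    L[p, 1L] <- L[p, 1L] * (stay * l0 + sw * l1)
    L[p, 2L] <- L[p, 2L] * (sw * l0 + stay * l1)
  }
  r <- prep$root
  l0 <- L[r, 1L]; l1 <- L[r, 2L]
  if (!is.na(clamp_node) && r == clamp_node) {
    if (clamp_state == 0L) l1 <- 0 else l0 <- 0
  }
  tot <- pi[1] * l0 + pi[2] * l1
  if (tot <= 0) -Inf else log(tot) + logscale
}

# ---- public likelihood surface --------------------------------------------

#' Log-likelihood of a binary character on a tree under Mk1
#'
#' Computes the Felsenstein pruning likelihood: a post-order pass propagates
#' per-state conditional likelihoods from the tips to the root, where they
#' are combined with the root prior. Per-node rescaling keeps the computation
#' stable on large trees and/or high rates. Missing tip states (`?`/`NA`)
#' contribute the uninformative conditional likelihood (1, 1).
#' Multifurcations are handled natively by the product over all children.
#'
#' @param tree A `phylo` object; branch lengths must be present (use
#'   [set_unit_branch_lengths()] for the punctuational convention).
#' @param tip_states Named vector (by tip label) of states 0/1/`NA` (or
#'   `"0"/"1"/"?"`); every tip must be present.
#' @param model An [mk_model()] object, or a single rate `q >= 0`.
#' @param pi Root prior (absent, present); default flat.
#' @param scale Use per-node rescaling (default `TRUE`; `FALSE` exposed for
#'   numerical comparison only).
#' @return The log-likelihood; `-Inf` if the data have probability zero
#'   (e.g. mixed tip states with `q = 0`).
#' @examples
#' tr <- set_unit_branch_lengths(parse_newick("((A,B),(C,D));"))
#' x <- c(A = 1, B = 1, C = 0, D = 0)
#' tree_log_likelihood(tr, x, 0.3)
#' @export
tree_log_likelihood <- function(tree, tip_states, model, pi = c(0.5, 0.5),
                                scale = TRUE) {
  q <- if (inherits(model, "mk_model")) model$q else model
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("'model' must be an mk_model or a non-negative rate")
  prep <- .mk_prep(tree)
  tipL <- .mk_tip_matrix(prep, tip_states)
  .mk_loglik(prep, tipL, q, pi = pi, scale = scale)
}

#' Brute-force Mk1 likelihood by exhaustive enumeration
#'
#' Reference implementation used to validate the pruning algorithm: sums,
#' over every assignment of states to the internal nodes (and to tips with
#' missing states), the product of the root prior and the per-edge
#' transition probabilities. Exponential in the number of internal nodes;
#' only usable on small trees.
#'
#' @inheritParams tree_log_likelihood
#' @param q Transition rate.
#' @return The log-likelihood.
#' @export
tree_log_likelihood_bruteforce <- function(tree, tip_states, q,
                                           pi = c(0.5, 0.5)) {
  prep <- .mk_prep(tree)
  tipL <- .mk_tip_matrix(prep, tip_states)
  n <- prep$ntip
  N <- n + prep$nnode
  # nodes whose state must be enumerated: internals + unknown-state tips
  known_tip <- rep(FALSE, N)
  state_fixed <- rep(NA_integer_, N)
  for (i in seq_len(n)) {
    if (tipL[i, 1] == 1 && tipL[i, 2] == 0) { known_tip[i] <- TRUE; state_fixed[i] <- 0L }
    if (tipL[i, 1] == 0 && tipL[i, 2] == 1) { known_tip[i] <- TRUE; state_fixed[i] <- 1L }
  }
  free <- c(which(!known_tip[seq_len(n)]), (n + 1L):N)
  if (length(free) > 20L)
    stop("enumeration over ", length(free), " free nodes is not tractable")
  P <- lapply(seq_len(nrow(prep$edge)),
              function(i) transition_matrix(q, prep$elen[i]))
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  for (g in seq_len(nrow(grid))) {
    st <- state_fixed
    st[free] <- grid[g, ]
    prob <- pi[st[prep$root] + 1L]
    for (i in seq_len(nrow(prep$edge))) {
      prob <- prob * P[[i]][st[prep$edge[i, 1L]] + 1L, st[prep$edge[i, 2L]] + 1L]
      if (prob == 0) break
    }
    total <- total + prob
  }
  if (total <= 0) -Inf else log(total)
}

#' Maximum-likelihood estimate of the Mk1 rate
#'
#' Fits the single symmetric rate `q` by bounded one-dimensional
#' optimization of the pruning log-likelihood over `log(q)`. The profile is
#' unimodal in practice, so a deterministic golden-section/parabolic search
#' suffices. Monomorphic characters drive the estimate to the lower bound
#' (the likelihood is monotone decreasing in `q`); boundary solutions are
#' flagged.
#'
#' @inheritParams tree_log_likelihood
#' @param q_bounds Search interval for `q` (default `c(1e-8, 1e3)`).
#' @param tol Convergence tolerance on `log(q)`.
#' @return An [mk_model()] with the fitted `q`, its log-likelihood, and a
#'   `boundary` flag.
#' @export
estimate_rate <- function(tree, tip_states, q_bounds = c(1e-8, 1e3),
                          tol = 1e-9, pi = c(0.5, 0.5)) {
  if (length(q_bounds) != 2L || any(q_bounds <= 0) || q_bounds[1] >= q_bounds[2])
    stop("'q_bounds' must be positive and increasing")
  prep <- .mk_prep(tree)
  tipL <- .mk_tip_matrix(prep, tip_states)
  nll <- function(lq) -.mk_loglik(prep, tipL, exp(lq), pi = pi)
  opt <- stats::optimize(nll, interval = log(q_bounds), tol = tol)
  if (!is.finite(opt$objective))
    stop("rate optimization failed to find a finite likelihood; last q = ",
         format(exp(opt$minimum)))
  # compare against the bounds: optimize() never evaluates the endpoints
  cand_lq <- c(opt$minimum, log(q_bounds))
  cand_obj <- c(opt$objective, nll(log(q_bounds[1])), nll(log(q_bounds[2])))
  best <- which.min(cand_obj)
  q_hat <- exp(cand_lq[best])
  at_bound <- best > 1L ||
    q_hat <= q_bounds[1] * (1 + 1e-6) || q_hat >= q_bounds[2] * (1 - 1e-6)
  mk_model(q = q_hat, logL = -cand_obj[best], bounds = q_bounds,
           boundary = at_bound, pi = pi)
}

# ---- marginal (proportional-likelihood) reconstruction ---------------------

#' Marginal ancestral state proportions at every internal node
#'
#' For each internal node and each state, computes the likelihood of the
#' full data with that node clamped to the state (at the fixed, already
#' fitted rate -- `q` is not re-optimized per node), then normalizes the two
#' values to sum to one. These are the "proportional likelihoods" that
#' Mesquite-style trace-character reports show as node pies. The
#' implementation is a single up-down (outside-inside) pass: an upward
#' pruning pass collects each node's inside likelihoods, a downward pass
#' propagates the outside likelihoods, and their product at a node gives the
#' clamped likelihoods up to a node-constant factor that cancels in the
#' normalization. [marginal_node_proportions_clamp()] is the direct
#' clamp-and-renormalize reference the pass is validated against.
#'
#' @inheritParams tree_log_likelihood
#' @param model An [mk_model()] (typically from [estimate_rate()]) or a rate.
#' @return An object of class `asr_table`: a data frame with one row per
#'   internal node (`node`, `p_absent`, `p_present`), with the tree, tip
#'   states, rate and log-likelihood attached as attributes.
#' @export
marginal_node_proportions <- function(tree, tip_states, model,
                                      pi = c(0.5, 0.5)) {
  q <- if (inherits(model, "mk_model")) model$q else model
  if (inherits(model, "mk_model")) pi <- model$pi
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("'model' must be an mk_model or a non-negative rate")
  prep <- .mk_prep(tree)
  tipL <- .mk_tip_matrix(prep, tip_states)
  edge <- prep$edge; elen <- prep$elen
  n <- prep$ntip; N <- n + prep$nnode
  nE <- nrow(edge)

  # upward pass: scaled inside likelihoods D and per-edge messages M
  D <- tipL
  M <- matrix(NA_real_, nE, 2) # M[i, s_parent] = sum_s P(s_parent, s) D[child, s]
  logl <- 0
  for (i in seq_len(nE)) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    e <- exp(-2 * q * elen[i]); stay <- (1 + e) / 2; sw <- (1 - e) / 2
    l0 <- D[ch, 1L]; l1 <- D[ch, 2L]
    s <- l0 + l1
    if (s <= 0)
      stop("data have zero probability under this model (q = ", format(q), ")")
    l0 <- l0 / s; l1 <- l1 / s
    D[ch, 1L] <- l0; D[ch, 2L] <- l1
    logl <- logl + log(s)
    M[i, 1L] <- stay * l0 + sw * l1
    M[i, 2L] <- sw * l0 + stay * l1
    D[p, 1L] <- D[p, 1L] * M[i, 1L]
    D[p, 2L] <- D[p, 2L] * M[i, 2L]
  }
  tot <- pi[1] * D[prep$root, 1L] + pi[2] * D[prep$root, 2L]
  if (tot <= 0)
    stop("data have zero probability under this model (q = ", format(q), ")")
  loglik <- log(tot) + logl

  # downward pass: outside likelihoods U, edges visited parent-first
  children_edges <- split(seq_len(nE), edge[, 1L])
  U <- matrix(NA_real_, N, 2)
  U[prep$root, ] <- pi
  for (i in rev(seq_len(nE))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    e <- exp(-2 * q * elen[i]); stay <- (1 + e) / 2; sw <- (1 - e) / 2
    W <- numeric(2)
    for (sp in 1:2) {
      sib <- if (M[i, sp] > 0) D[p, sp] / M[i, sp] else {
        others <- setdiff(children_edges[[as.character(p)]], i)
        if (length(others)) prod(M[others, sp]) else 1
      }
      W[sp] <- U[p, sp] * sib
    }
    u0 <- stay * W[1] + sw * W[2]
    u1 <- sw * W[1] + stay * W[2]
    s <- u0 + u1
    if (s > 0) { u0 <- u0 / s; u1 <- u1 / s }
    U[ch, ] <- c(u0, u1)
  }

  internal <- (n + 1L):N
  raw <- U[internal, , drop = FALSE] * D[internal, , drop = FALSE]
  props <- raw / rowSums(raw)
  out <- data.frame(node = internal,
                    p_absent = props[, 1], p_present = props[, 2])
  structure(out,
            tree = prep$tree, tip_states = tip_states, q = q, pi = pi,
            logL = loglik, class = c("asr_table", "data.frame"))
}

#' Marginal proportions by direct clamping (reference implementation)
#'
#' Computes, for every internal node, two full pruning likelihoods with the
#' node clamped to each state in turn, and renormalizes. This is the
#' defining computation of the marginal (proportional-likelihood)
#' reconstruction; it is quadratic in tree size and serves as the oracle for
#' the up-down pass in [marginal_node_proportions()].
#'
#' @inheritParams tree_log_likelihood
#' @param q Transition rate (fixed; not re-optimized per node).
#' @return An `asr_table`, as in [marginal_node_proportions()].
#' @export
marginal_node_proportions_clamp <- function(tree, tip_states, q,
                                            pi = c(0.5, 0.5)) {
  if (inherits(q, "mk_model")) { pi <- q$pi; q <- q$q }
  prep <- .mk_prep(tree)
  tipL <- .mk_tip_matrix(prep, tip_states)
  n <- prep$ntip
  internal <- (n + 1L):(n + prep$nnode)
  loglik <- .mk_loglik(prep, tipL, q, pi = pi)
  props <- t(vapply(internal, function(v) {
    l0 <- .mk_loglik(prep, tipL, q, pi = pi, clamp_node = v, clamp_state = 0L)
    l1 <- .mk_loglik(prep, tipL, q, pi = pi, clamp_node = v, clamp_state = 1L)
    m <- max(l0, l1)
    w <- exp(c(l0, l1) - m)
    w / sum(w)
  }, numeric(2)))
  out <- data.frame(node = internal,
                    p_absent = props[, 1], p_present = props[, 2])
  structure(out,
            tree = prep$tree, tip_states = tip_states, q = q, pi = pi,
            logL = loglik, class = c("asr_table", "data.frame"))
}

#' @export
print.asr_table <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Marginal ancestral state proportions (Mk1, q = %.6g, logL = %.4f)\n",
    attr(x, "q"), attr(x, "logL")))
  y <- as.data.frame(x)
  y$p_absent <- round(y$p_absent, digits)
  y$p_present <- round(y$p_present, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Branches whose child node supports presence above a threshold
#'
#' Reproduces the branch-painting rule used for trait maps: a branch is
#' painted when the marginal "present" proportion at its child node strictly
#' exceeds the threshold; a node at exactly the threshold is ambiguous and
#' not painted. Terminal branches are painted by the observed tip state
#' (missing states are not painted).
#'
#' @param asr An `asr_table` from [marginal_node_proportions()].
#' @param threshold Proportion in (0, 1); default 0.5.
#' @return Sorted integer vector of child node ids of the painted branches.
#' @export
paint_branches <- function(asr, threshold = 0.5) {
  if (!inherits(asr, "asr_table")) stop("'asr' must be an asr_table")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)")
  tree <- attr(asr, "tree")
  tip_states <- attr(asr, "tip_states")
  n <- ape::Ntip(tree)
  x <- tip_states[tree$tip.label]
  if (is.character(x)) { x[x == "?"] <- NA; x <- suppressWarnings(as.integer(x)) }
  painted_tips <- which(!is.na(x) & x == 1)
  pp <- asr$p_present[match(tree$edge[, 2L], asr$node)]
  internal_children <- tree$edge[, 2L][!is.na(pp) & pp > threshold]
  sort(unique(c(painted_tips, internal_children)))
}

# ---- clade-level report -----------------------------------------------------

#' Clade-level report of ancestral presence likelihoods
#'
#' For each character (column of the binary matrix): fits the Mk1 rate by
#' maximum likelihood, runs the marginal reconstruction at that rate, and
#' reports the percent likelihood of "present" at the MRCA of each named
#' clade. Cells strictly greater than `100 * threshold` are flagged as
#' "likely present" (the bold-cell convention of published clade tables).
#'
#' @param tree Rooted `phylo`; tip set must equal the matrix's species set.
#' @param matrix Binary character matrix: rows = species (rownames), columns
#'   = characters, cells 0/1/`NA` (see [character_matrix()]).
#' @param clades Named list of [clade_definition()]s or of tip-label vectors.
#' @param threshold Likelihood threshold, default 0.5 (strict).
#' @param q_bounds,pi Passed to [estimate_rate()].
#' @return A `clade_report`: numeric matrix (characters x clades) of
#'   unrounded percentages, with attributes `flags` (strict threshold
#'   exceedance), `clade_sizes` (tip counts, measuring inclusiveness),
#'   `models` (per-character fit summaries) and `threshold`.
#' @export
clade_report <- function(tree, matrix, clades, threshold = 0.5,
                         q_bounds = c(1e-8, 1e3), pi = c(0.5, 0.5)) {
  validate_tree(tree)
  mat <- validate_character_matrix(matrix)
  extra <- setdiff(rownames(mat), tree$tip.label)
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(extra) || length(missing))
    stop("species/tip mismatch; ",
         if (length(extra)) paste0("matrix species not in tree: ",
                                   paste(extra, collapse = ", "), "; ") else "",
         if (length(missing)) paste0("tree tips not in matrix: ",
                                     paste(missing, collapse = ", ")) else "")
  tipsets <- .resolve_clades(tree, clades)
  nodes <- vapply(tipsets, function(tp) mrca_node(tree, tp), integer(1))
  sizes <- vapply(tipsets, length, integer(1))
  chars <- colnames(mat)
  cells <- matrix(NA_real_, length(chars), length(tipsets),
                  dimnames = list(chars, names(tipsets)))
  models <- vector("list", length(chars)); names(models) <- chars
  ntip <- ape::Ntip(tree)
  for (j in seq_along(chars)) {
    states <- stats::setNames(mat[, j], rownames(mat))
    fit <- estimate_rate(tree, states, q_bounds = q_bounds, pi = pi)
    asr <- marginal_node_proportions(tree, states, fit)
    for (k in seq_along(nodes)) {
      nd <- nodes[k]
      cells[j, k] <- if (nd <= ntip) {
        100 * as.numeric(!is.na(states[tree$tip.label[nd]]) &&
                           states[tree$tip.label[nd]] == 1)
      } else {
        100 * asr$p_present[asr$node == nd]
      }
    }
    models[[j]] <- list(q = fit$q, logL = fit$logL, boundary = fit$boundary)
  }
  structure(cells,
            flags = cells > 100 * threshold,
            clade_sizes = sizes, models = models, threshold = threshold,
            class = c("clade_report", "matrix"))
}

#' Build a clade report from an externally supplied percentage table
#'
#' Wraps a precomputed characters-by-clades percentage matrix (e.g. a
#' published table) so that downstream summaries such as
#' [summarize_origins()] can be applied to it. Clade inclusiveness must be
#' supplied as tip counts since no tree is attached.
#'
#' @param cells Numeric matrix, rows = characters, columns = clades,
#'   values in `[0, 100]`.
#' @param clade_sizes Named integer vector of clade tip counts (names must
#'   match `colnames(cells)`).
#' @param threshold Likelihood threshold, default 0.5.
#' @return A `clade_report`.
#' @export
as_clade_report <- function(cells, clade_sizes, threshold = 0.5) {
  cells <- as.matrix(cells)
  if (is.null(rownames(cells)) || is.null(colnames(cells)))
    stop("'cells' needs row (character) and column (clade) names")
  if (any(!is.na(cells) & (cells < 0 | cells > 100)))
    stop("'cells' must be percentages in [0, 100]")
  if (is.null(names(clade_sizes)) ||
      !setequal(names(clade_sizes), colnames(cells)))
    stop("'clade_sizes' must be named by the clades of 'cells'")
  structure(cells,
            flags = cells > 100 * threshold,
            clade_sizes = clade_sizes[colnames(cells)],
            models = NULL, threshold = threshold,
            class = c("clade_report", "matrix"))
}

#' Half-up decimal rounding
#'
#' Rounding convention of the printed report tables (`round()` in R rounds
#' half to even, which would disagree with them on exact .x5 values).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.clade_report <- function(x, ...) {
  cat("Clade-level likelihood (%) of ancestral presence; '*' marks cells >",
      100 * attr(x, "threshold"), "%\n")
  cells <- unclass(x)
  attributes(cells) <- attributes(cells)[c("dim", "dimnames")]
  txt <- matrix(sprintf("%.1f%s", round_half_up(cells, 1),
                        ifelse(attr(x, "flags"), "*", "")),
                nrow(cells), ncol(cells), dimnames = dimnames(cells))
  print(txt, quote = FALSE)
  invisible(x)
}

#' Write a clade report as TSV
#'
#' Percentages are written rounded half-up to one decimal, with a parallel
#' logical flag column per clade marking strict threshold exceedance.
#'
#' @param report A `clade_report`.
#' @param path Output file.
#' @export
write_clade_report <- function(report, path) {
  if (!inherits(report, "clade_report")) stop("not a clade_report")
  cells <- round_half_up(unclass(report), 1)
  attributes(cells) <- attributes(cells)[c("dim", "dimnames")]
  flags <- attr(report, "flags")
  df <- data.frame(character = rownames(cells), check.names = FALSE)
  for (cl in colnames(cells)) {
    df[[cl]] <- sprintf("%.1f", cells[, cl])
    df[[paste0(cl, "_likely")]] <- flags[, cl]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-character annotated Newick
#'
#' Node labels carry the marginal "present" proportion (3 decimals), the
#' input format used for pie-chart style trait maps.
#'
#' @param asr An `asr_table`.
#' @param path Optional output file.
#' @return The Newick string.
#' @export
write_annotated_newick <- function(asr, path = NULL) {
  if (!inherits(asr, "asr_table")) stop("'asr' must be an asr_table")
  tree <- attr(asr, "tree")
  n <- ape::Ntip(tree)
  labs <- rep("", tree$Nnode)
  labs[asr$node - n] <- sprintf("%.3f", asr$p_present)
  tree$node.label <- labs
  write_newick(tree, path)
}
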