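## ---------------------------------------------------------------------------
## Felsenstein pruning engine (any state count), vectorized across columns.
## Partials are rescaled per column with log accumulators so that 75-taxon
## alignments do not underflow.
## ---------------------------------------------------------------------------

## tree_po: phylo in postorder; Pedges: list of P(t) per edge (postorder index);
## leafmat: list over leaf numbers of (nstate x ncol) indicator matrices.
## Returns column log-likelihoods and, optionally, normalized marginal
## posteriors at every internal node.
peel_engine <- function(tree_po, Pedges, pi, leafmat, posteriors = FALSE) {
  edge <- tree_po$edge
  ntip <- length(tree_po$tip.label)
  ntot <- ntip + tree_po$Nnode
  root <- ntip + 1L
  ncolm <- ncol(leafmat[[1]])
  nst <- length(pi)

  L <- vector("list", ntot)
  logs <- matrix(0, ntot, ncolm)
  msgs <- vector("list", nrow(edge))

  for (e in seq_len(nrow(edge))) {            # postorder: child done first
    p <- edge[e, 1]; ch <- edge[e, 2]
    Lc <- if (ch <= ntip) leafmat[[ch]] else L[[ch]]
    msg <- Pedges[[e]] %*% Lc
    msgs[[e]] <- msg
    L[[p]] <- if (is.null(L[[p]])) msg else L[[p]] * msg
    if (ch > ntip) logs[p, ] <- logs[p, ] + logs[ch, ]
    cm <- apply(L[[p]], 2, max)
    ok <- cm > 0
    sc <- ifelse(ok, cm, 1)
    L[[p]] <- sweep(L[[p]], 2, sc, "/")
    logs[p, ] <- logs[p, ] + ifelse(ok, log(sc), -Inf)
  }

  col_loglik <- log(colSums(pi * L[[root]])) + logs[root, ]

  out <- list(col_loglik = col_loglik, loglik = sum(col_loglik))
  if (posteriors) {
    out_edges <- vector("list", ntot)
    for (e in seq_len(nrow(edge)))
      out_edges[[edge[e, 1]]] <- c(out_edges[[edge[e, 1]]], e)
    D <- vector("list", ntot)
    D[[root]] <- matrix(pi, nst, ncolm)
    for (e in rev(seq_len(nrow(edge)))) {     # preorder
      p <- edge[e, 1]; ch <- edge[e, 2]
      if (ch <= ntip) next
      sib <- D[[p]]
      for (s in out_edges[[p]]) if (s != e) sib <- sib * msgs[[s]]
      Dc <- crossprod(Pedges[[e]], sib)
      cm <- apply(Dc, 2, max)
      D[[ch]] <- sweep(Dc, 2, ifelse(cm > 0, cm, 1), "/")
    }
    post <- vector("list", ntot)
    for (v in (ntip + 1L):ntot) {
      u <- L[[v]] * D[[v]]
      post[[v]] <- sweep(u, 2, colSums(u), "/")
    }
    out$posteriors <- post
  }
  out
}

## Precompute per-edge transition matrices for a (possibly rate-scaled) tree.
edge_transitions <- function(tree_po, model, rate = 1) {
  lens <- tree_po$edge.length * rate
  lapply(lens, function(t) transition_matrix(model, t))
}

## Build per-leaf indicator matrices for the alignment columns.
leaf_indicators <- function(tree_po, alignment, nst = 20) {
  m <- as.matrix(alignment)
  ord <- match(tree_po$tip.label, alignment$names)
  lapply(seq_along(tree_po$tip.label), function(i) {
    sets <- aa_state_sets(m[ord[i], ])
    ind <- matrix(0, nst, alignment$ncol)
    for (j in seq_along(sets)) ind[sets[[j]], j] <- 1
    ind
  })
}

check_tree_alignment <- function(tree, alignment) {
  miss <- setdiff(tree$tip.label, alignment$names)
  if (length(miss))
    stop("leaves missing from alignment: ", paste(miss, collapse = ", "))
}

#' Log-likelihood of a single alignment column
#'
#' Felsenstein pruning over a rooted tree: gaps and ambiguity codes
#' contribute all-ones (or subset) partials, the root is closed with the
#' model's equilibrium frequencies, and multifurcations multiply three or
#' more child messages.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param model A `substitution_model`.
#' @param column Named character vector: one residue (or `-`/`B`/`Z`/`X`) per
#'   leaf label.
#' @return The column log-likelihood.
#' @export
column_likelihood <- function(tree, model, column) {
  tree <- validate_tree(tree)
  miss <- setdiff(tree$tip.label, names(column))
  if (length(miss)) stop("leaf missing from column: ", paste(miss, collapse = ", "))
  aln <- protein_alignment(vapply(column[tree$tip.label], identity, ""))
  alignment_loglik(tree, model, aln)$loglik
}

#' Log-likelihood of a whole alignment
#'
#' @inheritParams column_likelihood
#' @param alignment A [protein_alignment()] whose names cover the tree leaves.
#' @param gamma Optional `list(k =, alpha =)` discrete-gamma rate variation;
#'   default is rate-homogeneous.
#' @return List with `loglik` and per-column `col_loglik`.
#' @export
alignment_loglik <- function(tree, model, alignment, gamma = NULL) {
  tree <- validate_tree(tree)
  check_tree_alignment(tree, alignment)
  po <- stats::reorder(tree, "postorder")
  leafmat <- leaf_indicators(po, alignment)
  rates <- if (is.null(gamma)) 1 else discrete_gamma_rates(gamma$alpha, gamma$k)
  per_rate <- lapply(rates, function(r)
    peel_engine(po, edge_transitions(po, model, r), model$pi, leafmat)$col_loglik)
  ll <- log_mean_exp_rows(do.call(rbind, per_rate))
  list(loglik = sum(ll), col_loglik = ll)
}

## log of the column-wise mean of exp(rows), stable
log_mean_exp_rows <- function(m) {
  mx <- apply(m, 2, max)
  out <- mx + log(colMeans(exp(sweep(m, 2, mx, "-"))))
  out[mx == -Inf] <- -Inf      # impossible column under every rate class
  out
}

#' Marginal ancestral residue posteriors at an internal node
#'
#' Up-down (inside-outside) algorithm: the posterior for state x at a node is
#' proportional to the product of the inside messages from all subtrees
#' around the node, weighted by the equilibrium frequencies at the root.
#'
#' @inheritParams alignment_loglik
#' @param node `"root"`, or an internal node number (ape numbering).
#' @return Matrix `ncol x 20` of per-column residue posteriors (rows sum
#'   to 1).
#' @export
marginal_posterior <- function(tree, model, alignment, node = "root",
                               gamma = NULL) {
  rec <- asr(alignment, tree, model, gamma = gamma, indels = FALSE)
  node <- resolve_node(tree, node)
  rec$residue_posterior[[as.character(node)]]
}

resolve_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (identical(node, "root")) return(ntip + 1L)
  node <- as.integer(node)
  if (node <= ntip) stop("node ", node, " is a leaf: leaves are observed")
  if (node > ntip + tree$Nnode) stop("no such node: ", node)
  node
}

## ---------------------------------------------------------------------------
## Indel (presence/absence) characters
## ---------------------------------------------------------------------------

#' Indel characters from the gap structure of an alignment
#'
#' Columns are grouped into maximal runs of consecutive columns sharing an
#' identical leaf gap pattern; each block is one binary (absent/present)
#' character.
#'
#' @param alignment A [protein_alignment()].
#' @return An object of class `indel_characters`: `columns` (block id per
#'   column) and `states` (blocks x leaves logical matrix, `TRUE` = present).
#' @export
indel_blocks <- function(alignment) {
  m <- as.matrix(alignment)
  present <- m != "-"
  pat <- apply(present, 2, paste, collapse = "")
  r <- rle(pat)
  block_of <- rep(seq_along(r$lengths), r$lengths)
  first_col <- cumsum(c(1L, utils::head(r$lengths, -1L)))
  states <- t(present[, first_col, drop = FALSE])
  rownames(states) <- NULL
  if (any(rowSums(states) == 0))
    stop("alignment has an all-gap column block")
  structure(list(columns = block_of, states = states,
                 leaves = alignment$names),
            class = "indel_characters")
}

#' Maximum-likelihood indel reconstruction
#'
#' Each gap block is a binary character under a two-state reversible CTMC
#' whose stationary frequencies are estimated from the observed leaf states
#' (with pseudocounts) and whose single exchange-rate parameter is optimized
#' by maximum likelihood across all blocks. Marginal presence posteriors at
#' every internal node come from the same up-down machinery on two states.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param indels An `indel_characters` object from [indel_blocks()].
#' @param rate Optional fixed exchange rate; default optimizes by ML.
#' @param pseudocount Added to both state counts for the stationary
#'   frequencies.
#' @return List: `rate`, `pi` (absent, present), `loglik`, and
#'   `presence` — a list over internal nodes of per-block presence
#'   posteriors (and `presence_by_column` matrices mapped back to columns).
#' @export
reconstruct_indels <- function(tree, indels, rate = NULL, pseudocount = 0.5) {
  tree <- validate_tree(tree)
  miss <- setdiff(tree$tip.label, indels$leaves)
  if (length(miss)) stop("leaves missing from indel characters: ",
                         paste(miss, collapse = ", "))
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nblock <- nrow(indels$states)
  ord <- match(po$tip.label, indels$leaves)

  n_present <- sum(indels$states) + pseudocount
  n_absent <- sum(!indels$states) + pseudocount
  pi2 <- c(absent = n_absent, present = n_present) / (n_absent + n_present)

  leafmat <- lapply(seq_len(ntip), function(i) {
    ind <- matrix(0, 2, nblock)
    st <- indels$states[, ord[i]]
    ind[1, !st] <- 1
    ind[2, st] <- 1
    ind
  })

  P2 <- function(r) {
    lapply(po$edge.length, function(t) {
      e <- exp(-r * t)
      PI <- matrix(pi2, 2, 2, byrow = TRUE)
      PI + e * (diag(2) - PI)
    })
  }
  negll <- function(logr) -peel_engine(po, P2(exp(logr)), pi2, leafmat)$loglik
  if (is.null(rate)) {
    opt <- stats::optimize(negll, interval = log(c(1e-4, 1e3)))
    rate <- exp(opt$minimum)
  }
  fit <- peel_engine(po, P2(rate), pi2, leafmat, posteriors = TRUE)
  presence <- lapply(fit$posteriors, function(p) if (!is.null(p)) p[2, ])
  presence_by_column <- lapply(presence, function(p)
    if (!is.null(p)) p[indels$columns])
  list(rate = rate, pi = pi2, loglik = fit$loglik,
       presence = presence, presence_by_column = presence_by_column)
}

## ---------------------------------------------------------------------------
## Full reconstruction object + sequence extraction
## ---------------------------------------------------------------------------

#' Maximum-likelihood marginal ancestral sequence reconstruction
#'
#' Runs the residue-level pruning/posterior machinery and, separately, the
#' binary indel reconstruction (gaps are missing data for residues;
#' presence/absence is modelled per gap block). Branch lengths are taken
#' from the input tree as fixed.
#'
#' @param alignment A [protein_alignment()].
#' @param tree Rooted `phylo`; leaf labels must occur in the alignment.
#' @param model A `substitution_model` (default WAG).
#' @param gamma Optional `list(k =, alpha =)` discrete-gamma rate variation.
#' @param indels If `FALSE`, skip indel reconstruction (all positions
#'   treated as present).
#' @return An object of class `ancestral_reconstruction`: `loglik`,
#'   `residue_posterior` (list over internal nodes of `ncol x 20` matrices),
#'   `presence_posterior` (per node, per column), `nodes`, `tree`, `model`.
#' @examples
#' sim <- evolve_alignment(sim_config(seed = 1, n_leaves = 8, length = 60))
#' rec <- asr(sim$alignment, sim$tree)
#' substr(ancestral_sequence(rec), 1, 20)
#' @export
asr <- function(alignment, tree, model = build_wag(), gamma = NULL,
                indels = TRUE) {
  tree <- validate_tree(tree)
  check_tree_alignment(tree, alignment)
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nodes <- (ntip + 1L):(ntip + po$Nnode)
  leafmat <- leaf_indicators(po, alignment)
  rates <- if (is.null(gamma)) 1 else discrete_gamma_rates(gamma$alpha, gamma$k)

  fits <- lapply(rates, function(r)
    peel_engine(po, edge_transitions(po, model, r), model$pi, leafmat,
                posteriors = TRUE))
  cl <- do.call(rbind, lapply(fits, `[[`, "col_loglik"))
  col_ll <- log_mean_exp_rows(cl)
  ## mixture posterior: weight each class by its column likelihood
  w <- exp(sweep(cl, 2, apply(cl, 2, max), "-"))
  w <- sweep(w, 2, colSums(w), "/")
  residue_posterior <- stats::setNames(lapply(nodes, function(v) {
    acc <- 0
    for (k in seq_along(fits))
      acc <- acc + sweep(fits[[k]]$posteriors[[v]], 2, w[k, ], "*")
    t(acc)            # ncol x 20
  }), nodes)
  for (v in seq_along(residue_posterior))
    colnames(residue_posterior[[v]]) <- model$states

  presence_posterior <- NULL
  indel_fit <- NULL
  if (indels && any(as.matrix(alignment) == "-")) {
    indel_fit <- reconstruct_indels(po, indel_blocks(alignment))
    presence_posterior <- stats::setNames(
      indel_fit$presence_by_column[nodes], nodes)
  } else {
    presence_posterior <- stats::setNames(
      rep(list(rep(1, alignment$ncol)), length(nodes)), nodes)
  }

  structure(list(loglik = sum(col_ll), col_loglik = col_ll,
                 residue_posterior = residue_posterior,
                 presence_posterior = presence_posterior,
                 indel_fit = indel_fit, nodes = nodes,
                 tree = po, model = model),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("ancestral_reconstruction: %d internal nodes, %d columns, log L = %.3f\n",
              length(x$nodes), length(x$col_loglik), x$loglik))
  invisible(x)
}

#' Extract the maximum-posterior ancestral sequence at a node
#'
#' Per retained column the argmax-posterior residue is taken; columns whose
#' presence posterior falls below `presence_threshold` are dropped. Exact
#' posterior ties are broken by higher equilibrium frequency, then
#' alphabetically.
#'
#' @param recon An `ancestral_reconstruction` from [asr()].
#' @param node `"root"` or an internal node number.
#' @param presence_threshold Minimum presence posterior for a column to be
#'   emitted (default 0.5).
#' @return A protein sequence string.
#' @export
ancestral_sequence <- function(recon, node = "root", presence_threshold = 0.5) {
  node <- resolve_node(recon$tree, node)
  key <- as.character(node)
  post <- recon$residue_posterior[[key]]
  pres <- recon$presence_posterior[[key]]
  keep <- pres >= presence_threshold
  pi <- recon$model$pi
  ## tie-break ordering: posterior desc, equilibrium frequency desc, alpha
  pick <- apply(post[keep, , drop = FALSE], 1, function(p) {
    top <- which(p >= max(p) - 1e-12)
    if (length(top) > 1) {
      top <- top[pi[top] >= max(pi[top]) - 1e-15]
      top <- top[order(recon$model$states[top])]
    }
    top[1]
  })
  paste(recon$model$states[pick], collapse = "")
}

#' Per-column posterior audit table
#'
#' @param recon An `ancestral_reconstruction`.
#' @param node `"root"` or an internal node number.
#' @return A data.frame: column, best residue, its posterior, presence
#'   posterior.
#' @export
posterior_table <- function(recon, node = "root") {
  node <- as.character(resolve_node(recon$tree, node))
  post <- recon$residue_posterior[[node]]
  best <- max.col(post, ties.method = "first")
  data.frame(column = seq_len(nrow(post)),
             residue = recon$model$states[best],
             posterior = post[cbind(seq_len(nrow(post)), best)],
             presence = recon$presence_posterior[[node]])
}

#' Resolve a polytomy with zero-length branches
#'
#' Splits the children of a multifurcating node: the children whose leaf sets
#' exactly tile `group` are re-attached under a new internal node joined to
#' the polytomy by a zero-length branch, which leaves the likelihood
#' unchanged.
#'
#' @param tree Rooted `phylo`.
#' @param node Internal node number of the multifurcation.
#' @param group Character vector of leaf labels spanned by the children to
#'   pull out (at least two children, not all of them).
#' @return A `phylo` with the polytomy (partially) resolved.
#' @export
resolve_polytomy <- function(tree, node, group) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  node <- resolve_node(tree, node)
  kid_edges <- which(tree$edge[, 1] == node)
  if (length(kid_edges) < 3) stop("node ", node, " is not a multifurcation")
  leafset <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    ape::extract.clade(tree, v)$tip.label
  }
  sets <- lapply(tree$edge[kid_edges, 2], leafset)
  inside <- vapply(sets, function(s) all(s %in% group), TRUE)
  straddle <- vapply(sets, function(s) any(s %in% group), TRUE) & !inside
  if (any(straddle) || !setequal(unlist(sets[inside]), group))
    stop("guide group does not tile a subset of the node's children")
  if (sum(inside) < 2) stop("guide must cover at least two children")
  if (all(inside)) stop("guide covers all children: nothing to resolve")

  newnode <- ntip + tree$Nnode + 1L
  tree$edge[kid_edges[inside], 1] <- newnode
  tree$edge <- rbind(tree$edge, c(node, newnode))
  tree$edge.length <- c(tree$edge.length, 0)
  tree$Nnode <- tree$Nnode + 1L
  ## canonicalize ape's internal numbering
  ape::read.tree(text = ape::write.tree(tree))
}
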