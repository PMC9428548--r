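## Independent oracles and fixture builders. Everything here is deliberately
## naive (exhaustive enumeration, direct path sums) and shares no code with
## the package's pruning engine.

ORACLE_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## residue char -> state-index set, oracle-side mapping
oracle_state_set <- function(ch, nst = 20) {
  if (ch == "-" || ch == "X") return(seq_len(nst))
  if (ch == "B") return(match(c("N", "D"), ORACLE_AA))
  if (ch == "Z") return(match(c("Q", "E"), ORACLE_AA))
  i <- match(ch, ORACLE_AA)
  stopifnot(!is.na(i))
  i
}

## Exhaustive sum over all internal-state assignments.
## leaf_sets: list indexed by tip label of state-index vectors.
## P_edges: list of transition matrices aligned with tree$edge rows.
enum_likelihood <- function(tree, P_edges, pi, leaf_sets, posterior_node = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nst <- length(pi)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nst)), nnode)))
  val <- pi[grid[, 1]]                      # root is node ntip+1 -> column 1
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    gp <- grid[, p - ntip]
    if (ch > ntip) {
      val <- val * P_edges[[e]][cbind(gp, grid[, ch - ntip])]
    } else {
      set <- leaf_sets[[tree$tip.label[ch]]]
      if (length(set) == nst) next          # uninformative leaf
      val <- val * rowSums(P_edges[[e]][gp, set, drop = FALSE])
    }
  }
  if (is.null(posterior_node)) return(log(sum(val)))
  marg <- tapply(val, grid[, posterior_node - ntip], sum)
  post <- rep(0, nst)
  post[as.integer(names(marg))] <- marg
  post / sum(post)
}

## random rooted tree with runif branch lengths, optionally with a polytomy
random_tree <- function(nleaf, multifurcate = FALSE) {
  tr <- ape::rtree(nleaf, rooted = TRUE, br = function(n) runif(n, 0.02, 0.8))
  if (multifurcate && nleaf >= 4) {
    internal_edges <- which(tr$edge[, 2] > nleaf)
    if (length(internal_edges)) {
      tr$edge.length[sample(internal_edges, 1)] <- 0
      tr <- ape::di2multi(tr, tol = 1e-12)
    }
  }
  tr
}

## random residue column over a tree's tips (chars, occasionally gap/ambiguous)
random_column <- function(tree, p_gap = 0.1) {
  ch <- sample(ORACLE_AA, length(tree$tip.label), replace = TRUE)
  odd <- runif(length(ch)) < p_gap
  ch[odd] <- sample(c("-", "B", "Z", "X"), sum(odd), replace = TRUE)
  names(ch) <- tree$tip.label
  ch
}

## brute-force patristic distances via root paths (independent of ape's
## cophenetic machinery)
brute_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  plen <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(v) {
    nodes <- v; d <- 0
    while (parent[v] != 0) {
      d <- c(d, d[length(d)] + plen[v])
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    stats::setNames(d, nodes)
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip - 1)) for (j in (i + 1):ntip) {
    common <- intersect(names(paths[[i]]), names(paths[[j]]))
    D[i, j] <- D[j, i] <- min(paths[[i]][common] + paths[[j]][common])
  }
  D
}

## tiny matrix exponential by scaling-and-squaring of the Taylor series,
## independent of the package's eigendecomposition route
naive_expm <- function(A, order = 24) {
  s <- max(0, ceiling(log2(max(1, norm(A, "1")))))
  B <- A / 2^s
  X <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% B / k
    X <- X + term
  }
  for (k in seq_len(s)) X <- X %*% X
  X
}

## default small evolved fixture used by several files
fixture_sim <- function(seed = 11, n_leaves = 8, length = 60, ...) {
  evolve_alignment(sim_config(seed = seed, n_leaves = n_leaves,
                              length = length, ...))
}
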