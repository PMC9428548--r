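#' Simulation configuration
#'
#' Collects every knob the synthetic-data generators use, with defaults set
#' to the measured conditions of the study system: a 350-residue motor
#' domain, a two-clade family tree, 8.7 Hz single-molecule movies of 200
#' frames, 40 pM motor on ~8 µm microtubules, and the measured kinetic
#' rates of the ancestral motor as generating parameters.
#'
#' @param seed Integer seed fixing all generator output bit-for-bit.
#' @param ... Overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    ## sequence evolution
    tree = NULL,             # NULL -> sim_tree(n_leaves, depth)
    n_leaves = 16,
    depth = 1.0,             # mean root-to-tip path, substitutions/site
    length = 350,            # root sequence length (motor domain)
    root_seq = NULL,
    indel_rate = 0.05,       # deletion events per unit branch length
    indel_mean_block = 4,    # geometric mean deleted block length
    ## single-molecule dwell times
    frame_interval = 1 / 8.7,
    movie_length = 200 / 8.7,
    k_on = 62.4,             # nM-1 s-1 um-1
    concentration = 0.04,    # nM (40 pM)
    mt_length = 8,           # um
    k_off_end = 1.23,        # s-1
    k_off_lattice = 1.36,    # s-1
    end_fraction = 0.25,     # fraction of arrivals landing on an end
    ## depolymerization traces
    v_depol = 23.05,         # um/min
    n_traces = 12,
    interval = 5,            # s between frames
    addition_time = 10,      # s; protein added after a short baseline
    init_length = c(8, 15),  # um, uniform range (or single value)
    length_noise = 0.2,      # um (~2-3 pixels)
    break_rate = 0,          # expected internal breaks per um
    ## ATPase
    atpase_k = 8.07,         # s-1 per active site
    atpase_mode = "nadh_coupled",
    atpase_motor = NULL,     # uM; default 3 (hplc) or 0.1 (coupled)
    atpase_duration = NULL,  # s; default 600 (hplc) or 60 (coupled)
    atpase_noise = NULL,     # signal s.d.; default 0.5 uM or 0.002 A
    extinction = 6220,
    path_length = 1,
    nadh0 = 200              # uM starting NADH, coupled mode
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

#' Deterministic two-clade test tree
#'
#' A rooted tree with two clades (emulating the 13A/13B subfamily split),
#' random topology and branch lengths under a fixed internal seed, scaled so
#' the mean root-to-tip path equals `depth` substitutions per site.
#'
#' @param n_leaves Total leaf count (default 16; 75 mirrors the family
#'   alignment size).
#' @param depth Mean root-to-tip path length.
#' @param seed Topology/branch-length seed (independent of analysis seeds).
#' @return A rooted `phylo` with leaf labels `cladeA_*` / `cladeB_*`.
#' @export
sim_tree <- function(n_leaves = 16, depth = 1.0, seed = 42) {
  stopifnot(n_leaves >= 4)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  na <- ceiling(n_leaves / 2); nb <- n_leaves - na
  clade <- function(n, tag) {
    tr <- ape::rtree(n, rooted = TRUE, br = function(k) stats::rexp(k, 10))
    tr$tip.label <- sprintf("%s_%02d", tag, seq_len(n))
    tr
  }
  a <- clade(na, "cladeA"); b <- clade(nb, "cladeB")
  nwk <- sprintf("(%s:0.1,%s:0.1);",
                 sub(";$", "", ape::write.tree(a)),
                 sub(";$", "", ape::write.tree(b)))
  tr <- ape::read.tree(text = nwk)
  d <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  tr$edge.length <- tr$edge.length * depth / mean(d)
  tr
}

#' Evolve an alignment along a tree under the WAG model
#'
#' The root sequence is drawn from the model's equilibrium frequencies (or
#' supplied); residues evolve independently per site along each branch by
#' sampling from the rows of `P(t)`. An optional indel process deletes
#' contiguous blocks (Poisson events per branch at `indel_rate` per unit
#' length, geometric block sizes), producing leaf gap patterns. The true
#' root sequence is retained for scoring.
#'
#' @param config A [sim_config()].
#' @return List: `alignment` ([protein_alignment()]), `tree`, `root_seq`
#'   (true ancestral string), `model`.
#' @export
evolve_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- build_wag()
  tree <- if (is.null(config$tree)) sim_tree(config$n_leaves, config$depth)
          else validate_tree(config$tree)
  L <- if (is.null(config$root_seq)) config$length
       else nchar(config$root_seq)
  if (L < 1) stop("zero-length alignment requested")
  root_states <- if (is.null(config$root_seq)) {
    sample.int(20, L, replace = TRUE, prob = model$pi)
  } else {
    match(strsplit(toupper(config$root_seq), "")[[1]], AA_STATES)
  }
  if (anyNA(root_states)) stop("root sequence contains non-standard residues")

  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  root <- ntip + 1L
  nnode <- ntip + po$Nnode
  states <- vector("list", nnode)
  present <- vector("list", nnode)
  states[[root]] <- root_states
  present[[root]] <- rep(TRUE, L)

  evolve_edge <- function(parent_states, t) {
    P <- transition_matrix(model, t)
    child <- integer(L)
    for (s in unique(parent_states)) {
      idx <- which(parent_states == s)
      child[idx] <- sample.int(20, length(idx), replace = TRUE, prob = P[s, ])
    }
    child
  }

  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]; t <- po$edge.length[e]
    states[[ch]] <- evolve_edge(states[[p]], t)
    pres <- present[[p]]
    n_del <- stats::rpois(1, config$indel_rate * t)
    for (k in seq_len(n_del)) {
      alive <- which(pres)
      if (length(alive) <= 1) break
      blk <- min(1 + stats::rgeom(1, 1 / config$indel_mean_block),
                 length(alive) - 1)
      start <- sample.int(length(alive) - blk + 1, 1)
      pres[alive[start:(start + blk - 1)]] <- FALSE
    }
    present[[ch]] <- pres
  }

  rows <- vapply(seq_len(ntip), function(i) {
    ch <- AA_STATES[states[[i]]]
    ch[!present[[i]]] <- "-"
    paste(ch, collapse = "")
  }, "")
  names(rows) <- po$tip.label
  list(alignment = protein_alignment(rows), tree = po,
       root_seq = paste(AA_STATES[root_states], collapse = ""), model = model)
}

#' Simulate single-molecule dwell-time data
#'
#' Arrivals are Poisson at `k_on * mt_length * concentration` over the
#' movie; durations are exponential with the location-specific off-rate.
#' Observed durations are what a kymograph measurement yields: the number
#' of frames the event overlaps times the frame interval (so each observed
#' duration carries on average one extra frame interval, the bias that
#' [koff_mle()] corrects). Events running into the movie end are flagged
#' right-censored.
#'
#' @param config A [sim_config()].
#' @return A [dwell_set()].
#' @export
simulate_dwells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  T <- config$movie_length
  dt <- config$frame_interval
  if (T <= 0) {
    return(dwell_set(numeric(0), character(0), logical(0),
                     movie_length = T, frame_interval = dt,
                     mt_length = config$mt_length,
                     concentration = config$concentration))
  }
  lambda <- config$k_on * config$mt_length * config$concentration * T
  n <- stats::rpois(1, lambda)
  start <- stats::runif(n, 0, T)
  loc <- ifelse(stats::runif(n) < config$end_fraction, "end", "lattice")
  k <- ifelse(loc == "end", config$k_off_end, config$k_off_lattice)
  true_dur <- stats::rexp(n, k)
  end <- start + true_dur
  censored <- end > T
  end[censored] <- T
  frames <- floor(end / dt) - floor(start / dt) + 1
  dwell_set(frames * dt, loc, censored,
            movie_length = T, frame_interval = dt,
            mt_length = config$mt_length,
            concentration = config$concentration)
}

#' Simulate depolymerization length traces
#'
#' Piecewise-linear shrinkage at `v_depol` starting at the addition time,
#' with Gaussian length noise. Optional internal break events (Poisson along
#' the initial length at `break_rate` per µm) are recorded per microtubule.
#'
#' @param config A [sim_config()].
#' @return List: `traces` (list of [length_trace()]), `breaks` (data.frame
#'   `length`, `breaks` per microtubule).
#' @export
simulate_length_traces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  v <- config$v_depol / 60          # um/s
  rng <- config$init_length
  traces <- vector("list", config$n_traces)
  brk <- integer(config$n_traces)
  init <- numeric(config$n_traces)
  for (i in seq_len(config$n_traces)) {
    L0 <- if (length(rng) == 2) stats::runif(1, rng[1], rng[2]) else rng
    init[i] <- L0
    t_end <- if (v > 0) config$addition_time + L0 / v + config$interval
             else config$addition_time + 20 * config$interval
    times <- seq(0, t_end, by = config$interval)
    len <- ifelse(times < config$addition_time, L0,
                  L0 - v * (times - config$addition_time))
    len <- pmax(len + stats::rnorm(length(len), 0, config$length_noise), 0)
    traces[[i]] <- length_trace(times, len,
                                addition_time = config$addition_time,
                                interval = config$interval, id = i)
    brk[i] <- stats::rpois(1, config$break_rate * L0)
  }
  list(traces = traces, breaks = data.frame(length = init, breaks = brk))
}

#' Simulate an ATPase progress assay
#'
#' HPLC mode: `[ADP](t) = k * [motor] * t` plus Gaussian noise. Coupled
#' mode: the same ADP production drawn down from the starting NADH pool and
#' converted to absorbance through the extinction coefficient, with its own
#' absorbance noise.
#'
#' @param config A [sim_config()].
#' @return An [atpase_assay()].
#' @export
simulate_atpase <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mode <- config$atpase_mode
  motor <- if (!is.null(config$atpase_motor)) config$atpase_motor
           else if (mode == "hplc_adp") 3 else 0.1
  dur <- if (!is.null(config$atpase_duration)) config$atpase_duration
         else if (mode == "hplc_adp") 600 else 60
  noise <- if (!is.null(config$atpase_noise)) config$atpase_noise
           else if (mode == "hplc_adp") 0.5 else 0.002
  k <- config$atpase_k
  if (mode == "hplc_adp") {
    times <- seq(0, dur, by = 60)
    adp <- k * motor * times + stats::rnorm(length(times), 0, noise)
    atpase_assay(times, adp, motor, mode = "hplc_adp")
  } else {
    times <- seq(0, dur, by = 2)
    a0 <- config$extinction * config$path_length * config$nadh0 * 1e-6
    a <- a0 - config$extinction * config$path_length * k * motor * 1e-6 * times +
      stats::rnorm(length(times), 0, noise)
    atpase_assay(times, a, motor, mode = "nadh_coupled",
                 extinction = config$extinction,
                 path_length = config$path_length)
  }
}
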