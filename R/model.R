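#' Build the WAG amino-acid substitution model
#'
#' Assembles the reversible rate matrix `Q[i,j] = s[i,j] * pi[j]` from the
#' published WAG exchangeabilities and either the published WAG equilibrium
#' frequencies (`frequencies = "model"`, the default) or frequencies counted
#' from an alignment (`"empirical"`, the `+F` variant). `Q` is normalized so
#' that the expected number of substitutions per unit time is 1, i.e. branch
#' lengths are in substitutions per site.
#'
#' @param frequencies `"model"` or `"empirical"`.
#' @param alignment A [protein_alignment()], required for empirical mode.
#'   Gaps and ambiguity codes are excluded from the counts.
#' @param pseudocount Added to every residue count in empirical mode so no
#'   frequency is ever zero.
#' @return An object of class `substitution_model` with elements
#'   `exchangeabilities`, `pi`, `Q` and a cached symmetric eigendecomposition.
#' @examples
#' m <- build_wag()
#' sum(m$pi)
#' @export
build_wag <- function(frequencies = c("model", "empirical"), alignment = NULL,
                      pseudocount = 0.5) {
  frequencies <- match.arg(frequencies)
  dat <- cache_get("wag", read_paml_matrix(
    system.file("extdata", "WAG.dat", package = "kinesin13", mustWork = TRUE)))
  pi <- dat$pi
  if (frequencies == "empirical") {
    if (is.null(alignment)) stop("empirical frequencies require an alignment")
    ch <- unlist(strsplit(alignment$seqs, ""))
    counts <- table(factor(ch, levels = AA_STATES))  # drops gaps/ambiguities
    pi <- as.numeric(counts + pseudocount)
    pi <- pi / sum(pi)
  }
  substitution_model(dat$exchangeabilities, pi)
}

#' Construct a reversible substitution model from exchangeabilities
#'
#' @param exchangeabilities Symmetric non-negative 20x20 matrix (diagonal
#'   ignored).
#' @param pi Equilibrium frequencies, strictly positive, summing to 1.
#' @return A `substitution_model`.
#' @export
substitution_model <- function(exchangeabilities, pi) {
  s <- as.matrix(exchangeabilities)
  n <- length(pi)
  stopifnot(nrow(s) == n, ncol(s) == n, all(pi > 0))
  pi <- pi / sum(pi)
  Q <- s * rep(pi, each = n)   # Q[i,j] = s[i,j] * pi[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))     # expected rate; rescale to 1 sub/site/unit time
  Q <- Q / mu
  ## symmetrize: B = D^{1/2} Q D^{-1/2} is symmetric for reversible Q
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2          # kill rounding asymmetry
  eig <- eigen(B, symmetric = TRUE)
  structure(list(exchangeabilities = s, pi = pi, Q = Q,
                 eigenvalues = eig$values,
                 left = t(eig$vectors) * rep(sp, each = n),     # V' D^{1/2}
                 right = eig$vectors / sp,                      # D^{-1/2} V
                 states = if (n == 20) AA_STATES else as.character(seq_len(n))),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution_model: %d states, mean rate %.6f\n",
              length(x$pi), -sum(x$pi * diag(x$Q))))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed through the cached symmetric eigendecomposition of the
#' pi-similarity-transformed rate matrix; rows are renormalized only when
#' they already sum to 1 within 1e-8.
#'
#' @param model A `substitution_model`.
#' @param t Branch length (substitutions per site), `t >= 0`.
#' @return A stochastic matrix with rows summing to 1.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be >= 0, got ", t)
  n <- length(model$pi)
  if (t == 0) {
    P <- diag(n)
    dimnames(P) <- list(model$states, model$states)
    return(P)
  }
  P <- model$right %*% (exp(model$eigenvalues * t) * model$left)
  P[P < 0] <- 0
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8))
    stop("transition matrix rows deviate from 1 beyond tolerance")
  P <- P / rs
  dimnames(P) <- list(model$states, model$states)
  P
}

#' Discrete-gamma rate classes
#'
#' Mean rates of `k` equiprobable classes of a Gamma(shape = alpha,
#' mean = 1) distribution, the standard discretization used for
#' among-site rate variation.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of classes.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  r <- diff(stats::pgamma(q, shape = alpha + 1, rate = alpha)) * k
  r / mean(r)
}
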