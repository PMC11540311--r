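# Nucleotide substitution models. Branch lengths are measured in expected
# substitutions per site, so every rate matrix is normalized to one expected
# substitution per unit branch length at stationarity.

BASES <- c("A", "C", "G", "T")

#' Jukes-Cantor (JC69) substitution model
#'
#' Equal base frequencies and a single exchange rate. The transition
#' probabilities have the closed form
#' \deqn{P_{ii}(t) = 1/4 + 3/4 e^{-4t/3}, \quad P_{ij}(t) = 1/4 - 1/4 e^{-4t/3}.}
#'
#' @return an object of class `subst_model`.
#' @export
jc69 <- function() {
  structure(list(name = "JC69", freqs = rep(0.25, 4)), class = "subst_model")
}

#' HKY85 substitution model
#'
#' Distinguishes transitions from transversions (ratio `kappa`) with
#' arbitrary stationary base frequencies. The rate matrix is normalized to
#' one expected substitution per site per unit branch length.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param freqs stationary frequencies for A, C, G, T; must sum to 1.
#' @return an object of class `subst_model`.
#' @export
hky85 <- function(kappa = 2, freqs = rep(0.25, 4)) {
  stopifnot(kappa > 0, length(freqs) == 4, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-8)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  is_transition <- function(i, j) {
    (BASES[i] %in% c("A", "G") && BASES[j] %in% c("A", "G")) ||
      (BASES[i] %in% c("C", "T") && BASES[j] %in% c("C", "T"))
  }
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- freqs[j] * if (is_transition(i, j)) kappa else 1
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  eig <- eigen(Q)
  structure(list(name = "HKY85", kappa = kappa, freqs = freqs, Q = Q,
                 evec = eig$vectors, eval = eig$values,
                 ivec = solve(eig$vectors)),
            class = "subst_model")
}

#' Transition probability matrix P(t)
#'
#' @param model a `subst_model`.
#' @param t branch length in substitutions/site (>= 0).
#' @return 4x4 matrix with rows = ancestral base, columns = descendant base.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), t >= 0)
  if (model$name == "JC69") {
    e <- exp(-4 * t / 3)
    p_same <- 0.25 + 0.75 * e
    p_diff <- 0.25 - 0.25 * e
    P <- matrix(p_diff, 4, 4, dimnames = list(BASES, BASES))
    diag(P) <- p_same
    P
  } else {
    P <- Re(model$evec %*% diag(exp(model$eval * t)) %*% model$ivec)
    P[P < 0] <- 0
    dimnames(P) <- list(BASES, BASES)
    P
  }
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("Substitution model: %s\n", x$name))
  cat("  stationary frequencies:",
      paste(sprintf("%s=%.3f", BASES, x$freqs), collapse = " "), "\n")
  if (!is.null(x$kappa)) cat(sprintf("  kappa: %g\n", x$kappa))
  invisible(x)
}

# Encode bases as integers 1..4 (A,C,G,T); anything else (N, gap) -> NA
encode_bases <- function(x) {
  m <- match(toupper(x), BASES)
  m
}
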