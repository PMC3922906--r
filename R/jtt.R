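# Empirical amino-acid substitution models.
#
# The JTT model is hard-coded from the published Jones-Taylor-Thornton (1992)
# exchangeability and frequency tables (the same constants distributed with
# PHYLIP/PAML). Amino acids are in the conventional ARNDCQEGHILKMFPSTWYV
# order; the lower-triangle exchangeabilities are read row-wise.

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

JTT_EXCH_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

# assemble a reversible rate matrix Q from a lower-triangle exchangeability
# vector and equilibrium frequencies, scaled to one expected substitution
# per site (-sum_i pi_i Q_ii == 1)
build_rate_matrix <- function(exch_lower, freqs) {
  k <- length(freqs)
  freqs <- freqs / sum(freqs)
  S <- matrix(0, k, k)
  S[lower.tri(S)] <- exch_lower
  S <- S + t(S)
  Q <- S %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(freqs * diag(Q))
  dimnames(Q) <- list(AA_ORDER[seq_len(k)], AA_ORDER[seq_len(k)])
  Q
}

# spectral decomposition of a reversible Q for fast matrix exponentials:
# Q = D^{-1/2} U L U' D^{1/2} with B = D^{1/2} Q D^{-1/2} symmetric
decompose_rate_matrix <- function(Q, freqs) {
  freqs <- freqs / sum(freqs)
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  list(left = diag(1 / d) %*% eig$vectors,
       right = t(eig$vectors) %*% diag(d),
       values = eig$values,
       freqs = freqs)
}

# cached model structures
.model_cache <- new.env(parent = emptyenv())

#' Substitution model components
#'
#' Returns equilibrium frequencies, the scaled rate matrix and its spectral
#' decomposition for a named amino-acid model. `"jtt"` is the published
#' Jones-Taylor-Thornton model; `"equal_rates_20state"` is the 20-state
#' equal-rates (Jukes-Cantor-like) model.
#'
#' @param model `"jtt"` or `"equal_rates_20state"`.
#' @return List with `freqs`, `Q`, and the eigendecomposition.
#' @export
substitution_model <- function(model = c("jtt", "equal_rates_20state")) {
  model <- match.arg(model)
  if (!is.null(.model_cache[[model]])) return(.model_cache[[model]])
  if (model == "jtt") {
    freqs <- JTT_FREQS / sum(JTT_FREQS)
    Q <- build_rate_matrix(JTT_EXCH_LOWER, freqs)
  } else {
    freqs <- rep(1 / 20, 20)
    Q <- build_rate_matrix(rep(1, 190), freqs)
  }
  dec <- decompose_rate_matrix(Q, freqs)
  out <- c(list(model = model, Q = Q), dec)
  .model_cache[[model]] <- out
  out
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param t Branch length in expected substitutions per site.
#' @param model Model name or the list from [substitution_model()].
#' @return 20x20 row-stochastic matrix in ARNDCQEGHILKMFPSTWYV order.
#' @export
transition_probs <- function(t, model = "jtt") {
  mod <- if (is.character(model)) substitution_model(model) else model
  P <- mod$left %*% (exp(mod$values * t) * mod$right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(mod$Q)
  P
}
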