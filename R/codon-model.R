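## Goldman-Yang style codon substitution model on the 61 sense codons of the
## standard genetic code. The model is parameterized by omega (dN/dS), kappa
## (transition/transversion rate ratio) and the codon equilibrium frequencies;
## only single-nucleotide codon changes have nonzero instantaneous rate.

.codon_env <- new.env(parent = emptyenv())

## Standard genetic code, codons enumerated with the first base slowest in
## T, C, A, G order (TTT, TTC, TTA, TTG, TCT, ...). '*' marks stop codons.
.GC_AA <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  bases <- c("T", "C", "A", "G")
  codons64 <- paste0(rep(bases, each = 16),
                     rep(rep(bases, each = 4), 4),
                     rep(bases, 16))
  aa64 <- strsplit(.GC_AA, "")[[1]]
  sense <- aa64 != "*"
  codons <- codons64[sense]
  aa <- aa64[sense]
  n <- length(codons)  # 61
  cmat <- do.call(rbind, strsplit(codons, ""))

  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(cmat[, p], cmat[, p], "!=")
  single <- ndiff == 1L
  ## transition = purine<->purine or pyrimidine<->pyrimidine at the changed site
  is_purine <- function(b) b %in% c("A", "G")
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    sel <- single & outer(cmat[, p], cmat[, p], "!=")
    ts[sel] <- outer(is_purine(cmat[, p]), is_purine(cmat[, p]), "==")[sel]
  }
  syn <- outer(aa, aa, "==")
  tab <- list(codons = codons, aa = aa, n = n, cmat = cmat,
              single = single, ts = ts & single, syn = syn)
  .codon_env$tab <- tab
  tab
}

#' Codon model parameters
#'
#' Container for the parameters of the codon substitution model: `omega`
#' (dN/dS, the nonsynonymous/synonymous rate ratio), `kappa` (the
#' transition/transversion rate ratio), the 61 sense-codon equilibrium
#' frequencies, and a global multiplier on input branch lengths.
#'
#' @param omega Positive real, dN/dS.
#' @param kappa Positive real, transition/transversion rate ratio.
#' @param codon_frequencies Numeric vector of length 61 summing to 1;
#'   defaults to equal frequencies.
#' @param branch_scale Positive multiplier applied to input branch lengths.
#' @return An object of class `codon_model_params`.
#' @export
#' @examples
#' p <- codon_model_params(omega = 0.2, kappa = 2)
codon_model_params <- function(omega, kappa, codon_frequencies = NULL,
                               branch_scale = 1) {
  tab <- codon_tables()
  if (is.null(codon_frequencies)) codon_frequencies <- rep(1 / tab$n, tab$n)
  if (!(is.numeric(omega) && length(omega) == 1L && omega >= 0))
    stop_invalid("omega must be a nonnegative scalar")
  if (!(is.numeric(kappa) && kappa > 0)) stop_invalid("kappa must be > 0")
  if (length(codon_frequencies) != tab$n ||
      any(codon_frequencies < 0) ||
      abs(sum(codon_frequencies) - 1) > 1e-9)
    stop_invalid("codon_frequencies must be a 61-vector of nonnegative values summing to 1")
  if (!(is.numeric(branch_scale) && branch_scale > 0))
    stop_invalid("branch_scale must be > 0")
  structure(list(omega = omega, kappa = kappa,
                 codon_frequencies = as.numeric(codon_frequencies),
                 branch_scale = branch_scale),
            class = "codon_model_params")
}

#' Build the codon instantaneous rate matrix
#'
#' Constructs the 61x61 generator of the codon model: codon pairs differing at
#' more than one position get rate 0; a single-nucleotide change i -> j gets
#' rate `pi_j * kappa^[transition] * omega^[nonsynonymous]`. Rows sum to zero
#' and the matrix is scaled so the expected substitution rate at equilibrium
#' is 1 per nucleotide site (i.e. 3 per codon site), so branch lengths are in
#' substitutions per nucleotide site.
#'
#' @param params A [codon_model_params()] object.
#' @return A 61x61 numeric matrix with codon row/column names.
#' @export
build_codon_rate_matrix <- function(params) {
  stopifnot(inherits(params, "codon_model_params"))
  tab <- codon_tables()
  pi <- params$codon_frequencies
  Q <- matrix(0, tab$n, tab$n, dimnames = list(tab$codons, tab$codons))
  Q[tab$single] <- rep(pi, each = tab$n)[tab$single]
  Q[tab$ts] <- Q[tab$ts] * params$kappa
  nonsyn <- tab$single & !tab$syn
  Q[nonsyn] <- Q[nonsyn] * params$omega
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(pi * diag(Q))  # substitutions per codon per time unit
  if (mean_rate > 0) Q <- Q * (3 / mean_rate)
  Q
}

## Eigendecomposition of the reversible generator via the symmetrized form
## B = D^{1/2} Q D^{-1/2} (D = diag(pi)); P(t) = D^{-1/2} U e^{Lt} U' D^{1/2}.
codon_eigen <- function(Q, pi) {
  s <- sqrt(pi)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2  # symmetrize roundoff
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, s = s)
}

codon_pmat <- function(eig, t) {
  if (t <= 0) return(diag(length(eig$lambda)))
  M <- eig$U %*% (exp(eig$lambda * t) * t(eig$U))
  P <- (1 / eig$s) * M * rep(eig$s, each = length(eig$s))
  P[P < 0] <- 0
  P
}

## Stationary distribution of a generator (left null vector), used by tests.
stationary_distribution <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
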