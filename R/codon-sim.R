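## Codon alignment container and the forward simulator (event-logging
## Gillespie sampling of the codon substitution process along each branch).

#' Codon alignment
#'
#' Equal-length in-frame nucleotide sequences over `{A,C,G,T}` with no
#' in-frame stop codons (standard genetic code).
#'
#' @param sequences Named character vector of sequences, or a character
#'   matrix of codons (rows = taxa).
#' @param taxa Optional taxon labels (defaults to `names(sequences)`).
#' @return An object of class `codon_alignment` with fields `taxa`,
#'   `sequences`, and `length_codons`.
#' @export
codon_alignment <- function(sequences, taxa = names(sequences)) {
  if (is.null(taxa) || anyDuplicated(taxa))
    stop_invalid("sequences must carry unique taxon labels")
  sequences <- toupper(unname(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop_invalid("all sequences must have the same length")
  if (lens[1] %% 3 != 0) stop_invalid("sequence length must be divisible by 3")
  if (any(grepl("[^ACGT]", sequences)))
    stop_invalid("sequences must contain only A, C, G, T")
  idx <- alignment_codon_indices_chr(sequences)
  if (anyNA(idx)) stop_invalid("alignment contains in-frame stop codons")
  structure(list(taxa = as.character(taxa), sequences = sequences,
                 length_codons = lens[1] %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa, %d codons\n",
              length(x$taxa), x$length_codons))
  invisible(x)
}

## taxa x codons integer matrix of sense-codon indices (NA for stops).
alignment_codon_indices_chr <- function(sequences) {
  tab <- codon_tables()
  n <- nchar(sequences[1]) %/% 3
  starts <- 3L * (seq_len(n) - 1L) + 1L
  out <- matrix(NA_integer_, length(sequences), n)
  for (i in seq_along(sequences)) {
    cods <- substring(sequences[i], starts, starts + 2L)
    out[i, ] <- match(cods, tab$codons)
  }
  out
}

alignment_codon_indices <- function(aln) {
  m <- alignment_codon_indices_chr(aln$sequences)
  rownames(m) <- aln$taxa
  m
}

codon_indices_to_seq <- function(idx) {
  tab <- codon_tables()
  paste(tab$codons[idx], collapse = "")
}

## Gillespie evolution of a vector of codon states along one branch.
## Returns the end states; attribute "n_events" carries the realized
## substitution count for expectation oracles.
evolve_codon_branch <- function(states, Q, len) {
  if (len <= 0) {
    attr(states, "n_events") <- 0L
    return(states)
  }
  rates <- -diag(Q)
  n <- length(states)
  remaining <- rep(len, n)
  active <- seq_len(n)
  nev <- 0L
  while (length(active)) {
    ## absorbing states (e.g. ATG/TGG under omega = 0) never leave
    active <- active[rates[states[active]] > 0]
    if (!length(active)) break
    w <- stats::rexp(length(active), rates[states[active]])
    remaining[active] <- remaining[active] - w
    active <- active[remaining[active] > 0]
    for (i in active) {
      p <- Q[states[i], ]
      p[states[i]] <- 0
      states[i] <- sample.int(length(p), 1L, prob = p)
    }
    nev <- nev + length(active)
  }
  attr(states, "n_events") <- nev
  states
}

#' Simulate a codon alignment on a tree
#'
#' Draws the root sequence from the model's codon frequencies and evolves it
#' along every branch of the rooted tree under the codon substitution model
#' (exact stochastic simulation, site-independent). Branch lengths are
#' multiplied by `params$branch_scale`.
#'
#' @param tree A `phylo` tree with branch lengths and unique tip labels.
#' @param params A [codon_model_params()] object.
#' @param n_codons Number of codon sites (>= 1).
#' @param seed Integer seed.
#' @return A `codon_alignment` over the tree's tips. Attribute `n_events`
#'   holds the total realized substitution count across the tree.
#' @export
simulate_alignment <- function(tree, params, n_codons, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "codon_model_params"))
  if (!(is.numeric(n_codons) && n_codons >= 1))
    stop_invalid("n_codons must be >= 1")
  if (anyDuplicated(tree$tip.label)) stop_invalid("tree tips must be unique")
  if (any(tree$edge.length < 0)) stop_invalid("branch lengths must be >= 0")
  n_codons <- as.integer(n_codons)
  Q <- build_codon_rate_matrix(params)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    states <- matrix(NA_integer_, ntip + tree$Nnode, n_codons)
    states[root, ] <- sample.int(codon_tables()$n, n_codons, replace = TRUE,
                                 prob = params$codon_frequencies)
    nev <- 0L
    for (e in rev(ape::postorder(tree))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      s <- evolve_codon_branch(states[par, ], Q,
                               tree$edge.length[e] * params$branch_scale)
      nev <- nev + attr(s, "n_events")
      states[child, ] <- as.integer(s)
    }
    seqs <- vapply(seq_len(ntip), function(i) codon_indices_to_seq(states[i, ]),
                   character(1))
    names(seqs) <- tree$tip.label
    aln <- codon_alignment(seqs)
    attr(aln, "n_events") <- nev
    aln
  })
}

#' Truncate a codon alignment to a target length
#'
#' Keeps the first `n_codons` codon columns (mirrors trimming long simulated
#' alignments to match an empirical length).
#'
#' @param aln A `codon_alignment`.
#' @param n_codons Target number of codons (<= current length).
#' @return A `codon_alignment`.
#' @export
truncate_alignment <- function(aln, n_codons) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (n_codons < 1 || n_codons > aln$length_codons)
    stop_invalid("n_codons must be in [1, %d]", aln$length_codons)
  seqs <- substr(aln$sequences, 1L, 3L * as.integer(n_codons))
  names(seqs) <- aln$taxa
  codon_alignment(seqs)
}

#' Read / write codon alignments as FASTA
#'
#' @param path File path.
#' @param aln A `codon_alignment`.
#' @return `read_alignment_fasta` returns a `codon_alignment`;
#'   `write_alignment_fasta` returns `path` invisibly.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  codon_alignment(stats::setNames(as.character(x), names(x)))
}

#' @rdname read_alignment_fasta
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  x <- Biostrings::DNAStringSet(stats::setNames(aln$sequences, aln$taxa))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
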