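## Splittable-lineage identification and subtree heterogeneity testing:
## find the branch that partitions a rooted tree into two deep, well-populated
## subtrees, extract them, and compare selection between them.

#' Phylogenetic depth of a tree
#'
#' Maximum root-to-tip path length, including the root edge when present.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Nonnegative numeric depth.
#' @export
phylogenetic_depth <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop_invalid("tree must have branch lengths")
  d <- max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  d + (tree$root.edge %||% 0)
}

## Total branch length, including the root edge when present.
tree_total_length <- function(tree) {
  sum(tree$edge.length) + (tree$root.edge %||% 0)
}

## Tip indices descending from each node (list over all nodes).
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::postorder(tree)
  for (e in po) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  desc
}

#' Find the best splitting branch of a tree
#'
#' Scans every edge of the rooted tree; an edge qualifies when removing it
#' yields two subtrees that each contain at least `min_tips` tips and have
#' phylogenetic depth strictly greater than `min_depth`. Among qualifying
#' edges the one maximizing the smaller tip count is returned (ties broken
#' by larger total, then by the deterministic postorder edge index).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param min_tips Minimum tips per subtree (default 20).
#' @param min_depth Minimum subtree depth, strict (default 0.2).
#' @return A `split_candidate` (list with `branch_id`, `tips_A`, `tips_B`,
#'   `depth_A`, `depth_B`, `score`) or `NULL` when no edge qualifies.
#' @export
find_split_branch <- function(tree, min_tips = 20, min_depth = 0.2) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2 * min_tips) return(NULL)
  desc <- descendant_tips(tree)
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    nA <- length(desc[[child]])
    nB <- ntip - nA
    if (nA < min_tips || nB < min_tips) next
    parts <- split_tree_at_edge(tree, e)
    dA <- phylogenetic_depth(parts$A)
    dB <- phylogenetic_depth(parts$B)
    if (dA <= min_depth || dB <= min_depth) next
    score <- min(nA, nB)
    if (is.null(best) || score > best$score) {
      best <- list(branch_id = e,
                   tips_A = tree$tip.label[desc[[child]]],
                   tips_B = setdiff(tree$tip.label, tree$tip.label[desc[[child]]]),
                   depth_A = dA, depth_B = dB, score = score)
    }
  }
  if (!is.null(best)) class(best) <- "split_candidate"
  best
}

## Cut the tree at edge `e`: A = clade below the edge (its root edge, the cut
## edge itself, is excluded); B = remainder, keeping the path length to the
## original root as a root edge where one survives collapsing.
split_tree_at_edge <- function(tree, e) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[e, 2]
  A <- ape::extract.clade(tree, child)
  A$root.edge <- NULL
  tipsA <- A$tip.label
  B <- ape::drop.tip(tree, tipsA, trim.internal = TRUE, collapse.singles = TRUE,
                     root.edge = 1)
  list(A = A, B = B, cut_length = tree$edge.length[e])
}

#' Extract the two subtrees defined by a split candidate
#'
#' @param tree The tree the candidate was computed from.
#' @param split A `split_candidate` from [find_split_branch()].
#' @return A list of two `phylo` trees, `A` and `B`, with original branch
#'   lengths; the cut edge's length is returned as attribute `cut_length`.
#' @export
extract_subtrees <- function(tree, split) {
  stopifnot(inherits(tree, "phylo"), inherits(split, "split_candidate"))
  e <- split$branch_id
  if (e > nrow(tree$edge))
    stop_invalid("stale split candidate: edge %d not in tree", e)
  child <- tree$edge[e, 2]
  desc <- descendant_tips(tree)
  if (!setequal(tree$tip.label[desc[[child]]], split$tips_A))
    stop_invalid("stale split candidate: edge %d no longer subtends tips_A", e)
  parts <- split_tree_at_edge(tree, e)
  out <- list(A = parts$A, B = parts$B)
  attr(out, "cut_length") <- parts$cut_length
  out
}

#' Flag a subtree whose dN/dS estimates are largely unreliable
#'
#' TRUE when more than `max_fraction` of the values equal `boundary_value`
#' (within `1e-6`), indicating estimates stuck at the uninformative boundary.
#'
#' @param dnds_values Positive numeric vector of per-gene dN/dS estimates.
#' @param boundary_value Value indicating an unreliable estimate (default 1).
#' @param max_fraction Strict threshold on the offending fraction
#'   (default 0.3).
#' @return Logical flag.
#' @export
flag_unreliable_subtree <- function(dnds_values, boundary_value = 1.0,
                                    max_fraction = 0.3) {
  if (length(dnds_values) == 0) stop_invalid("dnds_values must be non-empty")
  mean(abs(dnds_values - boundary_value) < 1e-6) > max_fraction
}

#' Compare lineage constraints between two subtrees
#'
#' The difference measure is the fold change between the subtrees'
#' multiplicative constraints minus one:
#' `max(exp(F_A - F_B), exp(F_B - F_A)) - 1`. Heterogeneity is flagged when
#' the measure strictly exceeds `threshold` (default 0.4, i.e. a >40%
#' difference).
#'
#' @param F_A,F_B Subtree lineage factors on the log scale.
#' @param threshold Strict flag threshold (default 0.4).
#' @return List with `difference_measure` and `flagged`.
#' @export
compare_subtree_constraints <- function(F_A, F_B, threshold = 0.4) {
  d <- max(exp(F_A - F_B), exp(F_B - F_A)) - 1
  list(difference_measure = d, flagged = d > threshold)
}

#' Site bootstrap of a subtree dN/dS estimate
#'
#' Resamples codon columns with replacement, restricts each replicate to the
#' subtree's taxa, re-estimates dN/dS by ML on the subtree, and returns the
#' proportion of replicate estimates strictly exceeding `full_tree_estimate`.
#' Replicate RNG streams derive from `(seed, gene_id, replicate)`, so results
#' do not depend on evaluation order.
#'
#' @param alignment A `codon_alignment` containing all subtree taxa.
#' @param subtree A `phylo` tree (tips must be a subset of alignment taxa).
#' @param full_tree_estimate dN/dS observed on the full tree.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param gene_id Label mixed into replicate seeds (default "").
#' @return Proportion in `[0, 1]`; attribute `n_failed` counts replicates
#'   where estimation failed (dropped from the proportion).
#' @export
bootstrap_subtree_dnds <- function(alignment, subtree, full_tree_estimate,
                                   n_replicates = 100, seed = 1,
                                   gene_id = "") {
  stopifnot(inherits(alignment, "codon_alignment"), inherits(subtree, "phylo"))
  if (!all(subtree$tip.label %in% alignment$taxa))
    stop_invalid("subtree tips must be a subset of alignment taxa")
  n_cod <- alignment$length_codons
  sub_seqs <- alignment$sequences[match(subtree$tip.label, alignment$taxa)]
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  codons <- lapply(sub_seqs, function(s) substring(s, starts, starts + 2L))
  ## canonicalize column order (sites are exchangeable under the model) so
  ## the bootstrap result does not depend on the input column order
  key <- do.call(paste0, codons)
  ord <- order(key)
  codons <- lapply(codons, function(cc) cc[ord])
  ests <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- with_seed(derive_seed(seed, gene_id, r),
                      sample.int(n_cod, n_cod, replace = TRUE))
    seqs <- vapply(codons, function(cc) paste(cc[cols], collapse = ""),
                   character(1))
    names(seqs) <- subtree$tip.label
    fit <- try(estimate_dnds_ml(codon_alignment(seqs), subtree), silent = TRUE)
    if (!inherits(fit, "try-error")) ests[r] <- fit$params$omega
  }
  ok <- !is.na(ests)
  if (!any(ok)) stop_invalid("estimation failed in every bootstrap replicate")
  out <- mean(ests[ok] > full_tree_estimate)
  attr(out, "n_failed") <- sum(!ok)
  out
}
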