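## Gene gain/loss flux from presence/absence profiles: Fitch parsimony
## reconstruction of ancestral states (a transparent stand-in for ML
## stochastic-mapping reconstructions, whose output can also be ingested),
## then branch-by-branch counting of gains and losses normalized by tree
## length.

#' Gene presence/absence matrix
#'
#' @param states Binary matrix, genomes x families.
#' @param genome_ids,family_ids Unique identifiers.
#' @return An object of class `presence_absence_matrix`.
#' @export
presence_absence_matrix <- function(states, genome_ids = rownames(states),
                                    family_ids = colnames(states)) {
  states <- as.matrix(states)
  if (!all(states %in% c(0L, 1L)))
    stop_invalid("states must be strictly binary (0/1)")
  genome_ids <- genome_ids %||% sprintf("g%03d", seq_len(nrow(states)))
  family_ids <- family_ids %||% sprintf("F%05d", seq_len(ncol(states)))
  if (anyDuplicated(genome_ids) || anyDuplicated(family_ids))
    stop_invalid("genome and family ids must be unique")
  storage.mode(states) <- "integer"
  dimnames(states) <- list(genome_ids, family_ids)
  structure(list(genome_ids = as.character(genome_ids),
                 family_ids = as.character(family_ids), states = states),
            class = "presence_absence_matrix")
}

#' Ancestral states container
#'
#' Binary state of every family at every node of a tree (tips included).
#'
#' @param states Binary matrix, nodes x families.
#' @param node_ids Node identifiers (tips first, then internal nodes).
#' @param family_ids Family identifiers.
#' @return An object of class `ancestral_states`.
#' @export
ancestral_states <- function(states, node_ids, family_ids) {
  states <- as.matrix(states)
  if (!all(states %in% c(0L, 1L))) stop_invalid("states must be binary")
  storage.mode(states) <- "integer"
  dimnames(states) <- list(node_ids, family_ids)
  structure(list(node_ids = as.character(node_ids),
                 family_ids = as.character(family_ids), states = states),
            class = "ancestral_states")
}

## Stable node labels: tips keep their labels; internal nodes get existing
## node labels or "node<k>" by number.
node_id_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", ntip + seq_len(tree$Nnode))
  c(tree$tip.label, internal)
}

#' Reconstruct ancestral presence/absence states by Fitch parsimony
#'
#' Per family, the standard two-pass Fitch algorithm: the up-pass builds
#' candidate state sets bottom-up (intersection when non-empty, else union);
#' the down-pass assigns states top-down, resolving ambiguity at the root to
#' 1 (present) and elsewhere by inheriting the parent's state. This yields a
#' minimum-change assignment for every family.
#'
#' @param tree A rooted `phylo` tree.
#' @param pam A [presence_absence_matrix()] whose genome ids equal the tips.
#' @param method Reconstruction method; only `"parsimony"` is built in.
#' @return An [ancestral_states()] over all nodes (tips first).
#' @export
reconstruct_ancestral_states <- function(tree, pam, method = "parsimony") {
  stopifnot(inherits(tree, "phylo"), inherits(pam, "presence_absence_matrix"))
  method <- match.arg(method, "parsimony")
  if (!setequal(tree$tip.label, pam$genome_ids))
    stop_invalid("tip labels and genome ids differ")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  nf <- length(pam$family_ids)
  tips <- pam$states[match(tree$tip.label, pam$genome_ids), , drop = FALSE]
  ## state sets as 2-bit masks: 1 = {0}, 2 = {1}, 3 = {0,1}
  sets <- matrix(0L, nn, nf)
  sets[seq_len(ntip), ] <- tips + 1L
  po <- ape::postorder(tree)
  for (e in po) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    s <- sets[par, ]
    if (all(s == 0L)) { sets[par, ] <- sets[child, ]; next }
    inter <- bitwAnd(s, sets[child, ])
    uni <- bitwOr(s, sets[child, ])
    sets[par, ] <- ifelse(inter > 0L, inter, uni)
  }
  states <- matrix(NA_integer_, nn, nf)
  root <- ntip + 1L
  states[root, ] <- ifelse(sets[root, ] == 3L, 1L,
                           as.integer(sets[root, ] == 2L))
  for (e in rev(po)) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    s <- sets[child, ]
    states[child, ] <- ifelse(s == 3L, states[par, ],
                              as.integer(s == 2L))
  }
  ancestral_states(states, node_id_labels(tree), pam$family_ids)
}

#' Load externally reconstructed ancestral states
#'
#' Reads a node-by-family TSV (first column `node_id`, remaining columns one
#' per family) of binary states or presence probabilities; probabilities at
#' or above 0.5 map to present. The node set must cover every node of the
#' tree (by the same labels [reconstruct_ancestral_states()] writes).
#'
#' @param tree The corresponding `phylo` tree.
#' @param path Path to the TSV table.
#' @return An [ancestral_states()].
#' @export
load_external_ancestral_states <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "node_id") stop_invalid("first column must be node_id")
  expected <- node_id_labels(tree)
  missing <- setdiff(expected, df$node_id)
  if (length(missing))
    stop_invalid("ancestral-state table is missing node '%s'", missing[1])
  m <- as.matrix(df[match(expected, df$node_id), -1, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop_invalid("states must be binary or probabilities in [0, 1]")
  states <- ifelse(m >= 0.5, 1L, 0L)  # boundary 0.5 maps to present
  ancestral_states(states, expected, colnames(df)[-1])
}

#' Write ancestral states to TSV
#'
#' @param ancestral An [ancestral_states()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestral_states_tsv <- function(ancestral, path) {
  stopifnot(inherits(ancestral, "ancestral_states"))
  out <- cbind(data.frame(node_id = ancestral$node_ids,
                          stringsAsFactors = FALSE),
               as.data.frame(ancestral$states, optional = TRUE))
  colnames(out) <- c("node_id", ancestral$family_ids)
  write_tsv_file(out, path)
}

#' Compute gene gain/loss flux rates
#'
#' Traverses every branch of the rooted tree; per family, the change along a
#' branch is the child state minus the parent state — positive changes count
#' as gains, negative as losses. Totals over all families are normalized by
#' the total tree length; the overall flux is the ratio of gain rate to loss
#' rate (undefined, reported as `NA` with `flux_defined = FALSE`, when no
#' losses occurred).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param ancestral An [ancestral_states()] covering the tree.
#' @return An object of class `flux_rates`: `total_gains`, `total_losses`,
#'   `tree_length`, `gain_rate`, `loss_rate`, `flux_ratio`, `flux_defined`.
#' @export
compute_flux <- function(tree, ancestral) {
  stopifnot(inherits(tree, "phylo"), inherits(ancestral, "ancestral_states"))
  expected <- node_id_labels(tree)
  if (!all(expected %in% ancestral$node_ids))
    stop_invalid("ancestral states do not cover every tree node")
  st <- ancestral$states[match(expected, ancestral$node_ids), , drop = FALSE]
  delta <- st[tree$edge[, 2], , drop = FALSE] - st[tree$edge[, 1], , drop = FALSE]
  gains <- sum(delta > 0)
  losses <- sum(delta < 0)
  tl <- sum(tree$edge.length)
  if (tl <= 0) stop_invalid("tree must have positive total length")
  defined <- losses > 0
  structure(list(total_gains = gains, total_losses = losses,
                 tree_length = tl,
                 gain_rate = gains / tl, loss_rate = losses / tl,
                 flux_ratio = if (defined) gains / losses else NA_real_,
                 flux_defined = defined),
            class = "flux_rates")
}

#' @export
print.flux_rates <- function(x, ...) {
  cat(sprintf(paste0("flux_rates: %d gains, %d losses over tree length %.4g",
                     " -> gain %.4g, loss %.4g, flux %s\n"),
              x$total_gains, x$total_losses, x$tree_length, x$gain_rate,
              x$loss_rate,
              if (x$flux_defined) sprintf("%.4g", x$flux_ratio) else "undefined"))
  invisible(x)
}

#' Read / write presence/absence FASTA
#'
#' One record per genome; each sequence is a string of `'0'`/`'1'` characters,
#' one per gene family, with a companion TSV mapping column index to family
#' id.
#'
#' @param pam A [presence_absence_matrix()].
#' @param fasta_path Path of the FASTA file.
#' @param map_path Path of the companion column-map TSV (default: fasta path
#'   with a `.families.tsv` suffix).
#' @return `read_pam_fasta` returns a `presence_absence_matrix`;
#'   `write_pam_fasta` returns `fasta_path` invisibly.
#' @export
write_pam_fasta <- function(pam, fasta_path,
                            map_path = paste0(fasta_path, ".families.tsv")) {
  stopifnot(inherits(pam, "presence_absence_matrix"))
  seqs <- apply(pam$states, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(stats::setNames(seqs, pam$genome_ids))
  Biostrings::writeXStringSet(x, fasta_path)
  write_tsv_file(data.frame(column = seq_along(pam$family_ids),
                            family_id = pam$family_ids), map_path)
  invisible(fasta_path)
}

#' @rdname write_pam_fasta
#' @export
read_pam_fasta <- function(fasta_path,
                           map_path = paste0(fasta_path, ".families.tsv")) {
  x <- Biostrings::readBStringSet(fasta_path)
  seqs <- as.character(x)
  if (any(grepl("[^01]", seqs)))
    stop_invalid("presence/absence sequences must contain only 0 and 1")
  states <- do.call(rbind, lapply(strsplit(seqs, ""), as.integer))
  fam <- if (file.exists(map_path)) {
    utils::read.table(map_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)$family_id
  } else sprintf("F%05d", seq_len(ncol(states)))
  presence_absence_matrix(states, names(x), fam)
}
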