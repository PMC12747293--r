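## Independent oracles used across the suite. Each deliberately avoids the
## package's own code path for the quantity it checks.

## Exact least-squares solution of the two-way additive model on an
## incomplete matrix, by explicit normal equations over (F, R) with the last
## gene effect pinned to zero, then realigned to the mean(R) = 0 gauge.
oracle_two_way_ls <- function(values, observed) {
  nL <- nrow(values); nG <- ncol(values)
  cells <- which(observed, arr.ind = TRUE)
  y <- values[observed]
  p <- nL + nG - 1L  # R_nG pinned at 0 for identifiability
  X <- matrix(0, length(y), p)
  for (k in seq_along(y)) {
    X[k, cells[k, 1]] <- 1
    if (cells[k, 2] < nG) X[k, nL + cells[k, 2]] <- 1
  }
  b <- solve(crossprod(X), crossprod(X, y))
  F <- b[seq_len(nL)]
  R <- c(b[nL + seq_len(nG - 1L)], 0)
  shift <- mean(R)
  list(F = F + shift, R = R - shift)
}

## Brute-force Nei-Gojobori pairwise counts: recursion over all orderings of
## the differing positions, translation via Biostrings' genetic code table.
oracle_ng86_pair <- function(seq_a, seq_b) {
  gc_tab <- Biostrings::GENETIC_CODE
  translate1 <- function(cod) unname(gc_tab[cod])
  split_codons <- function(s) {
    n <- nchar(s) / 3
    substring(s, 3 * (1:n) - 2, 3 * (1:n))
  }
  syn_sites_codon <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      alt <- ch; alt[p] <- b; altc <- paste(alt, collapse = "")
      if (translate1(altc) != "*" && translate1(altc) == translate1(cod))
        s <- s + 1 / 3
    }
    s
  }
  count_paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(c(0, 0, 1))
    total_s <- 0; total_n <- 0; n_ok <- 0
    recurse <- function(cur, remaining, s, n) {
      if (!length(remaining)) {
        total_s <<- total_s + s; total_n <<- total_n + n; n_ok <<- n_ok + 1
        return(invisible())
      }
      for (p in remaining) {
        ch <- strsplit(cur, "")[[1]]
        ch[p] <- strsplit(to, "")[[1]][p]
        nxt <- paste(ch, collapse = "")
        if (translate1(nxt) == "*") next
        step_syn <- translate1(nxt) == translate1(cur)
        recurse(nxt, setdiff(remaining, p),
                s + as.numeric(step_syn), n + as.numeric(!step_syn))
      }
    }
    recurse(from, pos, 0, 0)
    if (n_ok == 0) return(c(0, length(pos), 1))
    c(total_s / n_ok, total_n / n_ok, n_ok)
  }
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  S_sites <- mean(c(sum(vapply(ca, syn_sites_codon, 0)),
                    sum(vapply(cb, syn_sites_codon, 0))))
  N_sites <- 3 * length(ca) - S_sites
  sd_tot <- 0; nd_tot <- 0
  for (k in seq_along(ca)) {
    d <- count_paths(ca[k], cb[k])
    sd_tot <- sd_tot + d[1]; nd_tot <- nd_tot + d[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dN = jc(nd_tot / N_sites), dS = jc(sd_tot / S_sites))
}

## Minimum parsimony change count by exhaustive enumeration over all binary
## assignments to internal nodes.
oracle_fitch_min <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nint)]
    full <- c(tip_states, internal)
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

## Maximum root-to-tip path length summed edge by edge via node paths.
oracle_tree_depth <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  dd <- ape::dist.nodes(tree)
  max(dd[root, seq_len(ntip)])
}

## Exhaustive split scan: every internal edge, tip partition from the clade
## below it, depths straight from the node distance matrix of the original
## tree (subtree A re-rooted at the edge's child; B keeps the original root).
oracle_best_split <- function(tree, min_tips, min_depth) {
  ntip <- length(tree$tip.label)
  dd <- ape::dist.nodes(tree)
  root <- ntip + 1
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    ## clade membership: tips whose path to the root passes through child
    tipsA <- seq_len(ntip)[abs(dd[root, seq_len(ntip)] -
                                 (dd[root, child] + dd[child, seq_len(ntip)])) < 1e-9]
    nA <- length(tipsA); nB <- ntip - nA
    if (nA < min_tips || nB < min_tips) next
    depth_A <- max(dd[child, tipsA])
    depth_B <- max(dd[root, setdiff(seq_len(ntip), tipsA)])
    if (depth_A <= min_depth || depth_B <= min_depth) next
    score <- min(nA, nB)
    if (is.null(best) || score > best$score)
      best <- list(edge = e, nA = nA, nB = nB, score = score)
  }
  best
}

## Caterpillar clade in Newick, n tips, every edge `blen`.
make_caterpillar <- function(n, prefix, blen) {
  s <- sprintf("%s1:%g", prefix, blen)
  for (i in 2:n) s <- sprintf("(%s,%s%d:%g):%g", s, prefix, i, blen, blen)
  s
}

rand_tree_quick <- function(n, seed, total = 1) random_tree(n, total, seed)
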