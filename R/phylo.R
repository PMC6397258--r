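# Prepare a pruned tree for repeated unweighted-UniFrac evaluation:
# postorder edge list, branch lengths, and the tip rows each edge subtends.
unifrac_prepare <- function(tree, tips) {
  tips <- unique(tips)
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss))
    stop("tip(s) absent from tree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  tr <- if (length(tips) < length(tree$tip.label))
    ape::keep.tip(tree, tips) else tree
  tr <- ape::reorder.phylo(tr, "postorder")
  list(tree = tr, ntip = length(tr$tip.label),
       nnode = tr$Nnode, edge = tr$edge, len = tr$edge.length,
       labels = tr$tip.label)
}

# Score for one A/B assignment over the prepared tree. in_a / in_b are
# logical vectors over prep$labels (a tip may be in both groups).
unifrac_score <- function(prep, in_a, in_b) {
  nv <- prep$ntip + prep$nnode
  hasA <- logical(nv); hasB <- logical(nv)
  hasA[seq_len(prep$ntip)] <- in_a
  hasB[seq_len(prep$ntip)] <- in_b
  # postorder guarantees children are visited before parents
  for (e in seq_len(nrow(prep$edge))) {
    p <- prep$edge[e, 1L]; ch <- prep$edge[e, 2L]
    hasA[p] <- hasA[p] || hasA[ch]
    hasB[p] <- hasB[p] || hasB[ch]
  }
  child <- prep$edge[, 2L]
  unique_edge <- xor(hasA[child], hasB[child])
  either <- hasA[child] | hasB[child]
  tot <- sum(prep$len[either])
  if (tot == 0) return(0)
  sum(prep$len[unique_edge]) / tot
}

#' Unweighted UniFrac distance between two tip communities
#'
#' Fraction of branch length leading exclusively to tips of one community,
#' over the branch length leading to either, on the tree pruned to the two
#' communities' tips. Symmetric in its arguments and invariant to uniform
#' rescaling of branch lengths; identical communities score 0.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param group_a,group_b non-empty character vectors of tip labels
#'   (overlap allowed; shared tips make their branches shared).
#' @return UniFrac score in \[0, 1\].
#' @export
unweighted_unifrac <- function(tree, group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("contract error: empty group")
  prep <- unifrac_prepare(tree, c(group_a, group_b))
  unifrac_score(prep, prep$labels %in% group_a, prep$labels %in% group_b)
}

#' Permutation test of phylogenetic signal in a module partition
#'
#' For each module pair (or an overall statistic), computes the observed
#' unweighted UniFrac score between the modules' tip sets and a null
#' distribution obtained by shuffling tip-to-module labels while holding
#' module sizes fixed; p = (1 + #\{null >= observed\}) / (1 + n_perm).
#' Modules with fewer than 2 tips on the tree are skipped with a warning.
#' The overall statistic is the mean of pairwise scores weighted by the
#' pooled (pruned-tree) branch length of each pair.
#'
#' @param tree rooted `phylo` tree whose tips are OTUs.
#' @param partition `module_partition` (or named module vector) assigning
#'   tree tips to modules; nodes absent from the tree are ignored.
#' @param n_perm number of label permutations (default 1000; must be >= 1).
#' @param mode `"pairwise"` (default) or `"overall"`.
#' @param seed integer seed.
#' @return data.frame: pair label, unifrac_score, p_value, n_permutations.
#' @export
unifrac_permutation_test <- function(tree, partition, n_perm = 1000,
                                     mode = c("pairwise", "overall"),
                                     seed = 1) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("config error: n_perm must be >= 1")
  membership <- if (inherits(partition, "module_partition"))
    partition$membership else partition
  membership <- membership[names(membership) %in% tree$tip.label]
  if (!length(membership)) stop("no partition nodes found among tree tips")
  sizes <- table(membership)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("module(s) with < 2 tips skipped: ",
            paste(small, collapse = ", "))
    membership <- membership[!membership %in% small]
  }
  mods <- sort(unique(membership))
  if (length(mods) < 2) stop("need at least 2 modules with >= 2 tips")
  set.seed(seed)
  if (mode == "pairwise") {
    pairs <- utils::combn(mods, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      tips <- names(membership)[membership %in% pr]
      prep <- unifrac_prepare(tree, tips)
      lab <- membership[prep$labels]
      obs <- unifrac_score(prep, lab == pr[1], lab == pr[2])
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        pl <- sample(lab)
        if (unifrac_score(prep, pl == pr[1], pl == pr[2]) >= obs - 1e-12)
          exceed <- exceed + 1L
      }
      data.frame(pair = paste(pr, collapse = "-"), unifrac_score = obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  # overall: branch-length-weighted mean of pairwise scores
  pairs <- utils::combn(mods, 2, simplify = FALSE)
  preps <- lapply(pairs, function(pr)
    unifrac_prepare(tree, names(membership)[membership %in% pr]))
  weights <- vapply(preps, function(p) sum(p$len), numeric(1))
  overall_stat <- function(mem) {
    sc <- vapply(seq_along(pairs), function(k) {
      pr <- pairs[[k]]; prep <- preps[[k]]
      lab <- mem[prep$labels]
      # tips outside the pair (possible under global shuffles) count as
      # belonging to neither group
      unifrac_score(prep, !is.na(lab) & lab == pr[1],
                    !is.na(lab) & lab == pr[2])
    }, numeric(1))
    sum(weights * sc) / sum(weights)
  }
  obs <- overall_stat(membership)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- membership
    names(perm) <- sample(names(membership))
    if (overall_stat(perm) >= obs - 1e-12) exceed <- exceed + 1L
  }
  data.frame(pair = "all", unifrac_score = obs,
             p_value = (1 + exceed) / (1 + n_perm),
             n_permutations = n_perm, stringsAsFactors = FALSE)
}

#' Cophenetic (path-length) distances between tree tips
#'
#' @param tree `phylo` tree with branch lengths.
#' @return symmetric distance matrix over tips.
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  as_distance_matrix(ape::cophenetic.phylo(tree))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance by
#' simultaneous row/column permutation of the second matrix (one-sided,
#' positive association), via [vegan::mantel()].
#'
#' @param d1,d2 distance matrices over the identical id set.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `r` and one-sided `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  d1 <- as_distance_matrix(d1)
  d2 <- as_distance_matrix(d2)
  sym_diff <- union(setdiff(rownames(d1), rownames(d2)),
                    setdiff(rownames(d2), rownames(d1)))
  if (length(sym_diff))
    stop("id mismatch between matrices: ",
         paste(utils::head(sym_diff, 10L), collapse = ", "))
  d2 <- d2[rownames(d1), rownames(d1)]
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                      method = "pearson", permutations = n_perm)
  list(r = unname(mt$statistic), p = unname(mt$signif))
}
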