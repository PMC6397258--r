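#' Construct a bipartite host-OTU network from an incidence matrix
#'
#' @param inc 0/1 incidence matrix, hosts in rows, OTUs in columns, with
#'   dimnames. Any positive entry is treated as a link.
#' @return object of class `bipartite_network`: a list with `hosts`, `otus`,
#'   `inc` (0/1 matrix), `m` (link count) and per-node degrees.
#' @export
bipartite_network <- function(inc) {
  if (!is.matrix(inc) || is.null(rownames(inc)) || is.null(colnames(inc)))
    stop("incidence matrix must carry host (row) and OTU (column) ids")
  if (length(intersect(rownames(inc), colnames(inc))))
    stop("host and OTU identifiers must not overlap")
  inc <- (inc > 0) + 0
  net <- list(hosts = rownames(inc), otus = colnames(inc), inc = inc,
              m = sum(inc), host_degree = rowSums(inc),
              otu_degree = colSums(inc))
  class(net) <- "bipartite_network"
  net
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite_network:", length(x$hosts), "hosts,", length(x$otus),
      "OTUs,", x$m, "links\n")
  invisible(x)
}

#' Build the host-OTU occurrence network
#'
#' A link between host species h and OTU o exists whenever o has a positive
#' count in at least one sponge sample of h (presence/absence; no weights).
#' OTUs with zero counts everywhere are dropped.
#'
#' @param table OTU table (samples x OTUs).
#' @param meta sample metadata mapping samples to host species.
#' @return a `bipartite_network`.
#' @export
build_network <- function(table, meta) {
  meta <- sample_metadata(meta)
  keep <- meta$sample_id[meta$sample_type == "sponge"]
  tab <- table[rownames(table) %in% keep, , drop = FALSE]
  host_of <- meta$host_species[match(rownames(tab), meta$sample_id)]
  bad <- rownames(tab)[is.na(host_of)]
  if (length(bad))
    stop("sample(s) lacking host species: ", paste(bad, collapse = ", "))
  pres <- rowsum((tab > 0) + 0, group = host_of)
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  bipartite_network(pres)
}

#' Construct a module partition object
#'
#' @param membership named integer vector, node id -> module id
#'   (dense 1..n_modules).
#' @param node_class named character vector (`"host"`/`"otu"`), same names.
#' @param Q Barber modularity of the partition (NA if unknown).
#' @return object of class `module_partition`.
#' @export
module_partition <- function(membership, node_class, Q = NA_real_) {
  stopifnot(length(membership) == length(node_class),
            all(names(membership) == names(node_class)))
  if (anyNA(membership)) stop("every node needs a module")
  p <- list(membership = membership, node_class = node_class, Q = Q,
            n_modules = length(unique(membership)))
  class(p) <- "module_partition"
  p
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", x$n_modules, "modules over",
      length(x$membership), "nodes; Q =", format(x$Q, digits = 6), "\n")
  invisible(x)
}

# Relabel modules densely 1..K in order of first appearance along the
# node vector; makes partitions comparable across runs.
canonical_membership <- function(membership) {
  f <- match(membership, unique(membership))
  names(f) <- names(membership)
  f
}

#' Barber bipartite modularity Q
#'
#' Q = (1/m) * sum over host-OTU pairs of (A_ho - k_h d_o / m) delta(g_h, g_o),
#' with A the occurrence indicator and k, d the host and OTU degrees. Summing
#' each unordered pair once with weight 1/m is identical to summing both
#' orientations of the symmetric adjacency with weight 1/(2m).
#'
#' @param net `bipartite_network`.
#' @param membership named module vector covering all nodes of `net`, or a
#'   `module_partition`.
#' @return Q in \[-1, 1\].
#' @export
barber_Q <- function(net, membership) {
  if (inherits(membership, "module_partition"))
    membership <- membership$membership
  nodes <- c(net$hosts, net$otus)
  miss <- setdiff(nodes, names(membership))
  if (length(miss))
    stop("contract error: node(s) missing from partition: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  rlab <- membership[net$hosts]
  clab <- membership[net$otus]
  labs <- unique(c(rlab, clab))
  r <- match(rlab, labs)
  co <- match(clab, labs)
  m <- net$m
  within <- sum(net$inc * outer(r, co, "=="))
  Ksum <- vapply(seq_along(labs),
                 function(s) sum(net$host_degree[r == s]), numeric(1))
  Dsum <- vapply(seq_along(labs),
                 function(s) sum(net$otu_degree[co == s]), numeric(1))
  within / m - sum(Ksum * Dsum) / m^2
}

#' Remove OTUs linked to a single host
#'
#' Degree-one OTUs cannot affect the optimal partition of the remaining
#' nodes (each is always placed in its sole partner's module), so they are
#' set aside before modularity search and reattached afterwards with
#' [reattach_pruned()].
#'
#' @param net `bipartite_network`.
#' @return list with the pruned `net` and `pruned`: named character vector,
#'   OTU id -> its sole host.
#' @export
prune_degree_one <- function(net) {
  singles <- net$otus[net$otu_degree == 1]
  if (!length(singles))
    return(list(net = net, pruned = stats::setNames(character(0), character(0))))
  pruned <- vapply(singles, function(o) net$hosts[net$inc[, o] > 0],
                   character(1))
  keep <- setdiff(net$otus, singles)
  list(net = bipartite_network(net$inc[, keep, drop = FALSE]),
       pruned = pruned)
}

#' Reattach pruned degree-one OTUs to their host's module
#'
#' @param partition `module_partition` on the pruned network.
#' @param pruned named character vector from [prune_degree_one()].
#' @param net optional full (unpruned) `bipartite_network`; when supplied, Q
#'   is recomputed on it for the extended partition.
#' @return extended `module_partition`.
#' @export
reattach_pruned <- function(partition, pruned, net = NULL) {
  if (!length(pruned)) return(partition)
  hosts <- unname(pruned)
  miss <- setdiff(hosts, names(partition$membership))
  if (length(miss))
    stop("contract error: pruned OTU host(s) absent from partition: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  add <- partition$membership[hosts]
  names(add) <- names(pruned)
  membership <- c(partition$membership, add)
  node_class <- c(partition$node_class,
                  stats::setNames(rep("otu", length(pruned)), names(pruned)))
  Q <- if (!is.null(net)) barber_Q(net, membership) else partition$Q
  module_partition(membership, node_class, Q = Q)
}

# One label-propagation + agglomeration run from a fixed RNG substream.
lpa_once <- function(net, seed) {
  set.seed(seed)
  inc <- net$inc
  nh <- length(net$hosts); no <- length(net$otus)
  kh <- unname(net$host_degree); ko <- unname(net$otu_degree)
  m <- net$m
  nlab <- nh                       # label universe: initial host labels
  rlab <- sample(seq_len(nh))      # unique labels, random assignment order
  clab <- integer(no)
  Ksum <- numeric(nlab); Dsum <- numeric(nlab)
  Ksum[rlab] <- kh
  eps <- 1e-12

  pick_best <- function(cand, score) {
    best <- which(score >= max(score) - eps)
    cand[best[sample.int(length(best), 1L)]]
  }

  # initial OTU labels: best single-node placement given unique host labels
  for (j in seq_len(no)) {
    nb <- which(inc[, j] > 0)
    if (!length(nb)) { clab[j] <- 0L; next }
    cand <- unique(rlab[nb])
    score <- vapply(cand, function(s)
      sum(inc[nb, j][rlab[nb] == s]) / m - ko[j] * Ksum[s] / m^2, numeric(1))
    clab[j] <- pick_best(cand, score)
    Dsum[clab[j]] <- Dsum[clab[j]] + ko[j]
  }

  sweep_class <- function() {
    improved <- FALSE
    # rows (hosts)
    for (i in sample(seq_len(nh))) {
      nb <- which(inc[i, ] > 0)
      if (!length(nb)) next
      cand <- unique(c(rlab[i], clab[nb]))
      cand <- cand[cand > 0L]
      cnt <- vapply(cand, function(s) sum(clab[nb] == s), numeric(1))
      score <- cnt / m - kh[i] * Dsum[cand] / m^2
      new <- pick_best(cand, score)
      if (new != rlab[i] &&
          score[match(new, cand)] > score[match(rlab[i], cand)] + eps) {
        Ksum[rlab[i]] <<- Ksum[rlab[i]] - kh[i]
        Ksum[new] <<- Ksum[new] + kh[i]
        rlab[i] <<- new
        improved <- TRUE
      }
    }
    # columns (OTUs)
    for (j in sample(seq_len(no))) {
      nb <- which(inc[, j] > 0)
      if (!length(nb)) next
      cand <- unique(c(clab[j], rlab[nb]))
      cand <- cand[cand > 0L]
      cnt <- vapply(cand, function(s) sum(rlab[nb] == s), numeric(1))
      score <- cnt / m - ko[j] * Ksum[cand] / m^2
      new <- pick_best(cand, score)
      if (new != clab[j] &&
          score[match(new, cand)] > score[match(clab[j], cand)] + eps) {
        Dsum[clab[j]] <<- Dsum[clab[j]] - ko[j]
        Dsum[new] <<- Dsum[new] + ko[j]
        clab[j] <<- new
        improved <- TRUE
      }
    }
    improved
  }

  merge_phase <- function() {
    # test merging every pair of occupied modules; keep Q-raising merges
    merged <- FALSE
    repeat {
      labs <- sort(unique(c(rlab, clab)))
      labs <- labs[labs > 0L]
      if (length(labs) < 2L) break
      L <- length(labs)
      r_idx <- lapply(labs, function(s) which(rlab == s))
      c_idx <- lapply(labs, function(s) which(clab == s))
      E <- matrix(0, L, L)   # cross-links rows(a) x cols(b)
      for (a in seq_len(L)) {
        if (!length(r_idx[[a]])) next
        sub <- inc[r_idx[[a]], , drop = FALSE]
        for (b in seq_len(L))
          if (length(c_idx[[b]]))
            E[a, b] <- sum(sub[, c_idx[[b]], drop = FALSE])
      }
      # zero-gain merges are accepted: equal-Q partitions with fewer
      # modules are preferred
      bestgain <- -eps; bi <- 0L; bj <- 0L
      for (a in seq_len(L)) for (b in seq_len(L)) {
        if (a >= b) next
        s <- labs[a]; t2 <- labs[b]
        gain <- (E[a, b] + E[b, a]) / m -
          (Ksum[s] * Dsum[t2] + Ksum[t2] * Dsum[s]) / m^2
        if (gain > bestgain) { bestgain <- gain; bi <- s; bj <- t2 }
      }
      if (bi == 0L) break
      rlab[rlab == bj] <<- bi
      clab[clab == bj] <<- bi
      Ksum[bi] <<- Ksum[bi] + Ksum[bj]; Ksum[bj] <<- 0
      Dsum[bi] <<- Dsum[bi] + Dsum[bj]; Dsum[bj] <<- 0
      merged <- TRUE
    }
    merged
  }

  repeat {
    repeat if (!sweep_class()) break
    if (!merge_phase()) break
  }

  # isolated nodes (degree 0) keep private labels; give any label-0 column
  # its own fresh module
  if (any(clab == 0L)) {
    zero <- which(clab == 0L)
    clab[zero] <- nlab + seq_along(zero)
  }
  membership <- c(stats::setNames(rlab, net$hosts),
                  stats::setNames(clab, net$otus))
  membership <- canonical_membership(membership)
  list(membership = membership, Q = barber_Q(net, membership))
}

#' Find network modules by maximising Barber's bipartite modularity
#'
#' Label-propagation in the spirit of LPAwb+: one node class starts with
#' unique labels, nodes adopt the neighbouring-module label that maximally
#' increases Q (sweep order shuffled, equal-gain ties broken uniformly at
#' random), classes alternate until no single-node move improves Q; an
#' agglomeration phase then tests merging module pairs and keeps Q-raising
#' merges, after which propagation resumes until neither phase improves Q.
#' The best of `n_restarts` independent restarts is returned; restart ties
#' are broken by fewest modules, then lexicographic canonical labels.
#'
#' @param net `bipartite_network`.
#' @param n_restarts number of random restarts (default 20).
#' @param seed integer seed; fixes sweep orders and tie-breaks, making the
#'   result reproducible.
#' @return a `module_partition` with its Barber Q.
#' @export
find_modules <- function(net, n_restarts = 20, seed = 1) {
  if (net$m == 0) stop("empty network: no links to partition")
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- lpa_once(net, seeds[r])
    if (is.null(best)) { best <- res; next }
    if (res$Q > best$Q + 1e-12) { best <- res; next }
    if (abs(res$Q - best$Q) <= 1e-12) {
      nr <- length(unique(res$membership)); nb <- length(unique(best$membership))
      if (nr < nb ||
          (nr == nb && paste(res$membership, collapse = ",") <
                       paste(best$membership, collapse = ","))) best <- res
    }
  }
  node_class <- stats::setNames(
    c(rep("host", length(net$hosts)), rep("otu", length(net$otus))),
    c(net$hosts, net$otus))
  module_partition(best$membership, node_class[names(best$membership)],
                   Q = best$Q)
}

#' Per-module composition summary
#'
#' @param partition `module_partition`.
#' @param traits optional host-trait table (HMA/LMA).
#' @param meta optional sample metadata; temperature distributions are
#'   summarised over sponge samples of each module's member hosts.
#' @return data.frame with one row per module: host and OTU counts, HMA/LMA
#'   composition (percentages rounded to two decimals; NA when no member
#'   host is classified) and temperature mean/sd.
#' @export
module_summary <- function(partition, traits = NULL, meta = NULL) {
  mods <- sort(unique(partition$membership))
  out <- lapply(mods, function(s) {
    ids <- names(partition$membership)[partition$membership == s]
    hosts <- ids[partition$node_class[ids] == "host"]
    otus <- ids[partition$node_class[ids] == "otu"]
    n_hma <- n_lma <- NA_integer_; pct_hma <- NA_real_
    if (!is.null(traits)) {
      tt <- traits$host_type[match(hosts, traits$host_species)]
      n_hma <- sum(tt == "HMA", na.rm = TRUE)
      n_lma <- sum(tt == "LMA", na.rm = TRUE)
      n_cl <- n_hma + n_lma
      pct_hma <- if (n_cl > 0) round(100 * n_hma / n_cl, 2) else NA_real_
    }
    temp_mean <- temp_sd <- NA_real_
    if (!is.null(meta)) {
      tv <- meta$temperature[meta$sample_type == "sponge" &
                             meta$host_species %in% hosts]
      tv <- tv[!is.na(tv)]
      if (length(tv)) {
        temp_mean <- mean(tv)
        temp_sd <- stats::sd(tv)
      }
    }
    data.frame(module_id = s, n_hosts = length(hosts), n_otus = length(otus),
               n_hma = n_hma, n_lma = n_lma, pct_hma = pct_hma,
               temp_mean = temp_mean, temp_sd = temp_sd)
  })
  do.call(rbind, out)
}

#' Normalised mutual information between two partitions
#'
#' NMI with arithmetic-mean normalisation, 2 I(a;b) / (H(a) + H(b));
#' 1 means identical partitions up to relabelling.
#'
#' @param a,b module labels over the same nodes; if named, aligned by name.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  hx <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hy <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (hx + hy == 0) return(1)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pi_, pj_)), 0))
  2 * mi / (hx + hy)
}

# Derive n reproducible substream seeds (< 2^31) from one integer seed,
# so adding consumers never perturbs earlier draws.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
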