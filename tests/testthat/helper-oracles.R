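# Independent oracles and fixture builders shared across tests.

# Brute-force double-loop evaluation of bipartite modularity:
# Q = (1/m) sum_{i in hosts, j in otus} (A_ij - k_i d_j / m) delta(g_i, g_j)
brute_force_Q <- function(inc, membership) {
  k <- rowSums(inc)
  d <- colSums(inc)
  m <- sum(inc)
  q <- 0
  for (i in seq_len(nrow(inc))) {
    for (j in seq_len(ncol(inc))) {
      if (membership[rownames(inc)[i]] == membership[colnames(inc)[j]])
        q <- q + inc[i, j] - k[i] * d[j] / m
    }
  }
  unname(q / m)
}

# All set partitions of n items as restricted growth strings (rows).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(0), 0L)
  do.call(rbind, out)
}

# Exhaustive-enumeration optimum of Barber Q over every partition of the
# network's nodes (feasible for <= 10 nodes).
exhaustive_best_Q <- function(inc) {
  nodes <- c(rownames(inc), colnames(inc))
  parts <- all_partitions(length(nodes))
  k <- rowSums(inc); d <- colSums(inc); m <- sum(inc)
  nh <- nrow(inc)
  best <- -Inf
  for (r in seq_len(nrow(parts))) {
    g <- parts[r, ]
    gr <- g[seq_len(nh)]; gc <- g[nh + seq_len(ncol(inc))]
    within <- sum(inc * outer(gr, gc, "=="))
    labs <- unique(g)
    Ks <- vapply(labs, function(s) sum(k[gr == s]), numeric(1))
    Ds <- vapply(labs, function(s) sum(d[gc == s]), numeric(1))
    q <- within / m - sum(Ks * Ds) / m^2
    if (q > best) best <- q
  }
  best
}

# Random bipartite incidence with guaranteed positive degree everywhere.
random_incidence <- function(nh, no, p = 0.5) {
  repeat {
    inc <- matrix(rbinom(nh * no, 1, p), nh, no,
                  dimnames = list(paste0("H", seq_len(nh)),
                                  paste0("O", seq_len(no))))
    if (all(rowSums(inc) > 0) && all(colSums(inc) > 0)) return(inc)
  }
}

random_membership <- function(inc, k) {
  nodes <- c(rownames(inc), colnames(inc))
  stats::setNames(sample.int(k, length(nodes), replace = TRUE), nodes)
}

# Weighted Pearson correlation (oracle for the group-equalised r.g).
weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# Small deterministic OTU table + metadata for filter tests.
toy_dataset <- function() {
  counts <- rbind(
    A1 = c(otu1 = 12000, otu2 = 2, otu3 = 0, otu4 = 3),
    A2 = c(11000, 0, 5, 1),
    A3 = c(10500, 4, 6, 0),
    B1 = c(0, 10800, 7, 2),
    B2 = c(3, 11500, 0, 1),
    B3 = c(0, 12500, 9, 4))
  meta <- data.frame(
    sample_id = rownames(counts), sample_type = "sponge",
    host_species = rep(c("spA", "spB"), each = 3),
    health_status = "healthy", life_stage = "adult",
    taxonomic_id_unequivocal = TRUE, read_count = rowSums(counts),
    stringsAsFactors = FALSE)
  list(table = otu_table(counts), meta = meta)
}
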