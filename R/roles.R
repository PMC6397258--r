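#' Within-module degree z-score
#'
#' z_i = (k_i - mean(k)) / sd(k), where k_i is the number of links node i
#' has to nodes inside its own module and mean/sd are taken over the
#' normalisation group within that module using the population standard
#' deviation (Guimera-Amaral convention). Modules whose group has sd = 0
#' map to z = 0 ("indistinguishable from the module mean").
#'
#' @param net `bipartite_network`.
#' @param partition `module_partition` covering all nodes.
#' @param normalisation `"same-class"` (default; hosts normalised against
#'   hosts of the module, OTUs against OTUs) or `"all-nodes"` (against all
#'   module members regardless of class; degree scales differ by class in
#'   bipartite graphs, hence the default).
#' @return named numeric vector of z over all nodes.
#' @export
within_module_degree_z <- function(net, partition,
                                   normalisation = c("same-class",
                                                     "all-nodes")) {
  normalisation <- match.arg(normalisation)
  km <- within_module_links(net, partition)
  membership <- partition$membership[names(km)]
  cls <- partition$node_class[names(km)]
  grp <- if (normalisation == "same-class")
    paste(membership, cls) else as.character(membership)
  z <- km
  for (g in unique(grp)) {
    idx <- grp == g
    mu <- mean(km[idx])
    sdev <- sqrt(mean((km[idx] - mu)^2))   # population sd
    z[idx] <- if (sdev > 0) (km[idx] - mu) / sdev else 0
  }
  z
}

# Links of every node to nodes inside its own module.
within_module_links <- function(net, partition) {
  membership <- partition$membership
  miss <- setdiff(c(net$hosts, net$otus), names(membership))
  if (length(miss))
    stop("contract error: partition misses node(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  rlab <- membership[net$hosts]
  clab <- membership[net$otus]
  same <- outer(rlab, clab, "==") * net$inc
  c(rowSums(same), colSums(same))
}

# Links of every node split by the module of the opposite endpoint;
# returns a node x module matrix.
links_by_module <- function(net, partition) {
  membership <- partition$membership
  rlab <- membership[net$hosts]
  clab <- membership[net$otus]
  mods <- sort(unique(membership))
  nh <- length(net$hosts); no <- length(net$otus)
  ks <- matrix(0, nh + no, length(mods),
               dimnames = list(c(net$hosts, net$otus), mods))
  for (si in seq_along(mods)) {
    s <- mods[si]
    ks[seq_len(nh), si] <- rowSums(net$inc[, clab == s, drop = FALSE])
    ks[nh + seq_len(no), si] <- colSums(net$inc[rlab == s, , drop = FALSE])
  }
  ks
}

#' Participation coefficient
#'
#' P_i = 1 - sum_s (k_is / k_i)^2 over all modules s, where k_is is the
#' number of links node i has into module s and k_i its total degree
#' (equivalently 1 minus the Herfindahl concentration of the node's
#' module-link distribution). P = 0 means all links inside one module.
#'
#' @inheritParams within_module_degree_z
#' @return named numeric vector of P over all nodes.
#' @export
participation_coefficient <- function(net, partition) {
  deg <- c(net$host_degree, net$otu_degree)
  if (any(deg == 0))
    stop("contract error: isolated node(s): ",
         paste(utils::head(names(deg)[deg == 0], 5L), collapse = ", "))
  ks <- links_by_module(net, partition)
  1 - rowSums((ks / deg[rownames(ks)])^2)
}

#' Full connectivity profile per node
#'
#' @inheritParams within_module_degree_z
#' @return data.frame: node_id, node_class, degree, within_module_links,
#'   within_ratio (fraction of links inside own module), z, P.
#' @export
node_role_profiles <- function(net, partition,
                               normalisation = c("same-class",
                                                 "all-nodes")) {
  deg <- c(net$host_degree, net$otu_degree)
  km <- within_module_links(net, partition)
  z <- within_module_degree_z(net, partition, normalisation)
  P <- participation_coefficient(net, partition)
  ids <- names(deg)
  data.frame(node_id = ids, node_class = partition$node_class[ids],
             module_id = partition$membership[ids],
             degree = unname(deg),
             within_module_links = unname(km[ids]),
             within_ratio = unname(km[ids] / deg),
             z = unname(z[ids]), P = unname(P[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify node roles from z and P
#'
#' A node is a provincial hub iff z > z_hub and P < p_provincial (both
#' strict). The remaining combinations get descriptive Guimera-Amaral-style
#' labels: connector_hub (z > z_hub, P >= p_provincial), peripheral
#' (z <= z_hub, P < p_provincial), connector (z <= z_hub,
#' P >= p_provincial).
#'
#' @param profiles data.frame from [node_role_profiles()] (needs z and P).
#' @param z_hub hub threshold on z (default 2.5).
#' @param p_provincial provinciality threshold on P (default 0.3).
#' @return `profiles` with a `role` column appended.
#' @export
classify_roles <- function(profiles, z_hub = 2.5, p_provincial = 0.3) {
  hub <- profiles$z > z_hub
  prov <- profiles$P < p_provincial
  profiles$role <- ifelse(hub & prov, "provincial_hub",
                   ifelse(hub, "connector_hub",
                   ifelse(prov, "peripheral", "connector")))
  profiles
}

#' Host connectivity-profile table
#'
#' Per host node: degree, ratio of intra- to extra-module links (Inf when
#' all links are internal, flagged), and the fraction of its own module's
#' OTUs it is connected to.
#'
#' @inheritParams within_module_degree_z
#' @return data.frame per host: degree, within_module_links,
#'   extra_module_links, within_extra_ratio, all_links_internal flag,
#'   own_module_reach.
#' @export
within_ratio_table <- function(net, partition) {
  km <- within_module_links(net, partition)[net$hosts]
  deg <- net$host_degree
  extra <- deg - km
  membership <- partition$membership
  otus_per_module <- table(membership[net$otus])
  own <- as.vector(otus_per_module[as.character(membership[net$hosts])])
  own[is.na(own)] <- 0
  data.frame(node_id = net$hosts,
             degree = unname(deg),
             within_module_links = unname(km),
             extra_module_links = unname(extra),
             within_extra_ratio = unname(ifelse(extra > 0, km / extra, Inf)),
             all_links_internal = unname(extra == 0),
             own_module_reach = unname(ifelse(own > 0, km / own, NA_real_)),
             stringsAsFactors = FALSE, row.names = NULL)
}
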