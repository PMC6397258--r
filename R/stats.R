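#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum(min(x_i, y_i)) / sum(x_i + y_i), computed with
#' [vegan::vegdist()]. Rows may optionally be aggregated to host species
#' (mean of per-sample relative abundances) before the distance is taken.
#'
#' @param x non-negative abundance matrix, units in rows.
#' @param meta sample metadata; required when `aggregate_by =
#'   "host_species"`.
#' @param aggregate_by `"sample"` (default; rows used as-is) or
#'   `"host_species"`.
#' @return symmetric distance matrix.
#' @export
bray_curtis <- function(x, meta = NULL,
                        aggregate_by = c("sample", "host_species")) {
  aggregate_by <- match.arg(aggregate_by)
  if (aggregate_by == "host_species") {
    if (is.null(meta)) stop("meta required to aggregate by host species")
    meta <- sample_metadata(meta)
    sp <- meta$host_species[match(rownames(x), meta$sample_id)]
    if (anyNA(sp)) stop("all rows must map to a host species")
    rel <- sweep(x, 1, rowSums(x), "/")
    x <- rowsum(rel, group = sp) / as.vector(table(sp)[sort(unique(sp))])
  }
  zero <- rownames(x)[rowSums(x) == 0]
  if (length(zero))
    stop("all-zero row(s): ", paste(zero, collapse = ", "))
  as_distance_matrix(as.matrix(vegan::vegdist(x, method = "bray")))
}

# Pseudo-F and R2 from a squared-distance matrix and an integer group index.
permanova_F <- function(d2, g) {
  n <- nrow(d2)
  a <- length(unique(g))
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    sub <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssa <- sst - ssw
  Fv <- (ssa / (a - 1)) / (ssw / (n - a))
  c(F = Fv, R2 = ssa / sst, SST = sst, SSW = ssw)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the distance-based sums of squares:
#' SS_T = (1/n) sum_{i<j} d_ij^2, SS_W summed per group with weight 1/n_g,
#' SS_A = SS_T - SS_W, pseudo-F = (SS_A/(a-1)) / (SS_W/(n-a)). Significance
#' by free permutation of group labels, p = (1 + #\{F_null >= F_obs\}) /
#' (1 + n_perm), so p is never exactly zero.
#'
#' @param d distance matrix.
#' @param groups group label per row of `d`; if named, aligned by id.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return one-row data.frame: comparison, statistic (pseudo-F), R2, p_raw,
#'   p_adjusted (NA here), correction, n_permutations.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_distance_matrix(d)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  if (length(groups) != nrow(d)) stop("groups must match rows of d")
  g <- as.integer(factor(groups))
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("singleton group(s) make pseudo-F infinite: ",
         paste(names(table(groups))[table(groups) < 2], collapse = ", "))
  d2 <- d^2
  obs <- permanova_F(d2, g)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (permanova_F(d2, sample(g))["F"] >= obs["F"]) exceed <- exceed + 1L
  }
  data.frame(comparison = paste(sort(unique(as.character(groups))),
                                collapse = " vs "),
             statistic = unname(obs["F"]), R2 = unname(obs["R2"]),
             p_raw = (1 + exceed) / (1 + n_perm), p_adjusted = NA_real_,
             correction = "none", n_permutations = n_perm,
             stringsAsFactors = FALSE)
}

#' Pairwise PERMANOVA with FDR correction
#'
#' Runs [permanova()] on every pair of groups (submatrix of `d`) and
#' adjusts the raw p-values over the family of pairs by the selected
#' procedure (Benjamini-Yekutieli by default, as appropriate under
#' arbitrary dependence; Benjamini-Hochberg optionally).
#'
#' @inheritParams permanova
#' @param correction `"BY"` (default) or `"BH"`.
#' @return data.frame, one row per pair (failed pairs carried as NA rows).
#' @export
pairwise_permanova <- function(d, groups, correction = c("BY", "BH"),
                               n_perm = 999, seed = 1) {
  correction <- match.arg(correction)
  d <- as_distance_matrix(d)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  seeds <- derive_seeds(seed, length(pairs))
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    idx <- groups %in% pr
    out <- tryCatch(
      permanova(d[idx, idx, drop = FALSE], groups[idx], n_perm = n_perm,
                seed = seeds[k]),
      error = function(e)
        data.frame(comparison = paste(pr, collapse = " vs "),
                   statistic = NA_real_, R2 = NA_real_, p_raw = NA_real_,
                   p_adjusted = NA_real_, correction = "none",
                   n_permutations = n_perm, stringsAsFactors = FALSE))
    out
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = correction)
  res$correction <- correction
  res
}

#' Homogeneity of multivariate dispersion
#'
#' Wraps [vegan::betadisper()] (centroid type: distances are measured to
#' group centroids in the PCoA embedding, negative-eigenvalue axes
#' included with imaginary-part correction) and its permutation test.
#'
#' @param d distance matrix.
#' @param groups group label per row of `d`; named vectors aligned by id.
#' @param n_perm permutations for the homogeneity test (default 999).
#' @param seed integer seed.
#' @return list: `dispersion` (named mean distance-to-centroid per group),
#'   `distances` (per-unit distance to own-group centroid), `F`, `p`.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_distance_matrix(d)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  if (any(table(groups) < 2)) stop("groups of size >= 2 required")
  if (max(d) == 0) stop("degenerate input: all points identical")
  bd <- vegan::betadisper(stats::as.dist(d), group = factor(groups),
                          type = "centroid")
  set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm)
  disp <- tapply(bd$distances, groups, mean)
  list(dispersion = stats::setNames(as.numeric(disp), names(disp)),
       distances = stats::setNames(bd$distances, rownames(d)),
       F = unname(pt$tab$F[1L]),
       p = unname(pt$tab$`Pr(>F)`[1L]))
}

#' Principal coordinate analysis
#'
#' Gower-centred double-centering of -d^2/2 followed by
#' eigendecomposition. Coordinates are returned for positive-eigenvalue
#' axes; all eigenvalues (including negative ones) are reported.
#'
#' @param d distance matrix.
#' @return list: `points` (units x axes), `eigenvalues` (all, decreasing).
#' @export
pcoa <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(pts) <- rownames(d)
  if (length(pos)) colnames(pts) <- paste0("Axis", seq_along(pos))
  list(points = pts, eigenvalues = e$values)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b non-empty numeric samples.
#' @return list with `D` (sup ECDF difference) and asymptotic `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Nemenyi all-pairs rank comparison
#'
#' Joint ranking of all values (ties averaged), mean rank per group, and
#' pairwise comparison of mean-rank differences against the studentized
#' range distribution, with tie correction of the rank variance.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups, >= 2 members each).
#' @return symmetric matrix of pairwise p-values.
#' @export
nemenyi_ranks <- function(values, groups) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  k <- length(levs)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 members")
  n <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)[levs]
  sizes <- table(groups)[levs]
  tie_sizes <- table(r)
  C <- 1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n)
  p <- matrix(1, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- C * n * (n + 1) / 12 * (1 / sizes[i] + 1 / sizes[j])
    if (v <= 0) { p[i, j] <- p[j, i] <- 1; next }
    q <- abs(mean_rank[i] - mean_rank[j]) / sqrt(v) * sqrt(2)
    p[i, j] <- p[j, i] <- stats::ptukey(q, nmeans = k, df = Inf,
                                        lower.tail = FALSE)
  }
  p
}

# Group-equalised point-biserial correlation: weighted Pearson correlation
# between feature x and the indicator of group k, with each sample weighted
# 1/n_{g(i)} so every group contributes equal total weight.
r_g <- function(x, groups, target) {
  ind <- as.numeric(groups == target)
  w <- 1 / as.vector(table(groups)[groups])
  w <- w / sum(w)
  mx <- sum(w * x); mi <- sum(w * ind)
  vx <- sum(w * (x - mx)^2); vi <- sum(w * (ind - mi)^2)
  if (vx <= 0 || vi <= 0) return(0)
  sum(w * (x - mx) * (ind - mi)) / sqrt(vx * vi)
}

#' Indicator analysis with group-equalised point-biserial correlation
#'
#' For each feature x group, computes r.g, the point-biserial correlation
#' between feature abundance and group membership with samples reweighted
#' so that unequal group sizes contribute equally. Significance by
#' permutation of group labels (one-sided, association at least as strong),
#' adjusted across the feature x group family by Benjamini-Hochberg.
#'
#' @param features non-negative matrix, samples x features.
#' @param groups group label per sample (>= 2 groups).
#' @param n_perm permutations (default 999).
#' @param correction p-adjustment method (default "BH").
#' @param seed integer seed.
#' @return data.frame per feature x group: statistic (r.g), p_raw,
#'   p_adjusted, and a `constant` flag for zero-variance features
#'   (r.g = 0, p = 1).
#' @export
indicator_analysis <- function(features, groups, n_perm = 999,
                               correction = "BH", seed = 1) {
  if (any(features < 0)) stop("features must be non-negative")
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) < 2) stop("need at least 2 groups")
  nf <- ncol(features)
  const <- apply(features, 2, function(x) stats::var(x) == 0)
  obs <- matrix(0, nf, length(levs),
                dimnames = list(colnames(features), levs))
  for (k in levs) obs[, k] <- apply(features, 2, r_g, groups = groups,
                                    target = k)
  obs[const, ] <- 0
  set.seed(seed)
  exceed <- matrix(0L, nf, length(levs))
  for (b in seq_len(n_perm)) {
    gp <- sample(groups)
    for (ki in seq_along(levs)) {
      rp <- apply(features, 2, r_g, groups = gp, target = levs[ki])
      exceed[, ki] <- exceed[, ki] + (rp >= obs[, ki] - 1e-12)
    }
  }
  p_raw <- (1 + exceed) / (1 + n_perm)
  p_raw[const, ] <- 1
  out <- data.frame(
    feature = rep(rownames(obs), times = length(levs)),
    group = rep(levs, each = nf),
    statistic = as.vector(obs),
    p_raw = as.vector(p_raw),
    constant = rep(const, times = length(levs)),
    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = correction)
  out$correction <- correction
  out$n_permutations <- n_perm
  out
}
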