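# Community fingerprint (T-RFLP / ARISA) analysis chain: peak filtering,
# fragment alignment, relative-abundance normalisation, square-root
# transformed Bray-Curtis similarities, diversity indices, and the
# permutation machinery (ANOSIM, SIMPER, SIMPROF-flagged clustering).

#' Size windows conventionally analysed per fingerprint marker
#' @param marker "TRF" or "ARISA".
#' @return length-2 numeric window in nucleotides (50--500 for terminal
#'   restriction fragments, 94--827 for ARISA fragments).
#' @export
marker_size_window <- function(marker = c("TRF", "ARISA")) {
  switch(match.arg(marker), TRF = c(50, 500), ARISA = c(94, 827))
}

#' Construct a fingerprint profile
#'
#' @param sample_id sample label.
#' @param peaks data.frame with columns `size_nt`, `height`, `area`.
#' @param marker "TRF" or "ARISA" (sets the default size window).
#' @param size_window length-2 numeric; valid fragment sizes (nt).
#' @return A `fingerprint_profile`.
#' @export
fingerprint_profile <- function(sample_id, peaks, marker = c("TRF", "ARISA"),
                                size_window = NULL) {
  marker <- match.arg(marker)
  if (is.null(size_window)) size_window <- marker_size_window(marker)
  peaks <- as.data.frame(peaks)[, c("size_nt", "height", "area")]
  if (any(peaks$height < 0) || any(peaks$area < 0))
    stop("peak heights and areas must be non-negative")
  structure(list(sample_id = sample_id, peaks = peaks, marker = marker,
                 size_window = size_window),
            class = "fingerprint_profile")
}

#' Remove noise peaks from a fingerprint profile
#'
#' Only peaks with height strictly greater than `min_height` fluorescence
#' units are analysed (the electropherogram noise floor), and only peaks
#' inside the marker's size window.
#'
#' @param profile a `fingerprint_profile`.
#' @param min_height noise cutoff in fluorescence units (default 50;
#'   survival requires height > 50).
#' @return the filtered profile; empty results are allowed but warned
#'   about.
#' @export
filter_peaks <- function(profile, min_height = 50) {
  p <- profile$peaks
  keep <- p$height > min_height &
    p$size_nt >= profile$size_window[1L] &
    p$size_nt <= profile$size_window[2L]
  profile$peaks <- p[keep, , drop = FALSE]
  rownames(profile$peaks) <- NULL
  if (nrow(profile$peaks) == 0L)
    warning("no peaks survive filtering in sample ", profile$sample_id)
  profile
}

# Merge peaks within one sample that fall inside the confidence interval:
# ascending size, a peak joins the open cluster iff its size is within
# `tol` of the cluster's running-mean size; areas and heights are summed.
merge_within_sample <- function(peaks, tol = 0.5) {
  if (nrow(peaks) == 0L) return(peaks)
  o <- order(peaks$size_nt)
  peaks <- peaks[o, , drop = FALSE]
  sizes <- heights <- areas <- numeric(0)
  cl_sum <- peaks$size_nt[1L]; cl_n <- 1L
  cl_h <- peaks$height[1L]; cl_a <- peaks$area[1L]
  flush <- function() {
    sizes <<- c(sizes, cl_sum / cl_n)
    heights <<- c(heights, cl_h); areas <<- c(areas, cl_a)
  }
  for (i in seq_len(nrow(peaks))[-1L]) {
    if (abs(peaks$size_nt[i] - cl_sum / cl_n) < tol) {
      cl_sum <- cl_sum + peaks$size_nt[i]; cl_n <- cl_n + 1L
      cl_h <- cl_h + peaks$height[i]; cl_a <- cl_a + peaks$area[i]
    } else {
      flush()
      cl_sum <- peaks$size_nt[i]; cl_n <- 1L
      cl_h <- peaks$height[i]; cl_a <- peaks$area[i]
    }
  }
  flush()
  data.frame(size_nt = sizes, height = heights, area = areas)
}

#' Align fragment peaks across samples into consensus bins
#'
#' Two-pass alignment with a fixed confidence interval (default 0.5 nt):
#' first, peaks within each sample closer than the interval are merged
#' (areas summed); then consensus bins are grown over all samples'
#' peaks in ascending size order — a peak joins an existing bin iff its
#' size differs from the bin's running-mean consensus by less than the
#' interval, otherwise it opens a new bin.  Deterministic.
#'
#' @param profiles list of (filtered) `fingerprint_profile`s.
#' @param tol confidence interval in nt (default 0.5).
#' @return A `community_matrix`: samples x bins matrix of summed peak
#'   areas, column names = consensus fragment sizes (strictly
#'   increasing), with attribute `normalised = FALSE`.
#' @export
align_fragments <- function(profiles, tol = 0.5) {
  sample_ids <- vapply(profiles, `[[`, character(1L), "sample_id")
  merged <- lapply(profiles, function(p) merge_within_sample(p$peaks, tol))
  all_peaks <- do.call(rbind, lapply(seq_along(merged), function(i) {
    m <- merged[[i]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(sample = i, size_nt = m$size_nt, area = m$area)
  }))
  if (is.null(all_peaks) || nrow(all_peaks) == 0L)
    stop("no peaks to align")
  all_peaks <- all_peaks[order(all_peaks$size_nt), , drop = FALSE]
  bin_of <- integer(nrow(all_peaks))
  cons_sum <- numeric(0); cons_n <- integer(0)
  for (i in seq_len(nrow(all_peaks))) {
    s <- all_peaks$size_nt[i]
    nb <- length(cons_sum)
    if (nb > 0L && abs(s - cons_sum[nb] / cons_n[nb]) < tol) {
      cons_sum[nb] <- cons_sum[nb] + s
      cons_n[nb] <- cons_n[nb] + 1L
      bin_of[i] <- nb
    } else {
      cons_sum <- c(cons_sum, s); cons_n <- c(cons_n, 1L)
      bin_of[i] <- nb + 1L
    }
  }
  consensus <- cons_sum / cons_n
  mat <- matrix(0, nrow = length(profiles), ncol = length(consensus),
                dimnames = list(sample_ids, sprintf("%.3f", consensus)))
  for (i in seq_len(nrow(all_peaks)))
    mat[all_peaks$sample[i], bin_of[i]] <-
      mat[all_peaks$sample[i], bin_of[i]] + all_peaks$area[i]
  structure(mat, class = c("community_matrix", "matrix"),
            consensus_sizes = consensus, normalised = FALSE)
}

#' Normalise a community matrix to relative abundance
#'
#' Converts summed peak areas to within-sample relative abundances,
#' excludes fragments contributing less than `min_fraction` (default
#' 0.5%; an entry at exactly 0.5% is retained) to their sample's profile,
#' and by default renormalises each row to sum to 1 afterwards.
#'
#' @param matrix a `community_matrix` of raw areas.
#' @param min_fraction exclusion cutoff as a fraction (default 0.005).
#' @param renormalise re-divide rows by their post-exclusion sum
#'   (default TRUE).
#' @return the normalised `community_matrix` (attribute
#'   `normalised = TRUE`).
#' @export
normalise_community <- function(matrix, min_fraction = 0.005,
                                renormalise = TRUE) {
  rs <- rowSums(matrix)
  if (any(rs == 0)) stop("empty sample(s): ",
                         paste(rownames(matrix)[rs == 0], collapse = ", "))
  rel <- matrix / rs
  rel[rel < min_fraction] <- 0
  if (renormalise) {
    rs2 <- rowSums(rel)
    if (any(rs2 == 0)) stop("a sample lost all fragments to the cutoff")
    rel <- rel / rs2
  }
  structure(rel, class = c("community_matrix", "matrix"),
            consensus_sizes = attr(matrix, "consensus_sizes"),
            normalised = TRUE)
}

#' Bray-Curtis similarity matrix (percent) with square-root transform
#'
#' Abundances are square-root transformed (down-weighting dominant
#' fragments), then S = 100 (1 - sum|x'-y'| / sum(x'+y')) for every sample
#' pair.  Symmetric, 100 on the diagonal.
#'
#' @param matrix a normalised `community_matrix` (samples x bins).
#' @param transform "sqrt" (default) or "none".
#' @return samples x samples similarity matrix in percent.
#' @export
bray_curtis <- function(matrix, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  X <- unclass(matrix)
  if (transform == "sqrt") X <- sqrt(X)
  n <- nrow(X)
  num <- as.matrix(stats::dist(X, method = "manhattan"))
  rs <- rowSums(X)
  den <- outer(rs, rs, "+")
  sim <- 100 * (1 - num / den)
  diag(sim) <- 100
  dimnames(sim) <- list(rownames(matrix), rownames(matrix))
  sim
}

#' Ecological diversity indices per sample
#'
#' Richness S (number of fragments present), Shannon's H' = -sum p ln p,
#' and Pielou's evenness J' = H'/ln S (undefined, NA, when S = 1).
#'
#' @param matrix a normalised `community_matrix`.
#' @return data.frame: `sample`, `richness`, `shannon`, `pielou`.
#' @export
diversity_indices <- function(matrix) {
  out <- do.call(rbind, lapply(seq_len(nrow(matrix)), function(i) {
    p <- matrix[i, ]
    p <- p[p > 0]
    if (length(p) == 0L) stop("sample with zero richness: ",
                              rownames(matrix)[i])
    p <- p / sum(p)
    S <- length(p)
    H <- -sum(p * log(p))
    data.frame(sample = rownames(matrix)[i] %||% as.character(i),
               richness = S, shannon = H,
               pielou = if (S > 1L) H / log(S) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# run fn with a private, restored RNG stream
with_rng <- function(seed, fn) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  fn()
}

anosim_r <- function(rank_d, within) {
  rb <- mean(rank_d[!within]); rw <- mean(rank_d[within])
  n <- attr(rank_d, "n_samples")
  (rb - rw) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based permutation test of group separation:
#' R = (mean between-group rank dissimilarity - mean within-group rank
#' dissimilarity) / (n(n-1)/4), with the null distribution obtained by
#' permuting group labels.  When the number of distinct label permutations
#' is small (<= `n_perm`) the permutation distribution is enumerated
#' exhaustively and the p-value is exact.
#'
#' @param similarities samples x samples Bray-Curtis similarity matrix
#'   (percent) from [bray_curtis()], or a dissimilarity matrix with
#'   attribute `is_dissimilarity = TRUE`.
#' @param labels group factor, >= 2 groups with >= 2 members each.
#' @param n_perm permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @return list: `R`, `p_value`, `n_perm`, `exhaustive`.
#' @export
anosim <- function(similarities, labels, n_perm = 9999, seed = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L))
    stop("need >= 2 groups with >= 2 members each")
  n <- nrow(similarities)
  stopifnot(length(labels) == n)
  dis <- if (isTRUE(attr(similarities, "is_dissimilarity")))
    as.matrix(similarities) else 100 - as.matrix(similarities)
  dvec <- dis[lower.tri(dis)]
  rank_d <- rank(dvec)
  attr(rank_d, "n_samples") <- n
  pair_i <- row(dis)[lower.tri(dis)]
  pair_j <- col(dis)[lower.tri(dis)]
  within_of <- function(lab) lab[pair_i] == lab[pair_j]
  r_obs <- anosim_r(rank_d, within_of(labels))

  n_total <- factorial(n)
  exhaustive <- is.finite(n_total) && n_total <= n_perm
  if (exhaustive) {
    perms <- permutations_all(n)
    r_perm <- apply(perms, 1L, function(p) anosim_r(rank_d,
                                                    within_of(labels[p])))
    p_value <- mean(r_perm >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    r_perm <- with_rng(seed, function()
      vapply(seq_len(n_perm), function(i)
        anosim_r(rank_d, within_of(sample(labels))), numeric(1L)))
    p_value <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(R = r_obs, p_value = p_value, n_perm = n_used,
       exhaustive = exhaustive)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Similarity percentage decomposition (SIMPER)
#'
#' Decomposes the average square-root-transformed Bray-Curtis
#' dissimilarity between two groups into per-fragment contributions: for
#' each between-group sample pair, bin k contributes
#' 100 |x'_k - y'_k| / sum(x' + y'); contributions averaged over pairs sum
#' exactly to the average between-group dissimilarity.  Also reports the
#' average within-group similarity of each group (the "similarity between
#' replicates").
#'
#' @param matrix a normalised `community_matrix`.
#' @param labels two-group factor.
#' @param transform "sqrt" (default) or "none".
#' @return list: `contributions` (data.frame bin, consensus size, average
#'   dissimilarity contribution, percent contribution, sorted
#'   descending), `average_dissimilarity`, `within_similarity` (named per
#'   group; needs >= 2 members).
#' @export
simper <- function(matrix, labels, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("SIMPER compares exactly two groups")
  X <- unclass(matrix)
  if (transform == "sqrt") X <- sqrt(X)
  g1 <- which(labels == levels(labels)[1L])
  g2 <- which(labels == levels(labels)[2L])
  contrib <- numeric(ncol(X))
  n_pairs <- 0L
  for (i in g1) for (j in g2) {
    den <- sum(X[i, ] + X[j, ])
    contrib <- contrib + 100 * abs(X[i, ] - X[j, ]) / den
    n_pairs <- n_pairs + 1L
  }
  contrib <- contrib / n_pairs
  avg_d <- sum(contrib)
  within_sim <- vapply(levels(labels), function(l) {
    g <- which(labels == l)
    if (length(g) < 2L) return(NA_real_)
    s <- 0; np <- 0L
    for (a in seq_along(g)[-1L]) for (b in seq_len(a - 1L)) {
      i <- g[a]; j <- g[b]
      den <- sum(X[i, ] + X[j, ])
      s <- s + 100 * (1 - sum(abs(X[i, ] - X[j, ])) / den)
      np <- np + 1L
    }
    s / np
  }, numeric(1L))
  ord <- order(contrib, decreasing = TRUE)
  contributions <- data.frame(
    bin = colnames(matrix)[ord] %||% as.character(ord),
    consensus_size = (attr(matrix, "consensus_sizes") %||%
                        rep(NA_real_, ncol(X)))[ord],
    average_dissimilarity = contrib[ord],
    percent = 100 * contrib[ord] / avg_d)
  rownames(contributions) <- NULL
  list(contributions = contributions, average_dissimilarity = avg_d,
       within_similarity = within_sim)
}

# Bray-Curtis dissimilarity (percent) among rows of a plain matrix.
bray_dissim_rows <- function(X) {
  num <- as.matrix(stats::dist(X, method = "manhattan"))
  rs <- rowSums(X)
  100 * num / outer(rs, rs, "+")
}

simprof_pi <- function(sim_sorted, mean_profile) sum(abs(sim_sorted - mean_profile))

# SIMPROF test at one set of samples: are the pairwise similarities more
# structured than expected when every bin's values are shuffled
# independently across samples?
simprof_test <- function(X, n_perm, n_expected = 1000L) {
  m <- nrow(X)
  obs <- sort(100 - bray_dissim_rows(X)[lower.tri(diag(m))])
  perm_profile <- function() {
    Xp <- apply(X, 2L, sample)
    sort(100 - bray_dissim_rows(Xp)[lower.tri(diag(m))])
  }
  mean_prof <- Reduce(`+`, lapply(seq_len(n_expected), function(i)
    perm_profile())) / n_expected
  pi_obs <- simprof_pi(obs, mean_prof)
  pi_null <- vapply(seq_len(n_perm), function(i)
    simprof_pi(perm_profile(), mean_prof), numeric(1L))
  p <- (sum(pi_null >= pi_obs - 1e-12) + 1) / (n_perm + 1)
  list(pi = pi_obs, p_value = p)
}

#' Hierarchical clustering with similarity-profile (SIMPROF) assessment
#'
#' Group-average (UPGMA) clustering on square-root Bray-Curtis
#' dissimilarities, with a SIMPROF permutation test applied top-down at
#' each node: the pi statistic is the departure of the node's ordered
#' pairwise similarities from their mean under independent within-bin
#' permutation of values across the node's samples.  Nodes failing to
#' reject carry no interpretable internal structure and are flagged
#' homogeneous (together with everything below them).
#'
#' @param matrix a normalised `community_matrix` (>= 3 samples).
#' @param n_perm permutations for the null pi distribution (default
#'   20,000); the expected (mean) profile uses `n_expected` (default
#'   1,000) separate permutations.
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param n_expected permutations for the mean profile.
#' @param transform "sqrt" (default) or "none".
#' @return list: `hclust` (the tree), `nodes` (data.frame: node height,
#'   size, pi, p, significant), `homogeneous` (logical per node),
#'   `groups` (integer cluster id per sample from the significant
#'   splits), `newick` (tree with SIMPROF flags as node labels).
#' @export
simprof_cluster <- function(matrix, n_perm = 20000, alpha = 0.05,
                            seed = NULL, n_expected = 1000L,
                            transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (nrow(matrix) < 3L) stop("SIMPROF clustering needs >= 3 samples")
  X <- unclass(matrix)
  if (transform == "sqrt") X <- sqrt(X)
  d <- stats::as.dist(bray_dissim_rows(X))
  hc <- stats::hclust(d, method = "average")
  n <- nrow(X)
  members_of <- function(node) {
    # node > 0: merge row; node < 0: leaf
    if (node < 0L) return(-node)
    unlist(lapply(hc$merge[node, ], members_of))
  }
  n_nodes <- n - 1L
  res <- data.frame(node = seq_len(n_nodes), height = hc$height,
                    size = NA_integer_, pi = NA_real_, p_value = NA_real_,
                    significant = FALSE, tested = FALSE)
  with_rng(seed, function() {
    # top-down: root is the last merge; only test below significant nodes
    test_node <- function(node) {
      mem <- members_of(node)
      res[node, "size"] <<- length(mem)
      if (length(mem) < 3L) return(invisible())
      t <- simprof_test(X[mem, , drop = FALSE], n_perm, n_expected)
      res[node, c("pi", "p_value")] <<- c(t$pi, t$p_value)
      res[node, "tested"] <<- TRUE
      if (t$p_value <= alpha) {
        res[node, "significant"] <<- TRUE
        for (child in hc$merge[node, ]) if (child > 0L) test_node(child)
      }
    }
    test_node(n_nodes)
  })
  # cluster membership: cut at the significant structure
  groups <- rep(1L, n)
  assign_groups <- function(node, gid) {
    if (node < 0L) { groups[-node] <<- gid; return(gid) }
    if (res[node, "significant"]) {
      g1 <- assign_groups(hc$merge[node, 1L], gid)
      assign_groups(hc$merge[node, 2L], g1 + 1L)
    } else {
      for (m in members_of(node)) groups[m] <<- gid
      gid
    }
  }
  assign_groups(n_nodes, 1L)
  phy <- ape::as.phylo(hc)
  phy$node.label <- ifelse(res$significant[order_nodes(hc, phy)],
                           "significant", "homogeneous")
  list(hclust = hc, nodes = res, homogeneous = !res$significant,
       groups = groups, newick = ape::write.tree(phy))
}

# map hclust merge-row order onto ape internal node order
order_nodes <- function(hc, phy) {
  n <- length(hc$labels %||% seq_len(nrow(hc$merge) + 1L))
  # ape::as.phylo numbers internal nodes n+1 .. 2n-1 in its own traversal;
  # recover, for each phylo internal node, the hclust merge row with the
  # same leaf set
  leafsets_h <- lapply(seq_len(nrow(hc$merge)), function(node) {
    mem <- local({
      rec <- function(nd) if (nd < 0L) -nd else
        unlist(lapply(hc$merge[nd, ], rec))
      sort(rec(node))
    })
    paste(mem, collapse = ",")
  })
  key <- stats::setNames(seq_along(leafsets_h), leafsets_h)
  vapply(seq_len(phy$Nnode), function(i) {
    node_id <- n + i
    tips <- sort(phylo_tips(phy, node_id))
    unname(key[paste(tips, collapse = ",")])
  }, numeric(1L))
}

phylo_tips <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, phylo_tips, phy = phy))
}

#' Welch t-test comparison of diversity indices between groups
#'
#' Unequal-variance two-sample t-tests (hence fractional degrees of
#' freedom) of each index between two groups.
#'
#' @param indices data.frame from [diversity_indices()].
#' @param groups two-level factor, one entry per sample.
#' @return data.frame: index, group means/sds, t, df, p.
#' @export
compare_indices <- function(indices, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  idx_cols <- c("richness", "shannon", "pielou")
  out <- do.call(rbind, lapply(idx_cols, function(ic) {
    v <- indices[[ic]]
    ok <- !is.na(v)
    tt <- stats::t.test(v[ok] ~ droplevels(groups[ok]), var.equal = FALSE)
    data.frame(index = ic,
               mean_1 = tt$estimate[[1L]], mean_2 = tt$estimate[[2L]],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  }))
  rownames(out) <- NULL
  out
}

# Fit L = c/(m - m0) + L0 exactly through three (migration, size) points.
reciprocal_fit3 <- function(m, L) {
  # From the three equations: (L1-L2)/(L2-L3) =
  #   [(m2-m1)(m3-m0)] / [(m3-m2)(m1-m0)]  -> linear in m0
  A <- (L[1L] - L[2L]) * (m[3L] - m[2L])
  B <- (L[2L] - L[3L]) * (m[2L] - m[1L])
  # A (m1 - m0) = B (m3 - m0)
  m0 <- (A * m[1L] - B * m[3L]) / (A - B)
  c_ <- (L[1L] - L[2L]) / (1 / (m[1L] - m0) - 1 / (m[2L] - m0))
  L0 <- L[1L] - c_ / (m[1L] - m0)
  function(mq) c_ / (mq - m0) + L0
}

#' Local Southern fragment sizing
#'
#' Sizes each query peak against the internal size standard using the
#' Local Southern method: the reciprocal mobility model
#' L = c/(m - m0) + L0 is fitted exactly to each of the two overlapping
#' triplets of standards flanking the query (two below + one above, and
#' one below + two above), and the reported size is the mean of the two
#' fitted values.
#'
#' @param query_migration migration values of the peaks to size.
#' @param standards data.frame with columns `migration` and `size_nt`,
#'   >= 4 points; every query must be bracketed so both triplets exist.
#' @return numeric fragment sizes (nt) for each query.
#' @export
size_fragments_local_southern <- function(query_migration, standards) {
  standards <- standards[order(standards$migration), , drop = FALSE]
  m <- standards$migration; L <- standards$size_nt
  if (length(m) < 4L) stop("need >= 4 size-standard points")
  vapply(query_migration, function(q) {
    i <- findInterval(q, m)  # m[i] <= q < m[i+1]
    if (q == m[length(m)]) i <- length(m) - 1L
    if (i < 2L || i > length(m) - 2L)
      stop("query migration ", q,
           " is not bracketed by two standards on each side")
    f1 <- reciprocal_fit3(m[(i - 1L):(i + 1L)], L[(i - 1L):(i + 1L)])
    f2 <- reciprocal_fit3(m[i:(i + 2L)], L[i:(i + 2L)])
    (f1(q) + f2(q)) / 2
  }, numeric(1L))
}
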