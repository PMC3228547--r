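GROUP_LEVELS <- c("neutral", "acid", "basic", "aromatic", "imino")

#' Default five-group amino-acid property scheme
#'
#' Maps the 20 standard residues onto five biochemical property groups used
#' by the positional dependence test: acid \{D, E\}, basic \{K, R, H\},
#' aromatic \{F, W, Y\}, imino \{P\}, and neutral (the remaining eleven).
#'
#' @return named character vector residue -> group, with a `groups`
#'   attribute giving the fixed group order.
#' @export
default_group_scheme <- function() {
  scheme <- c(
    D = "acid", E = "acid",
    K = "basic", R = "basic", H = "basic",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    P = "imino",
    G = "neutral", A = "neutral", V = "neutral", L = "neutral",
    I = "neutral", M = "neutral", C = "neutral", S = "neutral",
    T = "neutral", N = "neutral", Q = "neutral"
  )
  scheme <- scheme[AA_ALPHABET]
  attr(scheme, "groups") <- GROUP_LEVELS
  scheme
}

validate_scheme <- function(scheme) {
  if (!setequal(names(scheme), AA_ALPHABET)) {
    stop("group scheme must map exactly the 20 standard amino acids")
  }
  if (!all(scheme %in% GROUP_LEVELS)) {
    stop("unknown group name(s): ",
         paste(setdiff(scheme, GROUP_LEVELS), collapse = ", "))
  }
  invisible(scheme)
}

#' Map residues to property groups
#'
#' Pad characters and non-standard letters map to `NA` ("unmapped") and are
#' excluded from contingency counts.
#'
#' @param residues character vector of single letters.
#' @param scheme group scheme (see [default_group_scheme()]).
#' @return factor with the five group levels; `NA` for unmapped letters.
#' @export
map_group <- function(residues, scheme = default_group_scheme()) {
  factor(unname(scheme[residues]), levels = GROUP_LEVELS)
}

# Group matrix for a set of windows: n x (2w+1) factor codes (NA = unmapped),
# with the center column forced to NA so position 0 never enters the test.
group_matrix <- function(windows, scheme) {
  mat <- window_matrix(windows)
  w <- half_window(ncol(mat))
  g <- matrix(unname(scheme[mat]), nrow = nrow(mat))
  g[, flank_col(0L, w)] <- NA_character_
  colnames(g) <- flank_coords(w)
  g
}

#' Group-occurrence contingency table for a position pair
#'
#' Cross-tabulates the five property groups at flank positions `i` and `j`
#' over a set of fragments. Fragments with an unmapped letter (pad or
#' non-standard residue) at either position are skipped.
#'
#' @param fragments fragment data.frame.
#' @param i,j flank coordinates in -w..+w, both nonzero and distinct.
#' @param scheme group scheme.
#' @return 5x5 integer matrix of class `contingency_table` with a
#'   `positions` attribute.
#' @export
contingency <- function(fragments, i, j, scheme = default_group_scheme()) {
  w <- half_window(nchar(fragments$window[1]))
  if (i == j) stop("positions must differ")
  if (i == 0L || j == 0L) stop("position 0 (the site) is excluded")
  if (abs(i) > w || abs(j) > w) stop("position outside -w..+w")
  g <- group_matrix(fragments$window, scheme)
  gi <- factor(g[, as.character(i)], levels = GROUP_LEVELS)
  gj <- factor(g[, as.character(j)], levels = GROUP_LEVELS)
  tab <- table(gi, gj, dnn = NULL)
  tab <- matrix(as.integer(tab), 5, 5, dimnames = list(GROUP_LEVELS,
                                                       GROUP_LEVELS))
  structure(tab, class = c("contingency_table", class(tab)),
            positions = c(i = i, j = j))
}

#' Pearson chi-square statistic on a group contingency table
#'
#' Computes `sum((X_mn - E_mn)^2 / E_mn)` with expected counts
#' `E_mn = X_mR * X_Cn / X` from the row and column margins. Cells whose
#' expected count is zero (an empty row or column margin) contribute
#' nothing, keeping the statistic defined on sparse tables.
#'
#' @param tab 5x5 count matrix (see [contingency()]).
#' @return non-negative chi-square value; 0 with a warning for an empty
#'   table.
#' @export
chi_square <- function(tab) {
  X <- sum(tab)
  if (X == 0) {
    warning("empty contingency table; chi-square undefined, returning 0")
    return(0)
  }
  E <- outer(rowSums(tab), colSums(tab)) / X
  ok <- E > 0
  sum((tab[ok] - E[ok])^2 / E[ok])
}

#' Chi-square critical value for the group independence test
#'
#' Upper-tail quantile of the chi-square distribution with
#' `(groups - 1)^2` degrees of freedom; at the default significance level
#' 0.005 on a 5x5 table (16 df) this is 34.27, i.e. 34.3 to one decimal --
#' the cutoff used to flag a strong positional dependence.
#'
#' @param p upper-tail probability (default 0.005).
#' @param groups number of property groups (default 5).
#' @return critical value.
#' @export
chi_square_cutoff <- function(p = 0.005, groups = 5L) {
  stats::qchisq(p, df = (groups - 1L)^2, lower.tail = FALSE)
}

#' Positional dependence matrix
#'
#' Chi-square statistics for every ordered pair of flank positions;
#' symmetric by construction.
#'
#' @param fragments fragment data.frame.
#' @param scheme group scheme.
#' @return symmetric matrix indexed by flank coordinates (position 0 and
#'   the diagonal are `NA`).
#' @export
dependence_matrix <- function(fragments, scheme = default_group_scheme()) {
  w <- half_window(nchar(fragments$window[1]))
  g <- group_matrix(fragments$window, scheme)
  pos <- setdiff(flank_coords(w), 0L)
  m <- matrix(NA_real_, length(pos), length(pos),
              dimnames = list(pos, pos))
  for (a in seq_along(pos)) {
    ga <- factor(g[, as.character(pos[a])], levels = GROUP_LEVELS)
    for (b in seq_along(pos)) {
      if (b <= a) next
      gb <- factor(g[, as.character(pos[b])], levels = GROUP_LEVELS)
      tab <- table(ga, gb, dnn = NULL)
      val <- suppressWarnings(chi_square(tab))
      m[a, b] <- m[b, a] <- val
    }
  }
  m
}

#' Choose the maximal-dependence split for a fragment set
#'
#' For each flank position `i` the dependence score `S_i` sums the
#' chi-square values of all pairs `(i, j)` exceeding the cutoff (only
#' significant dependencies count). The split position is the `argmax S_i`;
#' the split group is the most frequent mapped property group at that
#' position. Ties on `S_i` break toward the smallest flank coordinate in
#' magnitude, negative before positive; group ties follow the fixed group
#' order.
#'
#' @param fragments fragment data.frame (>= 2 rows).
#' @param scheme group scheme.
#' @param cutoff chi-square significance cutoff (default
#'   `chi_square_cutoff()`, 34.3 at P = 0.005 with 16 df).
#' @return list with `position`, `group`, and the dependence score `S`,
#'   or `NULL` when no pair is significant.
#' @export
choose_split <- function(fragments, scheme = default_group_scheme(),
                         cutoff = chi_square_cutoff()) {
  if (nrow(fragments) < 2L) return(NULL)
  m <- dependence_matrix(fragments, scheme)
  sig <- !is.na(m) & m > cutoff
  s <- rowSums(ifelse(sig, m, 0))
  if (all(s == 0)) return(NULL)
  pos <- as.integer(rownames(m))
  ord <- order(-s, abs(pos), pos)
  best <- pos[ord[1]]

  g <- group_matrix(fragments$window, scheme)[, as.character(best)]
  counts <- table(factor(g, levels = GROUP_LEVELS))
  grp <- GROUP_LEVELS[which.max(counts)]
  list(position = best, group = grp, S = unname(s[ord[1]]))
}

#' Maximal dependence decomposition of a fragment set
#'
#' Recursively partitions fragments into a binary tree: at each node the
#' maximal-dependence split position and property group are found
#' ([choose_split()]) and members are divided by presence/absence of that
#' group at that position. A node is split only while it holds at least
#' `min_cluster_size` members, a significant dependence exists, and both
#' children are non-empty; otherwise it is a leaf.
#'
#' @param fragments fragment data.frame (positive windows of one class).
#' @param scheme group scheme.
#' @param cutoff chi-square cutoff (default 34.3-level).
#' @param min_cluster_size nodes smaller than this are never split.
#'   Reference defaults per residue class: 200 (S), 100 (T), 30 (Y).
#' @return nested list of class `mdd_node`: `members` (row indices into
#'   `fragments`), `n`, `depth`, and for internal nodes `split_position`,
#'   `split_group`, `present_child`, `absent_child`. The input data.frame is
#'   attached to the root as attribute `fragments`.
#' @export
mdd_cluster <- function(fragments, scheme = default_group_scheme(),
                        cutoff = chi_square_cutoff(),
                        min_cluster_size = 200L) {
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  validate_scheme(scheme)
  g <- group_matrix(fragments$window, scheme)

  build <- function(members, depth) {
    node <- list(members = members, n = length(members), depth = depth,
                 split_position = NULL, split_group = NULL,
                 present_child = NULL, absent_child = NULL)
    class(node) <- "mdd_node"
    if (length(members) < min_cluster_size) return(node)
    split <- choose_split(fragments[members, , drop = FALSE], scheme, cutoff)
    if (is.null(split)) return(node)
    has_group <- !is.na(g[members, as.character(split$position)]) &
      g[members, as.character(split$position)] == split$group
    if (all(has_group) || !any(has_group)) return(node)
    node$split_position <- split$position
    node$split_group <- split$group
    node$present_child <- build(members[has_group], depth + 1L)
    node$absent_child <- build(members[!has_group], depth + 1L)
    node
  }

  root <- build(seq_len(nrow(fragments)), 0L)
  attr(root, "fragments") <- fragments
  root
}

# Collect leaf nodes of an MDD tree in depth-first (present-first) order.
mdd_leaf_nodes <- function(node) {
  if (is.null(node$split_position)) return(list(node))
  c(mdd_leaf_nodes(node$present_child), mdd_leaf_nodes(node$absent_child))
}

#' Extract motif clusters from an MDD tree
#'
#' Leaves are numbered by decreasing size (ties in tree order) and labeled
#' `<prefix>1`, `<prefix>2`, ... as in the subgroup tables (S1..S9 etc.).
#'
#' @param root `mdd_node` from [mdd_cluster()].
#' @param prefix cluster id prefix, usually the residue class.
#' @param scheme group scheme (stored for profile summaries).
#' @return list of `motif_cluster` objects: `id`, `members` (fragment
#'   data.frame), `group_freq` (5 x positions matrix), `info` (bits per
#'   position).
#' @export
motif_clusters <- function(root, prefix = "S",
                           scheme = default_group_scheme()) {
  fragments <- attr(root, "fragments")
  leaves <- mdd_leaf_nodes(root)
  ord <- order(-vapply(leaves, function(l) l$n, integer(1)))
  lapply(seq_along(ord), function(k) {
    members <- fragments[leaves[[ord[k]]]$members, , drop = FALSE]
    rownames(members) <- NULL
    new_motif_cluster(paste0(prefix, k), members, scheme)
  })
}

new_motif_cluster <- function(id, members, scheme) {
  cl <- list(id = id, members = members,
             group_freq = group_frequency_profile(members$window, scheme),
             summary = motif_summary_windows(members$window))
  class(cl) <- "motif_cluster"
  cl
}

# Per-position property-group frequency profile (5 x positions), pads
# excluded; positions with no mapped residue get uniform 1/5 (neutral for
# divergence computations on all-pad columns).
group_frequency_profile <- function(windows, scheme) {
  g <- group_matrix(windows, scheme)
  pos <- colnames(g)
  freq <- vapply(pos, function(p) {
    counts <- table(factor(g[, p], levels = GROUP_LEVELS))
    tot <- sum(counts)
    if (tot == 0) rep(1 / 5, 5) else as.numeric(counts) / tot
  }, numeric(5))
  rownames(freq) <- GROUP_LEVELS
  freq
}

# Jensen-Shannon divergence (base 2) between two discrete distributions.
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Mean per-position JS divergence between two group-frequency profiles.
motif_distance <- function(freq_a, freq_b) {
  mean(vapply(seq_len(ncol(freq_a)),
              function(j) js_divergence(freq_a[, j], freq_b[, j]),
              numeric(1)))
}

#' Merge motif clusters with very similar profiles
#'
#' Single-linkage agglomeration on motif distance (mean per-position
#' Jensen-Shannon divergence between property-group frequency profiles):
#' while the minimum pairwise distance is below `threshold`, the closest
#' pair is merged and its profile recomputed from the union. With the
#' default `threshold = 0` merging is off and the raw tree leaves are the
#' canonical clusters.
#'
#' @param clusters list of `motif_cluster` (one tree's leaves).
#' @param threshold motif-distance threshold in bits (0 disables).
#' @param scheme group scheme.
#' @return list of `motif_cluster`, re-labeled by decreasing size with the
#'   original id prefix.
#' @export
merge_similar <- function(clusters, threshold = 0,
                          scheme = default_group_scheme()) {
  if (threshold <= 0 || length(clusters) < 2L) return(clusters)
  prefix <- sub("[0-9]+$", "", clusters[[1]]$id)
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    dmin <- Inf
    pair <- NULL
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        d <- motif_distance(clusters[[a]]$group_freq,
                            clusters[[b]]$group_freq)
        if (d < dmin) {
          dmin <- d
          pair <- c(a, b)
        }
      }
    }
    if (dmin >= threshold) break
    merged_members <- rbind(clusters[[pair[1]]]$members,
                            clusters[[pair[2]]]$members)
    merged <- new_motif_cluster("tmp", merged_members, scheme)
    clusters <- c(clusters[-pair], list(merged))
  }
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  ord <- order(-sizes)
  lapply(seq_along(ord), function(k) {
    cl <- clusters[[ord[k]]]
    cl$id <- paste0(prefix, k)
    cl
  })
}

# Residue frequencies and information content per position for a window set.
motif_summary_windows <- function(windows) {
  mat <- window_matrix(windows)
  w <- half_window(ncol(mat))
  pos <- flank_coords(w)
  freq <- matrix(0, length(AA_ALPHABET), length(pos),
                 dimnames = list(AA_ALPHABET, pos))
  info <- numeric(length(pos))
  all_pad <- logical(length(pos))
  for (j in seq_along(pos)) {
    counts <- table(factor(mat[, j], levels = AA_ALPHABET))
    tot <- sum(counts)
    if (tot == 0) {
      all_pad[j] <- TRUE
      info[j] <- 0
      next
    }
    f <- as.numeric(counts) / tot
    freq[, j] <- f
    nz <- f > 0
    info[j] <- log2(20) - (-sum(f[nz] * log2(f[nz])))
  }
  names(info) <- pos
  list(frequencies = freq, information = info, all_pad = all_pad)
}

#' Per-position residue frequencies and information content of a cluster
#'
#' The numeric summary behind an entropy/sequence-logo plot: residue
#' frequencies (pads excluded) and information content
#' `log2(20) - H(position)` in bits at each flank coordinate. An all-pad
#' position is flagged and reported as 0 bits.
#'
#' @param cluster a `motif_cluster`.
#' @return list with `frequencies` (20 x positions), `information` (bits),
#'   `all_pad` (logical flags).
#' @export
motif_summary <- function(cluster) {
  if (nrow(cluster$members) == 0L) stop("empty cluster")
  motif_summary_windows(cluster$members$window)
}
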