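# Hamming distance from each row of a character matrix to one row.
hamming_to_row <- function(mat, row) {
  rowSums(mat != matrix(row, nrow = nrow(mat), ncol = length(row),
                        byrow = TRUE))
}

# Pairwise Hamming distances between rows of a character matrix.
hamming_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(mat))) {
    d <- d + outer(mat[, j], mat[, j], FUN = "!=")
  }
  d
}

#' Select representative negative fragments by k-medoids clustering
#'
#' Negatives are clustered on Hamming distance between window strings
#' (sequence identity) and the medoid of each cluster -- the member with
#' minimal total distance to the other members -- is returned. This replaces
#' uniform random subsampling with a representative, size-matched draw: the
#' number of clusters K is set to the number of positive fragments.
#'
#' Initialization is a k-means++-style seeded draw, followed by Lloyd
#' iterations (assign to nearest medoid, update medoid, at most `max_iter`
#' rounds). Medoid ties break by input order; an emptied cluster is reseeded
#' with the point farthest from its current medoid.
#'
#' @param negatives fragment data.frame (equal-length windows).
#' @param K number of representatives (typically the positive count).
#' @param seed integer RNG seed; the procedure is deterministic given the
#'   seed and input order.
#' @param max_iter iteration cap (default 100).
#' @return list of class `balance_result`: `selected` (data.frame of K
#'   fragments), `cluster_assignment` (integer vector over the input rows),
#'   `seed`.
#' @export
select_representatives <- function(negatives, K, seed, max_iter = 100L) {
  n <- nrow(negatives)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (n < K) stop("cannot select ", K, " representatives from ", n,
                  " negatives")
  mat <- window_matrix(negatives$window)

  if (n == K) {
    out <- list(selected = negatives, cluster_assignment = seq_len(n),
                seed = as.integer(seed))
    class(out) <- "balance_result"
    return(out)
  }

  with_seed(seed, {
    # k-means++-style init: first medoid uniform, then D^2-weighted draws
    medoids <- integer(K)
    medoids[1] <- sample.int(n, 1L)
    mind <- hamming_to_row(mat, mat[medoids[1], ])
    if (K > 1L) {
      for (k in 2L:K) {
        wts <- mind^2
        medoids[k] <- if (sum(wts) == 0) {
          cand <- setdiff(seq_len(n), medoids[seq_len(k - 1L)])
          cand[sample.int(length(cand), 1L)]
        } else {
          sample.int(n, 1L, prob = wts)
        }
        mind <- pmin(mind, hamming_to_row(mat, mat[medoids[k], ]))
      }
    }

    assign_nearest <- function(medoids) {
      d <- vapply(medoids, function(m) hamming_to_row(mat, mat[m, ]),
                  numeric(n))
      max.col(-d, ties.method = "first")
    }

    cl <- assign_nearest(medoids)
    for (iter in seq_len(max_iter)) {
      new_medoids <- medoids
      for (k in seq_len(K)) {
        members <- which(cl == k)
        if (length(members) == 0L) {
          # reseed an emptied cluster with the globally worst-fit point
          d_own <- vapply(seq_len(n), function(i) {
            sum(mat[i, ] != mat[medoids[cl[i]], ])
          }, numeric(1))
          new_medoids[k] <- which.max(d_own)
          next
        }
        if (length(members) == 1L) {
          new_medoids[k] <- members
          next
        }
        dd <- hamming_matrix(mat[members, , drop = FALSE])
        new_medoids[k] <- members[which.min(rowSums(dd))]
      }
      new_cl <- assign_nearest(new_medoids)
      if (identical(new_medoids, medoids) && identical(new_cl, cl)) break
      medoids <- new_medoids
      cl <- new_cl
    }

    selected <- negatives[medoids, , drop = FALSE]
    rownames(selected) <- NULL
    out <- list(selected = selected, cluster_assignment = cl,
                seed = as.integer(seed))
    class(out) <- "balance_result"
    out
  })
}
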