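#' Background residue frequencies pooled from fragments
#'
#' Pools flank residues (position 0 and pads excluded) over a set of
#' fragments, typically the class's positives plus its balanced negatives.
#'
#' @param fragments fragment data.frame (one or more rbind-ed sets).
#' @return probability vector over the 20 standard residues.
#' @export
background_frequencies <- function(fragments) {
  mat <- window_matrix(fragments$window)
  w <- half_window(ncol(mat))
  mat <- mat[, -flank_col(0L, w), drop = FALSE]
  counts <- table(factor(mat, levels = AA_ALPHABET))
  tot <- sum(counts)
  if (tot == 0) stop("no mapped flank residues to pool")
  out <- as.numeric(counts) / tot
  names(out) <- AA_ALPHABET
  out
}

#' Uniform background over the 20 residues
#' @return probability vector with every residue at 1/20.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
}

#' Train a positional profile model for one motif cluster
#'
#' Learns, from positive windows only, a per-flank-position emission
#' distribution over the 20 residues with Laplace-style pseudocounts:
#' `emission(p, a) = (count(p, a) + pseudocount) / (n_mapped(p) +
#' 20 * pseudocount)`. Pads are excluded from counts and position 0 carries
#' no emission (the center residue is fixed by the class). On gap-free
#' fixed-length windows this positional model is the degenerate form of a
#' profile HMM, scored as a log-odds sum against the background.
#'
#' @param cluster a `motif_cluster` (or a fragment data.frame).
#' @param pseudocount additive smoothing constant (> 0 unless every
#'   positional count is positive; default 1).
#' @param background residue probability vector (default uniform; training
#'   pipelines pass pooled frequencies from [background_frequencies()]).
#' @return object of class `profile_model`: `cluster_id`, `class`,
#'   `emissions` (20 x flank positions), `background`, `pseudocount`,
#'   `threshold_bits` (NA until calibrated), `training_size`.
#' @export
train_profile <- function(cluster, pseudocount = 1,
                          background = uniform_background()) {
  members <- if (inherits(cluster, "motif_cluster")) cluster$members else cluster
  id <- if (inherits(cluster, "motif_cluster")) cluster$id else "model"
  if (is.null(members) || nrow(members) == 0L) {
    stop("cannot train a profile on an empty cluster")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  stopifnot(abs(sum(background) - 1) < 1e-9)

  mat <- window_matrix(members$window)
  w <- half_window(ncol(mat))
  pos <- setdiff(flank_coords(w), 0L)
  emissions <- vapply(pos, function(p) {
    counts <- table(factor(mat[, flank_col(p, w)], levels = AA_ALPHABET))
    (as.numeric(counts) + pseudocount) /
      (sum(counts) + length(AA_ALPHABET) * pseudocount)
  }, numeric(20))
  dimnames(emissions) <- list(AA_ALPHABET, pos)

  model <- list(cluster_id = id,
                class = members$residue[1],
                w = w,
                emissions = emissions,
                background = background[AA_ALPHABET],
                pseudocount = pseudocount,
                threshold_bits = NA_integer_,
                training_size = nrow(members))
  class(model) <- "profile_model"
  model
}

#' Log-odds bit scores of windows under a profile model
#'
#' The bit score is the base-2 log ratio of the window's probability under
#' the positional emission model to its probability under the background:
#' `sum_p log2(emission(p, a_p) / background(a_p))` over flank positions
#' whose residue is one of the 20 standard letters. Pad positions contribute
#' 0 bits.
#'
#' @param model a `profile_model`.
#' @param windows character vector of windows of length `2w + 1` whose
#'   center residue matches the model's class.
#' @return numeric vector of bit scores.
#' @export
bit_score <- function(model, windows) {
  if (length(windows) == 0L) return(numeric(0))
  mat <- window_matrix(windows)
  w <- model$w
  if (ncol(mat) != 2L * w + 1L) {
    stop("window length ", ncol(mat), " does not match model (",
         2L * w + 1L, ")")
  }
  centers <- mat[, flank_col(0L, w)]
  if (any(centers != model$class)) {
    stop("window center residue must be '", model$class, "'")
  }
  lod <- log2(model$emissions / model$background)  # 20 x positions
  scores <- numeric(length(windows))
  for (pc in seq_len(ncol(lod))) {
    p <- as.integer(colnames(lod)[pc])
    a <- mat[, flank_col(p, w)]
    idx <- match(a, AA_ALPHABET)
    ok <- !is.na(idx)
    scores[ok] <- scores[ok] + lod[cbind(idx[ok], pc)]
  }
  scores
}

#' Write a set of profile models as a JSON model bundle
#'
#' @param models list of `profile_model` of one residue class.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_model_bundle <- function(models, path) {
  stopifnot(length(models) > 0)
  bundle <- list(
    format = "mddphos-model/1",
    class = models[[1]]$class,
    w = models[[1]]$w,
    background = as.list(models[[1]]$background),
    clusters = lapply(models, function(m) {
      list(id = m$cluster_id,
           threshold_bits = m$threshold_bits,
           pseudocount = m$pseudocount,
           training_size = m$training_size,
           emissions = as.data.frame(m$emissions))
    })
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON model bundle
#'
#' @param path path written by [write_model_bundle()].
#' @return list of `profile_model`.
#' @export
read_model_bundle <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(bundle$format, "mddphos-model/1")) {
    stop("unrecognized model bundle format: ", bundle$format)
  }
  background <- unlist(bundle$background)[AA_ALPHABET]
  lapply(seq_len(nrow(bundle$clusters)), function(i) {
    row <- bundle$clusters[i, ]
    em <- as.matrix(row$emissions[[1]])
    rownames(em) <- AA_ALPHABET
    colnames(em) <- setdiff(flank_coords(bundle$w), 0L)
    model <- list(cluster_id = row$id,
                  class = bundle$class,
                  w = bundle$w,
                  emissions = em,
                  background = background,
                  pseudocount = row$pseudocount,
                  threshold_bits = row$threshold_bits,
                  training_size = row$training_size)
    class(model) <- "profile_model"
    model
  })
}
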