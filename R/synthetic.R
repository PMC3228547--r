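#' Specify a planted substrate motif
#'
#' A motif plants symbols at chosen flank positions: at each position, with
#' the given probability, the residue is replaced by the planted residue
#' (or by a uniform draw within the planted property group). Two positions
#' may be coupled, in which case a single draw plants both symbols or
#' neither -- the construction that gives the positional chi-square test a
#' true dependence to detect.
#'
#' @param positions named list: names are flank coordinates (nonzero,
#'   within -w..+w), values are lists with `symbol` (a residue letter or a
#'   group name from the five-group scheme) and `prob` in (0, 1].
#' @param coupling optional integer pair of coupled positions (must carry
#'   equal probabilities).
#' @param weight mixture weight of this motif among a dataset's motifs.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(positions, coupling = NULL, weight = 1) {
  pos <- as.integer(names(positions))
  if (anyNA(pos) || any(pos == 0L)) {
    stop("planted positions must be nonzero flank coordinates")
  }
  for (p in positions) {
    stopifnot(is.list(p), !is.null(p$symbol), p$prob > 0, p$prob <= 1)
    if (!p$symbol %in% c(AA_ALPHABET, GROUP_LEVELS)) {
      stop("unknown symbol '", p$symbol, "'")
    }
  }
  if (!is.null(coupling)) {
    coupling <- as.integer(coupling)
    stopifnot(length(coupling) == 2L, all(coupling %in% pos))
    pr <- vapply(as.character(coupling),
                 function(p) positions[[p]]$prob, numeric(1))
    if (length(unique(pr)) != 1L) {
      stop("coupled positions must carry equal probabilities")
    }
  }
  structure(list(positions = positions, coupling = coupling,
                 weight = weight), class = "motif_spec")
}

#' Specify a synthetic labeled fragment dataset
#'
#' @param n_pos,n_neg numbers of positive and negative fragments.
#' @param w half-window size (default 10, 21-mers).
#' @param residue_class center residue, one of "S", "T", "Y".
#' @param motifs list of `motif_spec`; their weights must sum to 1.
#' @param background residue probability vector (default uniform over the
#'   20 residues).
#' @param seed integer RNG seed.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_pos, n_neg, w = 10L,
                         residue_class = c("S", "T", "Y"),
                         motifs = list(), background = uniform_background(),
                         seed = 1L) {
  residue_class <- match.arg(residue_class)
  stopifnot(n_pos >= 0, n_neg >= 0, w >= 1)
  if (length(motifs) > 0) {
    wts <- vapply(motifs, `[[`, numeric(1), "weight")
    if (abs(sum(wts) - 1) > 1e-9) stop("motif weights must sum to 1")
    for (m in motifs) {
      if (any(abs(as.integer(names(m$positions))) > w)) {
        stop("planted position outside -w..+w")
      }
    }
  }
  stopifnot(abs(sum(background) - 1) < 1e-9)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 w = as.integer(w), residue_class = residue_class,
                 motifs = motifs, background = background[AA_ALPHABET],
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

# n background windows as a character matrix with the class at the center.
random_window_matrix <- function(n, w, residue_class, background) {
  len <- 2L * w + 1L
  mat <- matrix(sample(AA_ALPHABET, n * len, replace = TRUE,
                       prob = background), nrow = n, ncol = len)
  mat[, w + 1L] <- residue_class
  mat
}

# Residues drawn for one planted symbol (letter or group) for n fragments.
draw_symbol <- function(symbol, n) {
  if (symbol %in% AA_ALPHABET) return(rep(symbol, n))
  members <- names(default_group_scheme())[default_group_scheme() == symbol]
  members[sample.int(length(members), n, replace = TRUE)]
}

#' Plant a motif into fragment windows
#'
#' At each planted position, a Bernoulli draw at the stated probability
#' decides whether the fragment's residue is replaced by the planted
#' symbol. Coupled positions share one draw, so their symbols co-occur
#' (both or neither per fragment).
#'
#' @param fragments fragment data.frame.
#' @param spec a `motif_spec`.
#' @param seed integer RNG seed.
#' @return fragment data.frame with planted windows; attribute `planted`
#'   flags fragments in which every position's draw fired.
#' @export
plant_motif <- function(fragments, spec, seed = 1L) {
  n <- nrow(fragments)
  if (n == 0L) return(fragments)
  mat <- window_matrix(fragments$window)
  w <- half_window(ncol(mat))
  with_seed(seed, {
    all_on <- rep(TRUE, n)
    coupled <- if (is.null(spec$coupling)) integer(0) else spec$coupling
    if (length(coupled) > 0) {
      p <- spec$positions[[as.character(coupled[1])]]$prob
      on_draw <- stats::runif(n) < p
      all_on <- all_on & on_draw
      for (cp in coupled) {
        sym <- spec$positions[[as.character(cp)]]$symbol
        mat[on_draw, flank_col(cp, w)] <- draw_symbol(sym, sum(on_draw))
      }
    }
    for (nm in names(spec$positions)) {
      cp <- as.integer(nm)
      if (cp %in% coupled) next
      p <- spec$positions[[nm]]$prob
      on_draw <- stats::runif(n) < p
      all_on <- all_on & on_draw
      mat[on_draw, flank_col(cp, w)] <- draw_symbol(spec$positions[[nm]]$symbol,
                                                    sum(on_draw))
    }
    fragments$window <- apply(mat, 1, paste0, collapse = "")
    # flag fragments that carry every planted symbol (all draws fired)
    attr(fragments, "planted") <- all_on
    fragments
  })
}

#' Generate a labeled synthetic fragment dataset
#'
#' Positives are drawn from the motif mixture over the background;
#' negatives are pure background. Which motif generated each positive is
#' returned separately (`truth`) so that clustering purity can be scored
#' without the labels ever entering a training or evaluation path.
#'
#' @param spec a `dataset_spec`.
#' @return list with `positives`, `negatives` (fragment data.frames) and
#'   `truth` (data.frame `index`, `motif`, `planted` for the positives;
#'   `planted` marks full consensus carriers). Fully deterministic given
#'   `spec$seed`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  make_frags <- function(mat, label, offset = 0L) {
    n <- nrow(mat)
    if (n == 0L) return(empty_fragments())
    data.frame(
      protein_id = sprintf("SYN%s_%05d",
                           ifelse(label == "positive", "P", "N"),
                           seq_len(n) + offset),
      position = spec$w + 1L,
      residue = spec$residue_class,
      window = apply(mat, 1, paste0, collapse = ""),
      label = label, stringsAsFactors = FALSE)
  }

  with_seed(spec$seed, {
    pos_mat <- random_window_matrix(spec$n_pos, spec$w, spec$residue_class,
                                    spec$background)
    neg_mat <- random_window_matrix(spec$n_neg, spec$w, spec$residue_class,
                                    spec$background)
    positives <- make_frags(pos_mat, "positive")
    negatives <- make_frags(neg_mat, "negative")

    motif_of <- rep(NA_character_, spec$n_pos)
    planted_flag <- rep(FALSE, spec$n_pos)
    if (length(spec$motifs) > 0 && spec$n_pos > 0) {
      wts <- vapply(spec$motifs, `[[`, numeric(1), "weight")
      comp <- sample.int(length(spec$motifs), spec$n_pos, replace = TRUE,
                         prob = wts)
      for (mi in seq_along(spec$motifs)) {
        idx <- which(comp == mi)
        if (length(idx) == 0L) next
        planted <- plant_motif(positives[idx, , drop = FALSE],
                               spec$motifs[[mi]],
                               seed = derive_seed(spec$seed, mi))
        positives$window[idx] <- planted$window
        planted_flag[idx] <- attr(planted, "planted")
      }
      motif_of <- paste0("M", comp)
    }
    list(positives = positives, negatives = negatives,
         truth = data.frame(index = seq_len(spec$n_pos), motif = motif_of,
                            planted = planted_flag, stringsAsFactors = FALSE))
  })
}

#' Write a synthetic dataset as FASTA + sites TSV + fragment TSVs
#'
#' Each fragment becomes one synthetic protein whose sequence is its
#' (unpadded) window, with positive centers annotated in the sites TSV, so
#' the full training pipeline can consume simulated data end to end.
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_frags <- rbind(dataset$positives, dataset$negatives)
  fasta <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", all_frags$protein_id, "\n", all_frags$window),
             fasta)
  sites <- file.path(dir, "sites.tsv")
  pos <- dataset$positives
  utils::write.table(
    data.frame(protein_id = pos$protein_id, position = pos$position,
               residue = pos$residue),
    sites, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  frag_tsv <- file.path(dir, "fragments.tsv")
  write_fragments(all_frags, frag_tsv)
  invisible(c(fasta = fasta, sites = sites, fragments = frag_tsv))
}
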