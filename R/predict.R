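#' Scan one protein for phosphosites of a residue class
#'
#' Every residue of the class yields one record: its window (extracted and
#' padded exactly as in training) is scored against all models of the class
#' and called a phosphosite when at least one model scores above its
#' calibrated threshold; a site called by several models reports the
#' highest-scoring cluster (ties break by model order). If every model
#' scores below threshold the residue is a non-site.
#'
#' @param models non-empty list of calibrated `profile_model`, all of one
#'   class.
#' @param protein single-row data.frame with `id` and `sequence` (or a
#'   list with those elements).
#' @param all_sites if `FALSE` (default) only phosphosite calls are
#'   returned; if `TRUE` every scanned residue is reported with its
#'   decision.
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `window`, `best_cluster`, `best_score`, `decision`.
#' @export
scan_protein <- function(models, protein, all_sites = FALSE) {
  stopifnot(length(models) > 0)
  classes <- unique(vapply(models, `[[`, "", "class"))
  if (length(classes) != 1L) stop("models must share one residue class")
  if (any(is.na(vapply(models, `[[`, numeric(1), "threshold_bits")))) {
    stop("models must carry calibrated thresholds")
  }
  w <- models[[1]]$w
  seq_chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  pos <- which(seq_chars == classes)
  if (length(pos) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), window = character(0),
                      best_cluster = character(0), best_score = numeric(0),
                      decision = character(0), stringsAsFactors = FALSE))
  }
  windows <- vapply(pos, function(p) extract_window(protein$sequence, p, w),
                    "")
  pred <- ensemble_predict(models, windows)
  out <- data.frame(protein_id = protein$id, position = pos,
                    residue = classes, window = windows,
                    best_cluster = pred$best_cluster,
                    best_score = pred$best_score,
                    decision = ifelse(pred$positive, "phosphosite",
                                      "non-site"),
                    stringsAsFactors = FALSE)
  if (!all_sites) out <- out[out$decision == "phosphosite", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict phosphosites across a set of proteins
#'
#' Applies [scan_protein()] to every protein. Model sets of different
#' residue classes (S, T, Y) are run independently and their predictions
#' concatenated.
#'
#' @param model_sets a list of `profile_model` lists (one per class), or a
#'   single list of models of one class.
#' @param proteins data.frame from [read_proteins()].
#' @param all_sites report non-sites too (default `FALSE`).
#' @return combined prediction data.frame, ordered by protein and position.
#' @export
predict_sites <- function(model_sets, proteins, all_sites = FALSE) {
  if (length(model_sets) > 0 && inherits(model_sets[[1]], "profile_model")) {
    model_sets <- list(model_sets)
  }
  out <- do.call(rbind, lapply(model_sets, function(models) {
    do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
      scan_protein(models, proteins[i, ], all_sites = all_sites)
    }))
  }))
  if (is.null(out)) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), window = character(0),
                      best_cluster = character(0), best_score = numeric(0),
                      decision = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
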