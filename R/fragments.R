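#' Read protein sequences from a FASTA file
#'
#' @param fasta_path path to a (multi-record) FASTA file of protein sequences.
#' @return data.frame with columns `id` and `sequence`. Record ids are the
#'   first whitespace-delimited token of each header and must be unique.
#' @export
read_proteins <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- tryCatch(
    Biostrings::readAAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- toupper(as.character(seqs))
  if (any(!nzchar(sequences))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(sequences), stringsAsFactors = FALSE)
}

#' Read phosphosite annotations from a TSV file
#'
#' Expected columns: `protein_id`, `position` (1-based), `residue`
#' (one of S/T/Y). A header line is optional and lines starting with `#`
#' are ignored.
#'
#' @param sites_path path to the annotation TSV.
#' @return data.frame with columns `protein_id`, `position`, `residue`.
#' @export
read_sites <- function(sites_path) {
  if (!file.exists(sites_path)) stop("sites file not found: ", sites_path)
  raw <- utils::read.table(sites_path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("protein_id", "position", "residue"),
                           colClasses = c("character", "character", "character"))
  # tolerate an optional header row
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.integer(raw$position[1])))) {
    raw <- raw[-1, , drop = FALSE]
  }
  pos <- suppressWarnings(as.integer(raw$position))
  if (anyNA(pos)) {
    stop("non-integer positions in sites file at data row(s): ",
         paste(utils::head(which(is.na(pos)), 5), collapse = ", "))
  }
  data.frame(protein_id = raw$protein_id, position = pos,
             residue = toupper(raw$residue), stringsAsFactors = FALSE)
}

#' Load and cross-validate proteins and site annotations
#'
#' Annotations referencing unknown proteins are dropped with a message;
#' an annotation whose residue does not match the protein sequence at the
#' annotated position is an error (it indicates inconsistent inputs).
#' Duplicate annotations (same protein and position) collapse to one.
#'
#' @param fasta_path path to the protein FASTA.
#' @param sites_path path to the site annotation TSV.
#' @return list with elements `proteins` and `sites` (validated data.frames).
#' @export
load_inputs <- function(fasta_path, sites_path) {
  proteins <- read_proteins(fasta_path)
  sites <- read_sites(sites_path)

  known <- sites$protein_id %in% proteins$id
  if (any(!known)) {
    message("dropped ", sum(!known),
            " annotation(s) referencing unknown proteins")
    sites <- sites[known, , drop = FALSE]
  }

  if (nrow(sites) > 0) {
    seqs <- proteins$sequence[match(sites$protein_id, proteins$id)]
    bad_pos <- sites$position < 1L | sites$position > nchar(seqs)
    if (any(bad_pos)) {
      i <- which(bad_pos)[1]
      stop("annotation position out of range: protein ", sites$protein_id[i],
           " position ", sites$position[i])
    }
    at <- substr(seqs, sites$position, sites$position)
    mism <- at != sites$residue
    if (any(mism)) {
      i <- which(mism)[1]
      stop("annotated residue mismatch: protein ", sites$protein_id[i],
           " position ", sites$position[i], " has '", at[i],
           "' but annotation says '", sites$residue[i], "'")
    }
    if (!all(sites$residue %in% c("S", "T", "Y"))) {
      i <- which(!sites$residue %in% c("S", "T", "Y"))[1]
      stop("annotated residue must be S, T or Y: protein ",
           sites$protein_id[i], " position ", sites$position[i])
    }
    dup <- duplicated(sites[c("protein_id", "position")])
    if (any(dup)) {
      warning(sum(dup), " duplicate annotation(s) collapsed")
      sites <- sites[!dup, , drop = FALSE]
    }
  }
  rownames(sites) <- NULL
  list(proteins = proteins, sites = sites)
}

#' Extract a fixed-length window around one position
#'
#' Windows overhanging the protein termini are padded with `X` so that all
#' windows have length `2w + 1` and remain positionally aligned.
#'
#' @param sequence protein sequence string.
#' @param position 1-based center position.
#' @param w half-window size.
#' @return window string of length `2w + 1`.
#' @export
extract_window <- function(sequence, position, w) {
  n <- nchar(sequence)
  lo <- position - w
  hi <- position + w
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - n)
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep(PAD_CHAR, left_pad), core, strrep(PAD_CHAR, right_pad))
}

#' Extract labeled peptide windows for one residue class
#'
#' Every residue of `residue_class` in every protein yields one fragment:
#' positive if annotated as a phosphosite, negative otherwise.
#'
#' @param proteins data.frame as returned by [read_proteins()].
#' @param sites validated annotation data.frame (see [load_inputs()]).
#' @param w half-window size (default 10, i.e. 21-mers).
#' @param residue_class one of "S", "T", "Y".
#' @return list with data.frames `positives` and `negatives`, each with
#'   columns `protein_id`, `position`, `residue`, `window`, `label`.
#' @export
extract_fragments <- function(proteins, sites, w = 10L,
                              residue_class = c("S", "T", "Y")) {
  residue_class <- match.arg(residue_class)
  stopifnot(w >= 1L)
  sites <- sites[sites$residue == residue_class, , drop = FALSE]

  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    seq_i <- proteins$sequence[i]
    pos <- which(strsplit(seq_i, "", fixed = TRUE)[[1]] == residue_class)
    if (length(pos) == 0L) return(NULL)
    ann <- sites$position[sites$protein_id == proteins$id[i]]
    data.frame(
      protein_id = proteins$id[i],
      position = pos,
      residue = residue_class,
      window = vapply(pos, function(p) extract_window(seq_i, p, w), ""),
      label = ifelse(pos %in% ann, "positive", "negative"),
      stringsAsFactors = FALSE
    )
  })
  frags <- do.call(rbind, c(rows, list(empty_fragments())))
  rownames(frags) <- NULL
  list(positives = frags[frags$label == "positive", , drop = FALSE],
       negatives = frags[frags$label == "negative", , drop = FALSE])
}

#' Remove redundant fragments
#'
#' Within each set, only the first occurrence of each window string is kept.
#' A window present in both sets survives only in the positive set: negative
#' copies of positive windows are removed.
#'
#' @param positives,negatives fragment data.frames of one residue class.
#' @return list with deduplicated `positives` and `negatives`.
#' @export
deduplicate_fragments <- function(positives, negatives) {
  pos <- positives[!duplicated(positives$window), , drop = FALSE]
  neg <- negatives[!duplicated(negatives$window), , drop = FALSE]
  neg <- neg[!neg$window %in% pos$window, , drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  list(positives = pos, negatives = neg)
}

#' Write fragments to the TSV exchange format
#'
#' Columns: `protein_id`, `position`, `residue`, `window`, `label`.
#'
#' @param fragments fragment data.frame.
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(
    fragments[c("protein_id", "position", "residue", "window", "label")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fragments from the TSV exchange format
#'
#' @param path path written by [write_fragments()].
#' @return fragment data.frame.
#' @export
read_fragments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "character", "character"))
  df
}
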