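# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

# A fragment data.frame from raw window strings.
frags_from_windows <- function(windows, label = "positive",
                               residue = NULL) {
  if (length(windows) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), window = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(residue)) {
    w <- (nchar(windows[1]) - 1L) %/% 2L
    residue <- substr(windows, w + 1L, w + 1L)
  }
  data.frame(protein_id = sprintf("F%04d", seq_along(windows)),
             position = 11L, residue = residue, window = windows,
             label = label, stringsAsFactors = FALSE)
}

# n random 21-mer windows centered on `center`, uniform background.
random_windows <- function(n, center = "S", w = 10L, seed = 1L) {
  set.seed(seed)
  mat <- matrix(sample(AA20, n * (2 * w + 1), replace = TRUE),
                nrow = n)
  mat[, w + 1L] <- center
  apply(mat, 1, paste0, collapse = "")
}

# Write a small FASTA + sites TSV fixture pair; returns the two paths.
write_protein_fixture <- function(dir, records, sites) {
  fasta <- file.path(dir, "prot.fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), fasta)
  sites_path <- file.path(dir, "sites.tsv")
  writeLines(c("# fixture annotations",
               vapply(sites, function(s) paste(s, collapse = "\t"), "")),
             sites_path)
  list(fasta = fasta, sites = sites_path)
}

# Independent textbook Pearson chi-square on a contingency matrix
# (brute-force double loop; deliberately not the package implementation).
oracle_pearson <- function(tab) {
  X <- sum(tab)
  total <- 0
  for (m in seq_len(nrow(tab))) {
    for (n in seq_len(ncol(tab))) {
      E <- sum(tab[m, ]) * sum(tab[, n]) / X
      if (E > 0) total <- total + (tab[m, n] - E)^2 / E
    }
  }
  total
}

# Strong-signal three-motif S-like dataset used by pipeline-level tests.
strong_three_motif_spec <- function(n_pos = 600L, n_neg = 600L, seed = 42L) {
  mk <- function(coords, syms) {
    motif_spec(setNames(lapply(syms, function(s) list(symbol = s, prob = 0.9)),
                        coords),
               coupling = as.integer(coords[1:2]), weight = 1 / 3)
  }
  dataset_spec(n_pos, n_neg, motifs = list(
    mk(c("1", "3", "5"), c("P", "D", "E")),
    mk(c("-3", "-5", "-1"), c("K", "R", "K")),
    mk(c("2", "-2", "4"), c("F", "W", "P"))
  ), seed = seed)
}
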