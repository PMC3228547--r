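test_that("the default group scheme covers the alphabet as documented", {
  scheme <- default_group_scheme()
  expect_setequal(names(scheme), AA20)
  expect_equal(as.character(map_group("P")), "imino")
  expect_equal(as.character(map_group(c("D", "E"))), c("acid", "acid"))
  expect_equal(as.character(map_group("G")), "neutral")
  expect_true(all(c("K", "R", "H") %in%
                    names(scheme)[scheme == "basic"]))
  # pads and non-standard letters are unmapped
  expect_true(is.na(map_group("X")))
  expect_true(is.na(map_group("B")))
})

test_that("contingency tables count group co-occurrence and skip pads", {
  # 10 fragments, all P at +1 and K at -3
  win <- paste0(strrep("A", 7), "K", strrep("A", 2), "S", "P",
                strrep("A", 9))
  frags <- frags_from_windows(rep(win, 10))
  tab <- contingency(frags, i = 1, j = -3)
  expect_equal(tab["imino", "basic"], 10L)
  expect_equal(sum(tab), 10L)

  # pads at a position exclude the fragment from the pair's total
  win_pad <- paste0("X", strrep("A", 6), "K", strrep("A", 2), "S", "P",
                    strrep("A", 9))
  frags2 <- frags_from_windows(c(rep(win, 5), rep(win_pad, 5)))
  tab2 <- contingency(frags2, i = -10, j = 1)
  expect_equal(sum(tab2), 5L)

  expect_error(contingency(frags, 2, 2), "differ")
  expect_error(contingency(frags, 0, 1), "position 0")
})

test_that("contingency counts match a brute-force double loop", {
  frags <- frags_from_windows(random_windows(50, seed = 21))
  scheme <- default_group_scheme()
  for (pair in list(c(-10, 1), c(2, 7), c(-4, -2))) {
    tab <- contingency(frags, pair[1], pair[2])
    # oracle: explicit per-fragment loop
    oracle <- matrix(0L, 5, 5,
                     dimnames = dimnames(tab))
    for (f in frags$window) {
      chars <- strsplit(f, "")[[1]]
      gi <- scheme[chars[pair[1] + 11]]
      gj <- scheme[chars[pair[2] + 11]]
      if (is.na(gi) || is.na(gj)) next
      oracle[gi, gj] <- oracle[gi, gj] + 1L
    }
    expect_equal(unclass(tab)[seq_len(5), seq_len(5)], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("chi-square follows the Pearson formula with zero-margin cells skipped", {
  # exact independence (outer-product table) scores 0
  tab <- outer(c(10, 20, 5, 5, 10), c(8, 2, 10, 20, 10)) / 50
  expect_equal(chi_square(tab), 0)

  # two-diagonal toy table: direct summation gives 20
  toy <- matrix(0, 5, 5)
  toy[1, 1] <- 10
  toy[2, 2] <- 10
  expect_equal(chi_square(toy), 20)

  expect_warning(z <- chi_square(matrix(0, 5, 5)), "empty")
  expect_equal(z, 0)
})

test_that("chi-square matches an independent Pearson oracle on random tables", {
  set.seed(314)
  for (rep in seq_len(100)) {
    tab <- matrix(rpois(25, lambda = sample(1:10, 1)), 5, 5)
    if (sum(tab) == 0) next
    ours <- chi_square(tab)
    ref <- oracle_pearson(tab)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("chi-square is symmetric under position transposition", {
  frags <- frags_from_windows(random_windows(80, seed = 77))
  for (pair in list(c(-3, 1), c(5, 9), c(-8, 8))) {
    a <- chi_square(contingency(frags, pair[1], pair[2]))
    b <- chi_square(contingency(frags, pair[2], pair[1]))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("the default cutoff is the upper-0.005 chi-square quantile at 16 df", {
  expect_equal(round(chi_square_cutoff(), 1), 34.3)
  expect_equal(chi_square_cutoff(), qchisq(0.995, df = 16))
})

test_that("choose_split finds planted couplings and returns none on noise", {
  # null case: i.i.d. uniform fragments
  null_frags <- frags_from_windows(random_windows(500, seed = 1234))
  expect_null(choose_split(null_frags))

  # planted coupling: imino at +1 with acid at +3, jointly, in half the data
  spec <- dataset_spec(1000, 0, motifs = list(
    motif_spec(list(`1` = list(symbol = "imino", prob = 0.5),
                    `3` = list(symbol = "acid", prob = 0.5)),
               coupling = c(1, 3), weight = 1)), seed = 5)
  ds <- generate_dataset(spec)
  split <- choose_split(ds$positives)
  expect_true(split$position %in% c(1L, 3L))
  # P-frequency at +1 exceeds any single acid residue draw spread over D/E,
  # and the S_i tie-break prefers the smaller coordinate: +1 wins
  expect_equal(split$position, 1L)
  expect_equal(split$group, "imino")
})

test_that("mdd_cluster partitions fragments into a valid tree", {
  spec <- dataset_spec(400, 0, motifs = list(
    motif_spec(list(`1` = list(symbol = "P", prob = 0.9),
                    `3` = list(symbol = "acid", prob = 0.9)),
               coupling = c(1, 3), weight = 0.5),
    motif_spec(list(`-3` = list(symbol = "K", prob = 0.9),
                    `-5` = list(symbol = "basic", prob = 0.9)),
               coupling = c(-3, -5), weight = 0.5)), seed = 9)
  ds <- generate_dataset(spec)
  root <- mdd_cluster(ds$positives, min_cluster_size = 200)

  # leaves partition the input exactly
  leaves <- mddphos:::mdd_leaf_nodes(root)
  idx <- sort(unlist(lapply(leaves, `[[`, "members")))
  expect_equal(idx, seq_len(nrow(ds$positives)))

  check_node <- function(node) {
    if (is.null(node$split_position)) return(invisible())
    expect_gte(node$n, 200)
    expect_setequal(c(node$present_child$members, node$absent_child$members),
                    node$members)
    expect_length(intersect(node$present_child$members,
                            node$absent_child$members), 0)
    # present child members all carry the split group at the split position
    w <- 10L
    chars <- substr(ds$positives$window[node$present_child$members],
                    node$split_position + w + 1, node$split_position + w + 1)
    grp <- as.character(map_group(chars))
    expect_true(all(grp == node$split_group, na.rm = TRUE))
    check_node(node$present_child)
    check_node(node$absent_child)
  }
  check_node(root)

  # two disjoint motifs end up in different leaves with high purity
  cls <- motif_clusters(root, "S")
  for (mo in c("M1", "M2")) {
    ids <- ds$positives$protein_id[ds$truth$motif == mo & ds$truth$planted]
    best <- max(vapply(cls, function(cl) {
      mean(ids %in% cl$members$protein_id)
    }, numeric(1)))
    expect_gte(best, 0.95)
  }

  # a set smaller than min_cluster_size is a single leaf
  small <- ds$positives[1:50, ]
  root_small <- mdd_cluster(small, min_cluster_size = 200)
  expect_null(root_small$split_position)
  expect_equal(root_small$n, 50L)
})

test_that("planted coupling recovery holds across seeds", {
  hits <- 0L
  for (s in 1:20) {
    ds <- generate_dataset(dataset_spec(800, 0, motifs = list(
      motif_spec(list(`1` = list(symbol = "imino", prob = 0.5),
                      `3` = list(symbol = "acid", prob = 0.5)),
                 coupling = c(1, 3), weight = 1)), seed = 1000 + s))
    split <- choose_split(ds$positives)
    if (!is.null(split) && split$position %in% c(1L, 3L)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("merge_similar collapses identical profiles and respects distance", {
  windows_p <- vapply(seq_len(30), function(i) {
    win <- random_windows(1, seed = 400 + i)
    substr(win, 12, 12) <- "P"
    win
  }, "")
  windows_d <- vapply(seq_len(30), function(i) {
    win <- random_windows(1, seed = 500 + i)
    substr(win, 14, 14) <- "D"
    win
  }, "")
  scheme <- default_group_scheme()
  cl_p1 <- mddphos:::new_motif_cluster("S1", frags_from_windows(windows_p),
                                       scheme)
  cl_p2 <- mddphos:::new_motif_cluster("S2", frags_from_windows(windows_p),
                                       scheme)
  cl_d <- mddphos:::new_motif_cluster("S3", frags_from_windows(windows_d),
                                      scheme)

  # identical profiles merge at any positive threshold
  merged <- merge_similar(list(cl_p1, cl_p2), threshold = 1e-6)
  expect_length(merged, 1L)
  expect_equal(nrow(merged[[1]]$members), 60L)

  # disjoint single-position consensus stays separate at threshold 0.1:
  # the oracle JS distance between the profiles exceeds it
  d <- mddphos:::motif_distance(cl_p1$group_freq, cl_d$group_freq)
  expect_gt(d, 0.1)
  kept <- merge_similar(list(cl_p1, cl_d), threshold = 0.1)
  expect_length(kept, 2L)

  # threshold 0 disables merging entirely
  expect_length(merge_similar(list(cl_p1, cl_p2), threshold = 0), 2L)
})

test_that("motif summaries report frequencies and information content", {
  # all members share P at +1: a point mass carries log2(20) bits
  win <- paste0(strrep("A", 10), "S", "P", strrep("A", 9))
  cl <- mddphos:::new_motif_cluster("S1", frags_from_windows(rep(win, 5)),
                                    default_group_scheme())
  s <- motif_summary(cl)
  expect_equal(unname(s$information[["1"]]), log2(20), tolerance = 1e-12)
  expect_equal(sum(s$frequencies[, "1"]), 1)

  # uniform residue usage scores 0 bits
  wins <- vapply(AA20, function(a) {
    paste0(a, strrep("A", 9), "S", strrep("A", 10))
  }, "")
  cl2 <- mddphos:::new_motif_cluster("S1", frags_from_windows(wins),
                                     default_group_scheme())
  s2 <- motif_summary(cl2)
  expect_equal(unname(s2$information[["-10"]]), 0, tolerance = 1e-12)

  # an all-pad position is flagged and reported as 0 bits
  win_pad <- paste0("X", strrep("A", 9), "S", strrep("A", 10))
  cl3 <- mddphos:::new_motif_cluster("S1", frags_from_windows(rep(win_pad, 3)),
                                     default_group_scheme())
  s3 <- motif_summary(cl3)
  expect_true(s3$all_pad[1])
  expect_equal(unname(s3$information[["-10"]]), 0)
})
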