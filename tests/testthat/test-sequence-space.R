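test_that("hamming_distance handles base cases and satisfies metric axioms", {
  expect_equal(hamming_distance("ACDE", "ACDE"), 0)
  expect_equal(hamming_distance("ACDE", "ACDF"), 1)
  expect_error(hamming_distance("ACDE", "AC"), "4 vs 2")

  withr::with_seed(42, {
    for (i in 1:50) {
      L <- sample(3:12, 1L)
      s <- replicate(3L, paste(sample(AA20, L, replace = TRUE),
                               collapse = ""))
      d12 <- hamming_distance(s[1], s[2])
      expect_equal(hamming_distance(s[1], s[1]), 0)
      expect_equal(d12, hamming_distance(s[2], s[1]))
      expect_equal(d12 == 0, s[1] == s[2])
      expect_lte(hamming_distance(s[1], s[3]),
                 d12 + hamming_distance(s[2], s[3]))
    }
  })
})

test_that("filter_by_distance keeps the parent's neighbourhood in order", {
  parent <- make_parent(10L)
  rows <- c("AAAAAAAAAA",              # d = 0
            "VAAAAAAAAK",              # d = 2
            "VVVVVAAAAA")              # d = 5
  data <- labeled_dataset(rows, c(1, 2, 3))
  out <- filter_by_distance(data, parent, max_d = 2L)
  expect_equal(out$sequence, rows[1:2])
  expect_equal(out$value, c(1, 2))
  expect_equal(filter_by_distance(data, parent, 0L)$sequence, rows[1])
  # input unmodified
  expect_equal(nrow(data), 3L)

  bad <- labeled_dataset(c("AAAAAAAAAA", "AAA"), c(1, 2))
  expect_error(filter_by_distance(bad, parent, 2L), "row 2")
})

test_that("build_search_space unions mutations of the top rows", {
  parent <- make_parent(25L)
  v10 <- sub_at(parent$residues, 10L, "V")
  k20 <- sub_at(parent$residues, 20L, "K")
  data <- labeled_dataset(c(v10, k20), c(5, 4))
  space <- build_search_space(data, parent, top_n = 2L)
  expect_equal(space$positions, c(10L, 20L))
  expect_setequal(space$candidates[[1]], c("A", "V"))
  expect_setequal(space$candidates[[2]], c("A", "K"))

  # top row identical to parent: degenerate zero-position space
  data2 <- labeled_dataset(c(parent$residues, v10), c(9, 1))
  space2 <- build_search_space(data2, parent, top_n = 1L)
  expect_length(space2$positions, 0L)
  expect_equal(realize_variant(space2, character(0)), parent$residues)

  # one top row carrying two mutations
  dbl <- sub_at(sub_at(parent$residues, 3L, "D"), 7L, "E")
  space3 <- build_search_space(labeled_dataset(dbl, 1), parent, top_n = 1L)
  expect_equal(space3$positions, c(3L, 7L))
  expect_setequal(space3$candidates[[1]], c("A", "D"))
  expect_setequal(space3$candidates[[2]], c("A", "E"))

  expect_error(build_search_space(data[0, ], parent, 1L), "empty")
})

test_that("build_search_space breaks value ties stably by input order", {
  parent <- make_parent(12L)
  rows <- c(sub_at(parent$residues, 2L, "V"),
            sub_at(parent$residues, 5L, "K"),
            sub_at(parent$residues, 8L, "D"))
  data <- labeled_dataset(rows, c(1, 1, 1))          # all tied
  space <- build_search_space(data, parent, top_n = 2L)
  expect_equal(space$positions, c(2L, 5L))           # first two rows win
})

test_that("spaces built from data contain the parent and every top row", {
  withr::with_seed(7, {
    parent <- make_parent(20L)
    seqs <- replicate(12L, {
      s <- parent$residues
      for (p in sample(20L, sample(1:3, 1L)))
        s <- sub_at(s, p, sample(setdiff(AA20, "A"), 1L))
      s
    })
    data <- labeled_dataset(seqs, rnorm(12L))
    space <- build_search_space(data, parent, top_n = 5L)
    # parent assignment realizes to the parent
    pv <- substring(parent$residues, space$positions, space$positions)
    expect_equal(realize_variant(space, pv), parent$residues)
    # each of the top 5 rows is realizable in the space
    top <- data$sequence[order(-data$value)][1:5]
    for (s in top) {
      v <- substring(s, space$positions, space$positions)
      expect_equal(realize_variant(space, v), s)
    }
  })
})

test_that("count_combinations is an exact product", {
  parent <- make_parent(8L)
  space <- search_space(parent, c(1L, 3L, 5L),
                        list(c("A", "V"), c("A", "V", "K"),
                             c("A", "V", "K", "D")))
  expect_identical(count_combinations(space), "24")
  space0 <- search_space(parent, integer(0), list())
  expect_identical(count_combinations(space0), "1")
})

test_that("count_combinations matches brute-force enumeration on small spaces", {
  withr::with_seed(3, {
    for (i in 1:5) {
      n_pos <- sample(2:4, 1L)
      space <- make_space(n_pos = n_pos, n_cand = sample(2:4, 1L))
      grid <- expand.grid(space$candidates, stringsAsFactors = FALSE)
      expect_identical(count_combinations(space), as.character(nrow(grid)))
    }
  })
})

test_that("realize_variant substitutes exactly at the mutable positions", {
  space <- make_space(n_pos = 3L, n_cand = 3L)   # positions 1, 3, 5
  parent <- space$parent$residues
  expect_equal(realize_variant(space, c("A", "A", "A")), parent)
  one <- realize_variant(space, c("A", "V", "A"))
  expect_equal(hamming_distance(one, parent), 1)
  expect_equal(substring(one, 3L, 3L), "V")
  expect_error(realize_variant(space, c("A", "W", "A")), "position 3")
  expect_error(realize_variant(space, c("A", "V")), "3")

  withr::with_seed(11, {
    for (i in 1:25) {
      v <- random_variant(space)
      pv <- c("A", "A", "A")
      expect_equal(hamming_distance(realize_variant(space, v), parent),
                   sum(v != pv))
    }
  })
})

test_that("search_space enforces its invariants", {
  parent <- make_parent(6L)
  expect_error(search_space(parent, c(3L, 1L), rep(list("V"), 2L)),
               "strictly increasing")
  expect_error(search_space(parent, c(1L, 9L), rep(list("V"), 2L)), "1..6")
  # parent residue added to candidate sets automatically
  sp <- search_space(parent, 2L, list("V"))
  expect_setequal(sp$candidates[[1]], c("A", "V"))
  expect_error(parent_sequence("bad", "ACDB1"), "outside the alphabet")
  expect_error(parent_sequence("empty", ""), "empty")
})

test_that("search-space TSV export is 1-based with comma-joined candidates", {
  space <- make_space(n_pos = 2L, n_cand = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_search_space(space, path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(df$position_1based, space$positions)
  expect_equal(df$parent_residue, c("A", "A"))
  expect_equal(df$candidate_residues, rep("A,V,K", 2L))
})
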