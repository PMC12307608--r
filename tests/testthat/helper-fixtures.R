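# Small builders shared across tests. Spaces use an all-alanine parent with
# evenly spaced mutable positions so distances and effects are easy to read.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

make_parent <- function(L, id = "parent") {
  parent_sequence(id, strrep("A", L))
}

make_space <- function(n_pos = 4L, n_cand = 2L, gap = 2L,
                       cand_pool = c("A", "V", "K", "D", "E")) {
  parent <- make_parent(n_pos * gap)
  search_space(parent, seq(1L, n_pos * gap, gap),
               rep(list(cand_pool[seq_len(n_cand)]), n_pos))
}

sub_at <- function(s, pos, res) {
  substring(s, pos, pos) <- res
  s
}

random_variant <- function(space) {
  vapply(space$candidates, function(cand)
    cand[sample.int(length(cand), 1L)], character(1L))
}

# A small trained proxy over a space, for objective/optimizer tests.
make_proxy <- function(space, landscape = NULL, n_train = 60L,
                       max_d = 2L, seed = 99L) {
  if (is.null(landscape))
    landscape <- generate_landscape(space,
                                    n_epistasis = min(2L, choose(length(space$positions), 2L)),
                                    effect_sd = 0.5,
                                    collapse_distance = 3L, noise_sd = 0.05,
                                    seed = seed)
  n_ball <- nrow(mdtpe:::enumerate_ball(space, max_d))
  train <- generate_training_set(landscape, min(n_train, n_ball),
                                 max_d = max_d, seed = seed + 1L)
  feat <- onehot_featurizer(space)
  X <- t(vapply(train$sequence, feat, numeric(20L * length(space$positions))))
  list(proxy = gp_fit(X, train$value, kernel_config(), seed = 1L),
       train = train, featurizer = feat, landscape = landscape)
}
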