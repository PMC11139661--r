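# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Star-shaped test mesh: icosphere vertices pushed radially by random factors.
jittered_star_mesh <- function(seed = 1, subdivisions = 2) {
  m <- blastonet::icosphere(1, c(0, 0, 0), subdivisions, cell_id = "star")
  set.seed(seed)
  f <- runif(nrow(m$vertices), 0.8, 1.2)
  blastonet::blastomere_mesh(m$vertices * f, m$faces, cell_id = "star")
}

# Brute force: every labelled simple graph on n nodes -> distinct degree
# count vectors. Feasible for n <= 6 (2^15 graphs).
brute_force_hickman <- function(n) {
  pairs <- t(combn(n, 2))
  m <- nrow(pairs)
  seen <- new.env(parent = emptyenv())
  for (mask in 0:(2^m - 1)) {
    on <- bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0L
    deg <- tabulate(c(pairs[on, 1], pairs[on, 2]), nbins = n)
    counts <- tabulate(deg + 1L, nbins = n)
    assign(paste(counts, collapse = ","), counts, envir = seen)
  }
  out <- lapply(sort(ls(seen)), function(k) get(k, envir = seen))
  out
}

# Exhaustive epsilon-grid threshold search: the oracle fit_threshold must
# match. Evaluates prediction-AUC on a dense grid plus sentinels.
grid_fit_threshold <- function(x, y, n_grid = 2000) {
  grid <- c(min(x) - 1,
            seq(min(x) - 0.5, max(x) + 0.5, length.out = n_grid),
            max(x) + 1)
  auc_of <- function(th) {
    pred <- as.integer(x > th)
    sens <- sum(pred == 1 & y == 1) / sum(y == 1)
    spec <- sum(pred == 0 & y == 0) / sum(y == 0)
    (sens + spec) / 2
  }
  aucs <- vapply(grid, auc_of, numeric(1))
  max(aucs)
}

# Simple graph -> contact_network for test construction; `edges` is a
# flat vector c(i1, j1, i2, j2, ...).
net_from_edges <- function(n, edges = integer()) {
  em <- if (length(edges)) matrix(edges, ncol = 2, byrow = TRUE)
        else matrix(integer(), 0, 2)
  blastonet::contact_network_obj(n, em)
}

# Unit-sphere embryo at explicit centers (radius 1 icospheres).
canonical_sphere_embryo <- function(centers, subdivisions = 2) {
  meshes <- lapply(seq_len(nrow(centers)), function(i) {
    blastonet::icosphere(1, centers[i, ], subdivisions,
                         cell_id = sprintf("c%d", i))
  })
  blastonet::embryo(meshes)
}

# Random simple graph on n nodes with edge probability p.
random_network <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  on <- runif(nrow(pairs)) < p
  blastonet::contact_network_obj(n, pairs[on, , drop = FALSE])
}
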