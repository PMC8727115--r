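# Independent oracles: the information measures written out literally as
# sums over full probability tables, using none of the package's counting
# machinery. Deliberately slow and explicit.

oracle_entropy <- function(x) {
  h <- 0
  for (v in unique(x)) {
    p <- mean(x == v)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# I(X;Y) = sum_i sum_j p(x_i, y_j) log2( p(x_i, y_j) / (p(x_i) p(y_j)) )
oracle_mi <- function(x, y) {
  total <- 0
  for (xv in unique(x)) for (yv in unique(y)) {
    pxy <- mean(x == xv & y == yv)
    if (pxy > 0) {
      total <- total + pxy * log2(pxy / (mean(x == xv) * mean(y == yv)))
    }
  }
  total
}

# I(X;Y|Z) = sum_t p(z_t) sum_i sum_j p(x,y|z) log2( p(x,y|z) / (p(x|z) p(y|z)) )
oracle_cmi <- function(x, y, z) {
  total <- 0
  for (zv in unique(z)) {
    pz <- mean(z == zv)
    xs <- x[z == zv]; ys <- y[z == zv]
    total <- total + pz * oracle_mi(xs, ys)
  }
  total
}

oracle_cond_entropy <- function(x, given) {
  total <- 0
  for (gv in unique(given)) {
    total <- total + mean(given == gv) * oracle_entropy(x[given == gv])
  }
  total
}

random_triple <- function(n_max = 30L, arity_max = 4L) {
  n <- sample(3:n_max, 1L)
  list(
    x = sample.int(sample(2:arity_max, 1L), n, replace = TRUE),
    y = sample.int(sample(2:arity_max, 1L), n, replace = TRUE),
    z = sample.int(sample(2:arity_max, 1L), n, replace = TRUE)
  )
}

# Exact XOR fixture: X, Y iid balanced bits, C = X xor Y, all four patterns
# equally frequent; plus an independent balanced noise bit.
xor_fixture <- function(reps = 2L) {
  g <- expand.grid(x = 0:1, y = 0:1, b = 0:1)
  g <- g[rep(seq_len(nrow(g)), reps), ]
  data.frame(x = g$x, y = g$y, noise = g$b, class = bitwXor(g$x, g$y))
}

toyA <- ndcrfs::toy_duplicate_data()

# Frozen Toy-A oracle values (computed from the literal summations above)
TOYA <- list(
  H_f1_given_C = 0.811278124459133,   # per-class entropy of (3,1) counts
  I_f1_C = 0.188721875540867,
  I_f3_f1_given_C = 0.311278124459133,
  CU_f1_f2 = 1.23262290680731,        # 2 / (2 * 0.8112781...)
  ndcrfs_f2 = -0.578655217651821,     # duplicate of selected f1
  ndcrfs_f3 = -0.135325709799385      # class-balanced feature
)
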