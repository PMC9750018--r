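# Independent brute-force oracle: enumerates every single-origin genotype
# configuration on the tree, scores it by direct products of numerically
# exponentiated rate matrices (Matrix::expm), multiplies by the error-model
# likelihood computed entrywise, and normalizes. Shares no code path with
# the package's clade-product formulas.

oracle_P <- function(Q, t) {
  as.matrix(Matrix::expm(Q * t))
}

oracle_Q_binary <- function(lambda) {
  matrix(c(-lambda, lambda, 0, 0), 2, 2, byrow = TRUE)
}

oracle_Q_ternary <- function(l1, l2) {
  matrix(c(-(l1 + l1 * l2), l1, l1 * l2,
           0, -l2, l2,
           0, 0, 0), 3, 3, byrow = TRUE)
}

# state of every node given transition events placed on specific edges.
# `edge_to_state` maps branch id -> state entered on that branch; states
# propagate down unchanged otherwise.
oracle_node_states <- function(tree, edge_to_state) {
  st <- integer(max(tree$edges$child, tree$root))
  st[tree$root] <- 0L
  for (b in seq_len(nrow(tree$edges))) {  # preorder: parent known
    p <- tree$edges$parent[b]; ch <- tree$edges$child[b]
    st[ch] <- if (!is.null(edge_to_state[[as.character(b)]]))
      edge_to_state[[as.character(b)]] else st[p]
  }
  st
}

# joint probability of a configuration: product over branches of the
# parent-state -> child-state transition probability
oracle_config_prob <- function(tree, edge_to_state, Pfun) {
  st <- oracle_node_states(tree, edge_to_state)
  prob <- 1
  for (b in seq_len(nrow(tree$edges))) {
    P <- Pfun(tree$edges$length[b])
    prob <- prob * P[st[tree$edges$parent[b]] + 1L, st[tree$edges$child[b]] + 1L]
  }
  list(prob = prob, tip_states = st[seq_len(tree$J)])
}

oracle_site_lik <- function(s_row, g, alpha, beta, mode) {
  N <- error_matrix(alpha, beta, mode)
  ns <- if (mode == "binary") 2L else 3L
  lik <- 1
  for (j in seq_along(s_row)) {
    s <- s_row[j]
    if (is.na(s)) next
    lik <- lik * if (s == -1L) mean(N[g[j] + 1L, ]) else N[g[j] + 1L, s + 1L]
  }
  lik
}

# posterior over branches by enumeration; binary: single-origin edges;
# ternary: all three mechanisms. `s_row` may be NULL (prior only). Missing
# cells (NA) are skipped in the likelihood but — matching the model — the
# enumeration must then run on the projected subtree, so oracle users pass
# complete rows unless they project first.
oracle_posterior <- function(tree, mode, rates, s_row = NULL,
                             alpha = 0, beta = 0) {
  n <- nrow(tree$edges)
  Pfun <- if (mode == "binary") {
    Q <- oracle_Q_binary(rates$lambda)
    function(t) oracle_P(Q, t)
  } else {
    Q <- oracle_Q_ternary(rates$lambda1, rates$lambda2)
    function(t) oracle_P(Q, t)
  }
  w <- numeric(n)
  for (x in seq_len(n)) {
    if (mode == "binary") {
      cfg <- oracle_config_prob(tree, stats::setNames(list(1L), x), Pfun)
      lik <- if (is.null(s_row)) 1 else
        oracle_site_lik(s_row, cfg$tip_states, alpha, beta, mode)
      w[x] <- cfg$prob * lik
    } else {
      # mechanism 0->1 only and 0->2
      for (st in 1:2) {
        w_x <- oracle_mechanism_prob(tree, Pfun, x, st)
        lik <- if (is.null(s_row)) 1 else {
          g <- oracle_genotype(tree, x, st)
          oracle_site_lik(s_row, g, alpha, beta, mode)
        }
        w[x] <- w[x] + w_x * lik
      }
      # mechanism 0->1 on x then 1->2 on y below x
      for (y in clade_desc_edges_oracle(tree, x)) {
        w_xy <- oracle_mechanism_prob2(tree, Pfun, x, y)
        lik <- if (is.null(s_row)) 1 else {
          g <- oracle_genotype2(tree, x, y)
          oracle_site_lik(s_row, g, alpha, beta, mode)
        }
        w[x] <- w[x] + w_xy * lik
      }
    }
  }
  w / sum(w)
}

# --- direct per-branch products for the ternary mechanisms -----------------

clade_desc_edges_oracle <- function(tree, x) {
  # recompute descendants from the raw edge table (no reuse of tree$desc_edges)
  out <- integer(0)
  frontier <- tree$edges$child[x]
  repeat {
    nxt <- which(tree$edges$parent %in% frontier)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- tree$edges$child[nxt]
  }
  sort(out)
}

clade_tip_idx_oracle <- function(tree, x) {
  e <- c(x, clade_desc_edges_oracle(tree, x))
  ch <- tree$edges$child[e]
  sort(ch[ch <= tree$J])
}

oracle_genotype <- function(tree, x, st) {
  g <- integer(tree$J)
  g[clade_tip_idx_oracle(tree, x)] <- st
  g
}

oracle_genotype2 <- function(tree, x, y) {
  g <- integer(tree$J)
  g[clade_tip_idx_oracle(tree, x)] <- 1L
  g[clade_tip_idx_oracle(tree, y)] <- 2L
  g
}

# P(state enters `st` on x, no further change anywhere): product over
# branches of the relevant entries, all taken from expm
oracle_mechanism_prob <- function(tree, Pfun, x, st) {
  desc <- clade_desc_edges_oracle(tree, x)
  prob <- 1
  for (b in seq_len(nrow(tree$edges))) {
    P <- Pfun(tree$edges$length[b])
    prob <- prob * if (b == x) P[1, st + 1L]
      else if (b %in% desc) P[st + 1L, st + 1L]
      else P[1, 1]
  }
  prob
}

oracle_mechanism_prob2 <- function(tree, Pfun, x, y) {
  descx <- clade_desc_edges_oracle(tree, x)
  descy <- clade_desc_edges_oracle(tree, y)
  prob <- 1
  for (b in seq_len(nrow(tree$edges))) {
    P <- Pfun(tree$edges$length[b])
    prob <- prob * if (b == x) P[1, 2]
      else if (b == y) P[2, 3]
      else if (b %in% descy) P[3, 3]
      else if (b %in% descx) P[2, 2]
      else P[1, 1]
  }
  prob
}
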