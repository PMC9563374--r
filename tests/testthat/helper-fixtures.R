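# Shared in-code fixtures and independent oracles.

# small named path graph A-B-C-D-E
path_graph <- function(n = 5) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- LETTERS[seq_len(n)]
  g
}

# two disconnected triangles
two_triangles <- function() {
  g <- igraph::make_graph(~ A - B, B - C, C - A, X - Y, Y - Z, Z - X)
  g
}

# minimal three-disease table built in code
tiny_disease_table <- function() {
  tibble::tibble(
    disease_id = c("D1", "D2", "D3"),
    name = c("one", "two", "three"),
    cluster = factor(c("DB", "DB", "UPB"), levels = c("DB", "PB", "MPB", "UPB")),
    processes = list(
      tibble::tibble(group = c(1L, 1L, 4L), label = c("b1", "b2", "c1")),
      tibble::tibble(group = c(2L, 3L), label = c("t1", "i1")),
      tibble::tibble(group = 3L, label = "i2")
    ),
    effectors = list(c("A", "B"), c("B", "C"), c("D")),
    effector_count = c(2L, 2L, 1L)
  )
}

# Independent enumeration oracle for the hypergeometric upper tail:
# probability that a uniform size-n subset of 1..N hits >= k of the first K.
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Independent step-up BH oracle: q_i = min_{j >= i} p_(j) * m / j on sorted p,
# mapped back to input order.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Independent Pearson chi-squared oracle: sum (O - E)^2 / E with
# margin-product expected counts.
pearson_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
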