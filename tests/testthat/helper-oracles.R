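# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (double loops, exhaustive scans)
# rather than calling the package's own code paths.

# Harrell's C by explicit pair enumeration.
brute_cindex <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (time[a] < time[b] && event[a] == 1) {
        den <- den + 1
        if (risk[a] > risk[b]) num <- num + 1
        else if (risk[a] == risk[b]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Second-order transition distribution recomputed from an adjacency matrix:
# alpha = 1/p, 1, 1/q for d(t,x) = 0, 1, 2 where d comes straight from the
# matrix (x == t; edge t-x; else two steps via v).
brute_transition <- function(A, t, v, p, q) {
  nbrs <- which(A[v, ] == 1)
  alpha <- vapply(nbrs, function(x) {
    if (x == t) 1 / p else if (A[t, x] == 1) 1 else 1 / q
  }, numeric(1))
  pr <- alpha / sum(alpha)
  names(pr) <- as.character(nbrs)
  pr
}

# Neighborhood rule by direct scan: nodes (except the source) present in at
# least `min_walks` distinct walks.
brute_neighborhood <- function(source, walks, min_walks = 2L) {
  all_nodes <- setdiff(unique(unlist(walks)), source)
  sort(all_nodes[vapply(all_nodes, function(nd) {
    sum(vapply(walks, function(w) nd %in% w, logical(1))) >= min_walks
  }, logical(1))])
}

# Benjamini-Hochberg step-up by hand.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Eq-5-style aggregation by exhaustive pair scan.
brute_protein_score <- function(imp, protein) {
  vals <- c()
  for (f in names(imp)) {
    pr <- strsplit(f, "|", fixed = TRUE)[[1]]
    if (protein %in% pr) vals <- c(vals, imp[[f]])
  }
  mean(vals)
}

# Small labelled test network: a 5-node graph with a triangle and a tail.
toy_net <- function() {
  ppi_network(data.frame(
    a = c("A", "A", "B", "C", "D"),
    b = c("B", "C", "C", "D", "E"),
    confidence = 1
  ))
}

# Tiny censored survival fixture generator.
random_surv <- function(n, seed) {
  set.seed(seed)
  survival_data(time = round(rexp(n, 0.2) + 0.01, 3),
                event = rbinom(n, 1, 0.7))
}
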