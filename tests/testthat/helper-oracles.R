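# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Matrix-exponential solution of the two-compartment bleach system
# dC1 = k (C2 - C1) - beta C1 ; dC2 = k (C1 - C2), C(0) = (1, 1).
expm_two_compartment <- function(k, beta, t) {
  A <- matrix(c(-(k + beta), k, k, -k), 2, 2, byrow = TRUE)
  vapply(t, function(tt) {
    as.numeric(Matrix::expm(A * tt) %*% c(1, 1))
  }, numeric(2))
}

# Exhaustive two-class threshold: the cut of the intensity histogram that
# minimises the total within-class sum of squares.
exhaustive_two_class_threshold <- function(x, n_bins = 256L) {
  brk <- seq(min(x), max(x), length.out = n_bins + 1L)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  bin <- pmin(n_bins, pmax(1L, findInterval(x, brk, rightmost.closed = TRUE)))
  w <- tabulate(bin, n_bins)
  best <- Inf; best_cut <- NA
  for (cut in seq_len(n_bins - 1L)) {
    lo <- seq_len(cut); hi <- (cut + 1L):n_bins
    wl <- sum(w[lo]); wh <- sum(w[hi])
    if (wl == 0 || wh == 0) next
    ml <- sum(w[lo] * mid[lo]) / wl
    mh <- sum(w[hi] * mid[hi]) / wh
    ss <- sum(w[lo] * (mid[lo] - ml)^2) + sum(w[hi] * (mid[hi] - mh)^2)
    if (ss < best) { best <- ss; best_cut <- brk[cut + 1L] }
  }
  best_cut
}

# Exact probability that an m-copy nucleus is single-coloured when every
# copy draws one of four colours uniformly: enumeration over 4^m.
enumerate_single_colour_prob <- function(m) {
  grids <- do.call(expand.grid, rep(list(1:4), m))
  mean(apply(grids, 1, function(r) length(unique(r)) == 1L))
}

# Reachability oracle on a compartment graph's open bridges.
reachable_nodes <- function(graph, from) {
  ed <- graph$edges[graph$edges$open & graph$edges$rate > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed[c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = graph$nodes$id))
  comp <- igraph::components(g)$membership
  names(comp)[comp == comp[from]]
}

# Independent clone recount from a population's final nuclei table,
# grouping by founder lineage and colour combination with base R only.
recount_clones <- function(population) {
  nuc <- population$nuclei
  combo <- vapply(nuc$colours, function(cc) {
    cc <- sort(unique(cc[cc != "uncoloured"]))
    if (!length(cc)) NA_character_ else paste(cc, collapse = "+")
  }, character(1))
  keep <- !is.na(combo)
  key <- paste(nuc$founder[keep], combo[keep])
  sizes <- as.integer(table(key))
  list(n_clones = length(sizes), sizes = sort(sizes))
}
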