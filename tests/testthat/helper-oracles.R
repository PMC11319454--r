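# Independent brute-force oracles used to freeze expected values. They
# deliberately avoid the code paths they check.

# grimace fixture with named action-unit columns
make_grimace <- function(values, n_images = nrow(values)) {
  m <- matrix(values, n_images, 5)
  colnames(m) <- mgs_action_units()
  m
}

# Spearman by hand: midranks, then the raw Pearson product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exhaustive episode scan: every bout chain i..j with gaps <= max_break is a
# candidate; qualification by single-bout or summed-duration rule
oracle_latency <- function(starts, ends, window, min_bout = 10,
                           bridged_min = 20, max_break = 5) {
  n <- length(starts)
  dur <- ends - starts
  qualifying <- c()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j > i) {
        gaps <- starts[(i + 1):j] - ends[i:(j - 1)]
        if (any(gaps > max_break)) break
      }
      single_ok <- j == i && dur[i] > min_bout
      chain_ok <- sum(dur[i:j]) > bridged_min
      if (single_ok || chain_ok) qualifying <- c(qualifying, starts[i])
    }
    # a long bout anywhere qualifies on its own
    if (dur[i] > min_bout) qualifying <- c(qualifying, starts[i])
  }
  if (length(qualifying) == 0) list(latency = window, censored = TRUE)
  else list(latency = min(qualifying), censored = FALSE)
}

# random non-overlapping bout log inside a window
random_log <- function(window = 600) {
  n <- sample(0:6, 1)
  if (n == 0) return(burrowing_log(window = window))
  pts <- sort(runif(2 * n, 0, window))
  starts <- pts[seq(1, 2 * n, 2)]
  ends <- pts[seq(2, 2 * n, 2)]
  burrowing_log(starts, ends, window)
}

# connected components of an undirected edge list by breadth-first search
oracle_components <- function(nodes, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- c(edges$parameter_2[edges$parameter_1 == v],
              edges$parameter_1[edges$parameter_2 == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# global k-means optimum at tiny n by enumerating every k=2 partition
oracle_best_partition <- function(x) {
  n <- nrow(x)
  best_ss <- Inf
  best_lab <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    ss <- 0
    for (g in 1:2) {
      xi <- x[lab == g, , drop = FALSE]
      ss <- ss + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    if (ss < best_ss) {
      best_ss <- ss
      best_lab <- lab
    }
  }
  list(labels = best_lab, ss = best_ss)
}
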