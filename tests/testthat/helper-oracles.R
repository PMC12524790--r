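# Independent oracles used by the property and acceptance tests. Each
# is deliberately implemented by a different route than the package
# code it checks.

# Upper tail of the chi-square distribution via the regularized
# incomplete gamma function, computed with the classical series /
# continued-fraction (modified Lentz) split — independent of pchisq.
oracle_chisq_upper <- function(x, df) {
  a <- df / 2
  xx <- x / 2
  if (xx <= 0) return(1)
  lead <- exp(-xx + a * log(xx) - lgamma(a))
  if (xx < a + 1) {
    term <- 1 / a
    s <- term
    n <- 0
    repeat {
      n <- n + 1
      term <- term * xx / (a + n)
      s <- s + term
      if (term < s * 1e-17) break
    }
    1 - s * lead
  } else {
    tiny <- 1e-300
    b <- xx + 1 - a
    c <- 1 / tiny
    d <- 1 / b
    h <- d
    for (i in 1:2000) {
      an <- -i * (i - a)
      b <- b + 2
      d <- an * d + b
      if (abs(d) < tiny) d <- tiny
      c <- b + an / c
      if (abs(c) < tiny) c <- tiny
      d <- 1 / d
      del <- d * c
      h <- h * del
      if (abs(del - 1) < 1e-17) break
    }
    lead * h
  }
}

# Brute-force BH oracle: the adjusted p of item i is the smallest
# candidate level q at which the literal step-up procedure rejects i.
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  cand <- sort(unique(pmin(1, ps * m / seq_len(m))))
  rejected_at <- function(q) {
    # tiny relative slack so that q = p_(j) m / j round-trips despite
    # floating-point rounding
    ok <- which(ps <= q * seq_len(m) / m * (1 + 1e-10))
    if (length(ok) == 0) return(rep(FALSE, m))
    p <= ps[max(ok)]
  }
  out <- rep(1, m)
  for (q in rev(cand)) {
    rej <- rejected_at(q)
    out[rej] <- pmin(out[rej], q)
  }
  out
}

# Exhaustive enumeration of simple directed paths up to max_len;
# returns shortest distance and consensus sign per reachable node.
oracle_signed_paths <- function(edges, source, max_len) {
  # edges: data.frame(source, sign, target) with numeric sign
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  res <- list()
  walk <- function(node, visited, len, sgn) {
    if (len > 0) {
      key <- node
      cur <- res[[key]]
      if (is.null(cur)) {
        res[[key]] <<- list(dist = len, signs = sgn)
      } else if (len < cur$dist) {
        res[[key]] <<- list(dist = len, signs = sgn)
      } else if (len == cur$dist) {
        res[[key]]$signs <<- union(cur$signs, sgn)
      }
    }
    if (len == max_len) return(invisible())
    out <- edges[edges$source == node, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      v <- out$target[i]
      if (v %in% visited) next
      walk(v, c(visited, v), len + 1, sgn * out$sign[i])
    }
  }
  walk(source, source, 0, 1)
  if (length(res) == 0) {
    return(data.frame(node = character(0), distance = integer(0),
                      path_sign = integer(0)))
  }
  out <- data.frame(
    node = names(res),
    distance = vapply(res, function(r) as.integer(r$dist), integer(1)),
    path_sign = vapply(res, function(r) {
      if (length(r$signs) > 1) 0L else as.integer(r$signs)
    }, integer(1)))
  out <- out[out$node != source, , drop = FALSE]
  out[order(out$distance, out$node), ]
}

# Random signed digraph generator for path-oracle comparisons.
random_signed_graph <- function(n_nodes, p_edge = 0.25, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  grid <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  keep <- stats::runif(nrow(grid)) < p_edge
  ed <- grid[keep, , drop = FALSE]
  ed$sign <- sample(c(-1, 1), nrow(ed), replace = TRUE)
  ed[, c("source", "sign", "target")]
}

# WLS slope of y on a binary membership via lm(), used as the
# independent route for the weighted-regression enrichment oracle.
oracle_wls_beta <- function(y, memb, w) {
  unname(stats::coef(stats::lm(y ~ memb, weights = w))[2])
}

expect_tsv_roundtrip <- function(df, writer, reader, ...) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writer(df, path)
  back <- reader(path, ...)
  expect_equal(back, df, ignore_attr = TRUE)
}
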