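# Shared fixtures and independent oracles, built in code at test time.

# an effective_range with prescribed endpoints (for interval-level tests)
fake_range <- function(fl, ce, p = 0.5) {
  stopifnot(fl <= ce)
  structure(
    list(mean = (fl + ce) / 2, sd = (ce - fl) / (4 * p * 1.732),
         floor = fl, ceiling = ce, p = p, n = 2, degenerate = fl == ce),
    class = "effective_range"
  )
}

# a dyn_network with prescribed edges (for network-analysis tests)
fake_network <- function(t, nodes, edges = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(feature_i = character(), feature_j = character(),
                            sign = character(), nor = numeric())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"nor" %in% names(edges)) {
      edges$nor <- ifelse(edges$sign == "red", 0.9, -0.9)
    }
  }
  structure(list(t = as.integer(t), nodes = nodes,
                 edges = edges[c("feature_i", "feature_j", "sign", "nor")],
                 tau = 0.85, gamma = 1.732, p_t = 0.5),
            class = c("dyn_network"))
}

fake_series <- function(...) structure(list(...), class = "dyn_network_series")

# small deterministic dataset from an abundance function f(subject, time, i)
tiny_ds <- function(n_sub = 3, n_time = 3, m = 4,
                    stage_map = rep(c("A", "B"), c(1, n_time - 1)),
                    group = "model", f = function(s, t, i) i + 0.1 * s + t) {
  feats <- sprintf("g%d", seq_len(m))
  tab <- expand.grid(subject = sprintf("s%d", seq_len(n_sub)),
                     time = seq_len(n_time), stringsAsFactors = FALSE)
  tab$group <- group
  for (i in seq_len(m)) {
    tab[[feats[i]]] <- mapply(function(s, t) f(match(s, unique(tab$subject)), t, i),
                              tab$subject, tab$time)
  }
  ts_dataset(tab, stage_map = stage_map)
}

# |NOR| by exact unit-segment counting for intervals with integer endpoints:
# symmetric-difference length over total length, independent of the
# closed-form implementation
nor_mag_oracle_int <- function(fa, ca, fb, cb) {
  segs <- seq(min(fa, fb), max(ca, cb) - 1)
  in_a <- segs >= fa & segs < ca
  in_b <- segs >= fb & segs < cb
  tot <- sum(in_a) + sum(in_b)
  if (tot == 0) return(1)
  sum(xor(in_a, in_b)) / tot
}

# exhaustive pair-counting AUC oracle (ties count one half)
auc_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}
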