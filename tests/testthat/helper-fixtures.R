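# Shared fixtures and independent oracles, built in code at test time.

# --- toy ontologies -------------------------------------------------------

obo_chain <- function() {
  # root <- A <- B
  paste(
    "format-version: 1.2", "",
    "[Term]", "id: T:root", "name: root", "",
    "[Term]", "id: T:A", "name: a", "is_a: T:root", "",
    "[Term]", "id: T:B", "name: b", "is_a: T:A", "",
    sep = "\n")
}

obo_diamond <- function() {
  # D is_a B, D is_a C, B is_a A, C is_a A
  paste(
    "format-version: 1.2", "",
    "[Term]", "id: T:A", "name: a", "",
    "[Term]", "id: T:B", "name: b", "is_a: T:A ! a", "",
    "[Term]", "id: T:C", "name: c", "is_a: T:A", "",
    "[Term]", "id: T:D", "name: d", "is_a: T:B", "is_a: T:C", "",
    sep = "\n")
}

write_obo_text <- function(text) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

chain_graph <- function() parse_obo(write_obo_text(obo_chain()))
diamond_graph <- function() parse_obo(write_obo_text(obo_diamond()))

# brute-force ancestor oracle: enumerate all directed paths
path_ancestors <- function(g, term) {
  out <- character(0)
  stack <- list(term)
  while (length(stack) > 0) {
    cur <- stack[[1]]; stack <- stack[-1]
    for (p in g$parents[[cur]]) {
      out <- union(out, p)
      stack <- c(stack, p)
    }
  }
  out
}

# --- exact Fisher oracles (independent of fisher_core) --------------------

# point probabilities of the (noncentral) hypergeometric by direct
# choose() enumeration over the support
nchg_weights <- function(m, n, K, psi = 1) {
  lo <- max(0, K - n); hi <- min(K, m)
  k <- lo:hi
  # log weights for numerical stability at psi far from 1
  lw <- lchoose(m, k) + lchoose(n, K - k) + k * log(psi)
  w <- exp(lw - max(lw))
  list(k = k, prob = w / sum(w))
}

oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  if (m == 0 || n == 0 || K == 0 || K == m + n) return(1)
  w <- nchg_weights(m, n, K)
  obs <- w$prob[w$k == a]
  min(1, sum(w$prob[w$prob <= obs * (1 + 1e-7)]))
}

oracle_tail <- function(psi, a, m, n, K, lower = TRUE) {
  w <- nchg_weights(m, n, K, psi)
  if (lower) sum(w$prob[w$k <= a]) else sum(w$prob[w$k >= a])
}

oracle_mean <- function(psi, m, n, K) {
  w <- nchg_weights(m, n, K, psi)
  sum(w$k * w$prob)
}

# --- brute-force Ward clustering (Lance-Williams, ward.D2) ----------------

oracle_ward_heights <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in active) for (j in active) {
      if (i < j && d2[i, j] < bestv) { bestv <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# --- small simulated cohort shared across tests ---------------------------

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(n_cases = 60, n_controls = 60,
                                           seed = 101))
    }
    cache
  }
})

# ten-pair replication fixture spanning matches, mismatches, boundary ORs
# and non-nominal stage-1 results; expected summaries hand-checked per pair
fixture_pairs <- function() {
  s1 <- tibble::tibble(
    term = LETTERS[1:10],
    or = c(2, 0.5, 2, 1, 3, Inf, 0, 1.5, 0.8, 2.5),
    ci_low = NA_real_, ci_high = NA_real_,
    p = c(0.01, 0.02, 0.04, 0.03, 0.2, 0.001, 0.005, 0.5, 0.04, 0.9))
  s2 <- tibble::tibble(
    term = LETTERS[1:10],
    or = c(3, 0.4, 0.5, 2, 2, 5, 0.1, 1.5, 1.2, 1),
    ci_low = c(1.2, 0.2, 0.3, 1, 1, 2, 0, 0.7, 0.6, 0.5),
    ci_high = c(5, 0.9, 0.9, 4, 4, Inf, 0.5, 3, 2.4, 2),
    p = rep(0.05, 10))
  pair_stages(s1, s2)
}
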