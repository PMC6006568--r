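# Independent oracles and small fixtures used across the test files.

# Greedy efficient-frontier oracle on the (effect, cost) plane: start from
# the cheapest strategy and repeatedly move to the more effective point
# reachable at the lowest incremental cost-effectiveness ratio. This is an
# independent construction of the lower convex hull, used to check the
# sort-and-prune frontier implementation.
oracle_frontier <- function(strategy, cost, effect) {
  ord <- order(cost, -effect)
  strategy <- strategy[ord]; cost <- cost[ord]; effect <- effect[ord]
  path <- 1L
  icers <- numeric(0)
  repeat {
    cur <- path[length(path)]
    cand <- which(effect > effect[cur])
    if (!length(cand)) break
    ratios <- (cost[cand] - cost[cur]) / (effect[cand] - effect[cur])
    best <- cand[which.min(ratios)]
    icers <- c(icers, min(ratios))
    path <- c(path, best)
  }
  list(strategies = strategy[path], icers = icers)
}

random_strategy_set <- function(n) {
  tibble::tibble(
    strategy = paste0("s", seq_len(n)),
    cost = runif(n, 0, 100),
    effect = runif(n, 0, 10))
}

# Minimal two-item ledger for allocation arithmetic.
toy_ledger <- function() {
  cost_ledger(tibble::tibble(
    item = c("shared_item", "screen_item"),
    cost_class = c("fixed", "variable"),
    basis = c("lump", "screened"),
    qty_per_basis = 1,
    unit_cost = c(100, 0.10),
    allocation = c("time_share", "screening")))
}

toy_counts <- function() {
  list(screened = 2736, positive = 531, accepted = 332,
       n_control = 110, n_mi = 113, n_mi_pst = 109, n_counsellors = 5)
}

strive_sessions <- function() strive_config()$sessions

# Annuity payment from first principles: solve sum_t P (1+r)^-t = K for P.
oracle_annuity <- function(K, n, r) {
  pv_factor <- sum((1 + r)^-(seq_len(n)))
  K / pv_factor
}
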