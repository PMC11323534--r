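# Independent oracles used across the suite.

# Exhaustive minimum-cost ancestral assignment for binary characters:
# enumerates every assignment of {0,1} to the internal nodes and scores
# each branch directly. Returns the global minimum and how many
# assignments attain it.
brute_force_parsimony <- function(tree, states, gain_cost = 2, loss_cost = 1) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edge <- tree$edge
  s_leaf <- as.integer(states[tree$tip.label] > 0)
  combos <- as.matrix(expand.grid(rep(list(0:1), nint)))
  full <- cbind(matrix(s_leaf, nrow(combos), ntip, byrow = TRUE), combos)
  ps <- full[, edge[, 1], drop = FALSE]
  cs <- full[, edge[, 2], drop = FALSE]
  cost <- rowSums((ps == 0 & cs == 1) * gain_cost +
                  (ps == 1 & cs == 0) * loss_cost)
  list(min_cost = min(cost), n_optima = sum(cost == min(cost)))
}

# Closed-form simple-regression coefficients from the normal equations.
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# All 0/1 leaf labelings for a tree with n tips, as a matrix (rows =
# labelings, columns = tips).
all_labelings <- function(n) as.matrix(expand.grid(rep(list(0:1), n)))

# Small random count design for quick DE checks.
tiny_design <- function(samples, species = "sp", nrep = length(samples) / 2,
                        require_replication = TRUE) {
  sample_design(data.frame(
    sample_id = samples, species_id = species,
    condition = rep(c("no_sulfur", "sulfur"), each = nrep),
    replicate = rep(seq_len(nrep), 2), stringsAsFactors = FALSE),
    require_replication = require_replication)
}
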