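# Independent oracles used by the engine tests.  These deliberately avoid
# the implementation paths they check: embeddings are counted by exhaustive
# enumeration of injective molecule assignments, and mass-action derivatives
# are assembled by a direct reaction-by-reaction R loop over the reaction
# table.

# all ordered selections of k distinct elements from v
ordered_selections <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in ordered_selections(v[-i], k - 1L))
      out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# brute-force subgraph matcher: count embeddings of a connected pattern in a
# species graph by checking every injective assignment
oracle_count_embeddings <- function(pattern, species) {
  np <- length(pattern$mols)
  ns <- length(species$mols)
  if (np > ns) return(0L)
  bonded <- character(0)
  pair_keys <- character(0)
  for (b in species$bonds) {
    bonded <- c(bonded, paste0(b$m1, "|", b$s1), paste0(b$m2, "|", b$s2))
    pair_keys <- c(pair_keys,
                   paste(sort(c(paste0(b$m1, "|", b$s1),
                                paste0(b$m2, "|", b$s2))), collapse = "+"))
  }
  n_found <- 0L
  for (assign in ordered_selections(seq_len(ns), np)) {
    ok <- TRUE
    for (p in seq_len(np)) {
      pm <- pattern$mols[[p]]
      sm <- species$mols[[assign[p]]]
      if (pm$type != sm$type) { ok <- FALSE; break }
      for (sname in names(pm$conds)) {
        cond <- pm$conds[[sname]]
        if (!is.na(cond$state) &&
            (is.na(sm$sites[[sname]]) || sm$sites[[sname]] != cond$state)) {
          ok <- FALSE; break
        }
        key <- paste0(assign[p], "|", sname)
        if (identical(cond$bond, "free") && key %in% bonded) { ok <- FALSE; break }
        if (is.numeric(cond$bond) && !(key %in% bonded)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    for (pb in pattern$bonds) {
      key <- paste(sort(c(paste0(assign[pb$m1], "|", pb$s1),
                          paste0(assign[pb$m2], "|", pb$s2))), collapse = "+")
      if (!(key %in% pair_keys)) { ok <- FALSE; break }
    }
    if (ok) n_found <- n_found + 1L
  }
  n_found
}

# direct mass-action derivative from the reaction table (plain R loop)
oracle_derivative <- function(network, x) {
  rr <- network$reactions
  dx <- numeric(length(network$species))
  for (j in seq_len(nrow(rr))) {
    f <- rr$rate[j]
    for (r in c(rr$r1[j], rr$r2[j])) if (!is.na(r)) f <- f * x[r]
    for (r in c(rr$r1[j], rr$r2[j])) if (!is.na(r)) dx[r] <- dx[r] - f
    for (p in c(rr$p1[j], rr$p2[j])) if (!is.na(p)) dx[p] <- dx[p] + f
  }
  dx
}

# relabel the molecules of a species graph according to a permutation
permute_species <- function(sp, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  list(mols = sp$mols[perm],
       bonds = lapply(sp$bonds, function(b)
         list(m1 = inv[b$m1], s1 = b$s1, m2 = inv[b$m2], s2 = b$s2)))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}
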