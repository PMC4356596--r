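# Rewrite rules: parsing of rule lines, derivation of the executable action
# (bond formation/breakage, site-state changes) by positional alignment of
# reactant and product patterns, and application of a rule to a tuple of
# species via an embedding.

parse_rate_expr <- function(txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([0-9.]+)\\*([A-Za-z_][A-Za-z0-9_]*)$", txt))[[1]]
  if (length(m) == 3L)
    return(list(ref = m[3], factor = as.numeric(m[2])))
  if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", txt))
    return(list(ref = txt, factor = 1))
  stop("cannot parse rate expression: ", txt)
}

#' Construct a rewrite rule
#'
#' A rule rewrites one or two reactant patterns into product patterns.
#' Reactant and product molecules are aligned positionally (in written order),
#' as in BNGL; the executable action (state changes, bonds formed or broken)
#' is derived from the difference between the two sides.
#'
#' @param id Rule label (e.g. `"8B"`).
#' @param lhs,rhs Left/right side text (patterns joined by `+`).
#' @param rate Rate expression for the forward direction: a parameter name,
#'   optionally with a numeric statistical factor, e.g. `"2*p4"`.
#' @param reverse_rate Reverse-direction rate expression for bidirectional
#'   rules, or `NULL` for unidirectional rules.
#' @return An object of class `rewrite_rule`.
#' @export
rewrite_rule <- function(id, lhs, rhs, rate, reverse_rate = NULL) {
  reactants <- lapply(split_complexes(lhs), parse_pattern)
  products <- lapply(split_complexes(rhs), parse_pattern)
  fr <- parse_rate_expr(rate)
  rule <- structure(list(
    id = id,
    lhs = lhs, rhs = rhs,
    reactants = reactants, products = products,
    rate_ref = fr$ref, stat_factor = fr$factor,
    direction = if (is.null(reverse_rate)) "unidirectional" else "bidirectional",
    reverse_rate_ref = NULL, reverse_stat_factor = NULL
  ), class = "rewrite_rule")
  if (!is.null(reverse_rate)) {
    rr <- parse_rate_expr(reverse_rate)
    rule$reverse_rate_ref <- rr$ref
    rule$reverse_stat_factor <- rr$factor
  }
  rule$action <- rule_action(reactants, products)
  rule
}

#' @export
print.rewrite_rule <- function(x, ...) {
  arrow <- if (x$direction == "bidirectional") "<->" else "->"
  rate <- if (x$stat_factor != 1) paste0(x$stat_factor, "*", x$rate_ref) else x$rate_ref
  if (x$direction == "bidirectional")
    rate <- paste0(rate, ", ", x$reverse_rate_ref)
  cat(sprintf("%s: %s %s %s  %s\n", x$id, x$lhs, arrow, x$rhs, rate))
  invisible(x)
}

# flatten pattern complexes into one molecule list, keeping slot boundaries
flatten_side <- function(patterns) {
  mols <- list()
  slot <- integer(0)
  bonds <- list()
  off <- 0L
  for (k in seq_along(patterns)) {
    p <- patterns[[k]]
    for (pm in p$mols) mols[[length(mols) + 1L]] <- pm
    slot <- c(slot, rep(k, length(p$mols)))
    for (b in p$bonds)
      bonds[[length(bonds) + 1L]] <-
        list(m1 = b$m1 + off, s1 = b$s1, m2 = b$m2 + off, s2 = b$s2)
    off <- off + length(p$mols)
  }
  list(mols = mols, slot = slot, bonds = bonds)
}

bond_key_set <- function(bonds) {
  vapply(bonds, function(b)
    paste(sort(c(paste0(b$m1, "|", b$s1), paste0(b$m2, "|", b$s2))), collapse = "+"), "")
}

# derive the action by positional molecule alignment between the two sides
rule_action <- function(reactants, products) {
  L <- flatten_side(reactants)
  R <- flatten_side(products)
  if (length(L$mols) != length(R$mols))
    stop("rule sides have different molecule counts; only binding and ",
         "state-change rules are supported")
  state_changes <- list()
  for (i in seq_along(L$mols)) {
    lm <- L$mols[[i]]; rm <- R$mols[[i]]
    if (lm$type != rm$type)
      stop("molecule type mismatch at position ", i, ": ", lm$type, " vs ", rm$type)
    for (s in union(names(lm$conds), names(rm$conds))) {
      ls <- if (s %in% names(lm$conds)) lm$conds[[s]]$state else NA_character_
      rs <- if (s %in% names(rm$conds)) rm$conds[[s]]$state else NA_character_
      if (!is.na(rs) && (is.na(ls) || ls != rs))
        state_changes[[length(state_changes) + 1L]] <-
          list(pos = i, site = s, from = ls, to = rs)
    }
  }
  lb <- L$bonds; rb <- R$bonds
  lk <- bond_key_set(lb); rk <- bond_key_set(rb)
  form <- rb[!(rk %in% lk)]
  break_ <- lb[!(lk %in% rk)]
  # drop "state changes" that merely restate an unchanged condition
  state_changes <- Filter(function(ch) is.na(ch$from) || ch$from != ch$to,
                          state_changes)
  list(state_changes = state_changes, form = form, breaks = break_,
       n_reactant_mols = length(L$mols), reactant_slot = L$slot)
}

# directed view of a rule set: each bidirectional rule contributes two
# directed rules (suffixes "f"/"r" internally; ids stay the printed labels)
directed_rules <- function(rules) {
  out <- list()
  for (r in rules) {
    out[[length(out) + 1L]] <- list(
      id = r$id, reverse = FALSE, reactants = r$reactants, products = r$products,
      action = r$action, rate_ref = r$rate_ref, stat_factor = r$stat_factor)
    if (r$direction == "bidirectional") {
      rev_action <- rule_action(r$products, r$reactants)
      out[[length(out) + 1L]] <- list(
        id = r$id, reverse = TRUE, reactants = r$products, products = r$reactants,
        action = rev_action, rate_ref = r$reverse_rate_ref,
        stat_factor = r$reverse_stat_factor)
    }
  }
  out
}

# Apply a directed rule to an ordered tuple of species via one combined
# embedding.  `embedding` maps flattened reactant molecule positions to
# molecule indices in the merged graph (offsets already applied).
apply_rule_embedding <- function(drule, species_tuple, embedding) {
  mols <- list()
  bonds <- list()
  off <- 0L
  for (sp in species_tuple) {
    for (m in sp$mols) mols[[length(mols) + 1L]] <- m
    for (b in sp$bonds)
      bonds[[length(bonds) + 1L]] <-
        list(m1 = b$m1 + off, s1 = b$s1, m2 = b$m2 + off, s2 = b$s2)
    off <- off + sp_n_mols(sp)
  }
  act <- drule$action
  for (ch in act$state_changes) {
    mi <- embedding[ch$pos]
    mols[[mi]]$sites[[ch$site]] <- ch$to
  }
  if (length(act$breaks)) {
    drop_keys <- vapply(act$breaks, function(b)
      paste(sort(c(paste0(embedding[b$m1], "|", b$s1),
                   paste0(embedding[b$m2], "|", b$s2))), collapse = "+"), "")
    keys <- bond_key_set(bonds)
    bonds <- bonds[!(keys %in% drop_keys)]
  }
  for (b in act$form) {
    bonds[[length(bonds) + 1L]] <-
      list(m1 = embedding[b$m1], s1 = b$s1, m2 = embedding[b$m2], s2 = b$s2)
  }
  split_components(new_species(mols, bonds))
}

# enumerate combined embeddings of a directed rule's reactant patterns into
# an ordered species tuple (one species per reactant slot)
combined_embeddings <- function(drule, species_tuple) {
  per_slot <- vector("list", length(drule$reactants))
  for (k in seq_along(drule$reactants)) {
    emb <- find_embeddings(drule$reactants[[k]], species_tuple[[k]])
    if (!length(emb)) return(list())
    per_slot[[k]] <- emb
  }
  offs <- c(0L, cumsum(vapply(species_tuple, sp_n_mols, 1L)))
  combos <- expand_grid_list(per_slot)
  lapply(combos, function(cc) {
    unlist(lapply(seq_along(cc), function(k) cc[[k]] + offs[k]))
  })
}
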