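# Site-graph machinery: molecule types, pattern/species graphs, canonical
# labels, and embedding (subgraph match) enumeration.  Species are connected
# complexes whose molecules carry fully specified site states; patterns carry
# per-site conditions (state or don't-care; bonded-with-index, required-free,
# or don't-care).

#' Define a molecule type
#'
#' A molecule type declares a molecule name and its sites.  A site may carry
#' an ordered set of internal state labels (e.g. phosphorylation states
#' `0`, `P`, `PP`), may act as a binding site, or both; sites with no state
#' labels are pure binding sites.
#'
#' @param name Molecule name (e.g. `"ULK1"`).
#' @param sites Named list; each element is a character vector of state labels
#'   (possibly empty) for that site.  Order is preserved and used for
#'   serialization.
#' @return An object of class `molecule_type`.
#' @examples
#' molecule_type("AMBRA1", list(ST = c("0", "P")))
#' @export
molecule_type <- function(name, sites = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(sites) > 0L && (is.null(names(sites)) || anyDuplicated(names(sites))))
    stop("site names must be unique and non-empty for molecule type ", name)
  for (s in names(sites)) {
    st <- sites[[s]]
    if (length(st) > 0L && anyDuplicated(st))
      stop("duplicate state labels in site ", s, " of ", name)
  }
  structure(list(name = name, sites = sites), class = "molecule_type")
}

#' @export
print.molecule_type <- function(x, ...) {
  cat(mt_signature(x), "\n")
  invisible(x)
}

mt_signature <- function(mt) {
  parts <- vapply(names(mt$sites), function(s) {
    st <- mt$sites[[s]]
    if (length(st)) paste0(s, paste0("~", st, collapse = "")) else s
  }, "")
  paste0(mt$name, "(", paste(parts, collapse = ","), ")")
}

# --- internal species-graph representation --------------------------------
# species: list(mols = list(list(type=, sites=named chr vector (NA for pure
# binding sites))), bonds = list(c(m1, s1, m2, s2)) with m as integer-like
# character? -> stored as list(m1=int, s1=chr, m2=int, s2=chr))

new_species <- function(mols, bonds = list()) {
  list(mols = mols, bonds = bonds)
}

sp_bond_keys <- function(sp) {
  if (!length(sp$bonds)) return(character(0))
  unlist(lapply(sp$bonds, function(b) c(paste0(b$m1, "|", b$s1),
                                        paste0(b$m2, "|", b$s2))))
}

sp_n_mols <- function(sp) length(sp$mols)

# serialize molecules in the given order; bond indices are renumbered in
# first-encounter order so the string depends only on the ordering
sg_serialize <- function(sp, order = seq_along(sp$mols)) {
  pos <- integer(sp_n_mols(sp))
  pos[order] <- seq_along(order)
  # bond lookup: key "m|s" -> bond row index
  bkey <- character(0)
  bidx <- integer(0)
  for (i in seq_along(sp$bonds)) {
    b <- sp$bonds[[i]]
    bkey <- c(bkey, paste0(b$m1, "|", b$s1), paste0(b$m2, "|", b$s2))
    bidx <- c(bidx, i, i)
  }
  names(bidx) <- bkey
  assigned <- integer(length(sp$bonds))
  nextid <- 1L
  out <- character(length(order))
  for (k in seq_along(order)) {
    m <- order[k]
    mol <- sp$mols[[m]]
    toks <- character(length(mol$sites))
    sn <- names(mol$sites)
    for (j in seq_along(sn)) {
      t <- sn[j]
      st <- mol$sites[[j]]
      tok <- t
      if (!is.na(st)) tok <- paste0(tok, "~", st)
      bi <- bidx[paste0(m, "|", t)]
      if (!is.na(bi)) {
        if (assigned[bi] == 0L) {
          assigned[bi] <- nextid
          nextid <- nextid + 1L
        }
        tok <- paste0(tok, "!", assigned[bi])
      }
      toks[j] <- tok
    }
    out[k] <- paste0(mol$type, "(", paste(toks, collapse = ","), ")")
  }
  paste(out, collapse = ".")
}

perms_of <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Canonical label of a species graph
#'
#' Produces a string label that is identical for isomorphic species graphs
#' (invariant under molecule reordering and bond renumbering) and distinct for
#' non-isomorphic ones.  Molecules are ordered by iterative sorted refinement
#' of (type, site states, bonded-neighbour keys); molecules still tied after
#' refinement (graph automorphisms) fall back to exhaustive permutation,
#' taking the lexicographically smallest serialization.
#'
#' @param sp A species graph (as produced by the expansion engine or
#'   [parse_species()]).
#' @return Canonical label string, in BNGL-style notation.
#' @export
canonical_label <- function(sp) {
  if (!is_connected(sp)) stop("canonical_label: species graph is not connected")
  n <- sp_n_mols(sp)
  keys <- vapply(sp$mols, function(m)
    paste0(m$type, "(", paste(ifelse(is.na(m$sites), "", m$sites), collapse = ","), ")"), "")
  # neighbourhood refinement until the partition stabilises
  if (length(sp$bonds) && anyDuplicated(keys)) {
    nb <- vector("list", n)
    for (b in sp$bonds) {
      nb[[b$m1]] <- c(nb[[b$m1]], list(c(b$s1, b$s2, b$m2)))
      nb[[b$m2]] <- c(nb[[b$m2]], list(c(b$s2, b$s1, b$m1)))
    }
    repeat {
      n_classes <- length(unique(keys))
      keys2 <- vapply(seq_len(n), function(i) {
        ext <- vapply(nb[[i]], function(e)
          paste0(e[1], ">", e[2], ":", keys[as.integer(e[3])]), "")
        paste0(keys[i], "[", paste(sort(ext), collapse = ";"), "]")
      }, "")
      keys <- keys2
      if (length(unique(keys)) == n_classes) break
    }
  }
  ord <- order(keys)
  groups <- split(ord, keys[ord])
  if (all(lengths(groups) == 1L)) return(sg_serialize(sp, ord))
  # exhaustive permutations within remaining (automorphic) ties
  n_orders <- prod(factorial(lengths(groups)))
  if (n_orders > 50000) stop("canonical_label: too many symmetric orderings")
  group_perms <- lapply(groups, perms_of)
  combos <- expand_grid_list(group_perms)
  labs <- vapply(combos, function(cc) sg_serialize(sp, unlist(cc, use.names = FALSE)), "")
  min(labs)
}

# cartesian product of a list of lists, preserving group order
expand_grid_list <- function(ll) {
  out <- list(list())
  for (g in ll) {
    out <- unlist(lapply(out, function(acc)
      lapply(g, function(el) c(acc, list(el)))), recursive = FALSE)
  }
  out
}

is_connected <- function(sp) {
  n <- sp_n_mols(sp)
  if (n <= 1L) return(TRUE)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (b in sp$bonds) {
    ra <- find(b$m1); rb <- find(b$m2)
    if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
  }
  length(unique(vapply(seq_len(n), find, 1L))) == 1L
}

# split a (possibly disconnected) graph into connected-component species,
# ordered by their smallest molecule index
split_components <- function(sp) {
  n <- sp_n_mols(sp)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (b in sp$bonds) {
    ra <- find(b$m1); rb <- find(b$m2)
    if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- list()
  for (r in sort(unique(roots))) {
    idx <- which(roots == r)
    remap <- integer(n)
    remap[idx] <- seq_along(idx)
    bonds <- Filter(function(b) roots[b$m1] == r, sp$bonds)
    bonds <- lapply(bonds, function(b)
      list(m1 = remap[b$m1], s1 = b$s1, m2 = remap[b$m2], s2 = b$s2))
    out[[length(out) + 1L]] <- new_species(sp$mols[idx], bonds)
  }
  out
}

# --- pattern representation ------------------------------------------------
# pattern: list(mols = list(list(type=, conds=list(site = list(state=chr|NA,
# bond="any"|"free"|<int id>)))), bonds = list(m1,s1,m2,s2))

#' Enumerate embeddings of a pattern into a species graph
#'
#' An embedding maps each pattern molecule injectively to a species molecule
#' of the same type such that all site conditions hold: required states match,
#' required-free sites are unbound, and pattern bonds map onto species bonds.
#' Sites not mentioned by the pattern are unconstrained.
#'
#' @param pattern A connected pattern graph (one reactant of a rule), e.g. from
#'   [parse_pattern()].
#' @param species A species graph.
#' @return A list of embeddings; each embedding is an integer vector mapping
#'   pattern molecule positions to species molecule indices.  Empty list if
#'   there is no match.
#' @export
find_embeddings <- function(pattern, species) {
  np <- length(pattern$mols)
  ns <- sp_n_mols(species)
  if (np == 0L) return(list())
  bond_keys <- sp_bond_keys(species)
  # candidates per pattern molecule
  cand <- vector("list", np)
  for (p in seq_len(np)) {
    pm <- pattern$mols[[p]]
    ok <- integer(0)
    for (m in seq_len(ns)) {
      sm <- species$mols[[m]]
      if (sm$type != pm$type) next
      good <- TRUE
      for (sname in names(pm$conds)) {
        cond <- pm$conds[[sname]]
        if (!sname %in% names(sm$sites)) { good <- FALSE; break }
        if (!is.na(cond$state)) {
          sv <- sm$sites[[sname]]
          if (is.na(sv) || sv != cond$state) { good <- FALSE; break }
        }
        bkey <- paste0(m, "|", sname)
        if (identical(cond$bond, "free")) {
          if (bkey %in% bond_keys) { good <- FALSE; break }
        } else if (!identical(cond$bond, "any")) {
          if (!(bkey %in% bond_keys)) { good <- FALSE; break }
        }
      }
      if (good) ok <- c(ok, m)
    }
    if (!length(ok)) return(list())
    cand[[p]] <- ok
  }
  # species bond set for pairwise checks
  sb <- vapply(species$bonds, function(b)
    paste(sort(c(paste0(b$m1, "|", b$s1), paste0(b$m2, "|", b$s2))), collapse = "+"), "")
  out <- list()
  assign_next <- function(p, map) {
    if (p > np) {
      for (pb in pattern$bonds) {
        key <- paste(sort(c(paste0(map[pb$m1], "|", pb$s1),
                            paste0(map[pb$m2], "|", pb$s2))), collapse = "+")
        if (!(key %in% sb)) return(invisible(NULL))
      }
      out[[length(out) + 1L]] <<- map
      return(invisible(NULL))
    }
    for (m in cand[[p]]) {
      if (m %in% map) next
      map2 <- map
      map2[p] <- m
      assign_next(p + 1L, map2)
    }
    invisible(NULL)
  }
  assign_next(1L, integer(np))
  out
}

# --- parsing ---------------------------------------------------------------

.site_aliases <- c(S855_Ser859 = "S855_S859", `S855-9` = "S855_S859")

normalize_site <- function(s) {
  hit <- .site_aliases[s]
  ifelse(is.na(hit), s, hit)
}

# parse "Name(tok,tok,...)" into list(type=, site_tokens=chr)
parse_mol_string <- function(txt) {
  m <- regmatches(txt, regexec("^([A-Za-z0-9_]+)\\(([^()]*)\\)$", txt))[[1]]
  if (length(m) != 3L) stop("cannot parse molecule string: ", txt)
  toks <- if (nzchar(m[3])) strsplit(m[3], ",", fixed = TRUE)[[1]] else character(0)
  list(type = m[2], site_tokens = trimws(toks))
}

parse_site_token <- function(tok) {
  bond <- NA_integer_
  state <- NA_character_
  if (grepl("!", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "!", fixed = TRUE)[[1]]
    tok <- parts[1]
    bond <- suppressWarnings(as.integer(parts[2]))
    if (is.na(bond)) stop("bad bond index in site token: ", parts[2])
  }
  if (grepl("~", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "~", fixed = TRUE)[[1]]
    tok <- parts[1]
    state <- parts[2]
  }
  list(site = normalize_site(tok), state = state, bond = bond)
}

# split a rule side at top-level "+" (no parentheses nesting in this dialect)
split_complexes <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "+" && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  trimws(vapply(seq_along(starts), function(k)
    paste(chars[starts[k]:ends[k]], collapse = ""), ""))
}

#' Parse a connected pattern graph from BNGL-style text
#'
#' @param txt Pattern text, e.g. `"RPTOR(ulk1!1).ULK1(straptor!1)"`.  A site
#'   mentioned without a bond index is required to be unbound; an unmentioned
#'   site is unconstrained.
#' @return A pattern graph usable with [find_embeddings()].
#' @export
parse_pattern <- function(txt) {
  mol_strs <- trimws(strsplit(txt, ".", fixed = TRUE)[[1]])
  mols <- list()
  half_bonds <- list()  # id -> list(m, s)
  bonds <- list()
  for (i in seq_along(mol_strs)) {
    pm <- parse_mol_string(mol_strs[i])
    conds <- list()
    for (tok in pm$site_tokens) {
      st <- parse_site_token(tok)
      bond <- if (is.na(st$bond)) "free" else st$bond
      conds[[st$site]] <- list(state = st$state, bond = bond)
      if (!is.na(st$bond)) {
        id <- as.character(st$bond)
        if (is.null(half_bonds[[id]])) {
          half_bonds[[id]] <- list(m = i, s = st$site)
        } else {
          hb <- half_bonds[[id]]
          bonds[[length(bonds) + 1L]] <-
            list(m1 = hb$m, s1 = hb$s, m2 = i, s2 = st$site)
          half_bonds[[id]] <- NA
        }
      }
    }
    mols[[i]] <- list(type = pm$type, conds = conds)
  }
  dangling <- Filter(function(x) is.list(x), half_bonds)
  if (length(dangling))
    stop("unpaired bond index in pattern: ", txt)
  list(mols = mols, bonds = bonds)
}

#' Parse a fully specified species graph from BNGL-style text
#'
#' All declared sites of every molecule must be mentioned, state sites must
#' carry a state, and the graph must be connected.
#'
#' @param txt Species text, e.g. `"AMPK(ulk1,ST~0,T172~P)"`.
#' @param types Named list of [molecule_type()] objects.
#' @return A species graph.
#' @export
parse_species <- function(txt, types) {
  mol_strs <- trimws(strsplit(txt, ".", fixed = TRUE)[[1]])
  mols <- list()
  half_bonds <- list()
  bonds <- list()
  for (i in seq_along(mol_strs)) {
    pm <- parse_mol_string(mol_strs[i])
    mt <- types[[pm$type]]
    if (is.null(mt)) stop("unknown molecule type: ", pm$type)
    sites <- stats::setNames(rep(NA_character_, length(mt$sites)), names(mt$sites))
    for (tok in pm$site_tokens) {
      st <- parse_site_token(tok)
      if (!st$site %in% names(mt$sites))
        stop("undeclared site ", st$site, " in ", pm$type)
      nstates <- length(mt$sites[[st$site]])
      if (nstates > 0L) {
        if (is.na(st$state))
          stop("species must specify state of site ", st$site, " in ", pm$type)
        if (!st$state %in% mt$sites[[st$site]])
          stop("undeclared state ", st$state, " for site ", st$site, " in ", pm$type)
        sites[[st$site]] <- st$state
      } else if (!is.na(st$state)) {
        stop("site ", st$site, " of ", pm$type, " has no states")
      }
      if (!is.na(st$bond)) {
        id <- as.character(st$bond)
        if (is.null(half_bonds[[id]])) {
          half_bonds[[id]] <- list(m = i, s = st$site)
        } else {
          hb <- half_bonds[[id]]
          bonds[[length(bonds) + 1L]] <-
            list(m1 = hb$m, s1 = hb$s, m2 = i, s2 = st$site)
          half_bonds[[id]] <- NA
        }
      }
    }
    mols[[i]] <- list(type = pm$type, sites = sites)
  }
  if (length(Filter(is.list, half_bonds)))
    stop("unpaired bond index in species: ", txt)
  sp <- new_species(mols, bonds)
  if (!is_connected(sp)) stop("species graph is not connected: ", txt)
  sp
}

# count molecules of a type in a species, optionally restricted to a site state
species_site_count <- function(sp, type, site = NULL, state = NULL) {
  n <- 0L
  for (m in sp$mols) {
    if (m$type != type) next
    if (is.null(site)) { n <- n + 1L; next }
    sv <- m$sites[[site]]
    if (!is.na(sv) && sv %in% state) n <- n + 1L
  }
  n
}
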