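# Network expansion: iterative application of the rule set to the seed
# species until closure, with canonical species identification, followed by
# deterministic enumeration of all implied unidirectional mass-action
# reactions.

#' Expand a rule-based model into a concrete reaction network
#'
#' Starting from the seed species (the unmodified monomers), every directed
#' rule is applied to every matching species tuple; novel product species are
#' identified by canonical label and queued, until no new species arise.  A
#' second pass then enumerates one unidirectional reaction per (directed
#' rule, ordered reactant tuple, product multiset), with rate value
#' rate constant x statistical factor x embedding multiplicity.  Reactions
#' are generated structurally: a rule whose rate constant is currently zero
#' (e.g. `p9` at its nominal value) still contributes species and reactions.
#'
#' @param model A `rule_model` from [build_model()] or [read_bngl()].
#' @param max_species Guard against non-terminating rule sets.
#' @return An object of class `reaction_network`: species labels and graphs,
#'   initial copy numbers, a reaction table, and the generating model.
#' @export
expand_network <- function(model, max_species = 10000) {
  drules <- directed_rules(model$rules)
  types <- model$molecule_types

  labels <- character(0)
  graphs <- list()
  index <- new.env(parent = emptyenv())
  add_species <- function(sp, label = NULL) {
    if (is.null(label)) label <- canonical_label(sp)
    i <- index[[label]]
    if (!is.null(i)) return(i)
    i <- length(labels) + 1L
    if (i > max_species)
      stop("network expansion exceeded max_species = ", max_species,
           "; rule set may not terminate")
    labels[[i]] <<- label
    graphs[[i]] <<- sp
    assign(label, i, envir = index)
    i
  }
  for (s in model$seeds)
    add_species(parse_species(s$species_text, types))
  n_seeds <- length(labels)

  # per-(directed rule, slot) match cache: species indices and embeddings
  matches <- lapply(drules, function(d)
    lapply(d$reactants, function(p) list(idx = integer(0), emb = list())))
  n_matched <- 0L

  update_matches <- function() {
    if (n_matched >= length(labels)) return(invisible(NULL))
    for (i in (n_matched + 1L):length(labels)) {
      for (k in seq_along(drules)) {
        for (s in seq_along(drules[[k]]$reactants)) {
          emb <- find_embeddings(drules[[k]]$reactants[[s]], graphs[[i]])
          if (length(emb)) {
            m <- matches[[k]][[s]]
            m$idx <- c(m$idx, i)
            m$emb[[length(m$emb) + 1L]] <- emb
            matches[[k]][[s]] <<- m
          }
        }
      }
    }
    n_matched <<- length(labels)
    invisible(NULL)
  }

  apply_tuple <- function(k, tuple_idx, tuple_emb) {
    combos <- expand_grid_list(tuple_emb)
    offs <- c(0L, cumsum(vapply(tuple_idx, function(i) sp_n_mols(graphs[[i]]), 1L)))
    sps <- graphs[tuple_idx]
    for (cc in combos) {
      embedding <- unlist(lapply(seq_along(cc), function(s) cc[[s]] + offs[s]))
      prods <- apply_rule_embedding(drules[[k]], sps, embedding)
      for (p in prods) add_species(p)
    }
  }

  # discovery rounds: apply rules to tuples containing >= 1 new species
  new_lo <- 1L
  repeat {
    update_matches()
    n_before <- length(labels)
    new_hi <- n_before
    for (k in seq_along(drules)) {
      ms <- matches[[k]]
      if (length(ms) == 1L) {
        sel <- which(ms[[1]]$idx >= new_lo)
        for (j in sel)
          apply_tuple(k, ms[[1]]$idx[j], list(ms[[1]]$emb[[j]]))
      } else {
        i1 <- ms[[1]]$idx; i2 <- ms[[2]]$idx
        for (j1 in seq_along(i1)) {
          for (j2 in seq_along(i2)) {
            if (i1[j1] < new_lo && i2[j2] < new_lo) next
            apply_tuple(k, c(i1[j1], i2[j2]),
                        list(ms[[1]]$emb[[j1]], ms[[2]]$emb[[j2]]))
          }
        }
      }
    }
    if (length(labels) == n_before && new_lo > n_before) break
    new_lo <- new_hi + 1L
    if (length(labels) == n_before && new_lo > length(labels)) break
  }
  update_matches()

  # enumeration pass: one reaction per (directed rule, ordered tuple,
  # product multiset); multiplicity = number of embeddings with identical
  # products (expected to be 1 throughout the nominal model)
  rx <- list()
  emit <- function(k, tuple_idx, tuple_emb) {
    combos <- expand_grid_list(tuple_emb)
    offs <- c(0L, cumsum(vapply(tuple_idx, function(i) sp_n_mols(graphs[[i]]), 1L)))
    sps <- graphs[tuple_idx]
    prod_sets <- list()
    for (cc in combos) {
      embedding <- unlist(lapply(seq_along(cc), function(s) cc[[s]] + offs[s]))
      prods <- apply_rule_embedding(drules[[k]], sps, embedding)
      pidx <- sort(vapply(prods, function(p) {
        lab <- canonical_label(p)
        i <- index[[lab]]
        if (is.null(i)) stop("closure violated: novel species in enumeration pass")
        i
      }, 1L))
      key <- paste(pidx, collapse = ",")
      if (is.null(prod_sets[[key]])) prod_sets[[key]] <- list(pidx = pidx, mult = 0L)
      prod_sets[[key]]$mult <- prod_sets[[key]]$mult + 1L
    }
    d <- drules[[k]]
    for (ps in prod_sets) {
      rx[[length(rx) + 1L]] <<- list(
        rule = d$id, reverse = d$reverse,
        r = tuple_idx, p = ps$pidx,
        rate_ref = d$rate_ref, stat_factor = d$stat_factor, mult = ps$mult)
    }
  }
  for (k in seq_along(drules)) {
    ms <- matches[[k]]
    if (length(ms) == 1L) {
      for (j in seq_along(ms[[1]]$idx))
        emit(k, ms[[1]]$idx[j], list(ms[[1]]$emb[[j]]))
    } else {
      for (j1 in seq_along(ms[[1]]$idx))
        for (j2 in seq_along(ms[[2]]$idx))
          emit(k, c(ms[[1]]$idx[j1], ms[[2]]$idx[j2]),
               list(ms[[1]]$emb[[j1]], ms[[2]]$emb[[j2]]))
    }
  }

  reactions <- data.frame(
    rule = vapply(rx, function(r) r$rule, ""),
    reverse = vapply(rx, function(r) r$reverse, TRUE),
    r1 = vapply(rx, function(r) r$r[1], 1L),
    r2 = vapply(rx, function(r) if (length(r$r) > 1L) r$r[2] else NA_integer_, 1L),
    p1 = vapply(rx, function(r) r$p[1], 1L),
    p2 = vapply(rx, function(r) if (length(r$p) > 1L) r$p[2] else NA_integer_, 1L),
    rate_ref = vapply(rx, function(r) r$rate_ref, ""),
    stat_factor = vapply(rx, function(r) r$stat_factor, 1),
    mult = vapply(rx, function(r) r$mult, 1L),
    stringsAsFactors = FALSE)
  reactions$rate <- reactions$stat_factor * reactions$mult *
    unlist(model$params[reactions$rate_ref], use.names = FALSE)

  init <- numeric(length(labels))
  for (s in model$seeds) {
    lab <- canonical_label(parse_species(s$species_text, types))
    init[index[[lab]]] <- seed_amount(model, s)
  }

  structure(list(
    species = labels, graphs = graphs, init = init,
    reactions = reactions, model = model, n_seeds = n_seeds,
    cache = new.env(parent = emptyenv())
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction network: %d species, %d unidirectional reactions\n",
              length(x$species), nrow(x$reactions)))
  invisible(x)
}

#' Per-molecule-type composition matrix
#'
#' Returns the matrix whose entry (t, s) is the number of molecules of type t
#' in species s.  For any reaction generated from binding/state-change rules,
#' the composition-weighted copy-number totals are conserved.
#'
#' @param network A `reaction_network`.
#' @return An integer matrix, molecule types x species.
#' @export
composition_matrix <- function(network) {
  tn <- names(network$model$molecule_types)
  M <- matrix(0L, nrow = length(tn), ncol = length(network$species),
              dimnames = list(tn, NULL))
  for (s in seq_along(network$graphs))
    for (m in network$graphs[[s]]$mols)
      M[m$type, s] <- M[m$type, s] + 1L
  M
}

#' Write a reaction network to a plain-text file
#'
#' Species table (index, canonical label, initial copies) and reaction table
#' (index, rule provenance, reactant/product species indices, rate value,
#' multiplicity).  `read_network(write_network(net))` reproduces both tables.
#'
#' @param network A `reaction_network`.
#' @param path Output path.
#' @param header Optional named character vector written as provenance
#'   comments.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, header = NULL) {
  out <- "# mtorswitch reaction network"
  for (h in names(header)) out <- c(out, paste0("# ", h, ": ", header[[h]]))
  out <- c(out, "begin species")
  for (i in seq_along(network$species))
    out <- c(out, sprintf("  %d %s %s", i, network$species[i],
                          format_num(network$init[i])))
  out <- c(out, "end species", "begin reactions")
  rr <- network$reactions
  for (j in seq_len(nrow(rr))) {
    rs <- paste(stats::na.omit(c(rr$r1[j], rr$r2[j])), collapse = ",")
    ps <- paste(stats::na.omit(c(rr$p1[j], rr$p2[j])), collapse = ",")
    out <- c(out, sprintf("  %d %s%s %s %s %s %s %d", j, rr$rule[j],
                          ifelse(rr$reverse[j], "r", ""), rs, ps,
                          format_num(rr$rate[j]), rr$rate_ref[j], rr$mult[j]))
  }
  out <- c(out, "end reactions")
  writeLines(out, path)
  invisible(path)
}

#' Read a reaction network written by [write_network()]
#'
#' @param path Path to the network file.
#' @param model Optional generating `rule_model`; if supplied, species graphs
#'   are reconstructed from their canonical labels.
#' @return A `reaction_network` (without graphs unless `model` is given).
#' @export
read_network <- function(path, model = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sp_lines <- character(0); rx_lines <- character(0); block <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "begin species") block <- "s"
    else if (ln == "begin reactions") block <- "r"
    else if (ln %in% c("end species", "end reactions")) block <- NULL
    else if (identical(block, "s")) sp_lines <- c(sp_lines, ln)
    else if (identical(block, "r")) rx_lines <- c(rx_lines, ln)
    else stop("network parse error at line ", i, ": ", ln)
  }
  parse_fields <- function(ln, n, what, lineno) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) != n)
      stop("network parse error in ", what, " line ", lineno, ": ", ln)
    f
  }
  ns <- length(sp_lines)
  species <- character(ns); init <- numeric(ns)
  for (i in seq_along(sp_lines)) {
    f <- parse_fields(sp_lines[i], 3L, "species", i)
    species[as.integer(f[1])] <- f[2]
    init[as.integer(f[1])] <- as.numeric(f[3])
  }
  n <- length(rx_lines)
  rule <- character(n); reverse <- logical(n)
  r1 <- r2 <- p1 <- p2 <- rep(NA_integer_, n)
  rate <- numeric(n); rate_ref <- character(n); mult <- integer(n)
  for (i in seq_along(rx_lines)) {
    f <- parse_fields(rx_lines[i], 7L, "reaction", i)
    j <- as.integer(f[1])
    reverse[j] <- endsWith(f[2], "r")
    rule[j] <- sub("r$", "", f[2])
    rs <- as.integer(strsplit(f[3], ",")[[1]])
    ps <- as.integer(strsplit(f[4], ",")[[1]])
    r1[j] <- rs[1]; if (length(rs) > 1L) r2[j] <- rs[2]
    p1[j] <- ps[1]; if (length(ps) > 1L) p2[j] <- ps[2]
    rate[j] <- as.numeric(f[5]); rate_ref[j] <- f[6]; mult[j] <- as.integer(f[7])
  }
  reactions <- data.frame(rule = rule, reverse = reverse, r1 = r1, r2 = r2,
                          p1 = p1, p2 = p2, rate_ref = rate_ref,
                          stat_factor = NA_real_, mult = mult, rate = rate,
                          stringsAsFactors = FALSE)
  graphs <- NULL
  if (!is.null(model))
    graphs <- lapply(species, parse_species, types = model$molecule_types)
  structure(list(species = species, graphs = graphs, init = init,
                 reactions = reactions, model = model, n_seeds = NA_integer_,
                 cache = new.env(parent = emptyenv())),
            class = "reaction_network")
}

# index of the monomeric seed species for a molecule type (used by input
# resets and drift augmentation)
monomer_index <- function(network, type) {
  cache <- network$cache
  if (!is.null(cache) && !is.null(cache$monomer[[type]]))
    return(cache$monomer[[type]])
  seed_labels <- vapply(network$model$seeds, function(x)
    canonical_label(parse_species(x$species_text,
                                  network$model$molecule_types)), "")
  for (s in seq_along(network$graphs)) {
    g <- network$graphs[[s]]
    if (sp_n_mols(g) == 1L && g$mols[[1]]$type == type &&
        network$species[s] %in% seed_labels) {
      if (!is.null(cache)) {
        if (is.null(cache$monomer)) cache$monomer <- list()
        cache$monomer[[type]] <- s
      }
      return(s)
    }
  }
  stop("no monomeric seed species of type ", type)
}
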