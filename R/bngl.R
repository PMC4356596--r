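# Reading and writing the BNGL-style model dialect used by this package:
# parameters, molecule types, seed species, and reaction rules.  Only the
# constructs needed by this model family are supported (binding, state
# change, mass-action rates); this is deliberately not a general BNGL
# compiler.

#' Read a model file
#'
#' Parses a plain-text model file in the package's BNGL-style dialect, with
#' blocks `parameters`, `molecule types`, `seed species`, and
#' `reaction rules`.  Rule lines may carry a label (`8B:`); bidirectional
#' rules use `<->` with comma-separated forward and reverse rates.
#' Transcription variants of the lumped RPTOR site (`S855_Ser859`, `S855-9`)
#' are accepted as aliases of `S855_S859`.
#'
#' @param path Path to the model file.
#' @return An object of class `rule_model` with elements `molecule_types`,
#'   `rules`, `params`, and `seeds` (list of species/amount-expression pairs).
#' @seealso [write_bngl()], [build_model()]
#' @export
read_bngl <- function(path) {
  parse_bngl(readLines(path, warn = FALSE))
}

#' @rdname read_bngl
#' @param lines Character vector of model text lines (alternative to a file).
#' @export
parse_bngl <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  block <- NULL
  blocks <- list(parameters = character(0), `molecule types` = character(0),
                 `seed species` = character(0), `reaction rules` = character(0))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^begin ", ln)) {
      block <- sub("^begin ", "", ln)
      if (!block %in% names(blocks))
        stop("line ", i, ": unknown block '", block, "'")
    } else if (grepl("^end ", ln)) {
      block <- NULL
    } else {
      if (is.null(block)) stop("line ", i, ": content outside of a block")
      blocks[[block]] <- c(blocks[[block]], ln)
    }
  }
  params <- list()
  for (ln in blocks$parameters) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(toks) != 2L) stop("bad parameter line: ", ln)
    params[[toks[1]]] <- as.numeric(toks[2])
  }
  types <- list()
  for (ln in blocks$`molecule types`) {
    pm <- parse_mol_string(ln)
    sites <- list()
    for (tok in pm$site_tokens) {
      parts <- strsplit(tok, "~", fixed = TRUE)[[1]]
      sites[[normalize_site(parts[1])]] <-
        if (length(parts) > 1L) parts[-1] else character(0)
    }
    types[[pm$type]] <- molecule_type(pm$type, sites)
  }
  seeds <- list()
  for (ln in blocks$`seed species`) {
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1]]
    if (length(m) != 3L) stop("bad seed species line: ", ln)
    seeds[[length(seeds) + 1L]] <- list(species_text = m[2], amount_ref = m[3])
  }
  rules <- list()
  for (ln in blocks$`reaction rules`) {
    lab <- NA_character_
    m <- regmatches(ln, regexec("^([A-Za-z0-9]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) { lab <- m[2]; ln <- m[3] }
    bidir <- grepl("<->", ln, fixed = TRUE)
    arrow <- if (bidir) "<->" else "->"
    sides <- strsplit(ln, arrow, fixed = TRUE)[[1]]
    if (length(sides) != 2L) stop("bad rule line: ", ln)
    lhs <- trimws(sides[1])
    # rhs text ends at the rate expression(s): split on 2+ spaces from the end
    m2 <- regmatches(sides[2], regexec("^(.*\\S)\\s\\s+(\\S.*)$", sides[2]))[[1]]
    if (length(m2) != 3L) stop("cannot separate rate from rule products: ", ln)
    rhs <- trimws(m2[2])
    rates <- trimws(strsplit(m2[3], ",", fixed = TRUE)[[1]])
    if (bidir && length(rates) != 2L)
      stop("bidirectional rule needs two rates: ", ln)
    if (is.na(lab)) lab <- as.character(length(rules) + 1L)
    rules[[length(rules) + 1L]] <- rewrite_rule(
      id = lab, lhs = lhs, rhs = rhs, rate = rates[1],
      reverse_rate = if (bidir) rates[2] else NULL)
  }
  structure(list(molecule_types = types, rules = rules, params = params,
                 seeds = seeds), class = "rule_model")
}

format_num <- function(x) {
  # shortest representation that round-trips exactly through as.numeric
  s <- format(x, digits = 15, scientific = NA, trim = TRUE)
  for (d in 1:15) {
    cand <- format(x, digits = d, trim = TRUE)
    if (as.numeric(cand) == x) return(cand)
  }
  s
}

#' Write a model to a file in the package's BNGL-style dialect
#'
#' Numeric parameter values are written so that `read_bngl(write_bngl(m))`
#' reproduces them bit-for-bit.
#'
#' @param model A `rule_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bngl <- function(model, path) {
  out <- character(0)
  out <- c(out, "begin parameters")
  for (p in names(model$params))
    out <- c(out, sprintf("  %-12s %s", p, format_num(model$params[[p]])))
  out <- c(out, "end parameters", "", "begin molecule types")
  for (mt in model$molecule_types)
    out <- c(out, paste0("  ", mt_signature(mt)))
  out <- c(out, "end molecule types", "", "begin seed species")
  for (s in model$seeds)
    out <- c(out, sprintf("  %-48s %s", s$species_text, s$amount_ref))
  out <- c(out, "end seed species", "", "begin reaction rules")
  for (r in model$rules) {
    arrow <- if (r$direction == "bidirectional") "<->" else "->"
    rate <- if (r$stat_factor != 1) paste0(format_num(r$stat_factor), "*", r$rate_ref) else r$rate_ref
    if (r$direction == "bidirectional") {
      rrate <- if (r$reverse_stat_factor != 1)
        paste0(format_num(r$reverse_stat_factor), "*", r$reverse_rate_ref)
      else r$reverse_rate_ref
      rate <- paste0(rate, ", ", rrate)
    }
    out <- c(out, sprintf("  %-4s %s %s %s  %s", paste0(r$id, ":"),
                          r$lhs, arrow, r$rhs, rate))
  }
  out <- c(out, "end reaction rules")
  writeLines(out, path)
  invisible(path)
}
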