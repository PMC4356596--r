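# Model construction: the nominal AMPK-MTORC1-ULK1 switch model, variants
# (negative feedback on/off, AMPK->RPTOR coupling strength p9, input levels),
# structural validation, and rule-class censuses.

#' Describe a model variant
#'
#' @param feedback If `FALSE`, ULK1-mediated inhibitory phosphorylation of
#'   AMPK is disabled (the rate constant `p6` is forced to 0), removing the
#'   slow negative feedback from ULK1 to AMPK.
#' @param p9 Optional override for the rate constant of AMPK-mediated
#'   phosphorylation of RPTOR S792 ((copies/cell)^-1 s^-1); nominal value 0.
#' @param ampk_star Input level of AMPK* (AMPK with activating kinase-domain
#'   phosphorylation), copies/cell.
#' @param rapamycin_star Input level of FKBP1A-bound rapamycin, copies/cell.
#' @param overrides Named list of additional parameter overrides.
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(feedback = TRUE, p9 = NULL,
                          ampk_star = 30000, rapamycin_star = 0,
                          overrides = list()) {
  stopifnot(isTRUE(feedback) || isFALSE(feedback),
            is.null(p9) || (is.numeric(p9) && p9 >= 0),
            is.numeric(ampk_star), ampk_star >= 0,
            is.numeric(rapamycin_star), rapamycin_star >= 0)
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be a named list")
  structure(list(feedback = feedback, p9 = p9, ampk_star = ampk_star,
                 rapamycin_star = rapamycin_star, overrides = overrides),
            class = "model_variant")
}

nominal_model_path <- function() {
  system.file("extdata", "nominal.bngl", package = "mtorswitch", mustWork = TRUE)
}

#' Build the switch model
#'
#' Loads the nominal model (seven molecule types, 29 interaction rules,
#' nominal rate constants and abundances) and applies a variant: feedback
#' on/off, `p9` override, input levels, and arbitrary parameter overrides.
#'
#' @param variant A [model_variant()]; default is the nominal model at the
#'   unstressed inputs (AMPK* = 30,000 copies/cell, no rapamycin*).
#' @param path Optional path to an alternative model file.
#' @return A `rule_model` with the variant applied.
#' @examples
#' m <- build_model()
#' length(m$molecule_types)  # 7
#' length(m$rules)           # 29
#' @export
build_model <- function(variant = model_variant(), path = NULL) {
  if (is.null(path)) path <- nominal_model_path()
  model <- read_bngl(path)
  # input and variant parameters only apply to models that declare them
  # (generic model files need not share the nominal parameter names)
  if ("AMPK_star" %in% names(model$params))
    model$params$AMPK_star <- variant$ampk_star
  if ("rapa_star" %in% names(model$params))
    model$params$rapa_star <- variant$rapamycin_star
  if (!variant$feedback) {
    if (!"p6" %in% names(model$params))
      stop("feedback = FALSE requires a p6 parameter in the model")
    model$params$p6 <- 0
  }
  if (!is.null(variant$p9)) {
    if (!"p9" %in% names(model$params))
      stop("p9 override requires a p9 parameter in the model")
    model$params$p9 <- variant$p9
  }
  for (nm in names(variant$overrides)) {
    if (!nm %in% names(model$params))
      stop("override of unknown parameter: ", nm)
    model$params[[nm]] <- variant$overrides[[nm]]
  }
  model$variant <- variant
  # registry indexed by rule id
  names(model$rules) <- vapply(model$rules, function(r) r$id, "")
  bad <- vapply(model$rules, function(r) {
    refs <- c(r$rate_ref, r$reverse_rate_ref)
    !all(refs %in% names(model$params))
  }, TRUE)
  if (any(bad))
    stop("rules reference unknown parameters: ",
         paste(names(model$rules)[bad], collapse = ", "))
  model
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("rule-based model: %d molecule types, %d rules (%d unidirectional, %d bidirectional)\n",
              length(x$molecule_types), length(x$rules),
              sum(vapply(x$rules, function(r) r$direction == "unidirectional", TRUE)),
              sum(vapply(x$rules, function(r) r$direction == "bidirectional", TRUE))))
  cat(sprintf("inputs: AMPK* = %g, rapamycin* = %g copies/cell\n",
              x$params$AMPK_star, x$params$rapa_star))
  invisible(x)
}

#' Validate a model's internal consistency
#'
#' Checks every rule pattern against the declared molecule types (undeclared
#' molecules, sites, or states), rate references against the parameter block,
#' and reports rules whose reactant patterns cannot match any species
#' reachable from the seeds (requires a quick expansion; skipped when
#' `check_reachability = FALSE`).
#'
#' @param model A `rule_model`.
#' @param check_reachability Also check that every rule fires at least once
#'   in the expanded network (slower).
#' @return A data frame of findings (zero rows when the model is clean) with
#'   columns `rule`, `kind`, `detail`.
#' @export
validate_model <- function(model, check_reachability = FALSE) {
  findings <- list()
  add <- function(rule, kind, detail)
    findings[[length(findings) + 1L]] <<- data.frame(rule = rule, kind = kind,
                                                     detail = detail)
  check_pattern <- function(pat, rule_id) {
    for (pm in pat$mols) {
      mt <- model$molecule_types[[pm$type]]
      if (is.null(mt)) {
        add(rule_id, "undeclared_molecule", pm$type)
        next
      }
      for (s in names(pm$conds)) {
        if (!s %in% names(mt$sites)) {
          add(rule_id, "undeclared_site", paste0(pm$type, ".", s))
          next
        }
        st <- pm$conds[[s]]$state
        if (!is.na(st) && !st %in% mt$sites[[s]])
          add(rule_id, "undeclared_state", paste0(pm$type, ".", s, "~", st))
      }
    }
  }
  for (r in model$rules) {
    for (pat in r$reactants) check_pattern(pat, r$id)
    for (pat in r$products) check_pattern(pat, r$id)
    for (ref in c(r$rate_ref, r$reverse_rate_ref))
      if (!ref %in% names(model$params))
        add(r$id, "unbound_parameter", ref)
  }
  for (s in model$seeds) {
    if (!s$amount_ref %in% names(model$params) &&
        is.na(suppressWarnings(as.numeric(s$amount_ref))))
      add("(seed)", "unbound_parameter", s$amount_ref)
  }
  if (check_reachability && !length(findings)) {
    net <- expand_network(model)
    fired <- unique(paste0(net$reactions$rule,
                           ifelse(net$reactions$reverse, ":r", ":f")))
    for (r in model$rules) {
      dirs <- if (r$direction == "bidirectional") c(":f", ":r") else ":f"
      for (d in dirs)
        if (!paste0(r$id, d) %in% fired)
          add(r$id, "unreachable_rule", paste0("direction ", d))
    }
  }
  if (!length(findings))
    return(data.frame(rule = character(0), kind = character(0),
                      detail = character(0)))
  do.call(rbind, findings)
}

# phosphorylation state order used to classify state-change rules
.state_rank <- c(`0` = 0L, P = 1L, PP = 2L)

classify_rule <- function(rule) {
  act <- rule$action
  if (length(act$form) || length(act$breaks) || rule$direction == "bidirectional")
    return("association_dissociation")
  if (length(act$state_changes)) {
    ch <- act$state_changes[[1]]
    from <- .state_rank[ch$from]
    to <- .state_rank[ch$to]
    if (is.na(from) || is.na(to)) return("other")
    return(if (to > from) "phosphorylation" else "dephosphorylation")
  }
  "other"
}

#' Census of rules by mechanistic class
#'
#' Partitions the rule set into association/dissociation rules (reversible
#' and unidirectional), phosphorylation rules, and dephosphorylation rules,
#' classified from each rule's derived action.
#'
#' @param model A `rule_model`.
#' @return A list with counts `reversible_assoc_dissoc`,
#'   `unidirectional_assoc_dissoc`, `phosphorylation`, `dephosphorylation`,
#'   and the per-rule classification `by_rule`.
#' @export
count_rules_by_class <- function(model) {
  cls <- vapply(model$rules, classify_rule, "")
  rev <- vapply(model$rules, function(r) r$direction == "bidirectional", TRUE)
  list(
    reversible_assoc_dissoc = sum(cls == "association_dissociation" & rev),
    unidirectional_assoc_dissoc = sum(cls == "association_dissociation" & !rev),
    phosphorylation = sum(cls == "phosphorylation"),
    dephosphorylation = sum(cls == "dephosphorylation"),
    by_rule = stats::setNames(cls, names(model$rules))
  )
}

# resolve a seed amount reference (parameter name or literal) to a number
seed_amount <- function(model, seed) {
  if (seed$amount_ref %in% names(model$params))
    return(model$params[[seed$amount_ref]])
  as.numeric(seed$amount_ref)
}
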