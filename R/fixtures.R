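# Toy rule systems with closed-form expected network sizes.  These exercise
# each construct the expansion engine relies on (binding, multi-state
# phosphoforms, scaffolds, same-site competition, required-unbound context)
# at a size where the full reachable state space can be enumerated by hand
# or by brute force.

#' Toy rule systems for engine validation
#'
#' Returns at least five small rule-based models, each with the closed-form
#' expected number of species and unidirectional reactions of its expanded
#' network:
#'
#' * `dimer` — reversible A-B binding: 3 species, 2 reactions.
#' * `phosphoforms` — one molecule with a 2-state and a 3-state site and
#'   free (de)phosphorylation: 6 species, 14 reactions.
#' * `scaffold` — an A-B-C chain assembling via two reversible bonds:
#'   6 species, 8 reactions.
#' * `competition` — two ligands competing for the same receptor site:
#'   5 species, 4 reactions (no doubly bound species).
#' * `context_unbound` — two binding partners on distinct sites with
#'   mutually exclusive required-unbound context (the rapamycin/RPTOR
#'   exclusivity motif): 5 species, 4 reactions, and no species with both
#'   sites bound.
#'
#' @return Named list; each element has `model` (a `rule_model`),
#'   `expected_species`, `expected_reactions`, and `note`.
#' @export
toy_models <- function() {
  mk <- function(lines) parse_bngl(lines)
  list(
    dimer = list(
      model = mk(c(
        "begin parameters", "  kon 1e-3", "  koff 1e-2", "end parameters",
        "begin molecule types", "  A(b)", "  B(a)", "end molecule types",
        "begin seed species", "  A(b) 100", "  B(a) 100", "end seed species",
        "begin reaction rules",
        "  1: A(b)+B(a) <-> A(b!1).B(a!1)  kon, koff",
        "end reaction rules")),
      expected_species = 3L, expected_reactions = 2L,
      note = "reversible dimerisation"),
    phosphoforms = list(
      model = mk(c(
        "begin parameters", "  kp 1", "  ku 0.1", "end parameters",
        "begin molecule types", "  M(s~0~P,t~0~P~PP)", "end molecule types",
        "begin seed species", "  M(s~0,t~0) 100", "end seed species",
        "begin reaction rules",
        "  1: M(s~0) -> M(s~P)  kp",
        "  2: M(s~P) -> M(s~0)  ku",
        "  3: M(t~0) -> M(t~P)  kp",
        "  4: M(t~P) -> M(t~PP)  kp",
        "  5: M(t~P) -> M(t~0)  ku",
        "  6: M(t~PP) -> M(t~P)  ku",
        "end reaction rules")),
      expected_species = 6L, expected_reactions = 14L,
      note = "2-state x 3-state phosphoform lattice"),
    scaffold = list(
      model = mk(c(
        "begin parameters", "  kon 1e-3", "  koff 1e-2", "end parameters",
        "begin molecule types", "  A(b)", "  B(a,c)", "  C(b)",
        "end molecule types",
        "begin seed species", "  A(b) 100", "  B(a,c) 100", "  C(b) 100",
        "end seed species",
        "begin reaction rules",
        "  1: A(b)+B(a) <-> A(b!1).B(a!1)  kon, koff",
        "  2: B(c)+C(b) <-> B(c!1).C(b!1)  kon, koff",
        "end reaction rules")),
      expected_species = 6L, expected_reactions = 8L,
      note = "A-B-C scaffold chain"),
    competition = list(
      model = mk(c(
        "begin parameters", "  kon 1e-3", "  koff 1e-2", "end parameters",
        "begin molecule types", "  R(s)", "  L1(r)", "  L2(r)",
        "end molecule types",
        "begin seed species", "  R(s) 100", "  L1(r) 100", "  L2(r) 100",
        "end seed species",
        "begin reaction rules",
        "  1: R(s)+L1(r) <-> R(s!1).L1(r!1)  kon, koff",
        "  2: R(s)+L2(r) <-> R(s!1).L2(r!1)  kon, koff",
        "end reaction rules")),
      expected_species = 5L, expected_reactions = 4L,
      note = "two ligands competing for one site"),
    context_unbound = list(
      model = mk(c(
        "begin parameters", "  kon 1e-3", "  koff 1e-2", "end parameters",
        "begin molecule types", "  T(h,f)", "  X(t)", "  Y(t)",
        "end molecule types",
        "begin seed species", "  T(h,f) 100", "  X(t) 100", "  Y(t) 100",
        "end seed species",
        "begin reaction rules",
        "  1: X(t)+T(h,f) <-> X(t!1).T(h,f!1)  kon, koff",
        "  2: Y(t)+T(h,f) <-> Y(t!1).T(h!1,f)  kon, koff",
        "end reaction rules")),
      expected_species = 5L, expected_reactions = 4L,
      note = "mutual exclusivity via required-unbound context")
  )
}
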