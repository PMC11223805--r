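# Independent oracles used to cross-check the package implementation.
# These deliberately use naive algorithms (exhaustive path enumeration,
# Kahn's topological sort) distinct from the package's own code paths.

# ancestor set by exhaustive enumeration of all parent paths
oracle_ancestors <- function(ped, id) {
  ind <- ped$ind
  parent_ids <- function(i) {
    r <- match(i, ind$id)
    setdiff(c(ind$father_id[r], ind$mother_id[r]), "0")
  }
  out <- character()
  stack <- list(id)
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (p in parent_ids(cur)) {
      if (p %in% ind$id && !(p %in% out)) {
        out <- c(out, p)
        stack[[length(stack) + 1L]] <- p
      }
    }
  }
  sort(out)
}

# consanguinity by brute force: shared ancestor, or one partner ancestral
# to the other
oracle_consanguineous <- function(ped, father, mother) {
  af <- oracle_ancestors(ped, father)
  am <- oracle_ancestors(ped, mother)
  length(intersect(af, am)) > 0L || father %in% am || mother %in% af
}

# TRUE iff the parent->child relation has a cycle (Kahn's algorithm)
oracle_has_cycle <- function(records) {
  ids <- records$individual_id
  edges <- rbind(
    data.frame(from = records$father_id, to = ids, stringsAsFactors = FALSE),
    data.frame(from = records$mother_id, to = ids, stringsAsFactors = FALSE))
  edges <- edges[edges$from %in% ids, , drop = FALSE]
  nodes <- ids
  repeat {
    indeg <- table(factor(edges$to, levels = nodes))
    src <- nodes[indeg == 0L]
    if (length(src) == 0L) break
    nodes <- setdiff(nodes, src)
    edges <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
  }
  length(nodes) > 0L
}

# small hand-built families -------------------------------------------

figure_family_text <- function() {
  c("FAM F1 0 0 1 1 consanguineous_partner",
    "FAM M1 0 0 2 1",
    "FAM C1 F1 M1 2 2",
    "FAM C2 F1 M1 1 1",
    "FAM C3 F1 M1 2 1")
}

figure_family <- function() {
  build_pedigree(parse_ped(figure_family_text()))
}

# three-generation family with a first-cousin union X (from branch A) and
# Y (from branch B), grandparents G1 x G2
cousin_loop_records <- function() {
  parse_ped(c(
    "L G1 0 0 1 1",
    "L G2 0 0 2 1",
    "L A1 G1 G2 1 1",
    "L B1 G1 G2 2 1",
    "L A2 0 0 2 1",
    "L B2 0 0 1 1",
    "L X1 A1 A2 1 1",
    "L Y1 B2 B1 2 1",
    "L K1 X1 Y1 1 2"))$records
}

# uncle-niece mating: uncle U (generation 1) with his brother's daughter
# N (generation 2): a generation-spanning union
uncle_niece_records <- function() {
  parse_ped(c(
    "U G1 0 0 1 1",
    "U G2 0 0 2 1",
    "U U1 G1 G2 1 1",
    "U B1 G1 G2 1 1",
    "U W1 0 0 2 1",
    "U N1 B1 W1 2 1",
    "U K1 U1 N1 1 2"))$records
}

# double first cousins: two brothers from family A marry two sisters from
# family B; children of those couples marry each other
double_cousin_records <- function() {
  parse_ped(c(
    "D FA 0 0 1 1", "D MA 0 0 2 1",
    "D FB 0 0 1 1", "D MB 0 0 2 1",
    "D A1 FA MA 1 1", "D A2 FA MA 1 1",
    "D B1 FB MB 2 1", "D B2 FB MB 2 1",
    "D X1 A1 B1 1 1",
    "D Y1 A2 B2 2 1",
    "D K1 X1 Y1 1 2"))$records
}

gen_ped <- function(seed, n_generations = 2 + seed %% 4, ...) {
  generate_pedigree(generator_params(n_generations = n_generations,
                                     seed = seed, ...))
}
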