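# Synthetic out-of-frame IgH lineages: germline-template V/J flanks with a
# randomized junction, random tree topologies with prescribed per-branch
# mutation counts, mutations placed without replacement proportionally to
# mu_x = gamma_w beta_x, and an optional exponential follow-up process that
# co-localizes mutations within branches.

#' Position-effect profiles used for simulation truths
#'
#' `"flat"` is `beta_x = 1`; `"sin"` is `exp(2 sin(x / delta) - 1)` and
#' `"cos"` is `exp(2 cos(x / delta) - 1)`, with 0-based `x`. The profiles
#' are truth parameters and are deliberately not renormalized.
#'
#' @param kind `"flat"`, `"sin"` or `"cos"`.
#' @param L profile length.
#' @param delta period parameter (nt).
#' @return Numeric vector of length `L`.
#' @export
make_beta_profile <- function(kind = c("flat", "sin", "cos"), L = 400L,
                              delta = 50) {
  kind <- match.arg(kind)
  stopifnot(L > 0, delta > 0)
  x <- seq_len(L) - 1
  switch(kind,
         flat = rep(1, L),
         sin = exp(2 * sin(x / delta) - 1),
         cos = exp(2 * cos(x / delta) - 1))
}

#' Seeded stand-in for a published 5-mer mutability table
#'
#' Two generators for ground-truth context rates. `"motif"` mimics a
#' published table such as S5F (Yaari et al., 2013, Front Immunol 4:358):
#' rates carry the classical AID / polymerase-eta targeting structure on
#' both strands -- hot WRC/GYW (x8), warm WA/TW (x3) and cold SYC/GRS
#' (x0.15) motifs around the focal base -- with log-normal variability
#' within each motif class. `"lognormal"` draws all 1024 rates i.i.d.
#' log-normal, reproducing only the overall dynamic range. Both span
#' several orders of magnitude, as empirical 5-mer models do.
#'
#' @param sdlog log-scale standard deviation (within motif class for
#'   `"motif"`); defaults to 0.5 for `"motif"` and 1 for `"lognormal"`.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @param style `"motif"` (default) or `"lognormal"`.
#' @return Named numeric vector of length 1024.
#' @export
random_gamma_table <- function(sdlog = NULL, seed = NULL,
                               style = c("motif", "lognormal")) {
  style <- match.arg(style)
  if (is.null(sdlog)) sdlog <- if (style == "motif") 0.5 else 1
  if (!is.null(seed)) set.seed(seed)
  fm <- all_fivemers()
  if (style == "lognormal")
    return(setNames(rlnorm(1024L, meanlog = 0, sdlog = sdlog), fm))
  n <- do.call(rbind, strsplit(fm, ""))
  w <- c("A", "T"); s <- c("C", "G"); r <- c("A", "G"); y <- c("C", "T")
  hot <- (n[, 1] %in% w & n[, 2] %in% r & n[, 3] == "C") |
    (n[, 3] == "G" & n[, 4] %in% y & n[, 5] %in% w)
  warm <- (n[, 2] %in% w & n[, 3] == "A") | (n[, 3] == "T" & n[, 4] %in% w)
  cold <- (n[, 1] %in% s & n[, 2] %in% y & n[, 3] == "C") |
    (n[, 3] == "G" & n[, 4] %in% r & n[, 5] %in% s)
  base <- rep(1, 1024L)
  base[warm] <- 3
  base[hot] <- 8
  base[cold] <- 0.15
  setNames(base * rlnorm(1024L, meanlog = 0, sdlog = sdlog), fm)
}

#' Simulation configuration
#'
#' Describes the synthetic repertoire: germline templates (a small panel of
#' random "V genes" and one "J gene"), the junction length support
#' (frameshifted lengths only, so every read is out-of-frame), the family
#' size distribution (discrete power law, matching the heavy-tailed clonal
#' family sizes of real repertoires) and the per-branch mutation count
#' support.
#'
#' @param L modelled positions.
#' @param n_v_templates number of germline V templates in the panel.
#' @param v_flank_length,j_flank_length template lengths (nt).
#' @param junction_lengths integer support of junction lengths; defaults to
#'   25..59 excluding multiples of 3.
#' @param family_size_range,family_size_alpha support and exponent of the
#'   power-law family size distribution `P(m) ~ m^-alpha`.
#' @param branch_mutations integer support of per-branch mutation counts
#'   (uniform by default).
#' @param branch_mutation_weights optional sampling weights over that
#'   support; e.g. a truncated geometric law mimics the short-branch-
#'   dominated length distribution of reconstructed B-cell lineages.
#' @param epsilon,xi follow-up amplitude in `[0, 1)` and correlation length
#'   (nt) of the co-localization process; `epsilon = 0` disables it.
#' @param delta period of the sinusoidal beta profiles.
#' @param seed RNG seed for template generation and simulation.
#' @return A list of class `sim_config` (germline templates included).
#' @export
sim_config <- function(L = 400L, n_v_templates = 12L, v_flank_length = 270L,
                       j_flank_length = 70L,
                       junction_lengths = setdiff(25:59, seq(27, 57, by = 3)),
                       family_size_range = c(6L, 60L),
                       family_size_alpha = 2.5,
                       branch_mutations = 1:9,
                       branch_mutation_weights = NULL,
                       epsilon = 0, xi = 10, delta = 50, seed = 1L) {
  stopifnot(epsilon >= 0, epsilon < 1, xi > 0, delta > 0,
            all(junction_lengths %% 3L != 0L),
            is.null(branch_mutation_weights) ||
              (length(branch_mutation_weights) == length(branch_mutations) &&
                 all(branch_mutation_weights > 0)))
  set.seed(seed)
  v_templates <- replicate(n_v_templates, random_sequence(v_flank_length))
  j_template <- random_sequence(j_flank_length)
  structure(list(L = as.integer(L),
                 v_templates = v_templates,
                 j_template = j_template,
                 junction_lengths = as.integer(junction_lengths),
                 family_size_range = as.integer(family_size_range),
                 family_size_alpha = family_size_alpha,
                 branch_mutations = as.integer(branch_mutations),
                 branch_mutation_weights = branch_mutation_weights,
                 epsilon = epsilon, xi = xi, delta = delta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a root sequence: template V flank + random junction + template J flank
#'
#' @param config a [sim_config()].
#' @param v_index which V template to use (defaults to a random one).
#' @param junction_length junction length (defaults to a random draw from
#'   the configured support).
#' @return list with `sequence`, `cdr3_start`, `cdr3_end` (0-based
#'   half-open junction bounds), `v_index`.
#' @export
generate_root_sequence <- function(config,
                                   v_index = sample.int(
                                     length(config$v_templates), 1L),
                                   junction_length = sample(
                                     config$junction_lengths, 1L)) {
  v <- config$v_templates[[v_index]]
  junction_length <- as.integer(junction_length)
  junc <- if (junction_length > 0) random_sequence(junction_length) else ""
  list(sequence = paste0(v, junc, config$j_template),
       cdr3_start = nchar(v),
       cdr3_end = nchar(v) + junction_length,
       v_index = v_index)
}

#' Germline sequence for a synthetic class
#'
#' The germline used by the reconstruction pipeline: V template, `N` at the
#' non-templated junction positions (unknown, as in real data), J template.
#'
#' @param config a [sim_config()].
#' @param v_index index into the V template panel.
#' @param junction_length junction (CDR3) length in nucleotides.
#' @return A germline sequence string.
#' @export
germline_for <- function(config, v_index, junction_length) {
  paste0(config$v_templates[[v_index]],
         strrep("N", junction_length), config$j_template)
}

# mutability of each position of `enc` (encoded parent sequence): NA where
# context undefined or x >= L
position_mutability <- function(enc, model) {
  ctx <- context_indices(enc)
  x <- seq_along(enc)
  mu <- rep(NA_real_, length(enc))
  ok <- !is.na(ctx) & x <= model$L
  mu[ok] <- model$gamma[ctx[ok]] * model$beta[x[ok]]
  mu
}

substitute_base <- function(from, omega_row = NULL) {
  alt <- setdiff(1:4, from)
  if (is.null(omega_row)) sample(alt, 1L)
  else sample(alt, 1L, prob = omega_row[alt])
}

# Shared placement law over 1-based positions `eligible` with rates `mu`
# (vector over the whole sequence). With epsilon = 0, `n` positions are
# drawn without replacement proportionally to mu. With epsilon > 0, the
# draw alternates one targeted position (mu-proportional over unmutated
# positions) with a sweep of follow-up Bernoulli draws at probability
# epsilon * exp(-|x - x0| / xi); a final follow-up batch that would exceed
# `n` is truncated by random subsampling, conserving the total exactly.
place_mutations <- function(mu, eligible, n, epsilon = 0, xi = 10) {
  if (n > length(eligible))
    stop("requested ", n, " mutations but only ", length(eligible),
         " eligible positions")
  if (n == 0L)
    return(list(pos = integer(0), label = character(0)))
  if (epsilon == 0) {
    pos <- eligible[sample.int(length(eligible), n, prob = mu[eligible])]
    return(list(pos = pos, label = rep("targeted", n)))
  }
  mutated <- integer(0)
  labels <- character(0)
  while (length(mutated) < n) {
    open <- setdiff(eligible, mutated)
    x0 <- open[sample.int(length(open), 1L, prob = mu[open])]
    mutated <- c(mutated, x0)
    labels <- c(labels, "targeted")
    remaining <- n - length(mutated)
    if (remaining == 0L) break
    open <- setdiff(eligible, mutated)
    p <- epsilon * exp(-abs(open - x0) / xi)
    hit <- open[runif(length(open)) < p]
    if (length(hit) > remaining)
      hit <- sample(hit, remaining)
    mutated <- c(mutated, hit)
    labels <- c(labels, rep("followup", length(hit)))
  }
  list(pos = mutated, label = labels)
}

#' Place mutations on one branch
#'
#' Computes `mu_x` once from the parent sequence (contexts are frozen
#' within a branch) and draws `n` distinct positions without replacement
#' with probability proportional to `mu_x`; each drawn position is
#' substituted uniformly among the three alternative bases (or according to
#' a substitution table).
#'
#' @param parent_seq parent nucleotide string.
#' @param n number of mutations.
#' @param model a `mutability_model` (the truth parameters).
#' @param omega optional `substitution_model` for target-base choice.
#' @return list with `child_seq` and `events` (data.frame `x`, 0-based,
#'   `from`, `to`, `label = "targeted"`).
#' @export
simulate_branch_mutations <- function(parent_seq, n, model, omega = NULL) {
  enc <- encode_seq(parent_seq)
  mu <- position_mutability(enc, model)
  eligible <- which(!is.na(mu) & mu > 0)
  placed <- place_mutations(mu, eligible, n, epsilon = 0)
  apply_substitutions(enc, placed, omega)
}

# substitute the placed positions and package the result
apply_substitutions <- function(enc, placed, omega) {
  pos <- placed$pos
  child <- enc
  to <- integer(length(pos))
  ctx <- context_indices(enc)
  for (k in seq_along(pos)) {
    i <- pos[k]
    orow <- if (!is.null(omega)) omega$omega[ctx[i], ] else NULL
    to[k] <- substitute_base(enc[i], orow)
    child[i] <- to[k]
  }
  list(child_seq = decode_seq(child),
       events = data.frame(x = pos - 1L, from = NUC[enc[pos]], to = NUC[to],
                           label = placed$label, stringsAsFactors = FALSE))
}

#' Place mutations on one branch with exponential follow-up co-localization
#'
#' Iterates: draw one targeted mutation from the `mu`-proportional law over
#' not-yet-mutated eligible positions, then visit every other not-yet-mutated
#' position `x` and mutate it with probability
#' `epsilon * exp(-|x - x0| / xi)`. The loop stops when the branch's
#' prescribed total `n` is reached; a final follow-up batch that would
#' overshoot is truncated by random subsampling, so per-branch totals are
#' conserved exactly. With `epsilon = 0` the law reduces to
#' [simulate_branch_mutations()].
#'
#' @inheritParams simulate_branch_mutations
#' @param epsilon follow-up amplitude in `[0, 1)`.
#' @param xi correlation length (nt), `> 0`.
#' @return list with `child_seq` and `events` (`label` is `"targeted"` or
#'   `"followup"`).
#' @export
simulate_with_colocalization_branch <- function(parent_seq, n, model,
                                                epsilon, xi, omega = NULL) {
  stopifnot(epsilon >= 0, epsilon < 1, xi > 0)
  enc <- encode_seq(parent_seq)
  mu <- position_mutability(enc, model)
  eligible <- which(!is.na(mu) & mu > 0)
  placed <- place_mutations(mu, eligible, n, epsilon = epsilon, xi = xi)
  apply_substitutions(enc, placed, omega)
}

# discrete power-law draw on [lo, hi]
rpowerlaw <- function(n, lo, hi, alpha) {
  support <- lo:hi
  sample(support, n, replace = TRUE, prob = support^(-alpha))
}

#' Random rooted topology with per-branch mutation counts
#'
#' @param n_leaves number of leaves.
#' @param branch_mutations integer support for per-branch counts.
#' @param weights sampling weights over the support (default uniform).
#' @return An `ape::phylo` tree with `$branch_counts` (one per edge).
#' @export
random_topology <- function(n_leaves, branch_mutations = 1:9,
                            weights = NULL) {
  tree <- ape::rtree(n_leaves, rooted = TRUE,
                     tip.label = sprintf("leaf%d", seq_len(n_leaves)))
  tree <- ape::makeNodeLabel(tree, "number", prefix = "true")
  tree$branch_counts <- sample(branch_mutations, nrow(tree$edge),
                               replace = TRUE, prob = weights)
  tree
}

#' Simulate one lineage along a topology
#'
#' Propagates sequences from the root to the leaves: each branch's
#' mutations are drawn from its own parent sequence (contexts evolve across
#' branches, frozen within a branch). Per-branch counts are prescribed and
#' conserved exactly.
#'
#' @param topology a rooted `phylo` with `$branch_counts` (see
#'   [random_topology()]).
#' @param root_seq root nucleotide string.
#' @param model a `mutability_model` (truth).
#' @param epsilon,xi follow-up parameters; `epsilon = 0` gives the plain
#'   targeting law.
#' @param omega optional `substitution_model`.
#' @param lineage_id identifier.
#' @return An object of class `simulated_lineage`: `tree`, `sequences`
#'   (root, internal nodes and leaves), `branches` (list of `shm_branch`,
#'   one per edge, in edge order), `truth` (events with targeted/followup
#'   labels), `lineage_id`.
#' @export
simulate_lineage <- function(topology, root_seq, model, epsilon = 0, xi = 10,
                             omega = NULL, lineage_id = "sim") {
  edges <- reorder(topology, "cladewise")$edge
  counts <- topology$branch_counts[match(
    paste(edges[, 1], edges[, 2]),
    paste(topology$edge[, 1], topology$edge[, 2]))]
  labels <- c(topology$tip.label, topology$node.label)
  n_tip <- length(topology$tip.label)
  root <- setdiff(edges[, 1], edges[, 2])[1]
  seqs <- setNames(vector("list", length(labels)), labels)
  seqs[[labels[root]]] <- toupper(root_seq)
  branches <- vector("list", nrow(edges))
  truth <- vector("list", nrow(edges))
  for (r in seq_len(nrow(edges))) {
    parent <- labels[edges[r, 1]]; child <- labels[edges[r, 2]]
    sim <- if (epsilon > 0)
      simulate_with_colocalization_branch(seqs[[parent]], counts[r], model,
                                          epsilon, xi, omega)
    else
      simulate_branch_mutations(seqs[[parent]], counts[r], model, omega)
    seqs[[child]] <- sim$child_seq
    branches[[r]] <- new_branch(seqs[[parent]], sim$child_seq, L = model$L,
                                lineage_id = lineage_id,
                                branch_id = paste0(parent, "..", child))
    if (nrow(sim$events))
      truth[[r]] <- cbind(data.frame(lineage_id = lineage_id,
                                     branch_id = paste0(parent, "..", child),
                                     stringsAsFactors = FALSE), sim$events)
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(lineage_id = character(), branch_id = character(),
                        x = integer(), from = character(), to = character(),
                        label = character())
  structure(list(tree = topology, sequences = seqs, branches = branches,
                 truth = truth, lineage_id = lineage_id,
                 n_leaves = n_tip),
            class = "simulated_lineage")
}

#' Simulate a synthetic out-of-frame repertoire
#'
#' Draws lineages (power-law family sizes, random topologies, per-branch
#' mutation counts uniform on the configured support, root sequences from
#' the germline template panel) until at least `n_events_target` mutation
#' events have been generated.
#'
#' @param model a `mutability_model` (truth parameters).
#' @param config a [sim_config()].
#' @param n_events_target total mutation events to generate.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with `lineages` (list of `simulated_lineage`), `reads` (an
#'   [annotated_reads()] table of all leaves, nonproductive, with junction
#'   coordinates), `n_events`, and `meta` (per-lineage v_index and junction
#'   length, used to look up germlines).
#' @export
simulate_repertoire <- function(model, config = sim_config(),
                                n_events_target = 2e5, seed = config$seed) {
  set.seed(seed)
  lineages <- list()
  meta <- list()
  reads <- list()
  n_events <- 0L
  k <- 0L
  while (n_events < n_events_target) {
    k <- k + 1L
    m <- rpowerlaw(1L, config$family_size_range[1], config$family_size_range[2],
                   config$family_size_alpha)
    topo <- random_topology(m, config$branch_mutations,
                            config$branch_mutation_weights)
    root <- generate_root_sequence(config)
    id <- sprintf("sim%05d", k)
    lin <- simulate_lineage(topo, root$sequence, model,
                            epsilon = config$epsilon, xi = config$xi,
                            lineage_id = id)
    lin$v_index <- root$v_index
    lin$cdr3_start <- root$cdr3_start
    lin$cdr3_end <- root$cdr3_end
    lineages[[k]] <- lin
    meta[[k]] <- data.frame(lineage_id = id, v_index = root$v_index,
                            junction_length = root$cdr3_end - root$cdr3_start,
                            stringsAsFactors = FALSE)
    leaf_seqs <- unlist(lin$sequences[topo$tip.label])
    reads[[k]] <- data.frame(
      read_id = paste0(id, "_", topo$tip.label),
      sequence = unname(leaf_seqs),
      v_gene = sprintf("V%02d", root$v_index),
      j_gene = "J1",
      cdr3_start = root$cdr3_start,
      cdr3_end = root$cdr3_end,
      productive = FALSE, stringsAsFactors = FALSE)
    n_events <- n_events + nrow(lin$truth)
  }
  rd <- do.call(rbind, reads)
  list(lineages = lineages,
       reads = annotated_reads(rd$read_id, rd$sequence, rd$v_gene, rd$j_gene,
                               rd$cdr3_start, rd$cdr3_end, rd$productive),
       n_events = n_events,
       meta = do.call(rbind, meta))
}

#' True post-MRCA branches of simulated lineages
#'
#' The simulated root is the lineage MRCA, so every simulated branch is
#' post-MRCA; branches are filtered with the same rules as
#' [extract_mutation_events()] (distinct-leaf count, mutation cap).
#'
#' @param lineages list of `simulated_lineage` objects.
#' @param config an [shm_config()].
#' @return list of `shm_branch` objects.
#' @export
true_branches <- function(lineages, config = shm_config()) {
  out <- list()
  for (lin in lineages) {
    leaves <- unlist(lin$sequences[lin$tree$tip.label])
    if (length(unique(leaves)) < config$min_family_size) next
    for (b in lin$branches) {
      if (b$n_eligible > 0L && b$n_mut < config$max_branch_mutations)
        out[[length(out) + 1L]] <- b
    }
  }
  out
}

#' Write simulation ground truth as TSV
#' @param lineages list of `simulated_lineage` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(lineages, path) {
  truth <- do.call(rbind, lapply(lineages, `[[`, "truth"))
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
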