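# Lineage reconstruction: K80 distances, neighbor-joining topologies rooted
# on the germline outgroup, ML branch lengths and marginal ancestral state
# reconstruction (via phangorn), and extraction of per-branch mutation
# events with their 5-mer contexts.

#' Kimura (1980) two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' fractions of transitions and transversions over comparable (both A/C/G/T)
#' positions.
#'
#' @param s1,s2 equal-length nucleotide strings (A/C/G/T/N).
#' @return Distance in substitutions per site.
#' @export
k80_distance <- function(s1, s2) {
  e1 <- encode_seq(s1); e2 <- encode_seq(s2)
  stopifnot(length(e1) == length(e2))
  ok <- !is.na(e1) & !is.na(e2)
  n <- sum(ok)
  if (n < 1L) stop("no comparable positions")
  diff <- ok & (e1 != e2)
  # transitions: A<->G (codes 1,3), C<->T (codes 2,4)
  ts <- diff & (abs(e1 - e2) == 2L)
  P <- sum(ts, na.rm = TRUE) / n
  Q <- (sum(diff, na.rm = TRUE) - sum(ts, na.rm = TRUE)) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop("saturated K80 distance (log of non-positive argument)",
         call. = FALSE)
  -0.5 * log(a1) - 0.25 * log(a2)
}

# K80 transition probability matrix for branch length t (expected
# substitutions per site) and transition/transversion rate ratio kappa.
# Rows/columns in A,C,G,T order.
k80_prob <- function(t, kappa) {
  # rate matrix normalized to one expected substitution per unit t
  b <- 1 / (kappa + 2)
  a <- kappa * b
  e1 <- exp(-4 * b * t)
  e2 <- exp(-2 * (a + b) * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  trs <- 0.25 + 0.25 * e1 - 0.5 * e2
  trv <- 0.25 - 0.25 * e1
  m <- matrix(trv, 4, 4, dimnames = list(NUC, NUC))
  diag(m) <- same
  m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- trs
  m
}

# Pooled transition/transversion rate ratio estimate from raw counts.
# Transitions arise from 1 of 3 alternative bases, transversions from 2,
# so the count ratio estimates kappa/2.
estimate_kappa <- function(seqs) {
  ts <- 0L; tv <- 0L
  n <- length(seqs)
  enc <- lapply(seqs, encode_seq)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- !is.na(enc[[i]]) & !is.na(enc[[j]]) & (enc[[i]] != enc[[j]])
      d <- abs(enc[[i]][ok] - enc[[j]][ok])
      ts <- ts + sum(d == 2L)
      tv <- tv + sum(d != 2L)
    }
  }
  if (tv == 0L) return(2)
  min(max(2 * ts / tv, 0.2), 100)
}

#' Build a lineage topology for a clonal family
#'
#' Neighbor-joining on pairwise K80 distances over the distinct member
#' sequences plus the germline sequence, rooted on the germline outgroup.
#' Families with fewer than two distinct member sequences carry no
#' phylogenetic signal and return `NULL` (skip signal).
#'
#' @param family a `clonal_family` from [cluster_clonal_families()], or an
#'   [annotated_reads()] table.
#' @param germline_seq germline (V + J template) sequence, same length as
#'   the member sequences; junction positions may be `N`.
#' @param dedupe collapse identical member sequences to one tip (default).
#' @return An object of class `shm_lineage` with the rooted topology, tip
#'   sequences and per-tip read multiplicities, or `NULL` if skipped.
#' @export
build_topology <- function(family, germline_seq, dedupe = TRUE) {
  members <- if (inherits(family, "clonal_family")) family$members else family
  lineage_id <- if (inherits(family, "clonal_family")) family$family_id
                else "lineage"
  germline_seq <- toupper(germline_seq)
  seqs <- toupper(members$sequence)
  if (any(nchar(seqs) != nchar(germline_seq)))
    stop("member sequences and germline must share alignment length")
  uniq <- if (dedupe) unique(seqs) else seqs
  n_distinct <- length(unique(seqs))
  if (n_distinct < 2L) return(NULL)
  tip_labels <- sprintf("u%d", seq_along(uniq))
  counts <- if (dedupe) as.integer(table(factor(seqs, levels = uniq)))
            else rep(1L, length(uniq))
  tips <- c(setNames(uniq, tip_labels), germline = germline_seq)
  k <- length(tips)
  d <- matrix(0, k, k, dimnames = list(names(tips), names(tips)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- k80_distance(tips[[i]], tips[[j]])
    }
  }
  utree <- ape::nj(as.dist(d))
  utree$edge.length <- pmax(utree$edge.length, 0)
  utree <- ape::makeNodeLabel(utree, "number", prefix = "anc")
  tree <- root_on_germline(utree)
  structure(list(lineage_id = lineage_id,
                 tree = tree,
                 utree = utree,
                 sequences = tips,
                 tip_counts = setNames(c(counts, 1L), names(tips)),
                 germline = "germline",
                 n_distinct = n_distinct,
                 kappa = estimate_kappa(tips),
                 fit = NULL),
            class = "shm_lineage")
}

as_phyDat <- function(seqs) {
  m <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  phangorn::phyDat(m, type = "DNA")
}

#' Maximum-likelihood branch lengths under K80
#'
#' Holds the neighbor-joining topology fixed and optimizes per-branch
#' lengths by maximizing the K80 pruning likelihood, with the
#' transition/transversion ratio fixed at the pooled estimate stored in the
#' lineage.
#'
#' @param lineage an `shm_lineage` from [build_topology()].
#' @return The lineage with optimized edge lengths and the likelihood fit
#'   attached.
#' @export
optimize_branch_lengths <- function(lineage) {
  pd <- as_phyDat(lineage$sequences)
  tr <- lineage$utree
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  kappa <- lineage$kappa
  fit <- suppressWarnings(
    phangorn::pml(tr, pd, bf = rep(0.25, 4),
                  Q = c(1, kappa, 1, 1, kappa, 1), k = 1))
  fit <- suppressWarnings(
    phangorn::optim.pml(fit, optEdge = TRUE, optQ = FALSE, optBf = FALSE,
                        control = phangorn::pml.control(trace = 0,
                                                        maxit = 10)))
  lineage$utree <- fit$tree
  lineage$tree <- root_on_germline(fit$tree)
  lineage$fit <- fit
  lineage$loglik <- fit$logLik
  lineage
}

# root on the germline outgroup and give the (possibly new) root node a
# deterministic label
root_on_germline <- function(utree, germline = "germline") {
  rooted <- suppressWarnings(
    ape::root(utree, outgroup = germline, resolve.root = TRUE))
  rooted$edge.length <- pmax(rooted$edge.length, 0)
  if (is.null(rooted$node.label))
    rooted$node.label <- rep("", rooted$Nnode)
  blank <- rooted$node.label == "" | is.na(rooted$node.label)
  rooted$node.label[blank] <- sprintf("root%d", seq_len(sum(blank)))
  rooted
}

#' Marginal ancestral sequence reconstruction
#'
#' Computes per-site marginal posterior probabilities of ancestral states
#' under the fitted K80 model (Felsenstein pruning) and assigns each
#' internal node the posterior-mode base. Ties (posterior within 1e-9 of
#' the maximum) are broken in favour of the parent node's assigned base,
#' else lexicographically (A < C < G < T), which avoids spurious mutation
#' events on zero-length branches.
#'
#' @param lineage an `shm_lineage` after [optimize_branch_lengths()].
#' @return The lineage with `sequences` extended to all internal nodes and
#'   the MRCA of the observed (non-germline) tips recorded in `$mrca`.
#' @export
reconstruct_ancestors <- function(lineage) {
  if (is.null(lineage$fit))
    lineage <- optimize_branch_lengths(lineage)
  fit <- lineage$fit
  anc <- phangorn::ancestral.pml(fit, type = "marginal")
  post <- extract_posteriors(anc)
  tree <- lineage$tree
  labels <- c(tree$tip.label, tree$node.label)
  n_tip <- length(tree$tip.label)
  seqs_enc <- lapply(lineage$sequences, encode_seq)
  L_aln <- length(seqs_enc[[1]])

  edges <- reorder(tree, "cladewise")$edge
  root_node <- setdiff(edges[, 1], edges[, 2])[1]
  assigned <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) assigned[[i]] <- seqs_enc[[tree$tip.label[i]]]
  # the root introduced by outgroup rooting has no data below conflict;
  # seed the downward tie-break with the germline sequence
  assigned[[root_node]] <- seqs_enc[[lineage$germline]]
  if (!is.null(post[[labels[root_node]]]))
    assigned[[root_node]] <- pick_bases(post[[labels[root_node]]],
                                        assigned[[root_node]], L_aln)
  for (r in seq_len(nrow(edges))) {
    child <- edges[r, 2]
    if (child <= n_tip) next
    lab <- labels[child]
    pp <- post[[lab]]
    if (is.null(pp))
      stop("no posterior for internal node ", lab)
    assigned[[child]] <- pick_bases(pp, assigned[[edges[r, 1]]], L_aln)
  }
  node_ids <- (n_tip + 1L):(n_tip + tree$Nnode)
  anc_seqs <- setNames(vapply(assigned[node_ids], decode_seq, character(1)),
                       labels[node_ids])
  lineage$sequences <- c(lineage$sequences[tree$tip.label], anc_seqs)
  lineage$mrca <- labels[ape::getMRCA(
    tree, setdiff(tree$tip.label, lineage$germline))]
  lineage
}

# per-node site-level posterior matrices from an ancestral.pml result
extract_posteriors <- function(anc) {
  idx <- attr(anc, "index")
  out <- lapply(anc, function(m) {
    m <- unclass(m)
    m[idx, , drop = FALSE]
  })
  names(out) <- names(anc)
  out
}

# posterior-mode base per site with parent-then-lexicographic tie-break
pick_bases <- function(pp, parent_enc, L_aln) {
  stopifnot(nrow(pp) == L_aln)
  mx <- pp[cbind(seq_len(L_aln), max.col(pp, ties.method = "first"))]
  in_set <- pp >= (mx - 1e-9)
  choice <- max.col(in_set, ties.method = "first")  # lexicographic: A<C<G<T
  use_parent <- !is.na(parent_enc) &
    in_set[cbind(seq_len(L_aln), replace(parent_enc, is.na(parent_enc), 1L))]
  choice[use_parent] <- parent_enc[use_parent]
  choice
}

#' Build, optimize and reconstruct one lineage
#'
#' Convenience wrapper: [build_topology()], [optimize_branch_lengths()],
#' [reconstruct_ancestors()].
#'
#' @inheritParams build_topology
#' @return An `shm_lineage` with ancestral sequences, or `NULL` if skipped.
#' @export
build_lineage <- function(family, germline_seq, dedupe = TRUE) {
  lin <- build_topology(family, germline_seq, dedupe = dedupe)
  if (is.null(lin)) return(NULL)
  reconstruct_ancestors(optimize_branch_lengths(lin))
}

#' Construct a branch with its mutation events
#'
#' A branch records the parent (ancestral) and child sequences, the list of
#' mutation events between them and the branch length
#' `t = (differing comparable positions) / (comparable positions)`.
#' A position x (0-based) is comparable when the parent 5-mer context
#' `x-2..x+2` is entirely A/C/G/T, the child base at x is A/C/G/T, and
#' `x < L`; other positions contribute neither events nor exposure.
#'
#' @param parent_seq,child_seq equal-length nucleotide strings.
#' @param L number of modelled positions.
#' @param lineage_id,branch_id identifiers carried through to event tables.
#' @return A list of class `shm_branch` with fields `parent_seq`,
#'   `child_seq`, `t`, `n_mut`, `n_eligible`, and `events` (data.frame with
#'   0-based `x`, `fivemer`, `from`, `to`).
#' @export
new_branch <- function(parent_seq, child_seq, L = 400L,
                       lineage_id = "lineage", branch_id = "branch") {
  pe <- encode_seq(parent_seq); ce <- encode_seq(child_seq)
  stopifnot(length(pe) == length(ce))
  ctx <- context_indices(pe)
  x0 <- seq_along(pe) - 1L
  eligible <- !is.na(ctx) & !is.na(ce) & x0 < L
  n_eligible <- sum(eligible)
  mut <- eligible & (pe != ce)
  n_mut <- sum(mut)
  t <- if (n_eligible > 0L) n_mut / n_eligible else 0
  events <- data.frame(x = x0[mut],
                       fivemer = all_fivemers()[ctx[mut]],
                       from = NUC[pe[mut]],
                       to = NUC[ce[mut]],
                       stringsAsFactors = FALSE)
  structure(list(parent_seq = toupper(parent_seq),
                 child_seq = toupper(child_seq),
                 t = t, n_mut = n_mut, n_eligible = n_eligible,
                 lineage_id = lineage_id, branch_id = branch_id,
                 events = events),
            class = "shm_branch")
}

#' Extract filtered mutation branches from a reconstructed lineage
#'
#' Returns the branches used for model inference: only branches strictly
#' below the MRCA of the observed sequences (the germline-to-MRCA branch is
#' excluded because pre-MRCA mutations may predate the frameshift), only
#' from lineages with at least `config$min_family_size` distinct observed
#' sequences, and only branches with fewer than
#' `config$max_branch_mutations` substitutions. Zero-mutation branches are
#' kept: they contribute exposure.
#'
#' @param lineage an `shm_lineage` after [reconstruct_ancestors()].
#' @param config an [shm_config()].
#' @return A list of `shm_branch` objects (possibly empty).
#' @export
extract_mutation_events <- function(lineage, config = shm_config()) {
  if (is.null(lineage) || lineage$n_distinct < config$min_family_size)
    return(list())
  tree <- lineage$tree
  labels <- c(tree$tip.label, tree$node.label)
  mrca_id <- which(labels == lineage$mrca)
  edges <- reorder(tree, "cladewise")$edge
  # mark nodes in the clade below the MRCA
  in_clade <- logical(length(labels))
  in_clade[mrca_id] <- TRUE
  keep <- logical(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    if (in_clade[edges[r, 1]]) {
      in_clade[edges[r, 2]] <- TRUE
      keep[r] <- TRUE
    }
  }
  out <- list()
  for (r in which(keep)) {
    p <- labels[edges[r, 1]]; ch <- labels[edges[r, 2]]
    br <- new_branch(lineage$sequences[[p]], lineage$sequences[[ch]],
                     L = config$L, lineage_id = lineage$lineage_id,
                     branch_id = paste0(p, "..", ch))
    if (br$n_eligible > 0L && br$n_mut < config$max_branch_mutations)
      out[[length(out) + 1L]] <- br
  }
  out
}

#' Flatten branches into one events table
#'
#' @param branches list of `shm_branch` objects.
#' @return data.frame with columns `lineage_id`, `branch_id`, `x`,
#'   `fivemer`, `from`, `to`, `t`.
#' @export
events_table <- function(branches) {
  rows <- lapply(branches, function(b) {
    if (nrow(b$events) == 0L) return(NULL)
    cbind(data.frame(lineage_id = b$lineage_id, branch_id = b$branch_id,
                     stringsAsFactors = FALSE),
          b$events, t = b$t)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lineage_id = character(), branch_id = character(),
                      x = integer(), fivemer = character(),
                      from = character(), to = character(), t = numeric())
  rownames(out) <- NULL
  out
}

#' Serialize a lineage to Newick and FASTA
#' @param lineage an `shm_lineage`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_lineage <- function(lineage, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- gsub("[^A-Za-z0-9._-]", "_", lineage$lineage_id)
  ape::write.tree(lineage$tree, file.path(dir, paste0(base, ".nwk")))
  write_fasta(lineage$sequences, file.path(dir, paste0(base, ".fasta")))
  invisible(dir)
}

#' Read a serialized lineage back
#'
#' Rebuilds an `shm_lineage` from the Newick/FASTA pair written by
#' [write_lineage()], sufficient for [extract_mutation_events()]. Tip
#' multiplicities and the likelihood fit are not serialized and are absent
#' from the result.
#'
#' @param dir directory containing `<lineage_id>.nwk` and
#'   `<lineage_id>.fasta`.
#' @param lineage_id the lineage identifier (file base name).
#' @return An `shm_lineage`.
#' @export
read_lineage <- function(dir, lineage_id) {
  base <- gsub("[^A-Za-z0-9._-]", "_", lineage_id)
  tree <- ape::read.tree(file.path(dir, paste0(base, ".nwk")))
  seqs <- read_fasta(file.path(dir, paste0(base, ".fasta")))
  obs_tips <- setdiff(tree$tip.label, "germline")
  labels <- c(tree$tip.label, tree$node.label)
  structure(list(lineage_id = lineage_id,
                 tree = tree,
                 sequences = seqs,
                 germline = "germline",
                 n_distinct = length(obs_tips),
                 mrca = labels[ape::getMRCA(tree, obs_tips)]),
            class = "shm_lineage")
}
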