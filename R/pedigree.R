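# Deterministic replicore pedigree under parity / disparity mutagenesis.
#
# Infinite-sites bookkeeping: every new base substitution hits a previously
# unmutated site, so mutation events are opaque, globally unique integer
# labels and a genotype is the set of labels inherited along the lineage.
# No back-mutation, no genome length, no selection (all mutants survive).

#' Replicate one genome semiconservatively
#'
#' Applies the replication rule of the replicore model to a single genotype.
#' Under disparity mutagenesis the leading-strand daughter is an exact copy of
#' the parent and the lagging-strand daughter gains `d` fresh mutation events;
#' under parity mutagenesis each daughter gains `d/2` fresh events (`d` must
#' be even), so the total mutational input per replication is `d` in both
#' modes.
#'
#' @param genotype integer vector of mutation-event labels carried by the
#'   parent (the root genotype is `integer(0)`).
#' @param mode `"disparity"` or `"parity"`.
#' @param d new mutation events introduced per replication (>= 1; even in
#'   parity mode).
#' @param next_event_id first unused event label; fresh labels are allocated
#'   consecutively, leading daughter before lagging daughter.
#' @return a list with elements `leading` and `lagging` (integer genotype
#'   vectors) and `next_event_id` (the updated allocator state).
#' @examples
#' replicate_node(integer(0), "disparity")          # {} and {1, 2}
#' replicate_node(integer(0), "parity")             # {1} and {2}
#' replicate_node(c(1L, 2L), "disparity", d = 2, next_event_id = 3L)
#' @export
replicate_node <- function(genotype, mode = c("disparity", "parity"), d = 2L,
                           next_event_id = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(genotype) || length(genotype) == 0L)
  stop_if_not_scalar_number(d, "d", min = 1, integer = TRUE)
  stop_if_not_scalar_number(next_event_id, "next_event_id", min = 1,
                            integer = TRUE)
  d <- as.integer(d)
  genotype <- as.integer(genotype)
  if (mode == "parity" && d %% 2L != 0L) {
    stop("parity mode splits the `d` new mutations evenly between the two ",
         "daughters, so `d` must be even (got d = ", d, ")", call. = FALSE)
  }
  nid <- as.integer(next_event_id)
  if (mode == "disparity") {
    lagging_new <- seq.int(nid, length.out = d)
    list(leading = genotype,
         lagging = c(genotype, lagging_new),
         next_event_id = nid + d)
  } else {
    half <- d %/% 2L
    leading_new <- seq.int(nid, length.out = half)
    lagging_new <- seq.int(nid + half, length.out = half)
    list(leading = c(genotype, leading_new),
         lagging = c(genotype, lagging_new),
         next_event_id = nid + d)
  }
}

#' Grow a complete replicore pedigree
#'
#' Deterministically expands a single ancestral replicore for `generations`
#' rounds of semiconservative replication, so generation `g` holds exactly
#' `2^g` genomes.  Event labels are allocated in depth-first pre-order,
#' leading daughter before lagging daughter, making the tree bit-reproducible.
#'
#' @param mode `"disparity"` (all new mutations on the lagging-strand
#'   daughter) or `"parity"` (split evenly between daughters).
#' @param d new mutation events per replication (default 2: under disparity
#'   the lagging daughter gains 2 mutations, under parity each daughter gains
#'   1).
#' @param generations number of replication rounds `g >= 0`.
#' @param max_generations node-budget guard; `2^(g+1) - 1` nodes are
#'   allocated, so the default cap of 20 bounds the tree at about two million
#'   nodes.
#' @return an object of class `replicore_pedigree`: a list with `mode`, `d`,
#'   `generations`, a `nodes` data frame (`node_id`, `parent_id`,
#'   `generation`, `strand`, `n_new`, `mutation_count`) and `new_events`, the
#'   per-node list of fresh event labels.
#' @examples
#' tr <- grow_pedigree("disparity", d = 2, generations = 3)
#' pedigree_census(tr, 3)   # mutation counts 0,2,4,6 in proportions 1:3:3:1
#' @seealso [pedigree_census()], [genotype_persistence()], [export_newick()]
#' @export
grow_pedigree <- function(mode = c("disparity", "parity"), d = 2L,
                          generations, max_generations = 20L) {
  mode <- match.arg(mode)
  stop_if_not_scalar_number(generations, "generations", min = 0,
                            integer = TRUE)
  stop_if_not_scalar_number(max_generations, "max_generations", min = 0,
                            integer = TRUE)
  g <- as.integer(generations)
  if (g > max_generations) {
    stop(sprintf(
      "generations = %d exceeds the node budget (max_generations = %d, i.e. at most %.0f nodes); raise `max_generations` explicitly if you mean it",
      g, as.integer(max_generations), 2^(max_generations + 1) - 1),
      call. = FALSE)
  }
  # validate d (and parity evenness) through the single-step rule
  replicate_node(integer(0), mode, d, 1L)
  d <- as.integer(d)

  n <- as.integer(2^(g + 1) - 1)
  parent_id <- rep(NA_integer_, n)
  generation <- integer(n)
  strand <- character(n)
  n_new <- integer(n)
  mutation_count <- integer(n)
  new_events <- vector("list", n)

  strand[1L] <- "root"
  new_events[[1L]] <- integer(0)
  next_node <- 2L
  next_event <- 1L
  stack <- integer(2L * (g + 1L))
  stack[1L] <- 1L
  top <- 1L
  while (top > 0L) {
    nd <- stack[top]
    top <- top - 1L
    if (generation[nd] == g) next
    lead <- next_node
    lag <- next_node + 1L
    next_node <- next_node + 2L
    parent_id[c(lead, lag)] <- nd
    generation[c(lead, lag)] <- generation[nd] + 1L
    strand[lead] <- "leading"
    strand[lag] <- "lagging"
    if (mode == "disparity") {
      new_events[[lead]] <- integer(0)
      new_events[[lag]] <- seq.int(next_event, length.out = d)
    } else {
      half <- d %/% 2L
      new_events[[lead]] <- seq.int(next_event, length.out = half)
      new_events[[lag]] <- seq.int(next_event + half, length.out = half)
    }
    next_event <- next_event + d
    n_new[lead] <- length(new_events[[lead]])
    n_new[lag] <- length(new_events[[lag]])
    mutation_count[c(lead, lag)] <- mutation_count[nd] + n_new[c(lead, lag)]
    # push lagging first so the leading subtree is explored (and labelled) first
    stack[top + 1L] <- lag
    stack[top + 2L] <- lead
    top <- top + 2L
  }

  structure(
    list(mode = mode, d = d, generations = g,
         nodes = data.frame(node_id = seq_len(n), parent_id = parent_id,
                            generation = generation, strand = strand,
                            n_new = n_new, mutation_count = mutation_count),
         new_events = new_events),
    class = "replicore_pedigree")
}

#' @export
print.replicore_pedigree <- function(x, ...) {
  cat(sprintf("Replicore pedigree: %s mutagenesis, d = %d, %d generation(s), %d nodes\n",
              x$mode, x$d, x$generations, nrow(x$nodes)))
  last <- x$nodes$mutation_count[x$nodes$generation == x$generations]
  cat(sprintf("  final generation: %d genomes, mutation counts %d..%d (mean %.2f)\n",
              length(last), min(last), max(last), mean(last)))
  invisible(x)
}

#' @export
summary.replicore_pedigree <- function(object, ...) {
  cen <- pedigree_census(object)
  pers <- genotype_persistence(object)
  out <- list(mode = object$mode, d = object$d,
              generations = object$generations, census = cen,
              persistent = pers$persistent)
  class(out) <- "summary.replicore_pedigree"
  out
}

#' @export
print.summary.replicore_pedigree <- function(x, ...) {
  cat(sprintf("Replicore pedigree summary (%s, d = %d, g = %d)\n",
              x$mode, x$d, x$generations))
  cat(sprintf("  every past genotype persists downstream: %s\n", x$persistent))
  print(x$census, row.names = FALSE)
  invisible(x)
}

#' Census of mutation counts per generation
#'
#' Tabulates how many genomes carry each mutation count.  Under disparity
#' mutagenesis with `d` mutations per replication, generation `g` holds
#' `choose(g, k)` genomes with `k * d` mutations (one lineage per choice of
#' which replications took the lagging copy), including exactly one
#' mutation-free genome at every generation.  Under parity every genome at
#' generation `g` carries exactly `(d/2) * g` mutations.
#'
#' @param tree a `replicore_pedigree`.
#' @param generation a single generation to tabulate, or `NULL` (default) for
#'   all generations `0..g`.
#' @return data frame with columns `generation`, `mutation_count`,
#'   `n_genomes`; within each generation the counts sum to `2^generation`.
#' @export
pedigree_census <- function(tree, generation = NULL) {
  stopifnot(inherits(tree, "replicore_pedigree"))
  gens <- if (is.null(generation)) 0:tree$generations else generation
  if (any(gens < 0) || any(gens > tree$generations)) {
    stop(sprintf("generation must be in 0..%d", tree$generations),
         call. = FALSE)
  }
  rows <- lapply(gens, function(gg) {
    mc <- tree$nodes$mutation_count[tree$nodes$generation == gg]
    tab <- table(mc)
    data.frame(generation = gg,
               mutation_count = as.integer(names(tab)),
               n_genomes = as.integer(tab))
  })
  do.call(rbind, rows)
}

# Canonical string keys of each node's genotype; parents precede daughters in
# node-id order, so one forward pass suffices.  Event ids increase along any
# root-to-leaf path, so concatenation order is already sorted.
genotype_keys <- function(tree) {
  n <- nrow(tree$nodes)
  keys <- character(n)
  parent <- tree$nodes$parent_id
  for (nd in seq_len(n)[-1L]) {
    ev <- tree$new_events[[nd]]
    keys[nd] <- if (length(ev) == 0L) keys[parent[nd]] else
      paste(c(keys[parent[nd]], ev), collapse = ",")
  }
  keys
}

#' Retrieve the genotype of a pedigree node
#'
#' @param tree a `replicore_pedigree`.
#' @param node_id node identifier (row in `tree$nodes`).
#' @return sorted integer vector of mutation-event labels.
#' @export
node_genotype <- function(tree, node_id) {
  stopifnot(inherits(tree, "replicore_pedigree"))
  stop_if_not_scalar_number(node_id, "node_id", min = 1,
                            max = nrow(tree$nodes), integer = TRUE)
  ev <- integer(0)
  nd <- as.integer(node_id)
  while (!is.na(nd)) {
    ev <- c(tree$new_events[[nd]], ev)
    nd <- tree$nodes$parent_id[nd]
  }
  sort(ev)
}

#' Do all past genotypes persist downstream?
#'
#' Checks, generation by generation, whether the set of genotypes present at
#' generation `t` is a subset of the set present at `t + 1`.  Under disparity
#' mutagenesis this holds for every `t` (each node's leading daughter is an
#' exact copy, so any genotype that ever appeared -- including the ancestral
#' mutation-free genotype -- is guaranteed at every later generation).  Under
#' parity mutagenesis every daughter mutates, so the ancestral genotype is
#' already lost after the first replication.
#'
#' @param tree a `replicore_pedigree`.
#' @return a `persistence_report`: list with `persistent` (overall logical)
#'   and `per_transition` (logical vector, one entry per generation step).
#' @export
genotype_persistence <- function(tree) {
  stopifnot(inherits(tree, "replicore_pedigree"))
  keys <- genotype_keys(tree)
  by_gen <- split(keys, tree$nodes$generation)
  g <- tree$generations
  per <- logical(max(g, 0L))
  if (g >= 1L) {
    for (t in seq_len(g)) {
      per[t] <- all(unique(by_gen[[t]]) %in% by_gen[[t + 1L]])
    }
    names(per) <- paste0(seq_len(g) - 1L, "->", seq_len(g))
  }
  structure(list(persistent = all(per), per_transition = per,
                 mode = tree$mode, generations = g),
            class = "persistence_report")
}

#' @export
print.persistence_report <- function(x, ...) {
  cat(sprintf("Genotype persistence (%s, g = %d): %s\n", x$mode,
              x$generations, if (x$persistent) "every past genotype is present at all later generations"
              else "some genotypes are lost"))
  if (length(x$per_transition) && !x$persistent) {
    lost <- names(x$per_transition)[!x$per_transition]
    cat("  first losses at transition(s): ",
        paste(utils::head(lost, 5), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Convert a replicore pedigree to an ape \code{phylo} tree
#'
#' Branch lengths are the number of new mutations on each edge (0 for leading
#' edges under disparity); tip and internal labels carry either the
#' cumulative mutation count or the per-edge new-mutation count.
#'
#' @param x a `replicore_pedigree` with at least one generation.
#' @param annotate `"mutation_count"` (cumulative, default) or
#'   `"new_mutations"` (per edge) for the node labels.
#' @param ... unused.
#' @return an object of class `phylo`.
#' @exportS3Method ape::as.phylo
as.phylo.replicore_pedigree <- function(x, annotate = c("mutation_count",
                                                        "new_mutations"),
                                        ...) {
  annotate <- match.arg(annotate)
  if (x$generations < 1L) {
    stop("a phylo object needs at least one replication (generations >= 1)",
         call. = FALSE)
  }
  nodes <- x$nodes
  is_tip <- nodes$generation == x$generations
  n_tip <- sum(is_tip)
  idx <- integer(nrow(nodes))
  idx[is_tip] <- cumsum(is_tip)[is_tip]
  idx[!is_tip] <- n_tip + cumsum(!is_tip)[!is_tip]
  val <- if (annotate == "mutation_count") nodes$mutation_count else nodes$n_new
  lab <- paste0("n", nodes$node_id, "_", val)
  phy <- list(edge = cbind(idx[nodes$parent_id[-1L]], idx[-1L]),
              edge.length = as.numeric(nodes$n_new[-1L]),
              tip.label = lab[is_tip],
              node.label = lab[!is_tip],
              Nnode = sum(!is_tip))
  class(phy) <- "phylo"
  phy
}

#' Serialize a replicore pedigree as Newick
#'
#' @inheritParams as.phylo.replicore_pedigree
#' @param tree a `replicore_pedigree`.
#' @return a single Newick string (branch lengths = new mutations per edge).
#' @examples
#' export_newick(grow_pedigree("disparity", generations = 1))
#' @export
export_newick <- function(tree, annotate = c("mutation_count",
                                             "new_mutations")) {
  stopifnot(inherits(tree, "replicore_pedigree"))
  annotate <- match.arg(annotate)
  if (tree$generations == 0L) {
    val <- if (annotate == "mutation_count") tree$nodes$mutation_count[1L] else 0L
    return(paste0("n1_", val, ";"))
  }
  ape::write.tree(as.phylo.replicore_pedigree(tree, annotate))
}
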