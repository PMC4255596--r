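test_that("single-step replication follows the strand rules", {
  r <- replicate_node(integer(0), "disparity", d = 2)
  expect_equal(r$leading, integer(0))
  expect_equal(r$lagging, c(1L, 2L))
  expect_equal(r$next_event_id, 3L)

  r <- replicate_node(integer(0), "parity", d = 2)
  expect_equal(r$leading, 1L)
  expect_equal(r$lagging, 2L)

  r <- replicate_node(c(1L, 2L), "disparity", d = 2, next_event_id = 3L)
  expect_identical(r$leading, c(1L, 2L))  # leading copy is the parent exactly
  expect_equal(r$lagging, 1:4)

  expect_error(replicate_node(integer(0), "parity", d = 3), "even")
})

test_that("grown pedigrees have the forced mutation counts", {
  tr <- grow_pedigree("disparity", d = 2, generations = 2)
  leaves <- tr$nodes$mutation_count[tr$nodes$generation == 2]
  expect_equal(sort(leaves), c(0, 2, 2, 4))

  tr <- grow_pedigree("parity", d = 2, generations = 3)
  leaves <- tr$nodes$mutation_count[tr$nodes$generation == 3]
  expect_equal(leaves, rep(3L, 8))

  tr0 <- grow_pedigree("disparity", generations = 0)
  expect_equal(nrow(tr0$nodes), 1L)
  expect_equal(tr0$nodes$mutation_count, 0L)

  expect_error(grow_pedigree("disparity", generations = 21),
               "max_generations = 20")
})

test_that("census matches exhaustive path enumeration and sums to 2^g", {
  for (mode in c("disparity", "parity")) {
    for (g in c(1L, 3L, 6L)) {
      tr <- grow_pedigree(mode, d = 2, generations = g)
      cen <- pedigree_census(tr, g)
      expect_equal(sum(cen$n_genomes), 2^g)
      oracle <- enumerate_census(mode, 2L, g)
      expect_equal(cen$mutation_count, as.integer(names(oracle)))
      expect_equal(cen$n_genomes, as.integer(oracle))
    }
  }
  tr <- grow_pedigree("disparity", d = 2, generations = 6)
  cen_all <- pedigree_census(tr)
  zero <- cen_all[cen_all$mutation_count == 0, ]
  expect_equal(zero$n_genomes, rep(1L, 7))  # one pristine genome per generation
  expect_error(pedigree_census(tr, 7), "generation")
})

test_that("disparity genotypes are distinct and binomially distributed", {
  g <- 8L
  tr <- grow_pedigree("disparity", d = 2, generations = g)
  cen <- pedigree_census(tr, g)
  expect_equal(cen$mutation_count, 2L * (0:g))
  expect_equal(cen$n_genomes, choose(g, 0:g))
  leaf_ids <- tr$nodes$node_id[tr$nodes$generation == g]
  keys <- vapply(leaf_ids, function(id) paste(node_genotype(tr, id),
                                              collapse = ","), "")
  expect_equal(length(unique(keys)), 2^g)
})

test_that("genotype persistence holds under disparity and fails under parity", {
  expect_true(genotype_persistence(grow_pedigree("disparity",
                                                 generations = 5))$persistent)
  expect_true(genotype_persistence(grow_pedigree("disparity",
                                                 generations = 1))$persistent)
  rep2 <- genotype_persistence(grow_pedigree("parity", generations = 2))
  expect_false(rep2$persistent)
  expect_false(rep2$per_transition[["0->1"]])  # the ancestor is lost at once
})

test_that("mutation counts never decrease along any lineage", {
  for (mode in c("disparity", "parity")) {
    tr <- grow_pedigree(mode, d = 4, generations = 5)
    kids <- tr$nodes$node_id[-1]
    expect_true(all(tr$nodes$mutation_count[kids] >=
                      tr$nodes$mutation_count[tr$nodes$parent_id[kids]]))
  }
})

test_that("pedigree growth is deterministic", {
  a <- grow_pedigree("disparity", d = 2, generations = 6)
  b <- grow_pedigree("disparity", d = 2, generations = 6)
  expect_identical(a, b)
})

test_that("Newick export carries new-mutation branch lengths and round-trips", {
  nw <- export_newick(grow_pedigree("disparity", generations = 1))
  phy <- ape::read.tree(text = nw)
  expect_equal(sort(phy$edge.length), c(0, 2))

  nw <- export_newick(grow_pedigree("parity", generations = 1))
  expect_equal(ape::read.tree(text = nw)$edge.length, c(1, 1))

  tr <- grow_pedigree("disparity", d = 2, generations = 4)
  phy <- ape::as.phylo(tr)
  reread <- ape::read.tree(text = export_newick(tr))
  expect_true(ape::all.equal.phylo(phy, reread, use.edge.length = TRUE))
  # labels carry the cumulative mutation count
  counts <- as.integer(sub("^n\\d+_", "", phy$tip.label))
  cen <- pedigree_census(tr, 4)
  expect_equal(sort(counts), rep(cen$mutation_count, cen$n_genomes))
})
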