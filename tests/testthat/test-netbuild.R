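mk_inter <- function(from, to, score = 0.9) {
  data.frame(source_id = from, target_id = to,
             score = rep_len(score, length(from)),
             origin = rep_len("t", length(from)),
             stringsAsFactors = FALSE)
}
mk_comp <- function(herb, comp) {
  data.frame(herb_id = herb, compound_id = comp, compound_name = comp,
             stringsAsFactors = FALSE)
}

test_that("compound-target network is bipartite over evidenced compounds", {
  comp <- mk_comp("H1", c("C1", "C2", "C3"))
  inter <- mk_inter(c("C1", "C1", "C2"), c("T1", "T2", "T1"))
  net <- suppressMessages(build_compound_target_network(comp, inter))
  expect_equal(igraph::vcount(net), 4)  # C3 excluded: no interaction
  expect_equal(igraph::ecount(net), 3)
  roles <- node_roles(net)
  expect_equal(sum(roles == "COMPOUND"), 2)
  expect_equal(sum(roles == "COMPOUND_TARGET"), 2)

  single <- suppressMessages(build_compound_target_network(
    mk_comp("H1", "C1"), mk_inter("C1", "T1")))
  expect_equal(igraph::vcount(single), 2)
  expect_equal(igraph::ecount(single), 1)

  shared <- suppressMessages(build_compound_target_network(
    mk_comp("H1", c("C1", "C2")), mk_inter(c("C1", "C2"), c("T1", "T1"))))
  expect_equal(igraph::vcount(shared), 3)
  expect_equal(igraph::ecount(shared), 2)

  expect_error(build_compound_target_network(comp, mk_inter("X9", "T1")),
               "empty network")
})

test_that("herb-target-disease network collapses compounds and keeps only
           PPI-linked disease targets", {
  comp <- mk_comp(c("H1", "H1", "H2"), c("C1", "C2", "C3"))
  inter <- mk_inter(c("C1", "C2", "C3"), c("T1", "T2", "T2"))
  disease <- list(disease_label = "d", target_ids = c("D1", "D2", "T2"))
  ppi <- mk_inter(c("T1", "D2"), c("D1", "P5"))   # D1 linked, D2 not
  net <- suppressMessages(
    build_herb_target_disease_network(comp, inter, disease, ppi))
  roles <- node_roles(net)
  expect_setequal(names(roles), c("H1", "H2", "T1", "T2", "D1"))
  expect_equal(unname(roles[c("T1", "T2", "D1")]),
               c("COMPOUND_TARGET", "SHARED_TARGET", "DISEASE_TARGET"))
  # H1 reaches T1, T2; H2 reaches T2; plus T1-D1
  expect_equal(igraph::ecount(net), 4)

  nolink <- suppressMessages(build_herb_target_disease_network(
    mk_comp("H1", "C1"), mk_inter("C1", "T1"),
    list(disease_label = "d", target_ids = "D1"),
    mk_inter(character(0), character(0))))
  expect_equal(igraph::vcount(nolink), 2)
  expect_equal(igraph::ecount(nolink), 1)
})

test_that("PPI expansion adds exactly the first neighbors of the seed set", {
  dis <- list(disease_label = "d", target_ids = character(0))
  net <- suppressMessages(build_ppi_expansion_network(
    "A", dis, mk_inter("A", "B")))
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(igraph::ecount(net), 1)

  net2 <- suppressMessages(build_ppi_expansion_network(
    "A", dis, mk_inter(c("A", "B"), c("B", "C"))))
  expect_setequal(igraph::V(net2)$name, c("A", "B"))  # C is 2 hops away
  expect_equal(igraph::ecount(net2), 1)

  expect_error(build_ppi_expansion_network(character(0), dis,
                                           mk_inter("A", "B")),
               "empty seed")
})

test_that("induced edge rule keeps neighbor-neighbor edges, star rule drops
           them", {
  ppi <- mk_inter(c("S", "S", "X"), c("X", "Y", "Y"))
  dis <- list(disease_label = "d", target_ids = character(0))
  ind <- suppressMessages(build_ppi_expansion_network("S", dis, ppi,
                                                      edges = "induced"))
  star <- suppressMessages(build_ppi_expansion_network("S", dis, ppi,
                                                       edges = "star"))
  expect_equal(igraph::ecount(ind), 3)
  expect_equal(igraph::ecount(star), 2)
  expect_setequal(igraph::V(star)$name, igraph::V(ind)$name)
})

test_that("expansion role partition is exhaustive, exclusive, and sums to the
           node count", {
  b <- paper_bundle()
  d <- paper_fixture_dir()
  compounds <- suppressMessages(read_compound_table(file.path(d, "compounds.tsv")))
  cti <- suppressMessages(read_interaction_table(
    file.path(d, "compound_interactions.tsv")))
  dis <- suppressMessages(read_disease_targets(file.path(d, "disease_targets.tsv")))
  ppi <- suppressMessages(merge_ppi_sources(lapply(
    file.path(d, c("ppi_source_a.tsv", "ppi_source_b.tsv")),
    function(p) suppressMessages(read_interaction_table(p)))))
  net <- suppressMessages(build_ppi_expansion_network(
    compound_target_ids(compounds, cti), dis, ppi))
  roles <- node_roles(net)
  expect_true(all(roles %in% pharmnet:::NODE_ROLES))
  expect_equal(sum(role_tally(net)), igraph::vcount(net))
  shared <- names(roles)[roles == "SHARED_TARGET"]
  expect_setequal(shared, intersect(compound_target_ids(compounds, cti),
                                    dis$target_ids))
})

test_that("expansion network is monotone in the seed set", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    ids <- sprintf("P%02d", 1:n)
    m <- 60
    ppi <- mk_inter(sample(ids, m, replace = TRUE),
                    sample(ids, m, replace = TRUE))
    ppi <- ppi[ppi$source_id != ppi$target_id, ]
    dis <- list(disease_label = "d", target_ids = character(0))
    seeds <- sample(ids, 3)
    extra <- sample(setdiff(ids, seeds), 2)
    small <- suppressMessages(build_ppi_expansion_network(seeds, dis, ppi))
    big <- suppressMessages(build_ppi_expansion_network(c(seeds, extra), dis,
                                                        ppi))
    expect_true(all(igraph::V(small)$name %in% igraph::V(big)$name))
  }
})

test_that("induced subnetwork restricts nodes and optionally drops isolates", {
  tri <- edge_net(c("a", "b", "b", "c", "c", "a"))
  sub <- induced_subnetwork(tri, c("a", "b"))
  expect_equal(igraph::vcount(sub), 2)
  expect_equal(igraph::ecount(sub), 1)

  same <- induced_subnetwork(tri, c("a", "b", "c"))
  expect_equal(igraph::vcount(same), 3)
  expect_equal(igraph::ecount(same), 3)

  path <- edge_net(c("a", "b"), isolated = "z")
  kept <- induced_subnetwork(path, c("a", "b", "z"), drop_isolated = FALSE)
  expect_equal(igraph::vcount(kept), 3)
  dropped <- suppressMessages(
    induced_subnetwork(path, c("a", "b", "z"), drop_isolated = TRUE))
  expect_setequal(igraph::V(dropped)$name, c("a", "b"))

  expect_error(induced_subnetwork(tri, character(0)), "empty keep")
  expect_error(induced_subnetwork(tri, c("a", "q")), "absent")
})

test_that("GraphML round trip preserves nodes, edges, and roles", {
  net <- edge_net(c("a", "b", "b", "c"),
                  roles = c(a = "HERB", b = "COMPOUND_TARGET",
                            c = "OTHER_PROTEIN"))
  f <- tempfile(fileext = ".graphml")
  write_network_graphml(net, f)
  back <- read_network_graphml(f)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  rb <- node_roles(back)
  expect_equal(rb[igraph::V(net)$name], node_roles(net))
})

test_that("SIF export writes one edge per line plus isolated nodes", {
  net <- edge_net(c("a", "b"), isolated = "z")
  f <- tempfile(fileext = ".sif")
  write_network_sif(net, f)
  lines <- readLines(f)
  expect_setequal(lines, c("a\tpp\tb", "z"))
})
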