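test_that("catalyst-product graph has one edge per catalyst-product pair", {
  # s1 = ABA catalyzes a cleavage of AAB into A + AB: edges ABA->A, ABA->AB
  chem <- chemistry(c("A", "B"), 4, 2,
                    reactions = cleavage_reaction("AAB", 1,
                                                  catalysts = "ABA"))
  g <- catalyst_product_graph(chem)
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]), c("ABA A", "ABA AB"))

  # no catalysis: edgeless graph
  g0 <- catalyst_product_graph(
    chemistry(c("A", "B"), 4, 2,
              reactions = cleavage_reaction("AAB", 1)))
  expect_equal(igraph::ecount(g0), 0)
})

test_that("catalyst-product edges match a brute-force triple scan", {
  for (seed in c(2, 9, 23)) {
    chem <- random_chemistry(p = 0.3, seed = seed)
    g <- catalyst_product_graph(chem)
    el <- igraph::as_edgelist(g)
    got <- sort(unique(paste(el[, 1], el[, 2])))
    rx <- chem$reactions
    want <- character()
    for (i in seq_len(nrow(rx))) {
      for (cat in rx$catalysts[[i]]) {
        for (p in na.omit(c(rx$prod1[i], rx$prod2[i]))) {
          want <- c(want, paste(cat, p))
        }
      }
    }
    expect_setequal(got, sort(unique(want)))
  }
})

test_that("nontrivial SCC detection agrees with the transitive-closure oracle", {
  # 3-cycle
  g <- igraph::graph_from_literal(a -+ b, b -+ c, c -+ a)
  expect_equal(find_sccs(g), list(c("a", "b", "c")))
  # DAG without self-loops
  g2 <- igraph::graph_from_literal(a -+ b, b -+ c, a -+ c)
  expect_equal(length(find_sccs(g2)), 0)
  # self-loop singleton counts as nontrivial
  g3 <- igraph::make_graph(c("a", "a", "a", "b"), directed = TRUE)
  expect_equal(find_sccs(g3), list("a"))

  for (seed in 1:200) {
    adj <- random_digraph(seed)
    got <- lapply(find_sccs(adj_to_igraph(adj)),
                  function(s) sort(as.integer(s)))
    got <- got[order(vapply(got, min, integer(1)))]
    expect_identical(got, oracle_sccs(adj))
  }
})

test_that("food closure is the least fixed point of substrate generation", {
  chem <- chemistry(c("A", "B"), 4, 2,
                    species = tibble::tibble(sequence = c("A", "B"),
                                             is_food = TRUE,
                                             external_conc = 1),
                    reactions = condensation_reaction("A", "B"))
  expect_setequal(food_closure(chem), c("A", "B", "AB"))
  expect_setequal(food_closure(chem, reaction_ids = integer()), c("A", "B"))

  # a chain with an unproducible intermediate stalls, as the oracle says
  rx <- dplyr::bind_rows(
    condensation_reaction("A", "B"),     # AB
    condensation_reaction("AB", "BA"),   # ABBA, but BA never producible
    condensation_reaction("ABBA", "B")   # unreachable
  )
  chem2 <- chemistry(c("A", "B"), 5, 2,
                     species = tibble::tibble(sequence = c("A", "B"),
                                              is_food = TRUE,
                                              external_conc = 1),
                     reactions = rx)
  expect_setequal(food_closure(chem2),
                  oracle_closure(oracle_parts(chem2), 1:3, c("A", "B")))
  expect_false("ABBA" %in% food_closure(chem2))
})

test_that("max RAF matches subset-enumeration oracle on random chemistries", {
  # a self-catalytic condensation from food is its own RAF
  chem <- chemistry(c("A", "B"), 3, 3,
                    species = tibble::tibble(
                      sequence = c("A", "AB"), is_food = TRUE,
                      external_conc = 1),
                    reactions = condensation_reaction("A", "AB",
                                                      catalysts = "AAB"))
  expect_equal(max_raf(chem), 1L)
  expect_equal(oracle_max_raf(chem), 1L)

  # catalyst neither food nor producible: empty RAF
  chem2 <- chemistry(c("A", "B"), 4, 3,
                     species = tibble::tibble(
                       sequence = c("A", "AB"), is_food = TRUE,
                       external_conc = 1),
                     reactions = condensation_reaction("A", "AB",
                                                       catalysts = "BBB"))
  expect_length(max_raf(chem2), 0)

  for (seed in 1:60) {
    chem <- random_small_chem(seed)
    expect_equal(sort(max_raf(chem)), oracle_max_raf(chem))
  }
})

test_that("max RAF reduction is idempotent and monotone in catalysis", {
  for (seed in c(4, 17, 31)) {
    chem <- random_small_chem(seed)
    mr <- max_raf(chem)
    if (length(mr) > 0) {
      sub <- chem
      sub$reactions <- sub$reactions[match(mr, sub$reactions$id), ]
      expect_setequal(max_raf(sub), mr)
      expect_true(is_raf(chem, mr))
    }
    # adding one catalysis assignment never shrinks the max RAF
    chem2 <- chem
    i <- ((seed * 7) %% nrow(chem2$reactions)) + 1
    chem2$reactions$catalysts[[i]] <-
      union(chem2$reactions$catalysts[[i]], "AAB")
    expect_true(all(mr %in% max_raf(chem2)))
  }
})

test_that("irrRAF cores match the brute-force minimal RAF subsets", {
  for (seed in 1:40) {
    chem <- random_small_chem(seed)
    got <- attr(find_irr_rafs(chem), "cores")
    want <- oracle_min_rafs(chem)
    expect_equal(length(got), length(want))
    key <- function(l) sort(vapply(l, paste, "", collapse = ","))
    expect_identical(key(got), key(want))
  }
})

test_that("fixture RAF topologies are detected as designed", {
  # fig3: one irrRAF containing both SCCs of the catalyst-product graph
  fx3 <- make_fixture("fig3_coupled_scc")
  raf3 <- find_raf(fx3$chem)
  expect_length(raf3$irr_rafs, 1)
  expect_length(raf3$sccs, 2)
  irr_species <- reaction_species(
    fx3$chem$reactions[match(raf3$irr_rafs[[1]], fx3$chem$reactions$id), ])
  for (scc in raf3$sccs) expect_true(all(scc %in% irr_species))

  # fig4: two disjoint irrRAFs
  raf4 <- find_raf(make_fixture("fig4_two_irrrafs")$chem)
  expect_length(raf4$irr_rafs, 2)
  expect_length(intersect(raf4$irr_rafs[[1]], raf4$irr_rafs[[2]]), 0)

  # a single-reaction max RAF yields that singleton as its only irrRAF
  chem <- chemistry(c("A", "B"), 3, 3,
                    species = tibble::tibble(
                      sequence = c("A", "AB"), is_food = TRUE,
                      external_conc = 1),
                    reactions = condensation_reaction("A", "AB",
                                                      catalysts = "AAB"))
  expect_equal(find_irr_rafs(chem)[[1]], 1L)
})

test_that("species labels distinguish food, RAF members and bystanders", {
  fx <- make_fixture("fig3_coupled_scc")
  lab <- classify_species(fx$chem)
  get <- function(s) lab$label[lab$sequence == s]
  expect_equal(get("A"), "food")
  expect_equal(get("AAB"), "RAF-member")
  # produced by no reaction: diluted bystander
  expect_equal(get("BBB"), "non-RAF")
  expect_equal(get("BBBB"), "non-RAF")
})

test_that("graph export writes readable DOT and GraphML", {
  fx <- make_fixture("fig4_two_irrrafs")
  g <- catalyst_product_graph(fx$chem)
  dot <- withr::local_tempfile(fileext = ".dot")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, dot)
  export_graph(g, gml)
  expect_true(any(grepl("digraph", readLines(dot))))
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})
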