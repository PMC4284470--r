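test_that("enumerate_reactions covers all cleavages and bounded condensations", {
  rx <- enumerate_reactions("AAAB", l_max = 4)
  expect_true(any(rx$kind == "cleavage" & rx$prod1 == "A" &
                    rx$prod2 == "AAB"))
  expect_equal(sum(rx$kind == "cleavage"), 3) # one per cut position

  rx <- enumerate_reactions(c("ABA", "BA"), l_max = 5)
  expect_true(any(rx$kind == "condensation" & rx$sub1 == "ABA" &
                    rx$sub2 == "BA" & rx$prod1 == "ABABA"))

  # complete length-<=2 universe over {A,B}: 4 cleavages + 4 condensations
  univ <- all_strings(c("A", "B"), 2)
  rx <- enumerate_reactions(univ, l_max = 2)
  expect_equal(nrow(rx), 8)
  expect_equal(sum(rx$kind == "cleavage"), 4)
  expect_equal(sum(rx$kind == "condensation"), 4)

  expect_error(enumerate_reactions("AXB", l_max = 3, alphabet = c("A", "B")),
               "outside the alphabet")
})

test_that("cleavage counts match the closed-form sum over the string universe", {
  # cleavages over all strings of length <= L on a letters:
  # sum_{l=2..L} a^l (l-1), checked against brute-force enumeration
  for (a in 2:3) {
    for (L in 2:4) {
      univ <- all_strings(LETTERS[seq_len(a)], L)
      rx <- enumerate_reactions(univ, l_max = 1) # no condensations fit
      expect_equal(sum(rx$kind == "cleavage"),
                   sum(a^(2:L) * ((2:L) - 1)))
    }
  }
})

test_that("catalysis assignment follows the per-species Kauffman scheme", {
  univ <- all_strings(c("A", "B"), 3)
  chem <- chemistry(c("A", "B"), l_max = 4, l_perm = 3,
                    species = tibble::tibble(sequence = univ),
                    reactions = enumerate_reactions(univ, 4))
  expect_equal(sum(lengths(assign_catalysis(chem, 0)$reactions$catalysts)), 0)

  # p = 1, per-species scheme: exactly one assignment per eligible species
  # (condensation products added to the species table are eligible too)
  n_elig <- sum(nchar(chem$species$sequence) >= 3)
  full <- assign_catalysis(chem, 1, seed = 5)
  expect_equal(sum(lengths(full$reactions$catalysts)), n_elig)

  # same seed => identical catalysis map
  again <- assign_catalysis(chem, 0.4, seed = 99)
  expect_identical(assign_catalysis(chem, 0.4, seed = 99)$reactions$catalysts,
                   again$reactions$catalysts)

  # assignment counts are Binomial(n_elig, p): mean within 3 SE
  p <- 0.5; n_seeds <- 400
  counts <- vapply(seq_len(n_seeds), function(s)
    sum(lengths(assign_catalysis(chem, p, seed = s)$reactions$catalysts)),
    numeric(1))
  se <- sqrt(n_elig * p * (1 - p) / n_seeds)
  expect_lt(abs(mean(counts) - n_elig * p), 3 * se)

  # no eligible species: warning, empty map
  small <- chemistry(c("A", "B"), 2, 2,
                     species = tibble::tibble(sequence = c("A", "B", "AB")),
                     reactions = enumerate_reactions(c("A", "B"), 2))
  expect_warning(out <- assign_catalysis(small, 0.5, seed = 1),
                 "no species")
  expect_equal(sum(lengths(out$reactions$catalysts)), 0)
})

test_that("container coupling is Bernoulli per non-food species", {
  univ <- all_strings(c("A", "B"), 3)
  chem <- chemistry(c("A", "B"), 4, 2,
                    species = tibble::tibble(
                      sequence = univ, is_food = nchar(univ) < 2,
                      external_conc = ifelse(nchar(univ) < 2, 1, 0)))
  expect_equal(sum(assign_container_coupling(chem, 0, 1)$species$k_cont > 0)
               , 0)
  all_on <- assign_container_coupling(chem, 1, 0.5, seed = 1)
  expect_true(all(all_on$species$k_cont[!all_on$species$is_food] == 0.5))
  expect_true(all(all_on$species$k_cont[all_on$species$is_food] == 0))

  n_nonfood <- sum(!chem$species$is_food)
  p <- 0.1; n_seeds <- 400
  counts <- vapply(seq_len(n_seeds), function(s)
    sum(assign_container_coupling(chem, p, 1, seed = s)$species$k_cont > 0),
    numeric(1))
  se <- sqrt(n_nonfood * p * (1 - p) / n_seeds)
  expect_lt(abs(mean(counts) - n_nonfood * p), 3 * se)
})

test_that("validate_chemistry reports structural violations", {
  # hand-broken cleavage AB -> A + A (mass balance) via direct table edit
  bad <- cleavage_reaction("AB", 1)
  bad$prod2 <- "A"
  chem <- chemistry(c("A", "B"), 3, 2,
                    species = tibble::tibble(sequence = c("A", "B", "AB")),
                    reactions = bad)
  rep <- validate_chemistry(chem)
  expect_true("mass_balance" %in% rep$check)

  # catalyst of length 2 is ineligible
  chem2 <- chemistry(c("A", "B"), 4, 2,
                     reactions = condensation_reaction("A", "B",
                                                       catalysts = "BA"))
  expect_true("catalyst_length" %in% validate_chemistry(chem2)$check)

  # entrapped or unbuffered food is flagged
  chem3 <- chemistry(c("A", "B"), 4, 2,
                     species = tibble::tibble(sequence = "AB",
                                              is_food = TRUE,
                                              external_conc = 0))
  expect_setequal(validate_chemistry(chem3)$check,
                  c("food_permeability", "food_concentration"))

  # the fixtures themselves are valid
  for (nm in c("fig3_coupled_scc", "fig4_two_irrrafs", "fig9_permeable")) {
    expect_equal(nrow(validate_chemistry(make_fixture(nm)$chem)), 0)
  }
})

test_that("chemistry JSON serialization round-trips exactly", {
  fx <- make_fixture("fig3_coupled_scc")
  path <- withr::local_tempfile(fileext = ".json")
  write_chemistry(fx$chem, path)
  back <- read_chemistry(path)
  expect_equal(back$species, fx$chem$species)
  expect_equal(back$reactions, fx$chem$reactions)
  expect_identical(back$alphabet, fx$chem$alphabet)
  expect_equal(unclass(back$kinetics), unclass(fx$chem$kinetics))

  rnd <- random_chemistry(p = 0.1, p_cont = 0.2, seed = 3)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_chemistry(rnd, path2)
  back2 <- read_chemistry(path2)
  expect_equal(back2$species, rnd$species)
  expect_equal(back2$reactions, rnd$reactions)
})

test_that("TSV reaction import builds well-formed reactions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kind\tsub1\tsub2\tcut_pos\tcatalysts",
               "condensation\tA\tAB\t\tABA,AAB",
               "cleavage\tAAB\t\t1\tABA"), path)
  rx <- read_reactions_tsv(path)
  expect_equal(rx$kind, c("condensation", "cleavage"))
  expect_equal(rx$prod1, c("AAB", "A"))
  expect_equal(rx$prod2, c(NA_character_, "AB"))
  expect_equal(rx$catalysts[[1]], c("ABA", "AAB"))
})

test_that("permeability uses the strict length < l_perm rule", {
  fx <- make_fixture("fig4_two_irrrafs") # l_perm = 3
  perm <- is_permeable(fx$chem)
  expect_true(all(perm[c("A", "B", "AB", "BA")]))
  expect_false(any(perm[c("AAB", "ABA", "BBA", "BAB")]))
})
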