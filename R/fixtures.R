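#' Reference fixture chemistries
#'
#' Hand-built chemistries with known RAF topology, each bundled with a
#' container geometry and initial copy numbers so that every simulation
#' scenario is reproducible without external data. Reactions are listed
#' explicitly (not drawn at random) so the RAF structure is exact:
#'
#' * `"fig3_coupled_scc"` -- a single heterogeneous irreducible RAF made of
#'   two distinct strongly connected components of the catalyst-product
#'   graph, mutually dependent through substrates: SCC-1 (`AAB`, `ABA`)
#'   produces the substrate `BAB` needed by SCC-2 (`BABB`, `ABAB`), while
#'   SCC-2 catalyzes the production of `AB`, a substrate SCC-1 needs; only
#'   SCC-2 is coupled to container growth. Two inert tracer species
#'   (`BBB`, `BBBB`), neither produced nor consumed, start at low copy
#'   numbers and undergo dilution.
#' * `"fig4_two_irrrafs"` -- two reaction-disjoint irreducible RAFs with
#'   distinct rate constants; the fast one (`AAB`/`ABA`, fed by foods `A`
#'   and `AB`) is container-coupled, the slow one (`BBA`/`BAB`, fed by `B`
#'   and `BA`) is not, so the slow one dilutes toward stochastic
#'   extinction.
#' * `"fig9_permeable"` -- the same two-irrRAF topology with equal rate
#'   constants, both coupled, and finite membrane diffusion coefficients on
#'   all permeable species, for Fick-transport simulations of novelty
#'   uptake (inject the second irrRAF at low copy number into a running
#'   lineage).
#' * `"random_kauffman"` -- a random chemistry over the full string
#'   universe, see [random_chemistry()].
#'
#' @param name fixture name.
#' @param seed integer seed (used by `"random_kauffman"` only).
#' @param food_conc buffered external concentration of the food species.
#' @param k_cont lipid production rate of container-coupled species.
#' @param slow_factor rate-constant ratio slow/fast of the second irrRAF
#'   (`"fig4_two_irrrafs"`).
#' @param diffusion_D membrane transport coefficient of permeable species
#'   (`"fig9_permeable"`).
#' @param geometry a [container_geometry()]; the default divides at
#'   `theta = 20000` lipids with `delta = 0.1`, `rho = 100` (close to the
#'   thin-membrane regime: daughter/mother volume ratio about 0.35) and
#'   batches lipid growth by `g = 2` so that about 5000 growth events occur
#'   per generation.
#' @param ... passed to [random_chemistry()] for `"random_kauffman"`.
#' @return an object of class `protocell_fixture`: a list with `chem`,
#'   `geometry`, `init_counts`, `mode` (suggested transport mode).
#' @export
make_fixture <- function(name = c("fig3_coupled_scc", "fig4_two_irrrafs",
                                  "fig9_permeable", "random_kauffman"),
                         seed = 1L,
                         food_conc = 2,
                         k_cont = 0.3,
                         slow_factor = 0.55,
                         diffusion_D = 0.15,
                         geometry = container_geometry(delta = 0.1,
                                                       rho = 100,
                                                       theta = 20000,
                                                       g = 2L),
                         ...) {
  name <- match.arg(name)
  switch(
    name,
    fig3_coupled_scc = fixture_fig3(food_conc, k_cont, geometry),
    fig4_two_irrrafs = fixture_fig4(food_conc, k_cont, slow_factor,
                                    geometry),
    fig9_permeable = fixture_fig9(food_conc, k_cont, diffusion_D,
                                  geometry),
    random_kauffman = {
      chem <- random_chemistry(seed = seed, ...)
      structure(list(chem = chem, geometry = geometry,
                     init_counts = integer(), mode = "instantaneous"),
                class = "protocell_fixture")
    }
  )
}

fixture_fig3 <- function(food_conc, k_cont, geometry) {
  rx <- dplyr::bind_rows(
    condensation_reaction("A", "B", catalysts = "BABB"),   # feeds SCC-1
    condensation_reaction("A", "AB", catalysts = "ABA"),   # SCC-1
    condensation_reaction("AB", "A", catalysts = "AAB"),   # SCC-1
    condensation_reaction("B", "AB", catalysts = "AAB"),   # SCC-1 -> BAB
    condensation_reaction("BAB", "B", catalysts = "ABAB"), # SCC-2
    condensation_reaction("A", "BAB", catalysts = "BABB")  # SCC-2
  )
  chem <- chemistry(
    alphabet = c("A", "B"), l_max = 4, l_perm = 2,
    species = tibble(
      sequence = c("A", "B", "BBB", "BBBB"),
      is_food = c(TRUE, TRUE, FALSE, FALSE),
      external_conc = c(food_conc, food_conc, 0, 0)
    ),
    reactions = rx
  )
  chem <- set_species(chem, c("BABB", "ABAB"), k_cont = k_cont)
  structure(
    list(chem = chem, geometry = geometry,
         init_counts = c(AAB = 30, ABA = 30, AB = 30, BAB = 10,
                         BABB = 30, ABAB = 30, BBB = 16, BBBB = 8),
         mode = "instantaneous"),
    class = "protocell_fixture"
  )
}

fig4_reactions <- function(fast = list(), slow = list()) {
  dplyr::bind_rows(
    condensation_reaction("A", "AB", catalysts = "ABA",
                          k_assoc = fast$k_assoc %||% NA_real_,
                          k_cond = fast$k_cond %||% NA_real_),
    condensation_reaction("AB", "A", catalysts = "AAB",
                          k_assoc = fast$k_assoc %||% NA_real_,
                          k_cond = fast$k_cond %||% NA_real_),
    condensation_reaction("B", "BA", catalysts = "BAB",
                          k_assoc = slow$k_assoc %||% NA_real_,
                          k_cond = slow$k_cond %||% NA_real_),
    condensation_reaction("BA", "B", catalysts = "BBA",
                          k_assoc = slow$k_assoc %||% NA_real_,
                          k_cond = slow$k_cond %||% NA_real_)
  )
}

fixture_fig4 <- function(food_conc, k_cont, slow_factor, geometry) {
  kd <- kinetic_params()
  rx <- fig4_reactions(
    slow = list(k_assoc = kd$k_assoc * slow_factor,
                k_cond = kd$k_cond * slow_factor)
  )
  chem <- chemistry(
    alphabet = c("A", "B"), l_max = 3, l_perm = 3,
    species = tibble(
      sequence = c("A", "B", "AB", "BA"),
      is_food = TRUE,
      external_conc = food_conc
    ),
    reactions = rx
  )
  chem <- set_species(chem, c("AAB", "ABA"), k_cont = k_cont)
  structure(
    list(chem = chem, geometry = geometry,
         init_counts = c(AAB = 30, ABA = 30, BBA = 300, BAB = 300),
         mode = "instantaneous"),
    class = "protocell_fixture"
  )
}

fixture_fig9 <- function(food_conc, k_cont, diffusion_D, geometry) {
  chem <- chemistry(
    alphabet = c("A", "B"), l_max = 3, l_perm = 3,
    species = tibble(
      sequence = c("A", "B", "AB", "BA"),
      is_food = TRUE,
      external_conc = food_conc
    ),
    reactions = fig4_reactions()
  )
  chem <- set_species(chem, c("A", "B", "AB", "BA"),
                      diffusion_D = diffusion_D)
  chem <- set_species(chem, c("AAB", "ABA", "BBA", "BAB"),
                      k_cont = k_cont)
  structure(
    list(chem = chem, geometry = geometry,
         init_counts = c(AAB = 30, ABA = 30),
         mode = "fick"),
    class = "protocell_fixture"
  )
}

#' @export
print.protocell_fixture <- function(x, ...) {
  cat("<protocell_fixture> mode =", x$mode, "\n")
  print(x$chem)
  invisible(x)
}
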