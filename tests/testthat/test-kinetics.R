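# small closed chemistry (l_perm = 1: nothing permeates, nothing buffered)
closed_chem <- function() {
  chemistry(
    c("A", "B"), l_max = 3, l_perm = 1,
    reactions = dplyr::bind_rows(
      condensation_reaction("A", "B", catalysts = "AAB"),
      cleavage_reaction("AAB", 1, catalysts = "AAB")
    )
  )
}

test_that("channel expansion follows the complex reaction scheme", {
  chem <- chemistry(
    c("A", "B"), l_max = 4, l_perm = 2,
    species = tibble::tibble(sequence = c("A", "B"), is_food = TRUE,
                             external_conc = 1),
    reactions = dplyr::bind_rows(
      cleavage_reaction("ABAB", 2, catalysts = "AAB"),
      condensation_reaction("A", "B", catalysts = "AAB")
    )
  )
  cs <- build_channels(chem, "instantaneous")
  # 1 cleavage + 3 condensation steps + 1 lipid growth
  expect_equal(nrow(cs$channels), 5)
  expect_setequal(cs$channels$kind,
                  c("cleavage", "complex_assoc", "complex_diss",
                    "final_cond", "lipid_growth"))
  # the complex pseudo-species exists, is tracked, never buffered
  expect_true("A:AAB" %in% cs$species$name)
  expect_false(cs$species$buffered[cs$species$name == "A:AAB"])

  # fick mode adds one in + one out channel per permeable species
  csf <- build_channels(chem, "fick")
  n_perm <- sum(chem$species$length < chem$l_perm)
  expect_equal(nrow(csf$channels), 5 + 2 * n_perm)
  expect_false(any(csf$species$buffered))

  # uncatalyzed reactions yield no channels (no spontaneous reactions)
  bare <- chemistry(c("A", "B"), 4, 2,
                    reactions = cleavage_reaction("ABAB", 2))
  expect_equal(build_channels(bare, "instantaneous")$channels$kind,
               "lipid_growth")
})

test_that("propensities follow mass action with volume scaling", {
  fx <- make_fixture("fig3_coupled_scc")
  st <- protocell_state(fx$chem, fx$geometry, fx$init_counts)
  a <- channel_propensities(st)
  cs <- st$channel_set
  V <- internal_volume(st$C, fx$geometry$delta, fx$geometry$rho)

  # hand-check one bimolecular channel: assoc of AB with catalyst AAB
  j <- which(cs$channels$kind == "complex_assoc" & cs$channels$r1 == "AB" &
               cs$channels$r2 == "AAB")
  expect_equal(a[j], fx$chem$kinetics$k_assoc * 30 * 30 / V)

  # buffered participant contributes ext_conc * V: A + ABA association
  j2 <- which(cs$channels$kind == "complex_assoc" & cs$channels$r1 == "A" &
                cs$channels$r2 == "ABA")
  expect_equal(a[j2], fx$chem$kinetics$k_assoc * 2 * 30)

  # zero-count participant: zero propensity
  st0 <- protocell_state(fx$chem, fx$geometry, c(AAB = 5))
  a0 <- channel_propensities(st0)
  expect_equal(a0[j], 0) # AB count is zero

  # lipid growth: sum(k_cont * x) / g
  jg <- which(cs$channels$kind == "lipid_growth")
  expect_equal(a[jg], (0.3 * 30 + 0.3 * 30) / fx$geometry$g)

  # bimolecular propensity scales as 1/V across container sizes
  geom2 <- container_geometry(fx$geometry$delta, fx$geometry$rho,
                              fx$geometry$theta, C0 = 18000, g = 2)
  st2 <- protocell_state(fx$chem, geom2, fx$init_counts)
  V2 <- internal_volume(18000, fx$geometry$delta, fx$geometry$rho)
  expect_equal(channel_propensities(st2)[j] / a[j], V / V2)
})

test_that("Fick transport has zero expected net flux at equilibrium", {
  fx <- make_fixture("fig9_permeable")
  st <- protocell_state(fx$chem, fx$geometry, mode = "fick")
  cs <- st$channel_set
  a <- channel_propensities(st)
  V <- internal_volume(st$C, fx$geometry$delta, fx$geometry$rho)
  for (s in c("A", "B", "AB", "BA")) {
    jin <- which(cs$channels$kind == "transport_in" & cs$channels$r1 == s)
    jout <- which(cs$channels$kind == "transport_out" & cs$channels$r1 == s)
    # counts initialized at round(conc * V): influx ~ efflux
    expect_equal(a[jin], a[jout], tolerance = 1 / (2 * V))
  }
})

test_that("SSA with no active channels idles to the horizon", {
  chem <- chemistry(c("A", "B"), 3, 1,
                    reactions = condensation_reaction("A", "B",
                                                      catalysts = "AAB"))
  geom <- container_geometry(0.1, 100, 2e4)
  st <- protocell_state(chem, geom) # all counts zero: a0 = 0
  res <- simulate_segment(st, horizon = 5)
  expect_equal(res$state$t, 5)
  expect_false(res$divided)
  expect_equal(res$n_events, 0)
  expect_equal(nrow(res$trajectory), 2) # endpoints only at thin = 0
})

test_that("a constant-rate channel produces exponential waiting times", {
  # substrate and catalyst both buffered: cleavage propensity is constant
  chem <- chemistry(
    c("A", "B"), l_max = 4, l_perm = 10,
    species = tibble::tibble(sequence = c("ABAB", "AAB"), is_food = TRUE,
                             external_conc = c(2, 3)),
    reactions = cleavage_reaction("ABAB", 2, catalysts = "AAB")
  )
  geom <- container_geometry(0.1, 100, 2e4, C0 = 1e4)
  st <- protocell_state(chem, geom)
  V <- internal_volume(1e4, 0.1, 100)
  lambda <- 1 * 2 * 3 * V # k * [S] * [C] * V
  a <- channel_propensities(st)
  expect_equal(sum(a), lambda)

  set.seed(101)
  res <- simulate_segment(st, horizon = 2000 / lambda, thin = 1)
  waits <- diff(res$trajectory$t)
  waits <- waits[seq_len(res$n_events - 1)] # drop the final clamp
  ks <- stats::ks.test(waits, "pexp", lambda)
  expect_gt(ks$p.value, 0.01)

  # event counts over [0, T] are Poisson(lambda * T): mean within 3 SE
  T <- 50 / lambda
  set.seed(202)
  n_ev <- vapply(1:300, function(i)
    simulate_segment(st, horizon = T)$n_events, numeric(1))
  se <- sqrt(50 / 300)
  expect_lt(abs(mean(n_ev) - 50), 3 * se)
})

test_that("transport ensemble mean follows the Fick ODE solution", {
  # pure transport, no reactions: x(t) = c V (1 - exp(-D A t / V))
  chem <- chemistry(c("A", "B"), 2, 3,
                    species = tibble::tibble(
                      sequence = "AB", is_food = TRUE, external_conc = 2,
                      diffusion_D = 0.1))
  geom <- container_geometry(0.1, 100, 2e4, C0 = 1e4)
  V <- internal_volume(1e4, 0.1, 100)
  A <- surface_area(1e4, 0.1, 100)
  times <- seq(0.5, 5, length.out = 10) * V / (0.1 * A)
  mean_th <- 2 * V * (1 - exp(-0.1 * A * times / V))
  set.seed(7)
  n_runs <- 250
  xs <- matrix(0, n_runs, length(times))
  for (r in seq_len(n_runs)) {
    st <- protocell_state(chem, geom, counts = c(AB = 0), mode = "fick")
    for (k in seq_along(times)) {
      st <- simulate_segment(st, horizon = times[k],
                             stop_at_division = FALSE)$state
      xs[r, k] <- st$counts[["AB"]]
    }
  }
  m <- colMeans(xs)
  se <- apply(xs, 2, sd) / sqrt(n_runs)
  expect_true(all(abs(m - mean_th) < 3 * se + 1e-9))
})

test_that("monomer mass is conserved in a closed protocell", {
  chem <- closed_chem()
  geom <- container_geometry(0.1, 100, 2e4)
  st <- protocell_state(chem, geom,
                        counts = c(A = 400, B = 400, AAB = 20))
  set.seed(33)
  res <- simulate_segment(st, horizon = 50, thin = 1,
                          stop_at_division = FALSE)
  traj <- res$trajectory
  totals <- apply(traj[, -(1:3)], 1, function(x) monomer_content(
    setNames(x, names(traj)[-(1:3)])))
  expect_gt(res$n_events, 100) # the system actually reacted
  expect_true(all(totals == totals[1]))
})

test_that("identical seeds give identical trajectories", {
  fx <- make_fixture("fig3_coupled_scc")
  go <- function() {
    set.seed(55)
    st <- protocell_state(fx$chem, fx$geometry, fx$init_counts)
    simulate_segment(st, horizon = 1, thin = 10,
                     stop_at_division = FALSE)$trajectory
  }
  expect_identical(go(), go())
})

test_that("injection adds copies and respects buffering", {
  fx <- make_fixture("fig9_permeable")
  st <- protocell_state(fx$chem, fx$geometry, mode = "fick")
  expect_equal(inject_species(st, "BAB", 5)$counts[["BAB"]], 5)
  expect_error(inject_species(st, "ZZZ", 1), "unknown")

  sti <- protocell_state(fx$chem, fx$geometry, mode = "instantaneous")
  expect_warning(out <- inject_species(sti, "A", 3), "buffered")
  expect_equal(out$counts[["A"]], 0)
})

test_that("an autocatalytic coupled fixture reaches the division threshold", {
  fx <- make_fixture("fig3_coupled_scc")
  set.seed(77)
  st <- protocell_state(fx$chem, fx$geometry, fx$init_counts)
  res <- simulate_segment(st, horizon = 500)
  expect_true(res$divided)
  expect_gte(res$state$C, fx$geometry$theta)
})
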