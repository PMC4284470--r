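#' Build the stochastic reaction channels of a chemistry
#'
#' Expands every catalyzed reaction into its elementary stochastic channels.
#' A cleavage `AB + C -> A + B + C` is one channel per catalyst. A
#' condensation runs through a transient catalyst-substrate complex and
#' yields three channels per catalyst: association `A + C -> A:C`,
#' dissociation `A:C -> A + C`, and final condensation `A:C + B -> AB + C`;
#' the complex `A:C` is an explicit pseudo-species (impermeable, never a
#' catalyst). One lipid-growth channel implements container growth
#' (propensity `sum(k_cont_i * x_i) / g`, each firing adds `g` lipids to the
#' membrane). Uncatalyzed reactions yield no channels: there are no
#' spontaneous reactions.
#'
#' Transport depends on `mode`. In `"instantaneous"` mode permeable species
#' are buffered: their internal concentration is pinned to the external one,
#' they carry no tracked count, and reactions consume or produce them
#' without changing it (permeable products vanish into the bath). In
#' `"fick"` mode permeable species are tracked and each gets two opposing
#' unit-molecule transport channels, influx with propensity
#' `D * A * [M_out]` and efflux with propensity `D * A * x / V`, whose
#' expectation reproduces Fick's law `dM/dt = D * A * ([M_out] - [M_in])`.
#'
#' @param chem a [chemistry()].
#' @param mode `"instantaneous"` or `"fick"`.
#' @return an object of class `channel_set`: a list with `species` (tibble:
#'   name, buffered, ext_conc, k_cont, diffusion_D, is_complex) and
#'   `channels` (tibble: kind, reaction_id, k, r1, r2, effects).
#' @export
build_channels <- function(chem, mode = c("instantaneous", "fick")) {
  stopifnot(inherits(chem, "chemistry"))
  mode <- match.arg(mode)
  kd <- chem$kinetics
  rx <- chem$reactions

  complexes <- character()
  chans <- list()
  addch <- function(kind, reaction_id, k, r1, r2, effects) {
    chans[[length(chans) + 1]] <<- tibble(
      kind = kind, reaction_id = reaction_id, k = k,
      r1 = r1, r2 = r2, effects = list(effects)
    )
  }
  for (i in seq_len(nrow(rx))) {
    cats <- rx$catalysts[[i]]
    if (length(cats) == 0) next
    if (rx$kind[i] == "cleavage") {
      k <- if (is.na(rx$k_cleav[i])) kd$k_cleav else rx$k_cleav[i]
      for (cat in cats) {
        eff <- collapse_effects(c(rx$sub1[i], rx$prod1[i], rx$prod2[i]),
                                c(-1L, 1L, 1L))
        addch("cleavage", rx$id[i], k, rx$sub1[i], cat, eff)
      }
    } else {
      ka <- if (is.na(rx$k_assoc[i])) kd$k_assoc else rx$k_assoc[i]
      kdi <- if (is.na(rx$k_diss[i])) kd$k_diss else rx$k_diss[i]
      kc <- if (is.na(rx$k_cond[i])) kd$k_cond else rx$k_cond[i]
      bind <- if (rx$complex_substrate[i] == 2L) rx$sub2[i] else rx$sub1[i]
      other <- if (rx$complex_substrate[i] == 2L) rx$sub1[i] else rx$sub2[i]
      for (cat in cats) {
        cplx <- paste0(bind, ":", cat)
        complexes <- union(complexes, cplx)
        addch("complex_assoc", rx$id[i], ka, bind, cat,
              collapse_effects(c(bind, cat, cplx), c(-1L, -1L, 1L)))
        addch("complex_diss", rx$id[i], kdi, cplx, NA_character_,
              collapse_effects(c(cplx, bind, cat), c(-1L, 1L, 1L)))
        addch("final_cond", rx$id[i], kc, cplx, other,
              collapse_effects(c(cplx, other, rx$prod1[i], cat),
                               c(-1L, -1L, 1L, 1L)))
      }
    }
  }

  sp <- chem$species
  perm <- sp$length < chem$l_perm
  species <- tibble(
    name = c(sp$sequence, complexes),
    buffered = c(perm & (mode == "instantaneous"),
                 rep(FALSE, length(complexes))),
    ext_conc = c(sp$external_conc, rep(0, length(complexes))),
    k_cont = c(sp$k_cont, rep(0, length(complexes))),
    diffusion_D = c(sp$diffusion_D, rep(0, length(complexes))),
    is_complex = c(rep(FALSE, nrow(sp)), rep(TRUE, length(complexes)))
  )

  addch("lipid_growth", NA_integer_, NA_real_, NA_character_,
        NA_character_, integer())
  if (mode == "fick") {
    for (s in sp$sequence[perm]) {
      D <- sp$diffusion_D[sp$sequence == s]
      addch("transport_in", NA_integer_, D, s, NA_character_,
            collapse_effects(s, 1L))
      addch("transport_out", NA_integer_, D, s, NA_character_,
            collapse_effects(s, -1L))
    }
  }
  structure(list(species = species,
                 channels = dplyr::bind_rows(chans),
                 mode = mode),
            class = "channel_set")
}

collapse_effects <- function(names, deltas) {
  agg <- tapply(deltas, names, sum)
  agg <- agg[agg != 0]
  setNames(as.integer(agg), names(agg))
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set>\n")
  cat(sprintf("  mode = %s; %d species slots (%d buffered, %d complexes); %d channels\n",
              x$mode, nrow(x$species), sum(x$species$buffered),
              sum(x$species$is_complex), nrow(x$channels)))
  print(table(x$channels$kind))
  invisible(x)
}

#' Initial protocell state
#'
#' @param chem a [chemistry()].
#' @param geometry a [container_geometry()].
#' @param counts named integer vector of initial copy numbers of tracked
#'   species (impermeable species and, in Fick mode, permeable ones);
#'   unnamed species start at zero. In Fick mode species with a positive
#'   external concentration default to their diffusion equilibrium
#'   `round(ext_conc * V_r(C0))` unless given explicitly.
#' @param mode `"instantaneous"` or `"fick"`.
#' @param t start time.
#' @return an object of class `protocell_state`.
#' @export
protocell_state <- function(chem, geometry, counts = integer(),
                            mode = c("instantaneous", "fick"), t = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(chem, "chemistry"),
            inherits(geometry, "container_geometry"))
  cs <- build_channels(chem, mode)
  x <- setNames(numeric(nrow(cs$species)), cs$species$name)
  if (mode == "fick") {
    V0 <- internal_volume(geometry$C0, geometry$delta, geometry$rho)
    eq <- !cs$species$buffered & cs$species$ext_conc > 0 &
      !cs$species$is_complex
    x[eq] <- round(cs$species$ext_conc[eq] * V0)
  }
  if (length(counts) > 0) {
    unknown <- setdiff(names(counts), names(x))
    if (length(unknown) > 0) {
      stop("unknown species in counts: ", paste(unknown, collapse = ", "))
    }
    x[names(counts)] <- counts
  }
  if (any(x[cs$species$buffered] != 0)) {
    x[cs$species$buffered] <- 0 # buffered species carry no tracked count
  }
  structure(
    list(chem = chem, geometry = geometry, mode = mode,
         channel_set = cs, t = t, C = geometry$C0,
         counts = x, generation = 1L),
    class = "protocell_state"
  )
}

#' @export
print.protocell_state <- function(x, ...) {
  cat("<protocell_state>\n")
  cat(sprintf("  t = %.4g, generation %d, mode = %s, C = %g (theta = %g)\n",
              x$t, x$generation, x$mode, x$C, x$geometry$theta))
  nz <- x$counts[x$counts > 0]
  if (length(nz) > 0) {
    cat("  counts:", paste(sprintf("%s=%g", names(nz), nz),
                           collapse = ", "), "\n")
  } else cat("  counts: all zero\n")
  invisible(x)
}

#' Mass-action propensities of all channels
#'
#' Reference implementation of the propensity rules used by the simulator:
#' bimolecular `a = k * x_A * x_B / V` (`k * x * (x - 1) / V` for identical
#' tracked reactants), unimolecular `a = k * x`, buffered participants
#' contribute `ext_conc * V` in place of a tracked count, lipid growth
#' `sum(k_cont * x) / g`, transport influx `D * A * [M_out]` and efflux
#' `D * A * x / V`.
#'
#' @param state a [protocell_state()].
#' @return numeric vector, one propensity per channel.
#' @export
channel_propensities <- function(state) {
  cs <- state$channel_set
  geom <- state$geometry
  V <- internal_volume(state$C, geom$delta, geom$rho)
  A <- surface_area(state$C, geom$delta, geom$rho)
  sp <- cs$species
  x <- state$counts
  effc <- function(nm) {
    i <- match(nm, sp$name)
    if (sp$buffered[i]) sp$ext_conc[i] * V else x[[i]]
  }
  purrr::map_dbl(seq_len(nrow(cs$channels)), function(j) {
    ch <- cs$channels[j, ]
    switch(ch$kind,
      cleavage = ,
      complex_assoc = ,
      final_cond = {
        if (identical(ch$r1, ch$r2) &&
            !sp$buffered[match(ch$r1, sp$name)]) {
          ch$k * x[[ch$r1]] * (x[[ch$r1]] - 1) / V
        } else {
          ch$k * effc(ch$r1) * effc(ch$r2) / V
        }
      },
      complex_diss = ch$k * effc(ch$r1),
      lipid_growth = sum(sp$k_cont *
                           ifelse(sp$buffered, sp$ext_conc * V, x)) / geom$g,
      transport_in = ch$k * A * sp$ext_conc[match(ch$r1, sp$name)],
      transport_out = ch$k * A * x[[ch$r1]] / V
    )
  })
}

kind_code <- c(cleavage = 0L, complex_assoc = 1L, complex_diss = 2L,
               final_cond = 3L, lipid_growth = 4L, transport_in = 5L,
               transport_out = 6L)

flatten_channels <- function(cs) {
  ch <- cs$channels
  sp_idx <- function(nm) {
    i <- match(nm, cs$species$name)
    ifelse(is.na(i), 0L, i) - 1L # 0-based; -1 for none
  }
  effs <- ch$effects
  lens <- lengths(effs)
  list(
    kind = unname(kind_code[ch$kind]),
    k = ifelse(is.na(ch$k), 0, ch$k),
    r1 = sp_idx(ch$r1),
    r2 = sp_idx(ch$r2),
    eff_ptr = as.integer(c(0, cumsum(lens))),
    eff_sp = if (sum(lens) == 0) integer() else
      sp_idx(unlist(purrr::map(effs, names))),
    eff_delta = if (sum(lens) == 0) integer() else
      as.integer(unlist(effs))
  )
}

#' Simulate a protocell segment with the extended Gillespie algorithm
#'
#' Runs the stochastic simulation (direct method) from the current state
#' until the time horizon, the division condition `C >= theta` (if
#' `stop_at_division`), or the event safety cap is reached. Waiting times
#' are exponential in the total propensity and all propensities (including
#' the geometric factors `V_r` and `A`) are recomputed after every firing,
#' so the algorithm remains exact under the time-varying volume. Randomness
#' comes from R's RNG: call `set.seed()` for reproducible trajectories.
#'
#' @param state a [protocell_state()].
#' @param horizon time horizon (absolute simulation time).
#' @param stop_at_division stop as soon as `C >= theta`?
#' @param thin record a trajectory snapshot every `thin` events (0 = record
#'   only the endpoints).
#' @param max_events event safety cap; exceeding it flags the result as
#'   truncated.
#' @return a list with elements `state` (the advanced state), `trajectory`
#'   (tibble: t, C, V_r, one column per tracked species), `divided`,
#'   `truncated`, `n_events`.
#' @export
simulate_segment <- function(state, horizon, stop_at_division = TRUE,
                             thin = 0L, max_events = 1e7) {
  stopifnot(inherits(state, "protocell_state"), horizon > state$t)
  cs <- state$channel_set
  fl <- flatten_channels(cs)
  geom <- state$geometry
  res <- ssa_run_cpp(
    counts0 = unname(state$counts), t0 = state$t, C0 = state$C,
    kind = fl$kind, kk = fl$k, r1 = fl$r1, r2 = fl$r2,
    eff_ptr = fl$eff_ptr, eff_sp = fl$eff_sp, eff_delta = fl$eff_delta,
    buffered = cs$species$buffered, ext_conc = cs$species$ext_conc,
    k_cont = cs$species$k_cont,
    delta = geom$delta, rho = geom$rho, theta = geom$theta,
    g = geom$g, horizon = horizon,
    stop_at_division = stop_at_division,
    max_events = max_events, thin = as.integer(thin)
  )
  new_state <- state
  new_state$t <- res$t
  new_state$C <- res$C
  new_state$counts <- setNames(res$counts, cs$species$name)
  traj <- as_tibble(as.data.frame(res$trajectory))
  names(traj) <- c("t", "C", "V_r", cs$species$name)
  list(state = new_state, trajectory = traj, divided = res$divided,
       truncated = res$truncated, n_events = res$n_events)
}

#' Inject copies of a species into a protocell
#'
#' Models the spontaneous appearance (or environmental intake) of a novelty:
#' `n_copies` molecules of `species` are added to the current state. In
#' instantaneous mode the species must be tracked (impermeable): buffered
#' species are pinned to the external bath and cannot hold an injection.
#'
#' @param state a [protocell_state()].
#' @param species species sequence.
#' @param n_copies number of molecules to add (>= 1).
#' @return the updated state.
#' @export
inject_species <- function(state, species, n_copies = 1L) {
  stopifnot(inherits(state, "protocell_state"), n_copies >= 1)
  i <- match(species, state$channel_set$species$name)
  if (is.na(i)) stop("unknown species: ", species)
  if (state$channel_set$species$buffered[i]) {
    warning("species is buffered in instantaneous mode; ",
            "injected copies dissolve into the bath")
    return(state)
  }
  state$counts[[i]] <- state$counts[[i]] + n_copies
  state
}
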