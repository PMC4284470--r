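#' Build an artificial polymer chemistry
#'
#' A chemistry is one "artificial world": the monomer alphabet, the set of
#' molecular species (ordered strings over the alphabet), the allowed
#' catalyzed reactions (cleavages and condensations), the food set (permeable
#' species buffered by the external environment), and the kinetic and
#' container-coupling constants. Species shorter than `l_perm` can cross the
#' semipermeable membrane; species of length `>= l_perm` are entrapped. Only
#' species of length at least 3 may act as catalysts. No spontaneous or
#' backward reactions exist: a reaction without a catalyst never fires.
#'
#' Species referenced by reactions but absent from `species` are added
#' automatically with default fields (not food, zero external concentration),
#' so reaction enumeration may create species (the species universe is open,
#' bounded by `l_max` for condensation products).
#'
#' @param alphabet character vector of single-symbol monomers, e.g.
#'   `c("A", "B")`.
#' @param l_max maximum polymer length a condensation may produce.
#' @param l_perm permeability cutoff: species with `length < l_perm` permeate.
#' @param species tibble with columns `sequence` and optionally `is_food`,
#'   `external_conc` (molecules per unit volume in the environment), `k_cont`
#'   (lipids produced per catalyst molecule per unit time; container
#'   coupling), `diffusion_D` (per-area transport coefficient, Fick mode).
#'   Missing columns are filled with defaults.
#' @param reactions tibble of reactions as produced by [cleavage_reaction()],
#'   [condensation_reaction()] or [enumerate_reactions()].
#' @param kinetics default kinetic constants, see [kinetic_params()].
#' @return an object of class `chemistry`.
#' @examples
#' chem <- chemistry(
#'   alphabet = c("A", "B"), l_max = 4, l_perm = 2,
#'   species = tibble::tibble(
#'     sequence = c("A", "B"),
#'     is_food = TRUE, external_conc = 10
#'   ),
#'   reactions = condensation_reaction("A", "B", catalysts = "AAB")
#' )
#' chem
#' @export
chemistry <- function(alphabet, l_max, l_perm,
                      species = tibble(sequence = character()),
                      reactions = empty_reactions(),
                      kinetics = kinetic_params()) {
  stopifnot(is.character(alphabet), all(nchar(alphabet) == 1L),
            l_max >= 1, l_perm >= 1)
  species <- fill_species_defaults(as_tibble(species))
  reactions <- as_tibble(reactions)
  if (nrow(reactions) > 0 && !"id" %in% names(reactions)) {
    reactions$id <- seq_len(nrow(reactions))
  }
  if (nrow(reactions) == 0) reactions <- empty_reactions()
  ref <- reaction_species(reactions)
  missing <- setdiff(ref, species$sequence)
  if (length(missing) > 0) {
    species <- dplyr::bind_rows(
      species,
      fill_species_defaults(tibble(sequence = missing))
    )
  }
  bad <- setdiff(unlist(strsplit(species$sequence, "")), alphabet)
  if (length(bad) > 0) {
    stop("sequences contain symbols outside the alphabet: ",
         paste(unique(bad), collapse = ", "))
  }
  obj <- structure(
    list(alphabet = alphabet, l_max = l_max, l_perm = l_perm,
         species = species, reactions = reactions,
         kinetics = kinetics),
    class = "chemistry"
  )
  obj
}

#' Default kinetic constants of a chemistry
#'
#' Second-order constants (`k_cleav`, `k_assoc`, `k_cond`) have units of
#' volume per molecule per time; the first-order complex dissociation
#' `k_diss` is per time. Per-reaction overrides may be set on the reaction
#' table; `NA` there means "use the default".
#'
#' @param k_cleav cleavage rate constant.
#' @param k_assoc catalyst-substrate complex formation rate constant.
#' @param k_diss complex dissociation rate constant.
#' @param k_cond final condensation rate constant.
#' @return a named list of class `kinetic_params`.
#' @export
kinetic_params <- function(k_cleav = 1, k_assoc = 1, k_diss = 0.1,
                           k_cond = 1) {
  vals <- list(k_cleav = k_cleav, k_assoc = k_assoc, k_diss = k_diss,
               k_cond = k_cond)
  stopifnot(all(unlist(vals) >= 0))
  structure(vals, class = "kinetic_params")
}

fill_species_defaults <- function(sp) {
  stopifnot("sequence" %in% names(sp))
  n <- nrow(sp)
  if (!"is_food" %in% names(sp)) sp$is_food <- rep(FALSE, n)
  if (!"external_conc" %in% names(sp)) sp$external_conc <- rep(0, n)
  if (!"k_cont" %in% names(sp)) sp$k_cont <- rep(0, n)
  if (!"diffusion_D" %in% names(sp)) sp$diffusion_D <- rep(0, n)
  sp$is_food[is.na(sp$is_food)] <- FALSE
  sp$external_conc[is.na(sp$external_conc)] <- 0
  sp$k_cont[is.na(sp$k_cont)] <- 0
  sp$diffusion_D[is.na(sp$diffusion_D)] <- 0
  sp$length <- nchar(sp$sequence)
  if (anyDuplicated(sp$sequence)) stop("duplicated species sequences")
  sp[, c("sequence", "length", "is_food", "external_conc", "k_cont",
         "diffusion_D")]
}

empty_reactions <- function() {
  tibble(
    id = integer(), kind = character(),
    sub1 = character(), sub2 = character(),
    prod1 = character(), prod2 = character(),
    cut_pos = integer(), complex_substrate = integer(),
    catalysts = list(),
    k_cleav = double(), k_assoc = double(), k_diss = double(),
    k_cond = double()
  )
}

#' Construct single reactions
#'
#' `cleavage_reaction()` cuts `substrate` after position `cut_pos` into two
#' products (`AB + C -> A + B + C` with catalyst `C`).
#' `condensation_reaction()` concatenates `sub1` then `sub2` into one product
#' via a transient catalyst-substrate complex: complex formation
#' `A + C -> A:C`, dissociation `A:C -> A + C`, and final condensation
#' `A:C + B -> AB + C`. `complex_substrate` selects which substrate binds the
#' catalyst first (1 or 2).
#'
#' @param substrate,sub1,sub2 species sequences.
#' @param cut_pos cut after this many symbols (`1 <= cut_pos < length`).
#' @param catalysts character vector of catalyst sequences (each of length
#'   at least 3); may be empty (the reaction then never fires).
#' @param complex_substrate which substrate forms the complex (condensation).
#' @param k_cleav,k_assoc,k_diss,k_cond optional per-reaction overrides of
#'   the chemistry's [kinetic_params()] defaults (`NA` = use default).
#' @return a one-row reaction tibble.
#' @examples
#' cleavage_reaction("AAAB", cut_pos = 1, catalysts = "ABA")
#' condensation_reaction("ABA", "BA", catalysts = "AABBA")
#' @export
cleavage_reaction <- function(substrate, cut_pos, catalysts = character(),
                              k_cleav = NA_real_) {
  stopifnot(cut_pos >= 1, cut_pos < nchar(substrate))
  tibble(
    kind = "cleavage",
    sub1 = substrate, sub2 = NA_character_,
    prod1 = substr(substrate, 1, cut_pos),
    prod2 = substr(substrate, cut_pos + 1, nchar(substrate)),
    cut_pos = as.integer(cut_pos), complex_substrate = NA_integer_,
    catalysts = list(as.character(catalysts)),
    k_cleav = k_cleav, k_assoc = NA_real_, k_diss = NA_real_,
    k_cond = NA_real_
  )
}

#' @rdname cleavage_reaction
#' @export
condensation_reaction <- function(sub1, sub2, catalysts = character(),
                                  complex_substrate = 1L,
                                  k_assoc = NA_real_, k_diss = NA_real_,
                                  k_cond = NA_real_) {
  stopifnot(complex_substrate %in% c(1L, 2L))
  tibble(
    kind = "condensation",
    sub1 = sub1, sub2 = sub2,
    prod1 = paste0(sub1, sub2), prod2 = NA_character_,
    cut_pos = NA_integer_, complex_substrate = as.integer(complex_substrate),
    catalysts = list(as.character(catalysts)),
    k_cleav = NA_real_, k_assoc = k_assoc, k_diss = k_diss, k_cond = k_cond
  )
}

reaction_species <- function(reactions) {
  if (nrow(reactions) == 0) return(character())
  unique(stats::na.omit(c(reactions$sub1, reactions$sub2, reactions$prod1,
                          reactions$prod2, unlist(reactions$catalysts))))
}

#' Which species permeate the membrane?
#'
#' A species permeates iff its length is strictly smaller than the chemistry's
#' `l_perm` cutoff ("shorter than" read strictly). Catalyst-substrate
#' complexes never permeate.
#'
#' @param chem a [chemistry()].
#' @param sequences species sequences; default all species in `chem`.
#' @return named logical vector.
#' @export
is_permeable <- function(chem, sequences = chem$species$sequence) {
  setNames(nchar(sequences) < chem$l_perm, sequences)
}

#' Enumerate all allowed reactions over a species set
#'
#' The allowed reactions are all cleavages (every cut position of every
#' species with at least two symbols) and every ordered condensation of two
#' species whose product is no longer than `l_max`
#' (e.g. `AAAB -> A + AAB`; `ABA + BA -> ABABA`). No catalysts are assigned.
#' Products absent from `species` become new species when the result is
#' wrapped in a [chemistry()]. Enumeration order is deterministic:
#' cleavages by substrate then cut position, condensations by first then
#' second substrate, following the order of `species`.
#'
#' @param species character vector of species sequences.
#' @param l_max maximum condensation product length.
#' @param alphabet monomer alphabet used to reject malformed sequences;
#'   default: the distinct symbols occurring in `species`.
#' @return a reaction tibble (no catalysts assigned).
#' @examples
#' enumerate_reactions(c("A", "B", "AB"), l_max = 3)
#' @export
enumerate_reactions <- function(species, l_max,
                                alphabet = sort(unique(unlist(strsplit(species, ""))))) {
  stopifnot(length(species) > 0, l_max >= 1)
  bad <- setdiff(unlist(strsplit(species, "")), alphabet)
  if (length(bad) > 0) {
    stop("sequences contain symbols outside the alphabet: ",
         paste(unique(bad), collapse = ", "))
  }
  cleav <- purrr::map(species[nchar(species) >= 2], function(s) {
    purrr::map(seq_len(nchar(s) - 1L), function(cut) {
      cleavage_reaction(s, cut)
    })
  })
  lens <- nchar(species)
  pairs <- expand.grid(i = seq_along(species), j = seq_along(species))
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  keep <- lens[pairs$i] + lens[pairs$j] <= l_max
  cond <- purrr::map2(pairs$i[keep], pairs$j[keep], function(i, j) {
    condensation_reaction(species[i], species[j])
  })
  out <- dplyr::bind_rows(c(purrr::flatten(cleav), cond))
  if (nrow(out) == 0) return(empty_reactions())
  out$id <- seq_len(nrow(out))
  out
}

eligible_catalysts <- function(chem) {
  chem$species$sequence[chem$species$length >= 3]
}

#' Randomly assign catalysts to reactions
#'
#' Catalysis is assigned at random following the Kauffman scheme: each species
#' of length at least 3 has probability `p` of being the catalyst of a
#' reaction chosen uniformly at random (`scheme = "per_species"`, the
#' default: one Bernoulli draw per eligible species, then one uniform
#' reaction draw). The alternative `scheme = "per_pair"` performs an
#' independent Bernoulli(p) draw for every (species, reaction) pair. Under
#' either scheme a species can catalyze several reactions and a reaction can
#' gain several catalysts; existing assignments are kept.
#'
#' @param chem a [chemistry()].
#' @param p catalysis probability in `[0, 1]`.
#' @param seed optional integer seed for reproducible assignment.
#' @param scheme `"per_species"` or `"per_pair"`.
#' @return the chemistry with an updated `catalysts` column.
#' @export
assign_catalysis <- function(chem, p, seed = NULL,
                             scheme = c("per_species", "per_pair")) {
  stopifnot(inherits(chem, "chemistry"), p >= 0, p <= 1)
  scheme <- match.arg(scheme)
  if (p == 0 || nrow(chem$reactions) == 0) return(chem)
  elig <- eligible_catalysts(chem)
  if (length(elig) == 0) {
    warning("no species of length >= 3: no catalysts assigned")
    return(chem)
  }
  draw <- function() {
    n_r <- nrow(chem$reactions)
    if (scheme == "per_species") {
      hit <- runif(length(elig)) < p
      rx <- sample.int(n_r, sum(hit), replace = TRUE)
      data.frame(species = elig[hit], reaction = rx)
    } else {
      grid <- expand.grid(species = elig, reaction = seq_len(n_r),
                          stringsAsFactors = FALSE)
      grid[runif(nrow(grid)) < p, , drop = FALSE]
    }
  }
  asg <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (nrow(asg) > 0) {
    for (k in seq_len(nrow(asg))) {
      i <- asg$reaction[k]
      chem$reactions$catalysts[[i]] <-
        unique(c(chem$reactions$catalysts[[i]], asg$species[k]))
    }
  }
  chem
}

#' Randomly couple species to container growth
#'
#' Each non-food species is independently coupled to membrane growth with
#' probability `p_cont`; coupled species produce membrane lipids at rate
#' `k_cont_value` per molecule per unit time (they catalyze lipid formation
#' from abundant, buffered precursors).
#'
#' @param chem a [chemistry()].
#' @param p_cont coupling probability in `[0, 1]`.
#' @param k_cont_value lipid production rate per catalyst molecule (> 0).
#' @param seed optional integer seed.
#' @return the chemistry with an updated `k_cont` column.
#' @export
assign_container_coupling <- function(chem, p_cont, k_cont_value,
                                      seed = NULL) {
  stopifnot(inherits(chem, "chemistry"), p_cont >= 0, p_cont <= 1,
            k_cont_value > 0)
  idx <- which(!chem$species$is_food)
  if (length(idx) == 0) return(chem)
  draw <- function() runif(length(idx)) < p_cont
  hit <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  chem$species$k_cont[idx[hit]] <- k_cont_value
  chem
}

#' Set species fields by sequence
#'
#' Convenience setter used when hand-building fixture chemistries: marks the
#' given sequences as food (buffered outside at `external_conc`), or sets
#' container coupling / diffusion coefficients.
#'
#' @param chem a [chemistry()].
#' @param sequences species sequences to modify.
#' @param is_food,external_conc,k_cont,diffusion_D values to set (NULL =
#'   leave unchanged).
#' @return the modified chemistry.
#' @export
set_species <- function(chem, sequences, is_food = NULL,
                        external_conc = NULL, k_cont = NULL,
                        diffusion_D = NULL) {
  stopifnot(inherits(chem, "chemistry"))
  i <- match(sequences, chem$species$sequence)
  if (anyNA(i)) stop("unknown species: ",
                     paste(sequences[is.na(i)], collapse = ", "))
  if (!is.null(is_food)) chem$species$is_food[i] <- is_food
  if (!is.null(external_conc)) chem$species$external_conc[i] <- external_conc
  if (!is.null(k_cont)) chem$species$k_cont[i] <- k_cont
  if (!is.null(diffusion_D)) chem$species$diffusion_D[i] <- diffusion_D
  chem
}

#' Validate a chemistry against its structural invariants
#'
#' Report-only check of every invariant: monomer mass balance of each reaction
#' (the multiset of symbols is conserved), catalyst eligibility (length >= 3),
#' condensation product length within `l_max`, food permeability and positive
#' external concentration, and resolution of all substrate / product /
#' catalyst references. An empty report means the chemistry is valid.
#'
#' @param chem a [chemistry()].
#' @return a tibble with columns `check`, `item`, `message`; zero rows if
#'   valid.
#' @export
validate_chemistry <- function(chem) {
  stopifnot(inherits(chem, "chemistry"))
  out <- list()
  add <- function(check, item, message) {
    out[[length(out) + 1]] <<- tibble(check = check, item = item,
                                      message = message)
  }
  sp <- chem$species
  rx <- chem$reactions
  bad_sym <- setdiff(unlist(strsplit(sp$sequence, "")), chem$alphabet)
  for (s in bad_sym) add("alphabet", s, "symbol outside alphabet")
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    subs <- stats::na.omit(c(r$sub1, r$sub2))
    prods <- stats::na.omit(c(r$prod1, r$prod2))
    lhs <- sort(unlist(strsplit(subs, "")))
    rhs <- sort(unlist(strsplit(prods, "")))
    if (!identical(lhs, rhs)) {
      add("mass_balance", paste0("reaction ", r$id),
          "monomer multiset not conserved")
    }
    if (r$kind == "cleavage") {
      if (!identical(paste0(r$prod1, r$prod2), r$sub1)) {
        add("cleavage", paste0("reaction ", r$id),
            "products do not concatenate to the substrate")
      }
    } else {
      if (!identical(r$prod1, paste0(r$sub1, r$sub2))) {
        add("condensation", paste0("reaction ", r$id),
            "product is not the concatenation of the substrates")
      }
      if (nchar(r$prod1) > chem$l_max) {
        add("l_max", paste0("reaction ", r$id),
            "condensation product longer than l_max")
      }
    }
    for (cat in r$catalysts[[1]]) {
      if (nchar(cat) < 3) {
        add("catalyst_length", cat,
            "catalysts must have at least three symbols")
      }
    }
    unresolved <- setdiff(c(subs, prods, r$catalysts[[1]]), sp$sequence)
    for (u in unresolved) {
      add("reference", u, paste0("reaction ", r$id,
                                 " references an unknown species"))
    }
  }
  food <- sp[sp$is_food, ]
  for (i in seq_len(nrow(food))) {
    if (food$length[i] >= chem$l_perm) {
      add("food_permeability", food$sequence[i],
          "food species must be permeable (length < l_perm)")
    }
    if (food$external_conc[i] <= 0) {
      add("food_concentration", food$sequence[i],
          "food species must have positive external concentration")
    }
  }
  if (length(out) == 0) {
    tibble(check = character(), item = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Generate a random Kauffman chemistry
#'
#' Enumerates every string over `alphabet` up to length `l_species` as the
#' initial species set, enumerates all allowed reactions (all cleavages plus
#' condensations with products up to `l_max`), marks every species shorter
#' than `l_perm` as food, assigns catalysis with probability `p` and
#' container coupling with probability `p_cont`.
#'
#' @param alphabet monomer alphabet.
#' @param l_species maximum length of the initially present species.
#' @param l_max maximum condensation product length.
#' @param l_perm permeability cutoff.
#' @param p catalysis probability (per eligible species; see
#'   [assign_catalysis()]).
#' @param p_cont container-coupling probability.
#' @param food_conc buffered external concentration of food species.
#' @param k_cont_value lipid production rate of coupled species.
#' @param seed optional integer seed.
#' @param scheme catalysis scheme, see [assign_catalysis()].
#' @return a [chemistry()].
#' @export
random_chemistry <- function(alphabet = c("A", "B"), l_species = 3,
                             l_max = 4, l_perm = 3, p = 0.05,
                             p_cont = 0, food_conc = 10,
                             k_cont_value = 0.01, seed = NULL,
                             scheme = c("per_species", "per_pair")) {
  scheme <- match.arg(scheme)
  seqs <- all_strings(alphabet, l_species)
  rx <- enumerate_reactions(seqs, l_max, alphabet)
  chem <- chemistry(
    alphabet, l_max, l_perm,
    species = tibble(sequence = seqs,
                     is_food = nchar(seqs) < l_perm,
                     external_conc = ifelse(nchar(seqs) < l_perm,
                                            food_conc, 0)),
    reactions = rx
  )
  chem <- assign_catalysis(chem, p, seed = seed, scheme = scheme)
  if (p_cont > 0) {
    seed2 <- if (is.null(seed)) NULL else seed + 1L
    chem <- assign_container_coupling(chem, p_cont, k_cont_value,
                                      seed = seed2)
  }
  chem
}

#' All strings over an alphabet up to a maximum length
#'
#' @param alphabet character vector of single symbols.
#' @param max_len maximum string length.
#' @return character vector in deterministic order (by length, then
#'   lexicographic in alphabet order).
#' @export
all_strings <- function(alphabet, max_len) {
  out <- list()
  prev <- ""
  for (l in seq_len(max_len)) {
    prev <- as.vector(t(outer(prev, alphabet, paste0)))
    out[[l]] <- prev
  }
  unlist(out)
}

#' @export
print.chemistry <- function(x, ...) {
  n_cat <- sum(lengths(x$reactions$catalysts) > 0)
  cat("<chemistry>\n")
  cat(sprintf("  alphabet: {%s}, l_max = %d, l_perm = %d\n",
              paste(x$alphabet, collapse = ","), x$l_max, x$l_perm))
  cat(sprintf("  %d species (%d food, %d container-coupled), %d reactions (%d catalyzed)\n",
              nrow(x$species), sum(x$species$is_food),
              sum(x$species$k_cont > 0), nrow(x$reactions), n_cat))
  invisible(x)
}
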