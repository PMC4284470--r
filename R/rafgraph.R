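#' Catalyst-product graph of a chemistry
#'
#' Directed graph on the species with an edge from u to v whenever u
#' catalyzes at least one reaction having v among its products. Substrate
#' information is deliberately dropped: in this representation candidate
#' collective replicators appear as strongly connected components.
#'
#' @param chem a [chemistry()].
#' @return an [igraph::igraph] with vertex attributes `is_food` and
#'   `k_cont`.
#' @export
catalyst_product_graph <- function(chem) {
  stopifnot(inherits(chem, "chemistry"))
  rx <- chem$reactions
  edges <- purrr::map(seq_len(nrow(rx)), function(i) {
    cats <- rx$catalysts[[i]]
    prods <- stats::na.omit(c(rx$prod1[i], rx$prod2[i]))
    if (length(cats) == 0) return(NULL)
    expand.grid(from = cats, to = as.character(prods),
                stringsAsFactors = FALSE)
  })
  edges <- dplyr::distinct(dplyr::bind_rows(edges))
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character())
  }
  igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = data.frame(name = chem$species$sequence,
                          is_food = chem$species$is_food,
                          k_cont = chem$species$k_cont)
  )
}

#' Nontrivial strongly connected components
#'
#' Returns the strongly connected components of a directed graph that could
#' sustain collective production: components of size greater than one, or
#' single nodes carrying a self-loop (a direct autocatalyst). Components are
#' returned in deterministic order (by their lexicographically smallest
#' member) as character vectors of node names.
#'
#' @param graph an [igraph::igraph], typically from
#'   [catalyst_product_graph()].
#' @return list of character vectors; empty list if none.
#' @export
find_sccs <- function(graph) {
  comp <- igraph::components(graph, mode = "strong")
  nm <- igraph::V(graph)$name
  sccs <- split(nm, comp$membership)
  keep <- purrr::keep(sccs, function(s) {
    length(s) > 1 ||
      igraph::are_adjacent(graph, s, s)
  })
  keep <- purrr::map(keep, sort)
  keep <- unname(keep[order(purrr::map_chr(keep, 1))])
  keep
}

reaction_parts <- function(chem) {
  rx <- chem$reactions
  list(
    subs = purrr::map(seq_len(nrow(rx)),
                      function(i) as.character(stats::na.omit(c(rx$sub1[i], rx$sub2[i])))),
    prods = purrr::map(seq_len(nrow(rx)),
                       function(i) as.character(stats::na.omit(c(rx$prod1[i], rx$prod2[i])))),
    cats = rx$catalysts,
    ids = rx$id
  )
}

#' Food closure of a reaction subset
#'
#' Least fixed point of substrate generation: starting from the food set,
#' repeatedly add the products of any reaction of the subset all of whose
#' substrates are already present. Catalysis is *not* required here: the
#' closure asks only what is generable from the food, the catalyst condition
#' is enforced separately during RAF reduction.
#'
#' @param chem a [chemistry()].
#' @param reaction_ids reaction ids forming the subset (default: all).
#' @param food character vector of food sequences (default: the chemistry's
#'   food set).
#' @return character vector of species sequences in the closure.
#' @export
food_closure <- function(chem, reaction_ids = chem$reactions$id,
                         food = chem$species$sequence[chem$species$is_food]) {
  parts <- reaction_parts(chem)
  sel <- match(reaction_ids, parts$ids)
  stopifnot(!anyNA(sel))
  closure <- unique(food)
  repeat {
    added <- FALSE
    for (i in sel) {
      if (all(parts$subs[[i]] %in% closure) &&
          !all(parts$prods[[i]] %in% closure)) {
        closure <- union(closure, parts$prods[[i]])
        added <- TRUE
      }
    }
    if (!added) break
  }
  closure
}

raf_reduce <- function(parts, ids, food) {
  sel <- match(ids, parts$ids)
  repeat {
    closure <- unique(food)
    repeat {
      added <- FALSE
      for (i in sel) {
        if (all(parts$subs[[i]] %in% closure) &&
            !all(parts$prods[[i]] %in% closure)) {
          closure <- union(closure, parts$prods[[i]])
          added <- TRUE
        }
      }
      if (!added) break
    }
    keep <- purrr::map_lgl(sel, function(i) {
      all(parts$subs[[i]] %in% closure) &&
        any(parts$cats[[i]] %in% closure)
    })
    if (all(keep)) break
    sel <- sel[keep]
    if (length(sel) == 0) break
  }
  parts$ids[sel]
}

#' Maximal RAF set of a chemistry
#'
#' Computes the maximal reflexively autocatalytic, food-generated (RAF)
#' subset of the reactions by iterative reduction: starting from the full
#' reaction set, compute the food closure, delete every reaction with a
#' substrate outside the closure or with no catalyst inside it, and repeat
#' until stable. The result is the union of all RAF subsets (possibly
#' empty); re-running the reduction on it is a no-op.
#'
#' @param chem a [chemistry()].
#' @param food food set override (default: the chemistry's food species).
#' @return integer vector of reaction ids (possibly empty).
#' @export
max_raf <- function(chem,
                    food = chem$species$sequence[chem$species$is_food]) {
  stopifnot(inherits(chem, "chemistry"))
  parts <- reaction_parts(chem)
  raf_reduce(parts, parts$ids, food)
}

#' Is a reaction subset a RAF?
#'
#' A subset is a RAF iff the reduction (see [max_raf()]) leaves it unchanged
#' and nonempty: every substrate lies in the food closure of the subset and
#' every reaction has a catalyst in that closure.
#'
#' @param chem a [chemistry()].
#' @param reaction_ids candidate subset of reaction ids.
#' @param food food set override.
#' @return logical scalar.
#' @export
is_raf <- function(chem, reaction_ids,
                   food = chem$species$sequence[chem$species$is_food]) {
  if (length(reaction_ids) == 0) return(FALSE)
  parts <- reaction_parts(chem)
  red <- raf_reduce(parts, reaction_ids, food)
  setequal(red, reaction_ids)
}

extend_tentacles <- function(parts, core, pool, food) {
  current <- core
  repeat {
    closure <- closure_of(parts, current, food)
    cand <- setdiff(pool, current)
    addable <- cand[purrr::map_lgl(match(cand, parts$ids), function(i) {
      all(parts$subs[[i]] %in% closure) && any(parts$cats[[i]] %in% closure)
    })]
    if (length(addable) == 0) break
    current <- union(current, addable)
  }
  sort(current)
}

closure_of <- function(parts, ids, food) {
  sel <- match(ids, parts$ids)
  closure <- unique(food)
  repeat {
    added <- FALSE
    for (i in sel) {
      if (all(parts$subs[[i]] %in% closure) &&
          !all(parts$prods[[i]] %in% closure)) {
        closure <- union(closure, parts$prods[[i]])
        added <- TRUE
      }
    }
    if (!added) break
  }
  closure
}

#' Irreducible RAFs (irrRAFs)
#'
#' Finds the minimal RAF subsets of the maximal RAF, each extended with its
#' dependent "tentacle" reactions (reactions of the maximal RAF that become
#' supported, one at a time, once the core runs: chains rooted in the core's
#' products). For maximal RAFs of at most `exact_limit` reactions the
#' minimal cores are found exactly by enumerating all subsets; above that a
#' randomized-deletion heuristic is used (`n_trials` random deletion orders,
#' deduplicated) and the result is flagged as possibly incomplete.
#'
#' @param chem a [chemistry()].
#' @param enumeration_cap maximum number of distinct irrRAFs to return.
#' @param exact_limit largest maximal-RAF size for which exact subset
#'   enumeration is used.
#' @param n_trials random deletion orders for the heuristic.
#' @param food food set override.
#' @return list of sorted integer id vectors, with attributes
#'   `incomplete` (logical) and `cores` (the minimal cores before tentacle
#'   extension).
#' @export
find_irr_rafs <- function(chem, enumeration_cap = 64L, exact_limit = 12L,
                          n_trials = 200L,
                          food = chem$species$sequence[chem$species$is_food]) {
  parts <- reaction_parts(chem)
  mr <- raf_reduce(parts, parts$ids, food)
  if (length(mr) == 0) {
    return(structure(list(), incomplete = FALSE, cores = list()))
  }
  incomplete <- FALSE
  if (length(mr) <= exact_limit) {
    rafs <- list()
    n <- length(mr)
    for (mask in seq_len(2^n - 1)) {
      sub <- mr[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      red <- raf_reduce(parts, sub, food)
      if (length(red) == length(sub) && setequal(red, sub)) {
        rafs[[length(rafs) + 1]] <- sort(sub)
      }
    }
    is_min <- purrr::map_lgl(rafs, function(s) {
      !any(purrr::map_lgl(rafs, function(o) {
        length(o) < length(s) && all(o %in% s)
      }))
    })
    cores <- unique(rafs[is_min])
  } else {
    cores <- list()
    for (k in seq_len(n_trials)) {
      cur <- mr
      for (r in sample(mr)) {
        if (!(r %in% cur)) next
        red <- raf_reduce(parts, setdiff(cur, r), food)
        if (length(red) > 0) cur <- red
      }
      cores <- unique(c(cores, list(sort(cur))))
      if (length(cores) >= enumeration_cap) break
    }
    incomplete <- TRUE
  }
  if (length(cores) > enumeration_cap) {
    cores <- cores[seq_len(enumeration_cap)]
    incomplete <- TRUE
  }
  irr <- unique(purrr::map(cores, extend_tentacles, parts = parts,
                           pool = mr, food = food))
  structure(irr, incomplete = incomplete, cores = cores)
}

#' Full RAF analysis of a chemistry
#'
#' Bundles the maximal RAF, the irreducible RAFs, the food closure of the
#' maximal RAF, and the nontrivial strongly connected components of the
#' catalyst-product graph.
#'
#' @param chem a [chemistry()].
#' @param ... passed to [find_irr_rafs()].
#' @return an object of class `raf_result` with elements `max_raf`,
#'   `irr_rafs`, `closure`, `sccs`.
#' @export
find_raf <- function(chem, ...) {
  mr <- max_raf(chem)
  irr <- find_irr_rafs(chem, ...)
  closure <- food_closure(chem, reaction_ids = mr)
  sccs <- find_sccs(catalyst_product_graph(chem))
  structure(
    list(max_raf = mr, irr_rafs = irr, closure = closure, sccs = sccs),
    class = "raf_result"
  )
}

#' @export
print.raf_result <- function(x, ...) {
  cat("<raf_result>\n")
  cat(sprintf("  max RAF: %d reactions; %d irrRAF(s); closure of %d species; %d nontrivial SCC(s)\n",
              length(x$max_raf), length(x$irr_rafs), length(x$closure),
              length(x$sccs)))
  invisible(x)
}

#' Label species by RAF membership
#'
#' Each species is labeled `"food"`, `"RAF-member"` (it takes part in the
#' maximal RAF as substrate, product or catalyst) or `"non-RAF"` (including
#' species neither produced nor consumed by any retained reaction, which
#' undergo dilution across generations).
#'
#' @param chem a [chemistry()].
#' @param raf a `raf_result` from [find_raf()] (computed if missing).
#' @return tibble with columns `sequence`, `label`.
#' @export
classify_species <- function(chem, raf = find_raf(chem)) {
  rx <- chem$reactions[match(raf$max_raf, chem$reactions$id), , drop = FALSE]
  members <- unique(stats::na.omit(c(rx$sub1, rx$sub2, rx$prod1, rx$prod2,
                                     unlist(rx$catalysts))))
  tibble(
    sequence = chem$species$sequence,
    label = dplyr::case_when(
      chem$species$is_food ~ "food",
      chem$species$sequence %in% members ~ "RAF-member",
      TRUE ~ "non-RAF"
    )
  )
}

#' Export a graph to DOT or GraphML
#'
#' Writes the catalyst-product graph (or any igraph) in a standard exchange
#' format, keeping the `is_food` / `k_cont` vertex attributes.
#'
#' @param graph an [igraph::igraph].
#' @param path output file; the extension (`.dot` / `.gv` or `.graphml`)
#'   selects the format unless `format` is given.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path)) "graphml" else "dot"
  }
  if (format == "dot") {
    # DOT has no boolean attribute type; igraph warns on conversion
    for (at in igraph::vertex_attr_names(graph)) {
      v <- igraph::vertex_attr(graph, at)
      if (is.logical(v)) graph <- igraph::set_vertex_attr(graph, at,
                                                          value = as.integer(v))
    }
  }
  igraph::write_graph(graph, path, format = format)
  invisible(path)
}
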