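# Independent brute-force oracles used to cross-check the package's graph
# and RAF algorithms. These deliberately re-derive everything from first
# principles (definition-level iteration, transitive closure, subset
# enumeration) and share no code with the implementation.

# Reaction subsets are represented as row indices into a plain data frame
# with list-columns subs / prods / cats.
oracle_parts <- function(chem) {
  rx <- chem$reactions
  list(
    subs = lapply(seq_len(nrow(rx)), function(i)
      as.character(na.omit(c(rx$sub1[i], rx$sub2[i])))),
    prods = lapply(seq_len(nrow(rx)), function(i)
      as.character(na.omit(c(rx$prod1[i], rx$prod2[i])))),
    cats = rx$catalysts,
    ids = rx$id
  )
}

oracle_closure <- function(parts, rows, food) {
  W <- unique(food)
  repeat {
    n0 <- length(W)
    for (i in rows) {
      if (all(parts$subs[[i]] %in% W)) W <- union(W, parts$prods[[i]])
    }
    if (length(W) == n0) return(W)
  }
}

# RA + F conditions checked directly on a candidate subset
oracle_is_raf <- function(parts, rows, food) {
  if (length(rows) == 0) return(FALSE)
  W <- oracle_closure(parts, rows, food)
  all(vapply(rows, function(i) {
    all(parts$subs[[i]] %in% W) && any(parts$cats[[i]] %in% W)
  }, logical(1)))
}

# all RAF subsets by full enumeration (<= ~12 reactions)
oracle_all_rafs <- function(chem, food = chem$species$sequence[chem$species$is_food]) {
  parts <- oracle_parts(chem)
  n <- nrow(chem$reactions)
  out <- list()
  if (n == 0) return(out)
  for (mask in seq_len(2^n - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (oracle_is_raf(parts, rows, food)) {
      out[[length(out) + 1]] <- sort(parts$ids[rows])
    }
  }
  out
}

oracle_max_raf <- function(chem, ...) {
  rafs <- oracle_all_rafs(chem, ...)
  if (length(rafs) == 0) integer() else sort(unique(unlist(rafs)))
}

oracle_min_rafs <- function(chem, ...) {
  rafs <- oracle_all_rafs(chem, ...)
  keep <- vapply(rafs, function(s) {
    !any(vapply(rafs, function(o) length(o) < length(s) && all(o %in% s),
                logical(1)))
  }, logical(1))
  unique(rafs[keep])
}

# nontrivial SCCs by pairwise reachability (transitive closure)
oracle_sccs <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %*% t(reach[k, ]) > 0)
  }
  both <- reach & t(reach)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[which(both[i, ])] <- cid
    }
  }
  sccs <- split(seq_len(n), comp)
  keep <- Filter(function(s) length(s) > 1 || adj[s, s], sccs)
  keep <- lapply(keep, function(s) sort(as.integer(s)))
  unname(keep[order(vapply(keep, min, integer(1)))])
}

# random abstract string chemistry with <= n_rx catalyzed reactions
random_small_chem <- function(seed, n_rx = 6) {
  withr::with_seed(seed, {
    universe <- all_strings(c("A", "B"), 3)
    rx_all <- enumerate_reactions(universe, l_max = 4)
    pick <- sort(sample.int(nrow(rx_all), n_rx))
    rx <- rx_all[pick, ]
    rx$id <- seq_len(nrow(rx))
    elig <- universe[nchar(universe) >= 3]
    rx$catalysts <- lapply(seq_len(nrow(rx)), function(i) {
      k <- sample(0:2, 1)
      if (k == 0) character() else sample(elig, k)
    })
    chemistry(
      alphabet = c("A", "B"), l_max = 4, l_perm = 3,
      species = tibble::tibble(
        sequence = universe,
        is_food = nchar(universe) <= 2,
        external_conc = ifelse(nchar(universe) <= 2, 1, 0)
      ),
      reactions = rx
    )
  })
}

random_digraph <- function(seed, n = 12, p = 0.15) {
  withr::with_seed(seed, {
    adj <- matrix(runif(n * n) < p, n, n)
    adj
  })
}

adj_to_igraph <- function(adj) {
  dimnames(adj) <- list(as.character(seq_len(nrow(adj))),
                        as.character(seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

# numeric shell-inversion oracle: recover inner radius r from lipid count C
# by bisection on the forward spherical-shell mass relation
oracle_radius <- function(C, delta, rho) {
  f <- function(r) rho * (4 / 3) * pi * ((r + delta)^3 - r^3) - C
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = 1e-14 * upper)$root
}
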