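#' Read and write chemistries as JSON
#'
#' The on-disk format is a JSON document with fields `alphabet`, `l_max`,
#' `l_perm`, `kinetic_defaults`, `species` (sequence, is_food,
#' external_concentration, k_cont, diffusion_D) and `reactions` (kind,
#' substrates, cut_position, complex_substrate, catalysts and per-reaction
#' kinetic overrides). A save/load round trip reproduces the chemistry
#' exactly.
#'
#' @param chem a [chemistry()].
#' @param path file path.
#' @return `read_chemistry()` returns a [chemistry()];
#'   `write_chemistry()` returns `path` invisibly.
#' @export
write_chemistry <- function(chem, path) {
  stopifnot(inherits(chem, "chemistry"))
  rx <- chem$reactions
  reactions <- purrr::map(seq_len(nrow(rx)), function(i) {
    r <- rx[i, ]
    list(
      kind = r$kind,
      substrates = as.list(stats::na.omit(c(r$sub1, r$sub2))),
      cut_position = if (is.na(r$cut_pos)) NULL else r$cut_pos,
      complex_substrate = if (is.na(r$complex_substrate)) NULL else
        r$complex_substrate,
      catalysts = as.list(r$catalysts[[1]]),
      overrides = Filter(Negate(is.na),
                         list(k_cleav = r$k_cleav, k_assoc = r$k_assoc,
                              k_diss = r$k_diss, k_cond = r$k_cond))
    )
  })
  doc <- list(
    alphabet = chem$alphabet,
    l_max = chem$l_max,
    l_perm = chem$l_perm,
    kinetic_defaults = unclass(chem$kinetics),
    species = purrr::map(seq_len(nrow(chem$species)), function(i) {
      s <- chem$species[i, ]
      list(sequence = s$sequence, is_food = s$is_food,
           external_concentration = s$external_conc,
           k_cont = s$k_cont, diffusion_D = s$diffusion_D)
    }),
    reactions = reactions
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_chemistry
#' @export
read_chemistry <- function(path) {
  doc <- jsonlite::read_json(path)
  species <- dplyr::bind_rows(purrr::map(doc$species, function(s) {
    tibble(sequence = s$sequence, is_food = isTRUE(s$is_food),
           external_conc = s$external_concentration %||% 0,
           k_cont = s$k_cont %||% 0,
           diffusion_D = s$diffusion_D %||% 0)
  }))
  rows <- purrr::map(doc$reactions, function(r) {
    ov <- r$overrides %||% list()
    cats <- as.character(unlist(r$catalysts))
    if (identical(r$kind, "cleavage")) {
      cleavage_reaction(r$substrates[[1]], r$cut_position, cats,
                        k_cleav = ov$k_cleav %||% NA_real_)
    } else {
      condensation_reaction(
        r$substrates[[1]], r$substrates[[2]], cats,
        complex_substrate = r$complex_substrate %||% 1L,
        k_assoc = ov$k_assoc %||% NA_real_,
        k_diss = ov$k_diss %||% NA_real_,
        k_cond = ov$k_cond %||% NA_real_
      )
    }
  })
  kd <- doc$kinetic_defaults
  chemistry(
    alphabet = as.character(unlist(doc$alphabet)),
    l_max = doc$l_max, l_perm = doc$l_perm,
    species = species,
    reactions = dplyr::bind_rows(rows),
    kinetics = kinetic_params(k_cleav = kd$k_cleav, k_assoc = kd$k_assoc,
                              k_diss = kd$k_diss, k_cond = kd$k_cond)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import a hand-written reaction list from TSV
#'
#' Columns: `kind` (cleavage/condensation), `sub1`, `sub2` (empty for
#' cleavage), `cut_pos` (empty for condensation), `catalysts`
#' (comma-separated, may be empty). Useful for toy chemistries written by
#' hand.
#'
#' @param path TSV file path.
#' @return a reaction tibble suitable for [chemistry()].
#' @export
read_reactions_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    cats <- if (is.na(r$catalysts) || r$catalysts == "") character() else
      strsplit(r$catalysts, ",")[[1]]
    if (r$kind == "cleavage") {
      cleavage_reaction(r$sub1, as.integer(r$cut_pos), trimws(cats))
    } else {
      condensation_reaction(r$sub1, r$sub2, trimws(cats))
    }
  })
  dplyr::bind_rows(rows)
}
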