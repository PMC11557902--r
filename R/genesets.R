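#' Construct a gene-set library
#'
#' A gene-set library is a tibble with one row per set and columns `set_id`
#' (character, unique), `description` (character) and `genes` (list of
#' character vectors, each free of duplicates and non-empty). All library
#' operations in the package take and return this shape, so calls chain with
#' the pipe.
#'
#' @param set_id Character vector of unique set identifiers.
#' @param genes List of character vectors of member gene IDs, one per set.
#' @param description Character vector of free-text descriptions (recycled
#'   from length 1).
#' @return A `geneset_library` tibble.
#' @examples
#' gs_library(c("S1", "S2"), list(c("g1", "g2"), c("g2", "g3")))
#' @export
gs_library <- function(set_id, genes, description = "") {
  set_id <- as.character(set_id)
  if (length(description) == 1L) description <- rep(description, length(set_id))
  lib <- tibble::tibble(
    set_id = set_id,
    description = as.character(description),
    genes = lapply(genes, as.character)
  )
  validate_gs_library(lib)
}

validate_gs_library <- function(lib) {
  if (anyDuplicated(lib$set_id)) {
    dup <- unique(lib$set_id[duplicated(lib$set_id)])
    abort(paste0("duplicate set_id in library: ", paste(dup, collapse = ", ")))
  }
  if (any(vapply(lib$genes, anyDuplicated, 0L) > 0L)) {
    abort("duplicate member genes within a set")
  }
  if (any(lengths(lib$genes) == 0L)) {
    abort("library contains sets with zero members")
  }
  class(lib) <- unique(c("geneset_library", class(lib)))
  lib
}

#' Restrict a library to a background gene list
#'
#' Intersects every set's membership with the background (universe) of
#' detected genes; sets emptied by the intersection are removed. Gene IDs are
#' matched as exact case-sensitive strings.
#'
#' @param lib A gene-set library tibble (see [gs_library()]).
#' @param background Character vector of background gene IDs.
#' @return The restricted library; member order within each set is preserved.
#' @export
restrict_to_background <- function(lib, background) {
  stopifnot(length(background) > 0L)
  bg <- unique(as.character(background))
  out <- lib
  out$genes <- lapply(lib$genes, function(g) g[g %in% bg])
  out <- out[lengths(out$genes) > 0L, ]
  validate_gs_library(out)
}

#' Filter a library by set size
#'
#' Keeps sets whose membership size lies in `[min_size, max_size]`. Sizes are
#' evaluated on the library as given; restrict with
#' [restrict_to_background()] first to filter on detected-gene sizes (the
#' default behaviour of [run_ora()]).
#'
#' @inheritParams restrict_to_background
#' @param min_size Minimum membership size retained (default 5).
#' @param max_size Maximum membership size retained; `Inf` (default) means no
#'   upper bound.
#' @return The filtered library.
#' @export
filter_by_size <- function(lib, min_size = 5, max_size = Inf) {
  if (min_size < 1) abort("min_size must be >= 1")
  if (min_size > max_size) abort("min_size exceeds max_size")
  sizes <- lengths(lib$genes)
  out <- lib[sizes >= min_size & sizes <= max_size, ]
  validate_gs_library(out)
}

#' Union of all annotated genes in a library
#'
#' @inheritParams restrict_to_background
#' @return Character vector of every gene ID that belongs to at least one set.
#' @export
annotated_genes <- function(lib) {
  unique(unlist(lib$genes, use.names = FALSE))
}

#' Append the background as a gene set (the background-problem workaround)
#'
#' Adds one set containing every background gene. Tools that silently drop
#' unannotated genes from the universe are thereby forced to retain the full
#' background, which restores the correct hypergeometric denominator. The
#' appended set is bookkeeping only: [run_ora()] never reports it.
#'
#' @inheritParams restrict_to_background
#' @param universe_id Reserved identifier for the appended set.
#' @return The library with one extra set of size `length(unique(background))`.
#' @export
append_universe_set <- function(lib, background, universe_id = "__UNIVERSE__") {
  if (universe_id %in% lib$set_id) {
    abort(paste0("reserved set id already present: ", universe_id))
  }
  extra <- tibble::tibble(
    set_id = universe_id,
    description = "appended background universe",
    genes = list(unique(as.character(background)))
  )
  validate_gs_library(dplyr::bind_rows(lib, extra))
}
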