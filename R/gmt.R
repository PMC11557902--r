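#' Read a gene-set library from a GMT file
#'
#' Parses the tab-separated GMT dialect used by MSigDB and friends: one set
#' per line, fields are set id, free-text description, then member gene IDs.
#' Duplicate members within a line are collapsed with a warning; empty member
#' fields are ignored; lines left without members are dropped with a warning;
#' duplicate set ids are an error.
#'
#' @param path Path to a GMT file.
#' @return A `geneset_library` tibble (see [gs_library()]).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(validate_gs_library(tibble::tibble(
      set_id = character(), description = character(), genes = list()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(paste0(
      "malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields"
    ))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate set id in GMT: ", paste(dup, collapse = ", ")))
  }
  members <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g[nzchar(g)]
  })
  n_dup <- sum(lengths(members) - vapply(members, function(g) length(unique(g)), 0L))
  if (n_dup > 0L) {
    warn(paste0("collapsed ", n_dup, " duplicate member ID(s) in GMT"))
    members <- lapply(members, unique)
  }
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warn(paste0("dropped ", sum(empty), " set(s) with no members"))
  }
  lib <- tibble::tibble(
    set_id = ids[!empty],
    description = vapply(fields, `[[`, "", 2L)[!empty],
    genes = members[!empty]
  )
  validate_gs_library(lib)
}

#' Write a gene-set library to a GMT file
#'
#' @param lib A gene-set library tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  lines <- mapply(
    function(id, desc, g) paste(c(id, desc, g), collapse = "\t"),
    lib$set_id, lib$description, lib$genes
  )
  writeLines(as.character(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene list from a plain-text file
#'
#' One gene ID per line; blank lines and `#` comment lines are skipped;
#' duplicates are removed keeping first occurrence so input order is
#' preserved.
#'
#' @param path Path to a UTF-8 text file.
#' @return Character vector of unique gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Write a gene list to a plain-text file
#'
#' @param ids Character vector of gene IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path, useBytes = TRUE)
  invisible(path)
}
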