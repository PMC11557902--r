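#' Read a gene x sample count matrix from TSV
#'
#' Expects gene IDs in the first column and a header row of sample IDs.
#' Header comment lines starting with `#` are skipped.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (anyDuplicated(rownames(m))) abort("duplicate gene IDs in counts")
  if (anyDuplicated(colnames(m))) abort("duplicate sample IDs in counts")
  if (any(m < 0)) abort("negative counts")
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Gene x sample matrix.
#' @param path Output path.
#' @param metadata Optional named list echoed as `#` header comments (see
#'   [run_metadata()]).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, metadata = NULL) {
  df <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(counts)),
    tibble::as_tibble(counts)
  )
  write_result_tsv(df, path, metadata)
}

#' Provenance metadata for an analysis run
#'
#' Every result file this package writes starts with comment lines carrying
#' the tool version, a hash of the configuration that produced it, and the
#' seed, so a run can be reproduced from its outputs alone. The hash covers
#' the configuration values only — never output paths — so re-running with
#' the same settings yields the same hash.
#'
#' @param config A named list (or config object) of analysis parameters.
#' @param seed The seed used, if any.
#' @return A named character vector of metadata fields.
#' @export
run_metadata <- function(config = list(), seed = NULL) {
  c(
    tool = paste0("orabench ", as.character(utils::packageVersion("orabench"))),
    config_hash = config_hash(config),
    seed = if (is.null(seed)) "none" else as.character(seed)
  )
}

#' Hash of a configuration object
#'
#' Deterministic across sessions for the same parameter values; changing any
#' value changes the hash.
#'
#' @inheritParams run_metadata
#' @return A character hash.
#' @export
config_hash <- function(config) {
  plain <- lapply(unclass(config), function(x) {
    if (is.numeric(x)) format(x, digits = 15) else as.character(x)
  })
  plain <- plain[order(names(plain))]
  rlang::hash(plain)
}

#' Write a result tibble to TSV with a provenance header
#'
#' @param x A tibble; list-columns are flattened to comma-joined strings.
#' @param path Output path.
#' @param metadata Named character vector from [run_metadata()], written as
#'   leading `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, metadata = NULL) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], paste, "", collapse = ",")
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(paste0("# ", names(metadata), "=", metadata), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result TSV written by this package
#'
#' @param path Path to a TSV; `#` comment lines are skipped.
#' @return A tibble.
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Read differential-expression results from TSV
#'
#' Accepts any TSV with the `de_result` columns (`gene_id`, `base_mean`,
#' `log2_fold_change`, `test_statistic`, `p_value`, `fdr`), making the DE
#' engine pluggable: results imported from an external tool feed the
#' enrichment functions directly.
#'
#' @param path Path to a TSV file.
#' @return A `de_result` tibble.
#' @export
read_de_results <- function(path) {
  de <- read_result_tsv(path)
  needed <- c("gene_id", "base_mean", "log2_fold_change", "test_statistic",
              "p_value", "fdr")
  missing <- setdiff(needed, names(de))
  if (length(missing) > 0L) {
    abort(paste0("DE results lack column(s): ", paste(missing, collapse = ", ")))
  }
  class(de) <- c("de_result", class(de))
  de
}
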