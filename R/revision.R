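#' Merge overlapping intervals of one grouping label
#'
#' Collapses overlapping intervals into disjoint ones while preserving the
#' exact set of covered base pairs. Adjacent (touching but non-overlapping)
#' intervals are left separate: density results are identical either way, and
#' keeping them separate makes the merge a pure interval-union operation.
#'
#' @param t0,t1 Integer vectors of 0-based inclusive interval bounds for one
#'   label on one pseudomolecule.
#' @return A tibble with columns `t0`, `t1`: disjoint intervals sorted by
#'   `t0`, covering exactly the union of the input base pairs.
#' @export
#' @examples
#' merge_label_subset(c(100, 150), c(200, 300)) # -> single (100, 300)
merge_label_subset <- function(t0, t1) {
  stopifnot(length(t0) == length(t1))
  if (any(t0 > t1)) {
    cli::cli_abort("Invalid interval(s): t0 > t1.")
  }
  if (length(t0) == 0) {
    return(tibble(t0 = integer(), t1 = integer()))
  }
  # IRanges uses 1-based closed intervals; min.gapwidth = 0 merges overlaps
  # only, never mere adjacency.
  ir <- IRanges::reduce(IRanges::IRanges(start = t0 + 1L, end = t1 + 1L),
                        min.gapwidth = 0L)
  tibble(t0 = IRanges::start(ir) - 1L, t1 = IRanges::end(ir) - 1L)
}

#' Revise a TE annotation into disjoint per-grouping intervals
#'
#' The three-pass revision that makes bounded densities possible: first TEs
#' sharing an order are merged, then TEs sharing a superfamily, and finally
#' all TEs regardless of identity are merged into the synthetic
#' `"Total_TE_Density"` grouping. After revision, no two intervals within any
#' (pseudomolecule, level, label) subset share a base pair, so summing
#' overlaps can never double-count and densities stay within \[0, 1\].
#'
#' @param tes TE tibble from [read_te_annotation()] (optionally passed
#'   through [reclassify_identities()] first).
#' @return A tibble with columns `pseudomolecule`, `level` (`"order"`,
#'   `"superfamily"` or `"total"`), `label`, `t0`, `t1`, sorted by
#'   (`pseudomolecule`, `level`, `label`, `t0`).
#' @export
revise_te_annotation <- function(tes) {
  if (is.null(tes) || nrow(tes) == 0) {
    cli::cli_abort("Cannot revise an empty TE annotation.")
  }
  one_level <- function(df, labels, level_name) {
    df |>
      dplyr::mutate(label = labels) |>
      dplyr::group_by(.data$pseudomolecule, .data$label) |>
      dplyr::reframe(merge_label_subset(.data$t0, .data$t1)) |>
      dplyr::mutate(level = level_name)
  }
  dplyr::bind_rows(
    one_level(tes, tes$order, "order"),
    one_level(tes, tes$superfamily, "superfamily"),
    one_level(tes, rep(.TOTAL_LABEL, nrow(tes)), "total")
  ) |>
    dplyr::select("pseudomolecule", "level", "label", "t0", "t1") |>
    dplyr::arrange(.data$pseudomolecule, .data$level, .data$label, .data$t0)
}

#' Persist or reload a revised annotation
#'
#' Revision only needs to happen once per TE annotation; the result can be
#' cached as a cleaned-tsv with an extra `Revision_Level` column and reused
#' for later runs (e.g. with a different window set). The cache records the
#' MD5 digest of the source annotation; `read_revised_annotation()` refuses a
#' stale cache when the source file has changed.
#'
#' @param revised Tibble from [revise_te_annotation()].
#' @param path Cache file path (TSV).
#' @param source_path Optional path of the TE annotation the revision was
#'   computed from; its digest is stored for staleness checking.
#' @return `write_revised_annotation()` returns `path` invisibly;
#'   `read_revised_annotation()` returns the revised tibble.
#' @export
write_revised_annotation <- function(revised, path, source_path = NULL) {
  out <- tibble(
    Chromosome = revised$pseudomolecule,
    Revision_Level = revised$level,
    Label = revised$label,
    Start = revised$t0 + 1L,
    Stop = revised$t1 + 1L
  )
  header <- if (!is.null(source_path)) {
    sprintf("# source_md5: %s\n", unname(tools::md5sum(source_path)))
  }
  lines <- c(header, readr::format_tsv(out))
  writeLines(lines, path, sep = "")
  invisible(path)
}

#' @rdname write_revised_annotation
#' @export
read_revised_annotation <- function(path, source_path = NULL) {
  check_file_exists(path)
  first <- readLines(path, n = 1L)
  if (!is.null(source_path) && startsWith(first, "# source_md5: ")) {
    cached <- sub("^# source_md5: ", "", first)
    now <- unname(tools::md5sum(source_path))
    if (!identical(cached, now)) {
      cli::cli_abort(
        "Revised annotation {.file {path}} is stale: {.file {source_path}} has changed since it was written."
      )
    }
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  tibble(
    pseudomolecule = as.character(df$Chromosome),
    level = as.character(df$Revision_Level),
    label = as.character(df$Label),
    t0 = as.integer(df$Start) - 1L,
    t1 = as.integer(df$Stop) - 1L
  )
}
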