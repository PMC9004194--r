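#' Read a gene annotation
#'
#' Parses a gene annotation into the internal coordinate model: one interval
#' per gene, spanning the first-exon start to the last-exon stop, with 0-based
#' coordinates inclusive on both ends. The on-disk formats are 1-based
#' inclusive, so both bounds are shifted by -1 on ingestion.
#'
#' The `cleaned-tsv` dialect is a tab-separated file with a header row and
#' columns `Chromosome`, `Gene_Name`, `Start`, `Stop`, `Strand` (`Length` is
#' accepted and ignored; it is recomputed). The `gff3` dialect keeps only
#' `gene` feature lines (mRNA/exon children are ignored) and takes the gene
#' name from the `ID` attribute (falling back to `Name`).
#'
#' @param path Path to the annotation file.
#' @param dialect Either `"cleaned-tsv"` or `"gff3"`.
#' @return A tibble with one row per gene and columns `pseudomolecule`,
#'   `name`, `g0`, `g1` (0-based inclusive bounds), `strand` (`"sense"` or
#'   `"antisense"`), and `length` (`g1 - g0 + 1`), sorted by
#'   (`pseudomolecule`, `g0`).
#' @seealso [read_te_annotation()], [write_gene_annotation()]
#' @export
read_gene_annotation <- function(path, dialect = c("cleaned-tsv", "gff3")) {
  dialect <- rlang::arg_match(dialect)
  check_file_exists(path)
  raw <- if (dialect == "cleaned-tsv") {
    read_cleaned_tsv(path, c("Chromosome", "Gene_Name", "Start", "Stop", "Strand"))
  } else {
    read_gff3_genes(path)
  }
  genes <- tibble(
    pseudomolecule = as.character(raw$Chromosome),
    name = as.character(raw$Gene_Name),
    g0 = as.integer(raw$Start) - 1L,
    g1 = as.integer(raw$Stop) - 1L,
    strand = parse_strand(raw$Strand)
  )
  validate_intervals(genes$g0, genes$g1, path)
  dup <- unique(genes$name[duplicated(genes$name)])
  if (length(dup) > 0) {
    cli::cli_abort("Duplicate gene name(s) in {.file {path}}: {.val {dup}}.")
  }
  genes |>
    dplyr::mutate(length = .data$g1 - .data$g0 + 1L) |>
    dplyr::arrange(.data$pseudomolecule, .data$g0)
}

#' Read a TE annotation
#'
#' Parses a transposable-element annotation into the internal model, with the
#' same 1-based to 0-based coordinate shift as [read_gene_annotation()]. TE
#' classification strings of the RepeatMasker-style form `"ORDER/SUPERFAMILY"`
#' are split on the first `/`; a bare label is taken as the order with an
#' unknown superfamily. Records whose classification cannot be determined get
#' the sentinel labels `"Unknown_Order"` / `"Unknown_Superfam"`.
#'
#' The `cleaned-tsv` dialect has columns `Chromosome`, `Start`, `Stop`,
#' `Strand`, `Order`, `SuperFamily` (optional `Length`, recomputed). The
#' `gff3` dialect reads the classification from a `Classification` attribute
#' when present, otherwise from the feature `type` column.
#'
#' @inheritParams read_gene_annotation
#' @return A tibble with one row per TE and columns `pseudomolecule`, `t0`,
#'   `t1` (0-based inclusive), `order`, `superfamily`, `length`, sorted by
#'   (`pseudomolecule`, `t0`). TE strand is not retained: it plays no role in
#'   density.
#' @export
read_te_annotation <- function(path, dialect = c("cleaned-tsv", "gff3")) {
  dialect <- rlang::arg_match(dialect)
  check_file_exists(path)
  if (dialect == "cleaned-tsv") {
    raw <- read_cleaned_tsv(path, c("Chromosome", "Start", "Stop", "Order", "SuperFamily"))
    ord <- trimws(as.character(raw$Order))
    sup <- trimws(as.character(raw$SuperFamily))
  } else {
    raw <- read_gff3_tes(path)
    cls <- split_classification(raw$Classification)
    ord <- cls$order
    sup <- cls$superfamily
  }
  ord[is.na(ord) | ord == ""] <- .UNKNOWN_ORDER
  sup[is.na(sup) | sup == ""] <- .UNKNOWN_SUPERFAM
  tes <- tibble(
    pseudomolecule = as.character(raw$Chromosome),
    t0 = as.integer(raw$Start) - 1L,
    t1 = as.integer(raw$Stop) - 1L,
    order = ord,
    superfamily = sup
  )
  if (nrow(tes) == 0) {
    cli::cli_abort("TE annotation {.file {path}} is empty; nothing to compute.")
  }
  validate_intervals(tes$t0, tes$t1, path)
  tes |>
    dplyr::mutate(length = .data$t1 - .data$t0 + 1L) |>
    dplyr::arrange(.data$pseudomolecule, .data$t0)
}

#' Write annotations back to cleaned-tsv
#'
#' Inverse of the readers: internal 0-based inclusive coordinates are shifted
#' back to 1-based inclusive on disk, so read/write round-trips exactly.
#'
#' @param genes,tes Tibbles as returned by [read_gene_annotation()] /
#'   [read_te_annotation()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  out <- tibble(
    Chromosome = genes$pseudomolecule,
    Gene_Name = genes$name,
    Start = genes$g0 + 1L,
    Stop = genes$g1 + 1L,
    Strand = ifelse(genes$strand == "antisense", "-", "+"),
    Length = genes$g1 - genes$g0 + 1L
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
write_te_annotation <- function(tes, path) {
  out <- tibble(
    Chromosome = tes$pseudomolecule,
    Start = tes$t0 + 1L,
    Stop = tes$t1 + 1L,
    Strand = ".",
    Order = tes$order,
    SuperFamily = tes$superfamily,
    Length = tes$t1 - tes$t0 + 1L
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

check_file_exists <- function(path, call = rlang::caller_env()) {
  if (!file.exists(path)) {
    cli::cli_abort("Annotation file {.file {path}} does not exist.", call = call)
  }
}

read_cleaned_tsv <- function(path, required, call = rlang::caller_env()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    cli::cli_abort(
      "File {.file {path}} is missing required column{?s} {.field {missing}}.",
      call = call
    )
  }
  if ("Strand" %in% required && !"Strand" %in% names(raw)) {
    raw$Strand <- NA_character_
  }
  raw
}

# start > stop is a record-level error; report 1-based data line numbers.
validate_intervals <- function(start0, stop0, path, call = rlang::caller_env()) {
  bad <- which(start0 > stop0)
  if (length(bad) > 0) {
    cli::cli_abort(
      "Start > Stop in {.file {path}} at data line{?s} {bad}.",
      call = call
    )
  }
  if (any(start0 < 0)) {
    cli::cli_abort("Coordinates below 1 in {.file {path}}.", call = call)
  }
}

parse_strand <- function(x, call = rlang::caller_env()) {
  x <- as.character(x)
  x[is.na(x)] <- "."
  known <- x %in% c("+", "-", ".")
  if (!all(known)) {
    cli::cli_abort(
      "Unknown strand symbol{?s} {.val {unique(x[!known])}}; expected +, - or . .",
      call = call
    )
  }
  if (any(x == ".")) {
    cli::cli_warn("{sum(x == '.')} record{?s} without strand treated as sense.")
  }
  ifelse(x == "-", "antisense", "sense")
}

split_classification <- function(x) {
  x <- trimws(as.character(x))
  has_slash <- grepl("/", x, fixed = TRUE)
  ord <- ifelse(has_slash, sub("/.*$", "", x), x)
  sup <- ifelse(has_slash, sub("^[^/]*/", "", x), NA_character_)
  list(order = ord, superfamily = sup)
}

import_gff3_df <- function(path) {
  rlang::check_installed("rtracklayer", reason = "to read GFF3 annotations")
  as.data.frame(rtracklayer::import(path, format = "gff3"))
}

read_gff3_genes <- function(path) {
  df <- import_gff3_df(path)
  df <- df[!is.na(df$type) & as.character(df$type) == "gene", , drop = FALSE]
  if (nrow(df) == 0) {
    cli::cli_abort("No {.val gene} feature lines found in {.file {path}}.")
  }
  name <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  if ("Name" %in% names(df)) {
    name <- dplyr::coalesce(name, as.character(df$Name))
  }
  if (anyNA(name)) {
    cli::cli_abort("GFF3 gene line{?s} without an ID or Name attribute in {.file {path}}.")
  }
  tibble(
    Chromosome = as.character(df$seqnames),
    Gene_Name = name,
    Start = df$start,
    Stop = df$end,
    Strand = sub("*", ".", as.character(df$strand), fixed = TRUE)
  )
}

read_gff3_tes <- function(path) {
  df <- import_gff3_df(path)
  cls <- if ("Classification" %in% names(df)) {
    as.character(df$Classification)
  } else {
    as.character(df$type)
  }
  tibble(
    Chromosome = as.character(df$seqnames),
    Start = df$start,
    Stop = df$end,
    Classification = cls
  )
}
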