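#' Write a pseudomolecule's density tensors to an HDF5 store
#'
#' One store per pseudomolecule holds both the order-level and the
#' superfamily-level tensor as 4-D double datasets (`ORDER_DENSITY`,
#' `SUPERFAMILY_DENSITY`, axis order identity x window x gene x direction),
#' the label vectors (`ORDER_NAMES`, `SUPERFAMILY_NAMES`, `WINDOWS`,
#' `GENE_NAMES`, `GENE_STRANDS`) and scalar attributes `GENOME_ID`,
#' `PSEUDOMOLECULE` and `SWAPPED`. Values are stored in raw left/intra/right
#' orientation (`SWAPPED = FALSE`); the strand-aware swap happens at read
#' time, never on disk.
#'
#' @param order_tensor,superfamily_tensor `density_tensor` objects from
#'   [compute_pseudomolecule_density()] sharing the same gene axis and
#'   windows.
#' @param path Output `.h5` path.
#' @param genome_id Genome identifier recorded in the store.
#' @param overwrite Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_density_store <- function(order_tensor, superfamily_tensor, path,
                                genome_id = "genome", overwrite = FALSE) {
  for (t in list(order_tensor, superfamily_tensor)) {
    if (!inherits(t, "density_tensor")) {
      cli::cli_abort("Tensors must be {.cls density_tensor} objects.")
    }
    if (isTRUE(t$swapped)) {
      cli::cli_abort("Refusing to persist a swapped (upstream/downstream) view; stores hold raw left/intra/right values.")
    }
    if (!identical(dim(t$values),
                   c(length(t$identities), length(t$windows), length(t$genes), 3L))) {
      cli::cli_abort("Tensor axis labels do not match the value array dimensions.")
    }
  }
  if (!identical(order_tensor$genes, superfamily_tensor$genes) ||
      !identical(order_tensor$windows, superfamily_tensor$windows) ||
      !identical(order_tensor$pseudomolecule, superfamily_tensor$pseudomolecule)) {
    cli::cli_abort("Order and superfamily tensors must share gene axis, windows and pseudomolecule.")
  }
  if (file.exists(path)) {
    if (!overwrite) cli::cli_abort("Store {.file {path}} already exists; use {.code overwrite = TRUE}.")
    file.remove(path)
  }

  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(order_tensor$values, path, "ORDER_DENSITY")
  rhdf5::h5write(superfamily_tensor$values, path, "SUPERFAMILY_DENSITY")
  rhdf5::h5write(order_tensor$identities, path, "ORDER_NAMES")
  rhdf5::h5write(superfamily_tensor$identities, path, "SUPERFAMILY_NAMES")
  rhdf5::h5write(as.integer(order_tensor$windows), path, "WINDOWS")
  rhdf5::h5write(order_tensor$genes, path, "GENE_NAMES")
  rhdf5::h5write(order_tensor$strands, path, "GENE_STRANDS")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(genome_id, fid, "GENOME_ID")
  rhdf5::h5writeAttribute(order_tensor$pseudomolecule, fid, "PSEUDOMOLECULE")
  rhdf5::h5writeAttribute(0L, fid, "SWAPPED")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Open a density store with the strand-aware swap applied
#'
#' Annotation files always list a gene's start as the smaller coordinate,
#' whatever its strand, so on disk the flank axes are "left" and "right". At
#' read time the left and right slices of every antisense gene are swapped so
#' that the accessor speaks the biological vocabulary: upstream, intragenic,
#' downstream. Sense genes are untouched, intragenic slices are never
#' swapped, and the file itself is never modified.
#'
#' @param path Path to a store written by [write_density_store()].
#' @return A `density_data` accessor: list with `genome_id`,
#'   `pseudomolecule`, `genes`, `strands`, `windows` and the two swapped
#'   tensors `order` and `superfamily` (direction axis upstream /
#'   intragenic / downstream, `swapped = TRUE`).
#' @export
read_density_store <- function(path) {
  check_file_exists(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)$name
  needed <- c("ORDER_DENSITY", "SUPERFAMILY_DENSITY", "ORDER_NAMES",
              "SUPERFAMILY_NAMES", "WINDOWS", "GENE_NAMES", "GENE_STRANDS")
  missing <- setdiff(needed, contents)
  if (length(missing) > 0) {
    cli::cli_abort("Store {.file {path}} is missing dataset{?s} {.val {missing}}.")
  }
  rd <- function(name) rhdf5::h5read(path, name)
  fid <- rhdf5::H5Fopen(path)
  genome_id <- as.character(rhdf5::h5readAttributes(fid, "/")$GENOME_ID)
  pseudomolecule <- as.character(rhdf5::h5readAttributes(fid, "/")$PSEUDOMOLECULE)
  rhdf5::H5Fclose(fid)

  genes <- as.character(rd("GENE_NAMES"))
  strands <- as.character(rd("GENE_STRANDS"))
  windows <- as.integer(rd("WINDOWS"))

  mk <- function(values, identities, level) {
    t <- new_density_tensor(
      values = values, identities = as.character(identities),
      windows = windows, genes = genes, strands = strands,
      pseudomolecule = pseudomolecule, level = level, swapped = FALSE
    )
    dimnames(t$values) <- list(
      identity = t$identities, window = as.character(windows),
      gene = genes, direction = .DIRECTIONS_RAW
    )
    swap_antisense(t)
  }
  structure(
    list(
      genome_id = genome_id, pseudomolecule = pseudomolecule,
      genes = genes, strands = strands, windows = windows,
      order = mk(rd("ORDER_DENSITY"), rd("ORDER_NAMES"), "order"),
      superfamily = mk(rd("SUPERFAMILY_DENSITY"), rd("SUPERFAMILY_NAMES"), "superfamily"),
      path = path
    ),
    class = "density_data"
  )
}

#' Swap antisense genes' flank slices
#'
#' Exchanges the left and right slices for every antisense gene and toggles
#' the tensor's `swapped` flag (renaming the direction axis between
#' left/intra/right and upstream/intragenic/downstream). The operation is an
#' involution: applying it twice restores the original tensor.
#'
#' @param tensor A `density_tensor`.
#' @return The tensor with antisense flanks exchanged and `swapped` toggled.
#' @export
swap_antisense <- function(tensor) {
  anti <- which(tensor$strands == "antisense")
  if (length(anti) > 0) {
    left <- tensor$values[, , anti, 1L, drop = FALSE]
    tensor$values[, , anti, 1L] <- tensor$values[, , anti, 3L, drop = FALSE]
    tensor$values[, , anti, 3L] <- left
  }
  tensor$swapped <- !isTRUE(tensor$swapped)
  dimnames(tensor$values)[[4]] <-
    if (tensor$swapped) .DIRECTIONS_SWAPPED else .DIRECTIONS_RAW
  tensor
}

#' @export
print.density_data <- function(x, ...) {
  cli::cli_text(
    "<density_data> genome {.val {x$genome_id}}, pseudomolecule {.val {x$pseudomolecule}}: ",
    "{length(x$genes)} gene{?s}, {length(x$windows)} window{?s}, ",
    "{length(x$order$identities)} order{?s}, {length(x$superfamily$identities)} superfamilies (swap applied)"
  )
  invisible(x)
}

#' Look up a single density value
#'
#' @param x A `density_data` accessor from [read_density_store()].
#' @param gene Gene name.
#' @param level `"order"` or `"superfamily"`.
#' @param identity Grouping label (including `"Total_TE_Density"`).
#' @param window Window length in bp.
#' @param direction `"upstream"`, `"intragenic"` or `"downstream"`
#'   (strand-aware; the antisense swap has already been applied). Intragenic
#'   values are independent of `window`.
#' @return The density, a single number in \[0, 1\].
#' @export
density_of <- function(x, gene, level = c("order", "superfamily"), identity,
                       window, direction = c("upstream", "intragenic", "downstream")) {
  stopifnot(inherits(x, "density_data"))
  level <- rlang::arg_match(level)
  direction <- rlang::arg_match(direction)
  tensor <- x[[level]]
  lookup <- function(value, axis, what) {
    i <- match(as.character(value), as.character(axis))
    if (is.na(i)) {
      cli::cli_abort(c(
        "Unknown {what} {.val {value}}.",
        "i" = "Valid options: {.val {axis}}."
      ))
    }
    i
  }
  gi <- lookup(gene, x$genes, "gene")
  ii <- lookup(identity, tensor$identities, paste0(level, " identity"))
  wi <- lookup(window, x$windows, "window")
  di <- match(direction, .DIRECTIONS_SWAPPED)
  unname(tensor$values[ii, wi, gi, di])
}
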