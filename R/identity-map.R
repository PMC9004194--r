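#' Read an identity-remapping file
#'
#' Identity maps rename TE groupings (e.g. `EnSpm_Cacta` to `CACTA`, or
#' carving `LINE/Penelope` elements out into their own `PLE` order) and/or
#' drop groupings entirely, at either the order or the superfamily level.
#'
#' Two on-disk forms are accepted. YAML:
#' ```yaml
#' level: order
#' rename:
#'   EnSpm_Cacta: CACTA
#' drop:
#'   - Simple_repeat
#' ```
#' or a TSV with columns `Level`, `Action` (`rename`/`drop`), `From`, `To`
#' (`To` empty for drops).
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or TSV file.
#' @return An identity map: a list with elements `level`, `rename` (named
#'   character vector, names are the labels to replace) and `drop`
#'   (character vector of labels to discard).
#' @export
read_identity_map <- function(path) {
  check_file_exists(path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    map <- identity_map(
      level = raw$level %||% "order",
      rename = unlist(raw$rename) %||% character(),
      drop = as.character(raw$drop %||% character())
    )
  } else {
    df <- read_cleaned_tsv(path, c("Level", "Action", "From"))
    lev <- unique(df$Level)
    if (length(lev) != 1) {
      cli::cli_abort("Identity-map file {.file {path}} must use a single level; found {.val {lev}}.")
    }
    ren <- df[df$Action == "rename", , drop = FALSE]
    map <- identity_map(
      level = lev,
      rename = setNames(as.character(ren$To), ren$From),
      drop = df$From[df$Action == "drop"]
    )
  }
  map
}

#' Construct an identity map in code
#'
#' @param level `"order"` or `"superfamily"`: which grouping level the rules
#'   apply to.
#' @param rename Named character vector; `c(old = "new")` pairs.
#' @param drop Character vector of labels whose records are discarded.
#' @return A validated identity map (list with `level`, `rename`, `drop`).
#' @export
#' @examples
#' identity_map("superfamily", rename = c(EnSpm_Cacta = "CACTA"))
identity_map <- function(level = c("order", "superfamily"),
                         rename = character(),
                         drop = character()) {
  level <- rlang::arg_match(level)
  rename <- unlist(rename) %||% character()
  if (length(rename) > 0 && (is.null(names(rename)) || any(names(rename) == ""))) {
    cli::cli_abort("{.arg rename} must be a named vector of old = \"new\" pairs.")
  }
  if (any(rename == "")) {
    cli::cli_abort("Rename rules may not map to the empty label.")
  }
  drop <- as.character(drop)
  clash <- intersect(drop, unname(rename))
  if (length(clash) > 0) {
    cli::cli_abort("Labels {.val {clash}} appear both as rename target and in the drop list.")
  }
  structure(list(level = level, rename = rename, drop = drop),
            class = "te_identity_map")
}

#' Rename or drop TE groupings
#'
#' Applies an identity map to a parsed TE annotation: every record whose
#' label (at the map's level) matches a rename rule is relabelled, and every
#' record whose label is in the drop list is removed. All other records pass
#' through unchanged. Rules that reference labels absent from the data
#' produce a warning, not an error.
#'
#' @param tes TE tibble from [read_te_annotation()].
#' @param map Identity map from [identity_map()] or [read_identity_map()].
#' @return The reclassified TE tibble; `nrow` equals the input minus the
#'   dropped records.
#' @export
reclassify_identities <- function(tes, map) {
  if (!inherits(map, "te_identity_map")) {
    cli::cli_abort("{.arg map} must be an identity map; see {.fun identity_map}.")
  }
  col <- if (map$level == "order") "order" else "superfamily"
  labels <- tes[[col]]
  referenced <- c(names(map$rename), map$drop)
  absent <- setdiff(referenced, labels)
  if (length(absent) > 0) {
    cli::cli_warn("Identity-map rule{?s} for label{?s} {.val {absent}} matched no records.")
  }
  keep <- !(labels %in% map$drop)
  out <- tes[keep, , drop = FALSE]
  hit <- out[[col]] %in% names(map$rename)
  out[[col]][hit] <- unname(map$rename[out[[col]][hit]])
  out
}
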