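#' Load a region-of-interest atlas table
#'
#' Reads a delimited atlas file with one row per parcellation region. Row
#' order defines the index order of every matrix in the pipeline: the i-th
#' atlas row corresponds to the i-th row/column of connectivity matrices.
#' Region ids are 1-based in files; indices returned by
#' [resolve_members()] are 0-based (documented on that function).
#'
#' @param path Path to a CSV file with header `id,label,abbreviation,x,y,z`.
#'   Coordinates are MNI millimetres at the region centre.
#' @return A data frame of class `atlas_table` with columns `id` (integer),
#'   `label`, `abbreviation` (character) and `x`, `y`, `z` (numeric).
#' @examples
#' atlas <- aal90_atlas()
#' nrow(atlas)      # 90
#' atlas$label[1]   # "Precentral_L"
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "label", "abbreviation", "x", "y", "z")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("atlas file is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) stop("atlas file has no regions")
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v))
      stop("non-numeric coordinate in atlas column '", col, "'")
    raw[[col]] <- v
  }
  ids <- suppressWarnings(as.integer(raw$id))
  if (anyNA(ids)) stop("non-integer region id in atlas file")
  if (anyDuplicated(ids)) stop("duplicate region id in atlas file")
  if (anyDuplicated(raw$label)) {
    dup <- unique(raw$label[duplicated(raw$label)])
    stop("duplicate region label(s) in atlas file: ",
         paste(dup, collapse = ", "))
  }
  out <- data.frame(
    id = ids,
    label = as.character(raw$label),
    abbreviation = as.character(raw$abbreviation),
    x = raw$x, y = raw$y, z = raw$z,
    stringsAsFactors = FALSE
  )
  class(out) <- c("atlas_table", "data.frame")
  out
}

#' The bundled 90-region AAL atlas
#'
#' Labels, abbreviations and MNI centre coordinates of the 90 cortical and
#' subcortical regions of the Automated Anatomical Labelling atlas, 45 per
#' hemisphere, left/right homologues interleaved (odd ids = left, even =
#' right).
#'
#' @return An `atlas_table` with 90 rows.
#' @export
aal90_atlas <- function() {
  load_atlas(system.file("extdata", "aal90_mni.csv", package = "rsfcnet",
                         mustWork = TRUE))
}

#' Define a named node set (resting-state network)
#'
#' @param name Network name, e.g. `"VN"`.
#' @param members Character vector of atlas labels belonging to the network.
#' @return A list of class `network_definition` with elements `name` and
#'   `members`.
#' @export
network_definition <- function(name, members) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("network name must be a single non-empty string")
  members <- as.character(members)
  if (length(members) == 0L)
    stop("network '", name, "' has no members")
  structure(list(name = name, members = members),
            class = "network_definition")
}

#' Default resting-state network definitions
#'
#' The four networks analysed by the pipeline over the AAL-90 atlas:
#' visual (VN, 12 regions: calcarine, cuneus, lingual, superior/middle/
#' inferior occipital, bilateral), default mode (DMN, 12), fronto-parietal
#' attentional (AN, 18) and salience (SN, 10). A YAML/JSON file with the
#' same `name: [labels]` layout can be supplied to override them.
#'
#' @param path Optional path to a YAML or JSON network definition file.
#' @return Named list of [network_definition()] objects.
#' @export
default_networks <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_networks.yaml",
                        package = "rsfcnet", mustWork = TRUE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("network file must map network names to label lists")
  stats::setNames(
    lapply(names(raw), function(nm) network_definition(nm, raw[[nm]])),
    names(raw)
  )
}

#' Resolve network members to atlas indices
#'
#' Maps a network's member labels to positions in the atlas row order.
#' Indices are returned 0-based (matching the convention used for exported
#' files and logs); add 1 for R subsetting, or use the `one_based`
#' convenience argument.
#'
#' @param atlas An `atlas_table`.
#' @param net A `network_definition`.
#' @param one_based Return 1-based indices suitable for direct R indexing.
#' @return Sorted, duplicate-free integer indices.
#' @examples
#' idx <- resolve_members(aal90_atlas(), default_networks()$VN)
#' range(idx) + 1L  # AAL rows 43..54
#' @export
resolve_members <- function(atlas, net, one_based = FALSE) {
  stopifnot(inherits(atlas, "atlas_table"),
            inherits(net, "network_definition"))
  pos <- match(net$members, atlas$label)
  if (anyNA(pos)) {
    bad <- net$members[is.na(pos)]
    stop("network '", net$name, "' has member(s) not in the atlas: ",
         paste(bad, collapse = ", "))
  }
  idx <- sort(unique(pos))
  if (one_based) idx else idx - 1L
}
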