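#' DMN nodes and their subsystem assignment
#'
#' The canonical parcellation used throughout the package: 11 default-mode
#' network (DMN) nodes grouped into the three Andrews-Hanna subsystems —
#' dorsomedial (5 nodes: TP, vlTC, dlTC, dmPFC, TPJ), medial temporal
#' (3 nodes: pHG, HIP, pIPL) and midline core (3 nodes: PCU, PCC, vmPFC).
#' Node ids are assigned 0-based in lexicographic order of the abbreviation,
#' which fixes a deterministic canonical order for node-pair keys and file
#' columns. Nodes are abstract labels; no spatial information is attached.
#'
#' @return a tibble with columns `node_id` (0-10), `abbreviation`, `name`
#'   and `subsystem` (one of `"dorsomedial"`, `"medial_temporal"`,
#'   `"midline_core"`).
#' @examples
#' dmn_nodes()
#' @export
dmn_nodes <- function() {
  nodes <- tibble::tribble(
    ~abbreviation, ~name,                                ~subsystem,
    "TP",    "temporal pole",                            "dorsomedial",
    "vlTC",  "ventrolateral temporal cortex",            "dorsomedial",
    "dlTC",  "dorsolateral temporal cortex",             "dorsomedial",
    "dmPFC", "dorsomedial prefrontal cortex",            "dorsomedial",
    "TPJ",   "temporoparietal junction",                 "dorsomedial",
    "pHG",   "parahippocampal gyrus",                    "medial_temporal",
    "HIP",   "hippocampus",                              "medial_temporal",
    "pIPL",  "posterior inferior parietal lobule",       "medial_temporal",
    "PCU",   "precuneus",                                "midline_core",
    "PCC",   "posterior cingulate cortex",               "midline_core",
    "vmPFC", "ventromedial prefrontal cortex",           "midline_core"
  )
  nodes <- nodes[order(tolower(nodes$abbreviation), method = "radix"), ]
  nodes$node_id <- seq_len(nrow(nodes)) - 1L
  dplyr::select(nodes, "node_id", "abbreviation", "name", "subsystem")
}

#' Read a node/subsystem map from a configuration file
#'
#' Alternative parcellations can be supplied as YAML, JSON or CSV with fields
#' `abbreviation`, `name` (optional) and `subsystem`. Node ids are assigned
#' in lexicographic abbreviation order, exactly as for [dmn_nodes()].
#'
#' @param path file path; format inferred from the extension
#'   (`.yaml`/`.yml`, `.json`, `.csv`).
#' @return a subsystem-map tibble (see [dmn_nodes()]).
#' @export
read_subsystem_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = purrr::map_dfr(yaml::read_yaml(path), tibble::as_tibble),
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    csv  = readr::read_csv(path, show_col_types = FALSE),
    abort(paste0("unsupported subsystem map format: '.", ext, "'"))
  )
  if (!all(c("abbreviation", "subsystem") %in% names(raw))) {
    abort("subsystem map needs columns 'abbreviation' and 'subsystem'")
  }
  if (!"name" %in% names(raw)) raw$name <- raw$abbreviation
  raw <- raw[order(tolower(raw$abbreviation), method = "radix"), ]
  raw$node_id <- seq_len(nrow(raw)) - 1L
  out <- dplyr::select(raw, "node_id", "abbreviation", "name", "subsystem")
  validate_subsystem_map(out)
  out
}

#' Validate a subsystem map
#'
#' Checks the structural invariants every downstream stage relies on:
#' unique abbreviations, contiguous 0-based `node_id`, and at least two
#' nodes. For the canonical 11-node map the subsystem sizes (5/3/3) are also
#' enforced.
#'
#' @param map a subsystem-map tibble.
#' @return `map`, invisibly, if valid; otherwise an error.
#' @export
validate_subsystem_map <- function(map) {
  if (!is.data.frame(map) || nrow(map) < 2L) {
    abort("invalid subsystem map: need at least 2 nodes")
  }
  if (anyDuplicated(map$abbreviation)) {
    abort("invalid subsystem map: duplicated abbreviations")
  }
  if (!identical(sort(map$node_id), seq_len(nrow(map)) - 1L) &&
      !identical(as.integer(sort(map$node_id)), seq_len(nrow(map)) - 1L)) {
    abort("invalid subsystem map: node_id must be a contiguous 0-based range")
  }
  canon <- c("dorsomedial", "medial_temporal", "midline_core")
  if (nrow(map) == 11L && all(map$subsystem %in% canon)) {
    sizes <- table(factor(map$subsystem, levels = canon))
    if (!identical(as.integer(sizes), c(5L, 3L, 3L))) {
      abort("canonical 11-node map must have subsystem sizes 5/3/3")
    }
  }
  invisible(map)
}

# Short block labels for the three canonical subsystems; generic fall-back
# labels for alternative parcellations.
block_label <- function(s1, s2) {
  intra <- c(dorsomedial = "intra_dorsomedial",
             medial_temporal = "intra_medial_temporal",
             midline_core = "intra_midline")
  inter <- c("dorsomedial|midline_core" = "dm_midline",
             "medial_temporal|midline_core" = "mtl_midline",
             "dorsomedial|medial_temporal" = "dm_mtl")
  same <- s1 == s2
  out <- character(length(s1))
  out[same] <- dplyr::coalesce(intra[s1[same]], paste0("intra_", s1[same]))
  key <- paste(pmin(s1[!same], s2[!same]), pmax(s1[!same], s2[!same]), sep = "|")
  out[!same] <- dplyr::coalesce(inter[key], gsub("\\|", "_", key))
  unname(out)
}

#' Enumerate all unordered node pairs
#'
#' Produces the full set of node pairs in deterministic canonical order
#' (lexicographic on `(a, b)` node ids); for the canonical 11-node map this
#' yields the 55 pairwise connectivity measures. Each pair carries a stable
#' key `"A-B"` used as a column name in connectivity tables, and its
#' subsystem block label.
#'
#' @param map a subsystem map, default [dmn_nodes()].
#' @return a tibble with columns `a`, `b` (node ids, `a < b`), `pair`
#'   (key `"abbrevA-abbrevB"`), `subsystem_a`, `subsystem_b`, `block`.
#' @examples
#' nrow(dmn_node_pairs()) # 55
#' dplyr::count(dmn_node_pairs(), block)
#' @export
dmn_node_pairs <- function(map = dmn_nodes()) {
  validate_subsystem_map(map)
  map <- map[order(map$node_id), ]
  n <- nrow(map)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  a <- idx[, "row"] - 1L
  b <- idx[, "col"] - 1L
  abbr <- map$abbreviation
  subs <- map$subsystem
  tibble::tibble(
    a = a, b = b,
    pair = paste(abbr[a + 1L], abbr[b + 1L], sep = "-"),
    subsystem_a = subs[a + 1L],
    subsystem_b = subs[b + 1L],
    block = block_label(subs[a + 1L], subs[b + 1L])
  )
}

#' Classify a node pair into its subsystem block
#'
#' Symmetric in argument order: the block is fully determined by the two
#' nodes' subsystems (e.g. PCU with dmPFC is `dm_midline`, PCU with PCC is
#' `intra_midline`).
#'
#' @param a,b node abbreviations (vectorized).
#' @param map a subsystem map.
#' @return character vector of block labels.
#' @examples
#' classify_pair("PCU", "dmPFC") # "dm_midline"
#' @export
classify_pair <- function(a, b, map = dmn_nodes()) {
  validate_subsystem_map(map)
  sa <- map$subsystem[match(a, map$abbreviation)]
  sb <- map$subsystem[match(b, map$abbreviation)]
  if (anyNA(sa) || anyNA(sb)) {
    abort(paste0("unknown node abbreviation: ",
                 paste(setdiff(c(a, b), map$abbreviation), collapse = ", ")))
  }
  block_label(sa, sb)
}

#' Node pairs spanning two subsystems
#'
#' All pairs with one node in subsystem `A` and the other in subsystem `B`
#' (`A != B`): 15 pairs for midline-dorsomedial, 9 for midline-temporal and
#' 15 for dorsomedial-temporal under the canonical map.
#'
#' @param A,B subsystem labels, must differ.
#' @param map a subsystem map.
#' @return the subset of [dmn_node_pairs()] rows whose block is the `A`-`B`
#'   block.
#' @export
inter_block_pairs <- function(A, B, map = dmn_nodes()) {
  if (identical(A, B)) {
    abort("A and B must be different subsystems (use the intra block instead)")
  }
  if (!all(c(A, B) %in% map$subsystem)) {
    abort("unknown subsystem label")
  }
  pairs <- dmn_node_pairs(map)
  lab <- block_label(A, B)
  dplyr::filter(pairs, .data$block == lab)
}

# Canonical "X-Y" key for arbitrary abbreviation order, matching
# dmn_node_pairs(); errors on unknown abbreviations.
normalize_pair_key <- function(pair, map = dmn_nodes()) {
  parts <- strsplit(pair, "-", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) abort(paste0("malformed pair key: ", paste(p, collapse = "-")))
    i <- match(p, map$abbreviation)
    if (anyNA(i)) abort(paste0("unknown node abbreviation in pair key: ",
                               paste(p[is.na(i)], collapse = ", ")))
    paste(p[order(i)], collapse = "-")
  }, character(1))
}
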