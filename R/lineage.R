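#' Haplogroup tree with defining variants
#'
#' A rooted phylogeny for a non-recombining (Y or mitochondrial) marker set.
#' Each non-root node represents the clade entered through the edge from its
#' parent; the edge carries one or more defining variants (markers whose
#' derived state is observed in every member of the clade). Nodes carry a
#' geographic-origin label.
#'
#' @param nodes Tibble with columns `node`, `parent` (`NA` for the root) and
#'   `geography`.
#' @param markers Tibble with columns `marker_id` and `node` (the child node
#'   of the edge the variant defines) and optionally `derived_allele`.
#' @return An object of class `fsnp_haplogroup_tree`.
#' @export
haplogroup_tree <- function(nodes, markers) {
  nodes <- as_tibble(nodes)
  markers <- as_tibble(markers)
  root <- nodes$node[is.na(nodes$parent)]
  if (length(root) != 1) stop("tree must have exactly one root")
  if (!all(stats::na.omit(nodes$parent) %in% nodes$node)) {
    stop("parent references unknown node")
  }
  if (anyDuplicated(markers$marker_id)) {
    stop("a defining variant may appear on exactly one edge")
  }
  if (!all(markers$node %in% nodes$node)) stop("marker on unknown node")
  nodes$depth <- node_depths(nodes)
  if (anyNA(nodes$depth)) stop("node unreachable from root")
  structure(list(nodes = nodes, markers = markers, root = root),
            class = "fsnp_haplogroup_tree")
}

node_depths <- function(nodes) {
  depth <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$node)
  depth[nodes$node[is.na(nodes$parent)]] <- 0
  repeat {
    todo <- is.na(depth) & !is.na(depth[nodes$parent])
    if (!any(todo, na.rm = TRUE)) break
    depth[nodes$node[which(todo)]] <- depth[nodes$parent[which(todo)]] + 1
  }
  unname(depth[nodes$node])
}

#' @export
print.fsnp_haplogroup_tree <- function(x, ...) {
  cat("<fsnp_haplogroup_tree> ", nrow(x$nodes), " nodes, ",
      nrow(x$markers), " defining variants, root ", x$root, "\n", sep = "")
  invisible(x)
}

# ancestors of `node` from root (excluding root), i.e. the path of clades
path_to <- function(tree, node) {
  path <- character()
  cur <- node
  parents <- stats::setNames(tree$nodes$parent, tree$nodes$node)
  while (!is.na(parents[[cur]])) {
    path <- c(cur, path)
    cur <- parents[[cur]]
  }
  path
}

#' Synthetic haplogroup tree fixture
#'
#' Builds a small abstract phylogeny (root plus four clades per geographic
#' region) with defining variants distributed round-robin over its edges.
#' The labels are abstract stand-ins, not a published nomenclature; real
#' trees can be loaded through [read_haplogroup_tree()] in the same format.
#'
#' @param type `"y"` or `"mt"` (controls marker-name prefix).
#' @param n_markers Number of defining variants (default 50).
#' @param regions Geographic regions, one top-level clade each.
#' @return An [haplogroup_tree()].
#' @export
synthetic_haplogroup_tree <- function(type = c("y", "mt"), n_markers = 50,
                                      regions = c("Africa", "Western Eurasia",
                                                  "East Asia", "South Asia",
                                                  "Americas")) {
  type <- match.arg(type)
  top <- LETTERS[seq_along(regions)]
  # clade depth adapts to the marker budget: at least one defining variant
  # per edge
  per_region <- max(1, min(4, n_markers %/% length(regions)))
  if (n_markers < length(regions)) {
    stop("need at least one defining variant per region (",
         length(regions), ")")
  }
  nodes <- tibble(node = "ROOT", parent = NA_character_,
                  geography = NA_character_)
  for (i in seq_along(regions)) {
    h <- top[i]
    sub <- list(
      list(node = h, parent = "ROOT"),
      list(node = c(h, paste0(h, "1")), parent = c("ROOT", h)),
      list(node = c(h, paste0(h, "1"), paste0(h, "2")),
           parent = c("ROOT", h, h)),
      list(node = c(h, paste0(h, "1"), paste0(h, "2"), paste0(h, "1a")),
           parent = c("ROOT", h, h, paste0(h, "1")))
    )[[per_region]]
    nodes <- dplyr::bind_rows(nodes, tibble(
      node = sub$node, parent = sub$parent, geography = regions[i]
    ))
  }
  edges <- nodes$node[-1]
  markers <- tibble(
    marker_id = paste0(type, "_", seq_len(n_markers)),
    node = rep_len(edges, n_markers),
    derived_allele = "alt"
  )
  haplogroup_tree(nodes, markers)
}

#' Write a haplogroup tree (newick + annotation TSV)
#'
#' @param tree An [haplogroup_tree()].
#' @param newick_path,annotation_path Output paths.
#' @return `newick_path`, invisibly.
#' @export
write_haplogroup_tree <- function(tree, newick_path, annotation_path) {
  children <- split(tree$nodes$node[-match(tree$root, tree$nodes$node)],
                    tree$nodes$parent[-match(tree$root, tree$nodes$node)])
  build <- function(node) {
    kids <- children[[node]]
    if (is.null(kids)) return(node)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", node)
  }
  writeLines(paste0(build(tree$root), ";"), newick_path)
  ann <- dplyr::left_join(tree$nodes[, c("node", "geography")],
                          tree$markers, by = "node")
  readr::write_tsv(ann[, c("node", "marker_id", "derived_allele", "geography")],
                   annotation_path, na = "NA", progress = FALSE)
  invisible(newick_path)
}

#' Read a haplogroup tree from newick + annotation TSV
#'
#' The newick topology (internal nodes labelled) is parsed with \pkg{ape};
#' the annotation TSV carries one row per defining variant
#' (`node`, `marker_id`, `derived_allele`, `geography`) plus rows with a
#' missing `marker_id` for nodes without variants.
#'
#' @param newick_path,annotation_path Input paths.
#' @return An [haplogroup_tree()].
#' @export
read_haplogroup_tree <- function(newick_path, annotation_path) {
  phy <- ape::read.tree(newick_path)
  labels <- c(phy$tip.label, phy$node.label)
  parent <- stats::setNames(rep(NA_character_, length(labels)), labels)
  for (i in seq_len(nrow(phy$edge))) {
    parent[labels[phy$edge[i, 2]]] <- labels[phy$edge[i, 1]]
  }
  ann <- readr::read_tsv(annotation_path, col_types = "cccc", na = "NA",
                         progress = FALSE)
  geo <- dplyr::distinct(ann[, c("node", "geography")])
  nodes <- tibble(node = names(parent), parent = unname(parent))
  nodes <- dplyr::left_join(nodes, geo, by = "node")
  markers <- ann[!is.na(ann$marker_id), c("marker_id", "node", "derived_allele")]
  haplogroup_tree(nodes, markers)
}

#' Call a haplogroup from haploid marker states
#'
#' Assigns the deepest node of the tree whose root-path defining variants are
#' observed in the derived state at a support fraction of at least
#' `min_support` (computed over non-missing path markers) while at most
#' `max_conflicts` derived states are observed off the path. With no
#' non-missing calls at all the result is `no_call` (which, for the Y tree,
#' signals absence of male DNA). Ties at equal depth are broken by support
#' fraction.
#'
#' @param states Named vector of haploid states over the tree's markers
#'   (0 ancestral, 1 derived, `NA` missing). Markers absent from the tree are
#'   ignored with a warning.
#' @param tree An [haplogroup_tree()].
#' @param min_support Minimum observed-derived fraction along the path.
#' @param max_conflicts Maximum derived states observed off the path.
#' @return One-row tibble: `node`, `depth`, `geography`,
#'   `n_derived_observed`, `n_expected_on_path`, `n_path_observed`,
#'   `support`, `conflicts`, `no_call`.
#' @export
call_haplogroup <- function(states, tree, min_support = 0.8,
                            max_conflicts = 1) {
  unknown <- setdiff(names(states), tree$markers$marker_id)
  if (length(unknown)) {
    warning(length(unknown), " marker(s) not in tree ignored")
    states <- states[setdiff(names(states), unknown)]
  }
  states <- states[tree$markers$marker_id[tree$markers$marker_id %in%
                                            names(states)]]
  no_call_row <- tibble(
    node = NA_character_, depth = NA_real_, geography = NA_character_,
    n_derived_observed = 0L, n_expected_on_path = 0L, n_path_observed = 0L,
    support = NA_real_, conflicts = NA_integer_, no_call = TRUE
  )
  if (length(states) == 0 || all(is.na(states))) return(no_call_row)
  marker_node <- stats::setNames(tree$markers$node, tree$markers$marker_id)
  derived_obs <- names(states)[!is.na(states) & states == 1]
  total_derived <- length(derived_obs)
  cand <- purrr::map_dfr(tree$nodes$node, function(nd) {
    path <- path_to(tree, nd)
    pm <- names(marker_node)[marker_node %in% path]
    st <- states[pm]
    n_obs <- sum(!is.na(st))
    n_der <- sum(st == 1, na.rm = TRUE)
    support <- if (n_obs > 0) n_der / n_obs else if (length(pm) == 0) 1 else NA_real_
    tibble(
      node = nd,
      depth = tree$nodes$depth[tree$nodes$node == nd],
      geography = tree$nodes$geography[tree$nodes$node == nd],
      n_derived_observed = as.integer(n_der),
      n_expected_on_path = length(pm),
      n_path_observed = as.integer(n_obs),
      support = support,
      conflicts = as.integer(total_derived - n_der)
    )
  })
  ok <- !is.na(cand$support) & cand$support >= min_support &
    cand$conflicts <= max_conflicts
  if (!any(ok)) return(no_call_row)
  best <- cand[ok, ]
  best <- best[order(-best$depth, -best$support), ][1, ]
  best$no_call <- FALSE
  best
}

#' Call haplogroups for every sample in a cohort
#'
#' @param g A [genotype_matrix()].
#' @param tree An [haplogroup_tree()].
#' @param class Chromosome class carrying the tree's markers (`"Y"` or
#'   `"mt"`).
#' @inheritParams call_haplogroup
#' @return A tibble with one row per sample (columns of [call_haplogroup()]
#'   plus `sample_id`).
#' @export
call_haplogroups <- function(g, tree, class = c("Y", "mt"),
                             min_support = 0.8, max_conflicts = 1) {
  class <- match.arg(class)
  idx <- markers_of_class(g, class)
  idx <- idx[g$panel$marker_id[idx] %in% tree$markers$marker_id]
  purrr::map_dfr(rownames(g$dosage), function(s) {
    states <- g$dosage[s, idx]
    names(states) <- g$panel$marker_id[idx]
    dplyr::bind_cols(tibble(sample_id = s),
                     call_haplogroup(states, tree, min_support, max_conflicts))
  })
}

#' Cross-check uniparental lineages against biparental ancestry
#'
#' Cross-tabulates the geographic origin of the Y and mitochondrial
#' haplogroup calls against the biparental (genome-wide) ancestry
#' assignment. Disagreements are flagged as admixture signals — a divergent
#' maternal or paternal line is informative, not an error.
#'
#' @param lineage_y,lineage_mt Tibbles from [call_haplogroups()] (either may
#'   be `NULL`).
#' @param ancestry Tibble with `sample_id` and `assignment` (population label
#'   or `"multiple groups"`), or `NULL`.
#' @param geo_map Named character vector mapping population labels to
#'   geographic regions.
#' @return A tibble per sample: uniparental geographies, biparental
#'   assignment and region, `paternal_divergent` / `maternal_divergent`
#'   flags and a human-readable `note`.
#' @export
lineage_consistency <- function(lineage_y = NULL, lineage_mt = NULL,
                                ancestry = NULL, geo_map = NULL) {
  if (is.null(lineage_y) && is.null(lineage_mt) && is.null(ancestry)) {
    stop("at least one of lineage_y, lineage_mt, ancestry must be given")
  }
  pick <- function(x, nm) {
    if (is.null(x)) return(tibble(sample_id = character()))
    out <- tibble(sample_id = x$sample_id)
    out[[nm]] <- x$geography
    out
  }
  tb <- dplyr::full_join(pick(lineage_y, "y_geography"),
                         pick(lineage_mt, "mt_geography"), by = "sample_id")
  anc <- if (is.null(ancestry)) tibble(sample_id = character(),
                                       assignment = character())
  else ancestry[, c("sample_id", "assignment")]
  tb <- dplyr::full_join(tb, anc, by = "sample_id")
  for (col in c("y_geography", "mt_geography", "assignment")) {
    if (!col %in% names(tb)) tb[[col]] <- NA_character_
  }
  tb$biparental_region <- if (!is.null(geo_map)) {
    unname(geo_map[tb$assignment])
  } else NA_character_
  single <- !is.na(tb$assignment) & tb$assignment != "multiple groups"
  tb$paternal_divergent <- single & !is.na(tb$y_geography) &
    !is.na(tb$biparental_region) & tb$y_geography != tb$biparental_region
  tb$maternal_divergent <- single & !is.na(tb$mt_geography) &
    !is.na(tb$biparental_region) & tb$mt_geography != tb$biparental_region
  tb$note <- dplyr::case_when(
    !is.na(tb$y_geography) & !is.na(tb$mt_geography) &
      (tb$paternal_divergent | tb$maternal_divergent |
         (!is.na(tb$assignment) & tb$assignment == "multiple groups")) ~
      paste0("paternal ", tb$y_geography, " / maternal ", tb$mt_geography),
    tb$maternal_divergent ~ paste0("maternal-line admixture (",
                                   tb$mt_geography, ")"),
    tb$paternal_divergent ~ paste0("paternal-line admixture (",
                                   tb$y_geography, ")"),
    TRUE ~ "consistent"
  )
  tb
}
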