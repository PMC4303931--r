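#' Read a time-scaled phylogeny (chronogram)
#'
#' Parses a single Newick tree whose branch lengths are in time units
#' (million years). Tip labels must be unique and branch lengths present and
#' non-negative. Ultrametricity (equal root-to-tip path lengths, relative
#' tolerance 1e-6) is checked: a violation produces a warning, not an error,
#' since published chronograms are often only numerically ultrametric.
#'
#' @param file Path to a Newick file, or
#' @param text the Newick string itself (exactly one of the two).
#' @param tol Relative tolerance for the ultrametricity check.
#' @return An [ape::read.tree()] `"phylo"` object with normalized tip labels
#'   (whitespace trimmed, spaces converted to underscores).
#' @export
read_chronogram <- function(file = NULL, text = NULL, tol = 1e-6) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `file` or `text`", call. = FALSE)
  }
  tree <- if (is.null(text)) ape::read.tree(file = file) else
    ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop("input contains more than one tree", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a chronogram requires them",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  tree$tip.label <- normalize_species(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol * max(depths)) {
    warning("tree is not ultrametric (root-to-tip depths range ",
            format(min(depths)), " to ", format(max(depths)),
            "); patristic distances remain valid but are no longer ",
            "twice the divergence time", call. = FALSE)
  }
  tree
}

#' Normalize species names for exact matching
#'
#' Trims surrounding whitespace and converts internal whitespace to single
#' underscores, so `"Poa annua"`, `" Poa  annua "` and `"Poa_annua"` all
#' compare equal. No fuzzy matching is attempted: a silent near-miss would
#' corrupt the distance covariate.
#'
#' @param x Character vector of species names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x) {
  x <- gsub("(^[ \t]+)|([ \t]+$)", "", as.character(x))
  # Newick labels may arrive still wrapped in quotes
  x <- gsub("^(['\"])(.*)\\1$", "\\2", x)
  x <- gsub("(^[ \t]+)|([ \t]+$)", "", x)
  gsub("[ \t]+", "_", x)
}

#' Patristic distance between two tips
#'
#' The patristic (cophenetic) distance is the sum of branch lengths along the
#' unique path between two tips; on an ultrametric chronogram it equals twice
#' the divergence time of the pair. Distances are taken from the full
#' cophenetic matrix (the same quantity `ape::cophenetic.phylo` returns).
#'
#' @param tree A `"phylo"` chronogram.
#' @param sp1,sp2 Species names (vectorized; recycled against each other).
#' @return Numeric distances in the tree's branch-length units (My).
#' @export
patristic_distance <- function(tree, sp1, sp2) {
  D <- ape::cophenetic.phylo(tree)
  sp1 <- normalize_species(sp1)
  sp2 <- normalize_species(sp2)
  missing <- setdiff(unique(c(sp1, sp2)), rownames(D))
  if (length(missing)) {
    stop("species not found in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  args <- vctrs_recycle(sp1 = sp1, sp2 = sp2)
  D[cbind(args$sp1, args$sp2)]
}

#' Attach phylogenetic distances to an experiment table
#'
#' Adds a `phylo_distance` column holding, for each experiment, the distance
#' between its focal and soil-culturing species.
#'
#' @inheritParams validate_records
#' @param tree A `"phylo"` chronogram containing every species in `records`.
#' @param convention `"patristic"` (tip-to-tip path length; default, matching
#'   cophenetic distance) or `"divergence"` (half of it, the divergence time
#'   on an ultrametric tree). Slope estimates scale accordingly: a slope per
#'   unit divergence time is twice the slope per unit patristic distance.
#' @return `records` with a `phylo_distance` column appended (tibble).
#' @export
annotate_distances <- function(records, tree,
                               convention = c("patristic", "divergence")) {
  convention <- match.arg(convention)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    records$phylo_distance <- double()
    return(records)
  }
  d <- patristic_distance(tree, records$focal_species, records$soil_species)
  records$phylo_distance <- if (convention == "divergence") d / 2 else d
  records
}
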