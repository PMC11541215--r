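#' @include AllClasses.R pdb-io.R
NULL

#' MolecularGraph: connectivity view of a model
#'
#' @slot graph an igraph object whose vertices are atom indices.
#' @slot ringMembership logical per atom, TRUE iff the atom lies on at
#'   least one cycle.
#' @slot degrees integer per atom.
#' @export
setClass("MolecularGraph",
  representation(graph = "ANY", ringMembership = "logical",
                 degrees = "integer"))

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", length(object@degrees), "atoms,",
      igraph::ecount(object@graph), "bonds,",
      sum(object@ringMembership), "ring atoms\n")
})

#' Build the molecular graph of a model
#'
#' Vertices are atoms, edges are bonds (perceived by covalent-radius
#' distance cutoffs when the model carries none). Ring membership is
#' obtained by bridge detection: an atom is part of a cyclic structure iff
#' it has at least one incident non-bridge edge.
#'
#' @param model a \linkS4class{MolecularModel}.
#' @return A \linkS4class{MolecularGraph}.
#' @examples
#' g <- buildGraph(makeToyGlycan())
#' sum(g@ringMembership)   # the six pyranose ring atoms
#' @export
buildGraph <- function(model) {
  if (nrow(bonds(model)) == 0L) model <- perceiveBonds(model)
  n <- nAtoms(model)
  b <- bonds(model)
  g <- igraph::graph_from_edgelist(b, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (igraph::count_components(g) > 1L && nrow(b) > 0L)
    warning("disconnected molecular graph: components handled independently")
  ring <- rep(FALSE, n)
  if (nrow(b)) {
    br <- igraph::bridges(g)
    cyclic <- setdiff(seq_len(nrow(b)), as.integer(br))
    ring[unique(as.vector(b[cyclic, , drop = FALSE]))] <- TRUE
  }
  new("MolecularGraph", graph = g, ringMembership = ring,
      degrees = as.integer(igraph::degree(g)))
}

#' Enumerate rotatable torsion quartets
#'
#' Scans the non-cyclic part of the molecule for atoms with exactly two
#' bonds; each such atom anchors rotation axes through its neighbours. For
#' every axis j-k whose two ends can be extended (i bonded to j, l bonded
#' to k), one quartet (i, j, k, l) is emitted, deduplicated per axis and
#' ordered by the central-bond atom indices. The rotating set is the
#' component containing l after cutting the central bond.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @return A list of quartets; each element is a list with \code{atoms}
#'   (integer 4-vector i, j, k, l) and \code{rotatingSet} (integer vector).
#' @examples
#' tq <- detectTorsionPairs(buildGraph(makeToyGlycan()))
#' length(tq)   # >= 3 for the GlcNAc-like test molecule
#' @export
detectTorsionPairs <- function(graph) {
  g <- graph@graph
  deg <- graph@degrees
  ring <- graph@ringMembership
  cand <- which(deg == 2L & !ring)
  seen <- character(0)
  out <- list()
  for (j in cand) {
    nb <- as.integer(igraph::neighbors(g, j))
    for (s in 1:2) {
      k <- nb[s]; i <- nb[3 - s]
      key <- paste(min(j, k), max(j, k))
      if (key %in% seen) next
      lCand <- setdiff(as.integer(igraph::neighbors(g, k)), j)
      if (!length(lCand)) next
      l <- min(lCand)
      seen <- c(seen, key)
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(j, k)))
      comp <- igraph::components(g2)$membership
      rotating <- which(comp == comp[k])
      out[[length(out) + 1L]] <- list(atoms = c(i, j, k, l),
                                      rotatingSet = as.integer(rotating))
    }
  }
  if (!length(out)) return(out)
  ord <- order(vapply(out, function(q) min(q$atoms[2:3]), numeric(1)),
               vapply(out, function(q) max(q$atoms[2:3]), numeric(1)))
  out[ord]
}
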