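#' @import methods
NULL

#' Atom table of a molecular object
#'
#' @param x a \linkS4class{MolecularModel} or object containing one.
#' @param ... further arguments for methods.
#' @return A data.frame with one row per atom (PDB-style fields).
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))

#' Cartesian coordinates
#'
#' @param x an object with atomic coordinates.
#' @param ... further arguments for methods.
#' @return A numeric N x 3 matrix in Angstrom.
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Replace Cartesian coordinates
#'
#' @param x an object with atomic coordinates.
#' @param value numeric N x 3 matrix in Angstrom.
#' @return The object with coordinates replaced.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Bond list of a molecular model
#'
#' @param x a \linkS4class{MolecularModel}.
#' @param ... further arguments for methods.
#' @return Integer two-column matrix of atom-index pairs, each bond once.
#' @export
setGeneric("bonds", function(x, ...) standardGeneric("bonds"))

#' Number of atoms
#'
#' @param x a molecular object.
#' @return Integer scalar.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames in a conformational ensemble
#'
#' @param x a \linkS4class{ConformationEnsemble}.
#' @return Integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of conformers in a library
#'
#' @param x a \linkS4class{ConformerLibrary}.
#' @return Integer scalar.
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' Conformer structures of a library
#'
#' @param x a \linkS4class{ConformerLibrary}.
#' @return List of \linkS4class{MolecularModel} objects, ordered by
#'   descending population weight (entry 1 is G0).
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' @importFrom stats weights
#' @export
stats::weights
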