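# Residue contact graphs and per-residue feature assembly.

#' Construct a per-residue feature bundle
#'
#' Holds the six feature groups used by the predictor: profile features (PSSM
#' and HMM, 20 columns each), secondary-structure descriptors (DSSP, 14),
#' atomic features (7), the 1-column pseudo-position embedding, and the
#' 1280-column protein language-model embedding. Derived views: the
#' 62-column handcrafted block, four contiguous 320-column language-model
#' chunks, and the full 1342-column concatenation.
#'
#' @param pssm,hmm,dssp,af,pef,llm numeric matrices with one row per residue
#'   and widths 20/20/14/7/1/1280 respectively.
#' @return a `feature_bundle`.
#' @export
feature_bundle <- function(pssm, hmm, dssp, af, pef, llm) {
  blocks <- list(pssm = pssm, hmm = hmm, dssp = dssp, af = af, pef = pef,
                 llm = llm)
  widths <- c(pssm = 20L, hmm = 20L, dssp = 14L, af = 7L, pef = 1L,
              llm = 1280L)
  blocks <- lapply(blocks, function(b) if (is.matrix(b)) b else as_mat(b))
  n <- nrow(blocks$pssm)
  for (nm in names(blocks)) {
    if (ncol(blocks[[nm]]) != widths[[nm]])
      stop(sprintf("block '%s' must have %d columns, got %d", nm,
                   widths[[nm]], ncol(blocks[[nm]])), call. = FALSE)
    if (nrow(blocks[[nm]]) != n)
      stop(sprintf("block '%s' has %d rows; expected %d", nm,
                   nrow(blocks[[nm]]), n), call. = FALSE)
  }
  structure(blocks, class = "feature_bundle")
}

#' @export
#' @method print feature_bundle
print.feature_bundle <- function(x, ...) {
  cat(sprintf("<feature_bundle: %d residues; handcrafted 62 + llm 1280>\n",
              nrow(x$pssm)))
  invisible(x)
}

#' Assemble the 62-column handcrafted feature block
#'
#' Column order is fixed: PSSM (20), HMM (20), DSSP (14), atomic (7),
#' pseudo-position (1).
#'
#' @param pssm,hmm,dssp,af,pef blocks with matching row counts and widths
#'   20/20/14/7/1.
#' @return an n x 62 matrix.
#' @export
assemble_handcrafted <- function(pssm, hmm, dssp, af, pef) {
  fb <- feature_bundle(pssm, hmm, dssp, af, pef,
                       llm = matrix(0, nrow(as_mat(pssm)), 1280L))
  cbind(fb$pssm, fb$hmm, fb$dssp, fb$af, fb$pef)
}

#' @rdname assemble_handcrafted
#' @param bundle a `feature_bundle`.
#' @export
fb_handcrafted <- function(bundle) {
  cbind(bundle$pssm, bundle$hmm, bundle$dssp, bundle$af, bundle$pef)
}

#' Split a language-model embedding into four contiguous chunks
#'
#' Chunk `i` holds columns `(i-1)*320 + 1` through `i*320`; concatenating the
#' four chunks recovers the input exactly.
#'
#' @param llm an n x 1280 matrix.
#' @return list of four n x 320 matrices.
#' @export
chunk_llm <- function(llm) {
  llm <- as_mat(llm)
  if (ncol(llm) != 1280L)
    stop(sprintf("llm block must have 1280 columns, got %d", ncol(llm)),
         call. = FALSE)
  lapply(1:4, function(i) llm[, ((i - 1L) * 320L + 1L):(i * 320L), drop = FALSE])
}

#' Extract a named feature group from a bundle
#'
#' @param bundle a `feature_bundle`.
#' @param group one of `"handcrafted"`, `"chunk1"` .. `"chunk4"`, `"all"`.
#' @return numeric matrix (widths 62, 320, or 1342).
#' @export
feature_group <- function(bundle, group) {
  group <- match.arg(group, c("handcrafted", paste0("chunk", 1:4), "all"))
  if (group == "handcrafted") return(fb_handcrafted(bundle))
  if (group == "all") return(cbind(fb_handcrafted(bundle), bundle$llm))
  chunk_llm(bundle$llm)[[as.integer(substring(group, 6L))]]
}

coerce_coords <- function(coords) {
  if (!is.matrix(coords)) {
    stopifnot(length(coords) == 3L)
    coords <- matrix(coords, 1L, 3L)
  }
  stopifnot(ncol(coords) == 3L)
  coords
}

#' Build the residue contact adjacency matrix
#'
#' Two residues are adjacent when their Euclidean distance is at most
#' `threshold` (boundary inclusive); the diagonal is zero.
#'
#' @param coords n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param threshold contact distance cutoff in Angstrom (default 14).
#' @return n x n binary symmetric matrix.
#' @export
#' @examples
#' A <- build_adjacency(generate_chain(10, 1)$coords)
build_adjacency <- function(coords, threshold = 14) {
  coords <- coerce_coords(coords)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  stopifnot(threshold > 0)
  A <- (as.matrix(stats::dist(coords)) <= threshold) * 1
  diag(A) <- 0
  unname(A)
}

#' Pseudo-position embedding
#'
#' Distance of each residue from the chain centroid, normalized by `scale`.
#' Invariant to global rotation and translation of the coordinates.
#'
#' @param coords n x 3 matrix (Angstrom).
#' @param scale normalizing length in Angstrom (default 15).
#' @return n x 1 matrix.
#' @export
pseudo_position_embedding <- function(coords, scale = 15) {
  coords <- coerce_coords(coords)
  stopifnot(scale > 0)
  ctr <- colMeans(coords)
  matrix(sqrt(rowSums(sweep(coords, 2L, ctr)^2)) / scale, ncol = 1L)
}

#' Read a C-alpha residue chain from a PDB file
#'
#' Parses the file with bio3d and keeps one C-alpha coordinate per residue of
#' the requested chain, in chain order. Residues lacking a C-alpha atom are
#' skipped with a warning.
#'
#' @param pdb_path path to a PDB file.
#' @param chain_id one-letter chain identifier (default `"A"`).
#' @return a `residue_chain` (`residue_ids`, `coords`).
#' @export
read_structure <- function(pdb_path, chain_id = "A") {
  if (!file.exists(pdb_path))
    stop(sprintf("PDB file not found: %s", pdb_path), call. = FALSE)
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom[pdb$atom$chain == chain_id & pdb$atom$type == "ATOM", ]
  if (nrow(atoms) == 0L)
    stop(sprintf("chain '%s' not found in %s", chain_id, pdb_path),
         call. = FALSE)
  res_keys <- unique(paste(atoms$resno, atoms$insert %||% "", sep = "_"))
  ca <- atoms[atoms$elety == "CA", ]
  ca_keys <- paste(ca$resno, ca$insert %||% "", sep = "_")
  missing <- setdiff(res_keys, ca_keys)
  if (length(missing) > 0L)
    warning(sprintf("%d residue(s) without a C-alpha atom skipped in chain %s",
                    length(missing), chain_id), call. = FALSE)
  ca <- ca[!duplicated(ca_keys), , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("no residues with C-alpha atoms retained", call. = FALSE)
  structure(list(residue_ids = paste0(ca$resid, ca$resno),
                 coords = unname(as.matrix(ca[, c("x", "y", "z")])),
                 labels = NULL),
            class = "residue_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a protein graph from structure and features
#'
#' @param coords n x 3 C-alpha coordinates.
#' @param features numeric feature matrix (one row per residue) or a
#'   `feature_bundle` plus `group`.
#' @param threshold contact cutoff in Angstrom.
#' @param group feature group name when `features` is a bundle.
#' @param labels optional 0/1 vector.
#' @return a `protein_graph`: list with `A`, `H`, `X`, optional `labels`.
#' @export
protein_graph <- function(coords, features, threshold = 14,
                          group = "handcrafted", labels = NULL) {
  coords <- coerce_coords(coords)
  H <- if (inherits(features, "feature_bundle")) feature_group(features, group)
       else as_mat(features)
  if (nrow(H) != nrow(coords))
    stop(sprintf("feature rows (%d) do not match residue count (%d)",
                 nrow(H), nrow(coords)), call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(coords))
    stop("label length does not match residue count", call. = FALSE)
  structure(list(A = build_adjacency(coords, threshold), H = unname(H),
                 X = unname(coords), labels = labels),
            class = "protein_graph")
}

#' @export
#' @method print protein_graph
print.protein_graph <- function(x, ...) {
  cat(sprintf("<protein_graph: %d residues, %d contacts, %d features>\n",
              nrow(x$A), sum(x$A) / 2, ncol(x$H)))
  invisible(x)
}
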