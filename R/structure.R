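#' Read a PDB structure into an atom table
#'
#' Parses a PDB-format file (via bio3d), keeping hetero records (e.g. a
#' covalently linked fluorophore) and, for alternate locations, conformer A.
#' The first model of multi-model files is used.
#'
#' @param path PDB file path.
#' @param model_id optional label; defaults to the file name.
#' @return object of class `structure_model`: data frame `atoms` with
#'   columns chain, resno, resid, elety (atom name), elesy (element), x, y,
#'   z (Angstrom), type (ATOM/HETATM).
#' @export
read_structure <- function(path, model_id = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, ]
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      elety = a$elety, elesy = a$elesy,
                      x = a$x, y = a$y, z = a$z, type = a$type,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in '", path, "'")
  key <- paste(atoms$chain, atoms$resno, atoms$elety, atoms$resid)
  atoms <- atoms[!duplicated(key), ]
  structure(list(atoms = atoms,
                 model_id = if (is.null(model_id)) basename(path) else model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure", x$model_id, "-", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s),",
      sum(x$atoms$type == "HETATM"), "hetero atoms\n")
  invisible(x)
}

sel_atom <- function(s, chain, resno, elety) {
  a <- s$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Cbeta-Cbeta distance between two residues
#'
#' Euclidean distance between the beta carbons (alpha carbon for glycine) of
#' two residues, the standard side-chain-orientation proxy for
#' quencher-fluorophore separation.
#'
#' @param s a [read_structure()] model.
#' @param chainA,resA,chainB,resB chain identifiers and residue numbers.
#' @return distance in Angstrom.
#' @export
cb_cb_distance <- function(s, chainA, resA, chainB, resB) {
  stopifnot(inherits(s, "structure_model"))
  get_cb <- function(chain, resno) {
    a <- s$atoms
    rows <- a[a$chain == chain & a$resno == resno, ]
    if (!nrow(rows))
      stop("residue ", chain, ":", resno, " not found in ", s$model_id)
    p <- sel_atom(s, chain, resno, "CB")
    if (is.null(p) && any(rows$resid == "GLY"))
      p <- sel_atom(s, chain, resno, "CA")
    if (is.null(p))
      stop("no CB (or glycine CA) atom for residue ", chain, ":", resno,
           " in ", s$model_id)
    p
  }
  pA <- get_cb(chainA, resA)
  pB <- get_cb(chainB, resB)
  sqrt(sum((pA - pB)^2))
}

#' Minimal distance between two atom selections
#'
#' Minimum pairwise Euclidean distance between two heavy-atom selections,
#' e.g. a bound fluorophore's hetero group and the indole ring of a
#' tryptophan quencher.
#'
#' @param s a [read_structure()] model.
#' @param selectionA,selectionB either integer row indices into `s$atoms` or
#'   a list with elements `chain`, `resno` and optionally `elety` (vector of
#'   atom names).  Hydrogens are excluded.
#' @return minimal distance in Angstrom.
#' @export
min_group_distance <- function(s, selectionA, selectionB) {
  stopifnot(inherits(s, "structure_model"))
  resolve <- function(sel) {
    a <- s$atoms
    i <- if (is.numeric(sel)) sel
    else {
      j <- a$chain == sel$chain & a$resno %in% sel$resno
      if (!is.null(sel$elety)) j <- j & a$elety %in% sel$elety
      which(j)
    }
    i <- i[!(a$elesy[i] %in% c("H", "D"))]
    if (!length(i)) stop("empty atom selection")
    as.matrix(a[i, c("x", "y", "z")])
  }
  A <- resolve(selectionA)
  B <- resolve(selectionB)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Quencher distance rule
#'
#' Empirical quenching radii of aromatic quenchers acting on a small
#' fluorophore: about 15 Angstrom for tryptophan and 10 Angstrom for
#' tyrosine.  The boundary is inclusive.
#'
#' @param quencher_type `"Trp"` or `"Tyr"`.
#' @param max_distance override of the radius (Angstrom).
#' @return object of class `quencher_rule`.
#' @export
quencher_rule <- function(quencher_type = c("Trp", "Tyr"),
                          max_distance = NULL) {
  quencher_type <- match.arg(quencher_type)
  if (is.null(max_distance))
    max_distance <- if (quencher_type == "Trp") 15 else 10
  structure(list(quencher_type = quencher_type,
                 max_distance = max_distance),
            class = "quencher_rule")
}

#' Is a pair within quenching range?
#'
#' @param distance inter-residue distance (Angstrom), >= 0.
#' @param rule a [quencher_rule()].
#' @return logical.
#' @examples
#' classify_pair(14.9, quencher_rule("Trp"))  # TRUE
#' classify_pair(10.1, quencher_rule("Tyr"))  # FALSE
#' @export
classify_pair <- function(distance, rule) {
  stopifnot(inherits(rule, "quencher_rule"), all(distance >= 0))
  distance <= rule$max_distance
}

#' Rigid-body superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of the common atoms of two structures
#' (matched by chain, residue number and atom name) via the Kabsch/SVD
#' algorithm, returning the post-superposition RMSD together with the
#' rotation and translation.
#'
#' @param sA,sB [read_structure()] models.
#' @param selection atom name(s) used for matching (default `"CA"`); `NULL`
#'   matches all atoms.
#' @return list with `rmsd` (Angstrom), `rotation` (3x3), `translation`
#'   (length 3, applied after rotation of centered B coordinates),
#'   `n_atoms`.
#' @export
superpose_rmsd <- function(sA, sB, selection = "CA") {
  stopifnot(inherits(sA, "structure_model"), inherits(sB, "structure_model"))
  pick <- function(s) {
    a <- s$atoms
    if (!is.null(selection)) a <- a[a$elety %in% selection, ]
    a$key <- paste(a$chain, a$resno, a$elety)
    a[!duplicated(a$key), ]
  }
  a <- pick(sA); b <- pick(sB)
  common <- intersect(a$key, b$key)
  if (length(common) < 3)
    stop("fewer than 3 common atoms for superposition")
  A <- as.matrix(a[match(common, a$key), c("x", "y", "z")])
  B <- as.matrix(b[match(common, b$key), c("x", "y", "z")])
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  sv <- svd(t(B0) %*% A0)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  list(rmsd = rmsd, rotation = R, translation = cA,
       n_atoms = length(common))
}

#' Per-pair distance changes between two conformational states
#'
#' Cbeta-Cbeta distances of sensor pairs measured in two structures (e.g. a
#' closed pH 7 and an open pH 4 state), their change (state B minus state A)
#' and an approach/separation/unchanged call.
#'
#' @param s_closed,s_open [read_structure()] models (states A and B).
#' @param pairs data frame with columns chainA, resA, chainB, resB and
#'   optionally label.
#' @param tolerance absolute change (Angstrom) under which a pair is called
#'   unchanged (default 0.5).
#' @return data frame: label, d_closed, d_open, delta, classification.
#' @export
pair_distance_delta <- function(s_closed, s_open, pairs, tolerance = 0.5) {
  stopifnot(is.data.frame(pairs))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    dA <- cb_cb_distance(s_closed, p$chainA, p$resA, p$chainB, p$resB)
    dB <- cb_cb_distance(s_open, p$chainA, p$resA, p$chainB, p$resB)
    delta <- dB - dA
    data.frame(
      label = if (!is.null(pairs$label)) p$label
      else paste0(p$resA, "-", p$resB),
      d_closed = dA, d_open = dB, delta = delta,
      classification = if (abs(delta) < tolerance) "unchanged"
      else if (delta < 0) "approach" else "separation")
  }))
  rownames(out) <- NULL
  out
}
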