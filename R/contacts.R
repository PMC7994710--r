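# Interface contact extraction from a representative complex structure and
# mapping of residue contacts onto alignment columns.

# one representative atom per residue: C-beta, falling back to C-alpha
# (glycine has no C-beta); highest-occupancy altloc, ties to file order
.residueAtoms <- function(atoms, chain) {
  sel <- atoms[atoms$chain %in% chain & atoms$elety %in% c("CB", "CA"), , drop = FALSE]
  if (nrow(sel) == 0L) stop("chain '", chain, "' not found or has no CA/CB atoms")
  key <- paste(sel$resno, sel$insert)
  picked <- lapply(split(seq_len(nrow(sel)), key), function(idx) {
    sub <- sel[idx, , drop = FALSE]
    cb <- sub[sub$elety == "CB", , drop = FALSE]
    use <- if (nrow(cb) > 0) cb else sub
    occ <- use$o; occ[is.na(occ)] <- 1
    use[which.max(occ), , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out[order(out$resno), , drop = FALSE]
}

#' Extract interface residue contacts from a complex structure
#'
#' All inter-chain residue pairs whose representative-atom (C-beta;
#' C-alpha for glycine) Euclidean distance is at most `cutoff` angstroms.
#' Only the first model of a multi-model file is used. Residues lacking both
#' atoms are skipped with a warning.
#'
#' @param structure a `bio3d` pdb object or a path to a PDB/mmCIF file.
#' @param chainA,chainB chain identifiers of the two partners.
#' @param cutoff maximum representative-atom separation in angstroms
#'   (default 8).
#' @return A data.frame with one row per contact: `resnoA`, `resnoB` (author
#'   residue numbers), `residA`, `residB` (one-letter codes) and `distance`.
#' @export
extractContacts <- function(structure, chainA, chainB, cutoff = 8.0) {
  if (is.character(structure)) {
    structure <- if (grepl("\\.cif$", structure, ignore.case = TRUE))
      bio3d::read.cif(structure) else bio3d::read.pdb(structure)
  }
  atoms <- structure$atom
  a <- .residueAtoms(atoms, chainA)
  b <- .residueAtoms(atoms, chainB)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
            outer(a$z, b$z, "-")^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  out <- data.frame(
    resnoA = a$resno[hit[, 1]], resnoB = b$resno[hit[, 2]],
    residA = bio3d::aa321(a$resid[hit[, 1]]),
    residB = bio3d::aa321(b$resid[hit[, 2]]),
    distance = d[hit])
  out[order(out$resnoA, out$resnoB), , drop = FALSE]
}

# aligned column holding the u-th non-gap residue of a reference row
.ungappedToColumn <- function(alignedRow, u) {
  which(strsplit(alignedRow, "")[[1]] != "-")[u]
}

#' Map residue contacts onto alignment columns
#'
#' Each residue contact becomes the pair of alignment columns holding those
#' residues in user-designated reference rows. Residue numbers are related
#' to ungapped reference positions by a fixed offset per chain
#' (`position = resno - offset`); residue identities are checked against the
#' reference sequence and any mismatch is a hard error. Contacts falling
#' outside the mapped range are dropped with a message.
#'
#' @param contacts data.frame from [extractContacts()].
#' @param pair an [AlignmentPair-class].
#' @param refA,refB reference row of each MSA: an index or a sequence name.
#' @param offsetA,offsetB residue-number offsets (author numbering of the
#'   first reference residue minus one); default 0, i.e. residue 1 is the
#'   first reference position.
#' @return A [ContactMap-class] with per-contact metadata.
#' @export
mapContactsToMSA <- function(contacts, pair, refA = 1L, refB = 1L,
                             offsetA = 0L, offsetB = 0L) {
  resolveRow <- function(msa, ref) {
    if (is.character(ref)) ref <- match(ref, names(msa))
    if (is.na(ref) || ref < 1 || ref > length(msa)) stop("reference row not found")
    as.character(msa[[ref]])
  }
  rowA <- resolveRow(msaA(pair), refA)
  rowB <- resolveRow(msaB(pair), refB)
  ungA <- gsub("-", "", rowA); ungB <- gsub("-", "", rowB)
  uA <- contacts$resnoA - offsetA
  uB <- contacts$resnoB - offsetB
  inA <- uA >= 1 & uA <= nchar(ungA)
  inB <- uB >= 1 & uB <= nchar(ungB)
  keep <- inA & inB
  if (any(!keep))
    message(sum(!keep), " contact(s) fall outside the reference rows; dropped")
  if (!any(keep)) stop("no contact maps onto the reference rows")
  ct <- contacts[keep, , drop = FALSE]
  uA <- uA[keep]; uB <- uB[keep]
  chkA <- substring(ungA, uA, uA); chkB <- substring(ungB, uB, uB)
  badA <- which(!is.na(ct$residA) & ct$residA != "X" & chkA != ct$residA)
  if (length(badA))
    stop(sprintf("structure/reference mismatch on chain A at residue %d: structure %s, reference %s",
                 ct$resnoA[badA[1]], ct$residA[badA[1]], chkA[badA[1]]))
  badB <- which(!is.na(ct$residB) & ct$residB != "X" & chkB != ct$residB)
  if (length(badB))
    stop(sprintf("structure/reference mismatch on chain B at residue %d: structure %s, reference %s",
                 ct$resnoB[badB[1]], ct$residB[badB[1]], chkB[badB[1]]))
  colA <- vapply(uA, function(u) .ungappedToColumn(rowA, u), integer(1))
  colB <- vapply(uB, function(u) .ungappedToColumn(rowB, u), integer(1))
  dup <- duplicated(paste(colA, colB))
  if (any(dup)) {
    message(sum(dup), " contact(s) collapse onto duplicate column pairs; dropped")
    colA <- colA[!dup]; colB <- colB[!dup]; ct <- ct[!dup, , drop = FALSE]
  }
  ContactMap(colA, colB,
             meta = data.frame(resnoA = ct$resnoA, resnoB = ct$resnoB,
                               distance = ct$distance))
}

#' Write a contact map as TSV
#'
#' Columns `col_a`, `col_b` plus `resnum_a`, `resnum_b`, `distance` when the
#' map carries structural metadata.
#'
#' @param cmap a [ContactMap-class].
#' @param path output path.
#' @export
writeContactMap <- function(cmap, path) {
  cp <- contactPairs(cmap)
  tab <- data.frame(col_a = cp[, 1], col_b = cp[, 2])
  if (nrow(cmap@meta) == nrow(cp) && ncol(cmap@meta) > 0) {
    tab$resnum_a <- cmap@meta$resnoA
    tab$resnum_b <- cmap@meta$resnoB
    tab$distance <- cmap@meta$distance
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contact map written by [writeContactMap()]
#'
#' @param path TSV path with columns `col_a`, `col_b`.
#' @return A [ContactMap-class].
#' @export
readContactMap <- function(path) {
  tab <- read.delim(path)
  meta <- if (all(c("resnum_a", "resnum_b", "distance") %in% names(tab)))
    data.frame(resnoA = tab$resnum_a, resnoB = tab$resnum_b,
               distance = tab$distance) else data.frame()
  ContactMap(tab$col_a, tab$col_b, meta = meta)
}
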