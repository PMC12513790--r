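# Structure reading and sequence-to-structure residue mapping.
#
# All cross-referencing between 1-based human sequence positions and
# author-numbered structure residues goes through a ResidueMap; nothing
# downstream assumes the two numbering schemes agree.

residue_key <- function(chain, resno, ins = "") {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste(chain, resno, ins, sep = ":")
}

#' Construct a structure model from a residue table
#'
#' A `StructureModel` is the package's minimal representation of a solved
#' structure: one row per residue, in file order, with the alpha-carbon
#' (C-alpha) coordinate in Angstroms or `NA` when the residue is present
#' in the file but its C-alpha was not resolved.
#'
#' @param structure_id Identifier for the structure (e.g. a PDB code).
#' @param residues Data frame with columns `chain` (character),
#'   `resno` (integer author residue number), `ins` (insertion code,
#'   `""` when absent), `resid` (3-letter residue name), `aa` (1-letter
#'   code, `"X"` for residues with no standard parent), and `x`, `y`, `z`
#'   (C-alpha coordinates in Angstroms, `NA` if unresolved).
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(structure_id, residues) {
  required <- c("chain", "resno", "ins", "resid", "aa", "x", "y", "z")
  missing_cols <- setdiff(required, names(residues))
  if (length(missing_cols) > 0) {
    stop("residue table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  residues <- as.data.frame(residues)[required]
  residues$ins[is.na(residues$ins) | residues$ins == " "] <- ""
  key <- residue_key(residues$chain, residues$resno, residues$ins)
  if (anyDuplicated(key)) {
    stop("duplicate residue keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (nrow(residues) == 0 || length(unique(residues$chain)) < 1) {
    stop("a StructureModel needs at least one residue in at least one chain")
  }
  has_ca <- !is.na(residues$x)
  if (any(has_ca & (!is.finite(residues$x) | !is.finite(residues$y) |
                      !is.finite(residues$z)))) {
    stop("non-finite C-alpha coordinates")
  }
  residues$has_ca <- has_ca
  structure(list(structure_id = structure_id, residues = residues),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  r <- x$residues
  cat(sprintf("StructureModel '%s': %d residues, %d chains (%s), %d with C-alpha\n",
              x$structure_id, nrow(r), length(unique(r$chain)),
              paste(unique(r$chain), collapse = ","), sum(r$has_ca)))
  invisible(x)
}

#' Read a protein structure into a StructureModel
#'
#' Parses a PDB or mmCIF file and extracts one record per residue with its
#' C-alpha coordinate. Residues lacking a C-alpha atom are retained but
#' flagged coordinate-absent. When the C-alpha has alternate locations the
#' first-listed one is kept. Modified amino acids with a standard parent
#' (e.g. selenomethionine, MSE) are translated to the parent 1-letter code;
#' residues with no standard parent get `aa = "X"`. Non-amino-acid HETATM
#' groups (waters, ligands) are dropped.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param chains Optional character vector restricting to these chain ids.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chains = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  aa1 <- suppressWarnings(bio3d::aa321(atoms$resid))
  # protein residues: ATOM records, plus HETATMs that are modified amino acids
  keep <- atoms$type == "ATOM" | (atoms$type == "HETATM" & aa1 != "X")
  atoms <- atoms[keep, , drop = FALSE]
  aa1 <- aa1[keep]
  if (nrow(atoms) == 0) stop("no protein residues found in '", path, "'")

  available <- unique(atoms$chain)
  if (!is.null(chains)) {
    sel <- atoms$chain %in% chains
    if (!any(sel)) {
      stop("no residues in chains {", paste(chains, collapse = ","),
           "}; available chains: ", paste(available, collapse = ","))
    }
    atoms <- atoms[sel, , drop = FALSE]
    aa1 <- aa1[sel]
  }

  key <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  first <- !duplicated(key)
  residues <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    ins = atoms$insert[first], resid = atoms$resid[first],
    aa = aa1[first], x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE
  )
  # first-listed C-alpha per residue (keeps the first altLoc)
  ca_rows <- which(atoms$elety == "CA")
  ca_rows <- ca_rows[!duplicated(key[ca_rows])]
  ca <- atoms[ca_rows, , drop = FALSE]
  idx <- match(residue_key(ca$chain, ca$resno, ca$insert),
               residue_key(residues$chain, residues$resno, residues$ins))
  residues$x[idx] <- ca$x
  residues$y[idx] <- ca$y
  residues$z[idx] <- ca$z

  sid <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  structure_model(sid, residues)
}

#' Write a StructureModel as a C-alpha-only PDB file
#'
#' Residues without a resolved C-alpha have no atom to write and are
#' omitted. Reading the file back reproduces residue keys and coordinates
#' of all C-alpha-bearing residues.
#'
#' @param model A [structure_model()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  r <- model$residues[model$residues$has_ca, , drop = FALSE]
  if (nrow(r) == 0) stop("no residues with C-alpha coordinates to write")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(r[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(r)),
    resno = r$resno, resid = r$resid, chain = r$chain,
    insert = ifelse(r$ins == "", NA, r$ins),
    eleno = seq_len(nrow(r)), elety = rep("CA", nrow(r)),
    o = rep(1, nrow(r)), b = rep(0, nrow(r))
  )
  invisible(path)
}

chain_sequence <- function(structure, chain_id) {
  r <- structure$residues
  r <- r[r$chain == chain_id, , drop = FALSE]
  if (nrow(r) == 0) {
    stop("chain '", chain_id, "' not in structure; available: ",
         paste(unique(structure$residues$chain), collapse = ","))
  }
  r
}

read_alignment_rows <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1 &&
        file.exists(alignment)) {
    ali <- bio3d::read.fasta(alignment)$ali
    if (nrow(ali) != 2) stop("pairwise alignment must have exactly 2 records")
    return(c(paste(ali[1, ], collapse = ""), paste(ali[2, ], collapse = "")))
  }
  if (is.matrix(alignment)) {
    return(apply(alignment, 1, paste, collapse = ""))
  }
  if (is.character(alignment) && length(alignment) == 2) return(alignment)
  stop("alignment must be a 2-record FASTA path, a 2-row matrix, ",
       "or a character vector of 2 gapped sequences")
}

#' Map human sequence positions onto structure residues
#'
#' Consumes a pairwise alignment of the full human sequence (first record)
#' against the residue sequence of one structure chain (second record) and
#' returns, for every human position, either the structure residue it lands
#' on or the reason it cannot be used: `"gap"` (aligned to a gap in the
#' structure row), `"unresolved"` (residue present but without a C-alpha),
#' or `"nonstandard"` (residue with no standard parent amino acid).
#' Aligned columns whose letters differ are still mapped — substitutions
#' between orthologous sequences are expected — and flagged via the
#' `match` column.
#'
#' @param human_seq Human amino acid sequence (1-letter string).
#' @param alignment Pairwise alignment: FASTA path, 2-row character matrix,
#'   or character vector of the two gapped rows (human first).
#' @param structure A [structure_model()].
#' @param chain_id Chain of `structure` the second alignment row refers to.
#' @return Object of class `ResidueMap`: list with `entries` (data frame
#'   `human_pos`, `human_aa`, `chain`, `resno`, `ins`, `struct_aa`,
#'   `match`), `unmapped` (`human_pos`, `human_aa`, `reason`), `chain_id`,
#'   `structure_id`, and `human_length`.
#' @export
build_residue_map <- function(human_seq, alignment, structure, chain_id) {
  rows <- read_alignment_rows(alignment)
  if (nchar(rows[1]) != nchar(rows[2])) {
    stop("alignment rows differ in length (", nchar(rows[1]), " vs ",
         nchar(rows[2]), ")")
  }
  h <- strsplit(toupper(rows[1]), "")[[1]]
  s <- strsplit(toupper(rows[2]), "")[[1]]
  gap <- c("-", ".")
  h_res <- !(h %in% gap)
  s_res <- !(s %in% gap)

  human_seq <- toupper(gsub("[-. ]", "", human_seq))
  hseq <- strsplit(human_seq, "")[[1]]
  h_ungapped <- h[h_res]
  if (length(h_ungapped) != length(hseq) || any(h_ungapped != hseq)) {
    bad <- which(h_res)[which(h_ungapped != hseq[seq_along(h_ungapped)])[1]]
    if (is.na(bad)) bad <- nchar(rows[1])
    stop("alignment row 1 does not reproduce the human sequence ",
         "(first offending alignment column: ", bad, ")")
  }
  cres <- chain_sequence(structure, chain_id)
  s_ungapped <- s[s_res]
  if (length(s_ungapped) != nrow(cres) ||
        any(s_ungapped != cres$aa[seq_along(s_ungapped)])) {
    mism <- which(s_ungapped != cres$aa[seq_len(min(length(s_ungapped),
                                                    nrow(cres)))])
    bad <- if (length(mism) > 0) which(s_res)[mism[1]] else nchar(rows[2])
    stop("alignment row 2 does not match the residue sequence of chain '",
         chain_id, "' (first offending alignment column: ", bad, ")")
  }

  hpos <- cumsum(h_res)
  spos <- cumsum(s_res)
  cols <- which(h_res)

  status <- character(length(cols))
  sidx <- integer(length(cols))
  for (j in seq_along(cols)) {
    col <- cols[j]
    if (!s_res[col]) {
      status[j] <- "gap"
    } else {
      i <- spos[col]
      sidx[j] <- i
      if (cres$aa[i] == "X") status[j] <- "nonstandard"
      else if (!cres$has_ca[i]) status[j] <- "unresolved"
      else status[j] <- "mapped"
    }
  }

  ok <- status == "mapped"
  entries <- data.frame(
    human_pos = hpos[cols][ok],
    human_aa = h[cols][ok],
    chain = chain_id,
    resno = cres$resno[sidx[ok]],
    ins = cres$ins[sidx[ok]],
    struct_aa = cres$aa[sidx[ok]],
    stringsAsFactors = FALSE
  )
  entries$match <- entries$human_aa == entries$struct_aa
  unmapped <- data.frame(
    human_pos = hpos[cols][!ok],
    human_aa = h[cols][!ok],
    reason = status[!ok],
    stringsAsFactors = FALSE
  )
  structure(list(entries = entries, unmapped = unmapped,
                 chain_id = chain_id, structure_id = structure$structure_id,
                 human_length = length(hseq)),
            class = "ResidueMap")
}

#' @export
print.ResidueMap <- function(x, ...) {
  cat(sprintf("ResidueMap to %s chain %s: %d mapped (%d substitutions), %d unmapped",
              x$structure_id, x$chain_id, nrow(x$entries),
              sum(!x$entries$match), nrow(x$unmapped)))
  if (nrow(x$unmapped) > 0) {
    tab <- table(x$unmapped$reason)
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @describeIn build_residue_map Flatten a ResidueMap to one row per human
#'   position with a `status` column (`mapped`/`gap`/`unresolved`/
#'   `nonstandard`).
#' @param map A `ResidueMap`.
#' @export
as.data.frame.ResidueMap <- function(x, ...) {
  e <- data.frame(human_pos = x$entries$human_pos,
                  human_aa = x$entries$human_aa,
                  chain = x$entries$chain,
                  struct_resnum = paste0(x$entries$resno, x$entries$ins),
                  struct_aa = x$entries$struct_aa,
                  status = "mapped", stringsAsFactors = FALSE)
  u <- data.frame(human_pos = x$unmapped$human_pos,
                  human_aa = x$unmapped$human_aa,
                  chain = NA_character_, struct_resnum = NA_character_,
                  struct_aa = NA_character_, status = x$unmapped$reason,
                  stringsAsFactors = FALSE)
  out <- rbind(e, u)
  out[order(out$human_pos), , drop = FALSE]
}

#' Write a ResidueMap as TSV
#'
#' @param map A `ResidueMap`.
#' @param path Output TSV path.
#' @export
write_residue_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Resolve variants to structure residues
#'
#' Places each variant of a [variant_table()] onto the structure through a
#' `ResidueMap`. Variants whose reference amino acid disagrees with the
#' human sequence at that position are a validation error. Multiple
#' variants at one position collapse to a single unique site in the
#' returned site set, so a position's site status is independent of how
#' many distinct substitutions were observed there.
#'
#' @param variants A [variant_table()].
#' @param map A `ResidueMap` from [build_residue_map()].
#' @param label Label for the returned [site_set()] (default `"all"`).
#' @return List with `sites` (a [site_set()] of unique mapped positions),
#'   `mapped` (variant rows plus structure residue columns) and
#'   `unmapped` (variant rows plus `reason`).
#' @export
map_variants <- function(variants, map, label = "all") {
  stopifnot(inherits(map, "ResidueMap"))
  variants <- as.data.frame(variants)
  known <- rbind(
    data.frame(human_pos = map$entries$human_pos,
               human_aa = map$entries$human_aa),
    data.frame(human_pos = map$unmapped$human_pos,
               human_aa = map$unmapped$human_aa)
  )
  pos_aa <- known$human_aa[match(variants$human_pos, known$human_pos)]
  outside <- is.na(pos_aa)
  if (any(outside)) {
    stop("variant positions outside the mapped human sequence: ",
         paste(unique(variants$human_pos[outside]), collapse = ", "))
  }
  bad_ref <- variants$ref_aa != pos_aa
  if (any(bad_ref)) {
    off <- variants[bad_ref, , drop = FALSE]
    stop("reference residue disagrees with the human sequence for: ",
         paste(sprintf("p.%s%d%s (sequence has %s)", off$ref_aa,
                       off$human_pos, off$alt_aa, pos_aa[bad_ref]),
               collapse = ", "))
  }
  idx <- match(variants$human_pos, map$entries$human_pos)
  is_mapped <- !is.na(idx)
  mapped <- cbind(variants[is_mapped, , drop = FALSE],
                  map$entries[idx[is_mapped],
                              c("chain", "resno", "ins", "struct_aa")])
  rownames(mapped) <- NULL
  uidx <- match(variants$human_pos[!is_mapped], map$unmapped$human_pos)
  unmapped <- cbind(variants[!is_mapped, , drop = FALSE],
                    reason = map$unmapped$reason[uidx])
  rownames(unmapped) <- NULL
  usite <- !duplicated(mapped$human_pos)
  sites <- if (nrow(mapped) == 0) NULL else site_set(label,
                    chain = mapped$chain[usite],
                    resno = mapped$resno[usite],
                    ins = mapped$ins[usite],
                    human_pos = mapped$human_pos[usite])
  list(sites = sites, mapped = mapped, unmapped = unmapped)
}
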