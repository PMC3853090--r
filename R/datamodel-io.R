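#' Create a protein record
#'
#' A protein record holds a sequence identifier and its amino acid sequence
#' over the 20 standard one-letter codes; positions are 1-based.
#'
#' @param id Single string identifier.
#' @param sequence Single string over the 20-letter amino acid alphabet.
#' @return An object of class `protein_record` with elements `id` and
#'   `sequence`.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  check_aa_sequence(sequence, id)
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' The token before the first whitespace in each header is the protein id.
#' Sequences containing letters outside the 20 standard codes are rejected
#' unless `on_illegal = "drop"`, in which case the offending records are
#' skipped with a warning.
#'
#' @param path Path to a FASTA file.
#' @param on_illegal `"error"` (default) or `"drop"`.
#' @return Named list of [protein_record()] objects.
#' @export
read_fasta <- function(path, on_illegal = c("error", "drop")) {
  on_illegal <- match.arg(on_illegal)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  out <- list()
  for (i in seq_along(seqs)) {
    id <- strsplit(names(seqs)[i], "[ \t]")[[1]][1]
    rec <- tryCatch(protein_record(id, as.character(seqs[[i]])),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (on_illegal == "error") stop(conditionMessage(rec), call. = FALSE)
      warning("dropping record '", id, "': ", conditionMessage(rec),
              call. = FALSE)
    } else {
      out[[id]] <- rec
    }
  }
  out
}

#' Write protein records to a FASTA file
#'
#' @param proteins List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqinr::write.fasta(lapply(proteins, function(p) p$sequence),
                      names = vapply(proteins, function(p) p$id, ""),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

#' Construct a table of phosphorylation sites
#'
#' Sites are kept in a plain data frame with one row per site. Each row is
#' validated against the protein records: the residue letter must be one of
#' S/T/Y, must match the protein sequence at that position, and the position
#' must be within the protein.
#'
#' @param protein_id,position,residue Vectors describing each site.
#' @param kinase_group Kinase group label per site (`NA` allowed).
#' @param label `"positive"` or `"negative"` per site.
#' @param proteins Named list of [protein_record()] to validate against, or
#'   `NULL` to skip sequence validation.
#' @return A `data.frame` with columns `protein_id`, `position`, `residue`,
#'   `kinase_group`, `label`.
#' @export
phospho_sites <- function(protein_id, position, residue,
                          kinase_group = NA_character_,
                          label = "positive", proteins = NULL) {
  sites <- data.frame(protein_id = as.character(protein_id),
                      position = as.integer(position),
                      residue = as.character(residue),
                      kinase_group = as.character(kinase_group),
                      label = as.character(label),
                      stringsAsFactors = FALSE)
  bad <- character()
  if (any(!sites$residue %in% c("S", "T", "Y"))) {
    bad <- c(bad, paste("rows with residue not in {S,T,Y}:",
                        paste(which(!sites$residue %in% c("S", "T", "Y")),
                              collapse = ", ")))
  }
  if (any(!sites$label %in% c("positive", "negative"))) {
    bad <- c(bad, "labels must be 'positive' or 'negative'")
  }
  if (!is.null(proteins)) {
    for (i in seq_len(nrow(sites))) {
      p <- proteins[[sites$protein_id[i]]]
      if (is.null(p)) {
        bad <- c(bad, sprintf("row %d: unknown protein '%s'", i,
                              sites$protein_id[i]))
        next
      }
      pos <- sites$position[i]
      if (is.na(pos) || pos < 1L || pos > nchar(p$sequence)) {
        bad <- c(bad, sprintf("row %d: position %s outside protein '%s' (length %d)",
                              i, pos, p$id, nchar(p$sequence)))
      } else if (substr(p$sequence, pos, pos) != sites$residue[i]) {
        bad <- c(bad, sprintf(
          "row %d: residue '%s' does not match protein '%s' position %d ('%s')",
          i, sites$residue[i], p$id, pos, substr(p$sequence, pos, pos)))
      }
    }
  }
  if (length(bad)) {
    stop("invalid phosphosite table:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  sites
}

#' Read a phosphosite table from TSV
#'
#' Expects tab-separated columns `protein_id`, `position`, `residue`,
#' `kinase_group`, `label` with a header row.
#'
#' @param path Path to the TSV file.
#' @param proteins Named list of [protein_record()] for validation
#'   (recommended), or `NULL`.
#' @return Validated site `data.frame` (see [phospho_sites()]).
#' @export
read_site_table <- function(path, proteins = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "kinase_group", "label")
  if (!all(need %in% names(tab))) {
    stop("site table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  phospho_sites(tab$protein_id, tab$position, tab$residue,
                tab$kinase_group, tab$label, proteins = proteins)
}

#' Write a phosphosite table as TSV
#'
#' @param sites Site `data.frame` from [phospho_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract the sequence window around a candidate site
#'
#' Returns the `2 * flank + 1`-mer centred on the site (offsets `-flank` to
#' `+flank`); positions beyond the protein ends are padded with the terminal
#' symbol `"-"`.
#'
#' @param protein A [protein_record()].
#' @param position 1-based site position; residue there must be S, T or Y.
#' @param flank Number of residues on each side (default 6, a 13-mer).
#' @return Single string of length `2 * flank + 1`.
#' @export
extract_window <- function(protein, position, flank = 6L) {
  n <- nchar(protein$sequence)
  stopifnot(position >= 1L, position <= n)
  centre <- substr(protein$sequence, position, position)
  if (!centre %in% c("S", "T", "Y")) {
    stop("window centre at position ", position, " of '", protein$id,
         "' is '", centre, "', not S/T/Y", call. = FALSE)
  }
  offsets <- (position - flank):(position + flank)
  letters <- ifelse(offsets < 1L | offsets > n, TERMINAL_SYMBOL,
                    substring(protein$sequence, offsets, offsets))
  paste(letters, collapse = "")
}

#' Enumerate negative sites on a phosphorylated protein
#'
#' Every S/T/Y residue of the protein that is not among the known positive
#' positions is returned as a negative site, following the convention that
#' unannotated acceptor residues on phosphoproteins form the negative set.
#'
#' @param protein A [protein_record()].
#' @param positive_positions Integer vector of known positive positions.
#' @param residue_types Acceptor residue types considered (default S, T, Y).
#' @param kinase_group Group label to attach to the negatives.
#' @return Site `data.frame` with `label = "negative"` (zero rows if none).
#' @export
build_negative_set <- function(protein, positive_positions,
                               residue_types = c("S", "T", "Y"),
                               kinase_group = NA_character_) {
  letters <- seq_chars(protein$sequence)
  cand <- which(letters %in% residue_types)
  cand <- setdiff(cand, as.integer(positive_positions))
  if (!length(cand)) {
    return(phospho_sites(character(), integer(), character(),
                         character(), character()))
  }
  phospho_sites(protein$id, cand, letters[cand], kinase_group, "negative")
}

# ---- structures -----------------------------------------------------------

#' Construct a structure from per-residue C-alpha coordinates
#'
#' Convenience constructor used by the synthetic generator: one CA atom per
#' residue on a single chain, residues numbered 1..n.
#'
#' @param structure_id Identifier string.
#' @param sequence Amino acid sequence (one CA per letter).
#' @param xyz Numeric matrix `n x 3` of CA coordinates in Angstroms.
#' @param chain_id Chain identifier (default `"A"`).
#' @return Object of class `phos_structure`: a list with `structure_id` and
#'   an `atoms` data frame (`chain`, `resno`, `aa`, `atom`, `x`, `y`, `z`).
#' @export
ca_structure <- function(structure_id, sequence, xyz, chain_id = "A") {
  check_aa_sequence(sequence, structure_id)
  letters <- seq_chars(sequence)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == length(letters), ncol(xyz) == 3L,
            all(is.finite(xyz)))
  atoms <- data.frame(chain = chain_id, resno = seq_along(letters),
                      aa = letters, atom = "CA",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  structure(list(structure_id = structure_id, atoms = atoms),
            class = "phos_structure")
}

#' @export
print.phos_structure <- function(x, ...) {
  cat(sprintf("<phos_structure> %s: %d atoms, %d residues, chains: %s\n",
              x$structure_id, nrow(x$atoms),
              nrow(unique(x$atoms[c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records via `bio3d::read.pdb` and reduces them to the subset
#' used for spatial feature computation: first model, first alternate
#' location per atom, HETATM and non-standard residues dropped. Residues
#' without a C-alpha atom are discarded.
#'
#' @param path Path to a PDB file.
#' @return A `phos_structure` (see [ca_structure()]); its `atoms` table may
#'   contain several atoms per residue.
#' @export
read_pdb_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path, call. = FALSE)
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  keep <- !is.na(aa1) & aa1 %in% AA20
  at <- at[keep, , drop = FALSE]
  aa1 <- aa1[keep]
  if (!nrow(at)) stop("no standard amino acid ATOM records in ", path,
                      call. = FALSE)
  # first altloc per (chain, residue, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  first <- !duplicated(key)
  at <- at[first, , drop = FALSE]
  aa1 <- aa1[first]
  atoms <- data.frame(chain = at$chain, resno = at$resno, aa = aa1,
                      atom = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  # keep only residues that retain a CA
  has_ca <- unique(paste(atoms$chain, atoms$resno)[atoms$atom == "CA"])
  atoms <- atoms[paste(atoms$chain, atoms$resno) %in% has_ca, , drop = FALSE]
  if (!nrow(atoms)) stop("no residues with a C-alpha atom in ", path,
                         call. = FALSE)
  ord <- order(atoms$chain, atoms$resno, match(atoms$atom, "CA",
                                               nomatch = 2L))
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(structure_id = sub("\\.pdb$", "", basename(path)),
                 atoms = atoms),
            class = "phos_structure")
}

#' Write a structure to a PDB file
#'
#' @param struct A `phos_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = bio3d::aa123(a$aa),
                   chain = a$chain, elety = a$atom)
  invisible(path)
}

#' Per-chain residue table of a structure
#'
#' @param struct A `phos_structure`.
#' @param chain_id Chain to extract (default: first chain).
#' @param atom_mode Reference atom per residue: `"CA"`, `"CB"` (CA fallback
#'   for glycine) or `"any_heavy"` (all heavy atoms retained; the residue
#'   coordinate is resolved at distance-computation time).
#' @return Data frame with one row per residue (`resno`, `aa`, `x`, `y`, `z`)
#'   ordered by residue number; for `"any_heavy"` an additional list column
#'   `coords` holds the per-residue atom coordinate matrices.
#' @export
chain_residues <- function(struct, chain_id = NULL,
                           atom_mode = c("CA", "CB", "any_heavy")) {
  atom_mode <- match.arg(atom_mode)
  a <- struct$atoms
  if (is.null(chain_id)) chain_id <- sort(unique(a$chain))[1]
  a <- a[a$chain == chain_id, , drop = FALSE]
  if (!nrow(a)) stop("chain '", chain_id, "' not found in structure ",
                     struct$structure_id, call. = FALSE)
  resnos <- sort(unique(a$resno))
  ref <- lapply(resnos, function(r) {
    ra <- a[a$resno == r, , drop = FALSE]
    if (atom_mode == "any_heavy") {
      return(list(aa = ra$aa[1],
                  coords = as.matrix(ra[, c("x", "y", "z")])))
    }
    want <- if (atom_mode == "CB" && any(ra$atom == "CB")) "CB" else "CA"
    row <- ra[ra$atom == want, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    list(aa = row$aa[1], coords = as.matrix(row[1, c("x", "y", "z")]))
  })
  keep <- !vapply(ref, is.null, TRUE)
  resnos <- resnos[keep]
  ref <- ref[keep]
  out <- data.frame(resno = resnos,
                    aa = vapply(ref, function(r) r$aa, ""),
                    x = vapply(ref, function(r) r$coords[1, 1], 0),
                    y = vapply(ref, function(r) r$coords[1, 2], 0),
                    z = vapply(ref, function(r) r$coords[1, 3], 0),
                    stringsAsFactors = FALSE)
  if (atom_mode == "any_heavy") {
    out$coords <- lapply(ref, function(r) r$coords)
  }
  out
}

#' Derive the one-letter sequence of a chain
#'
#' @inheritParams chain_residues
#' @return Single string (residues in residue-number order).
#' @export
chain_sequence <- function(struct, chain_id = NULL) {
  paste(chain_residues(struct, chain_id)$aa, collapse = "")
}

# ---- DSSP and annotation tables -------------------------------------------

#' Parse a DSSP output file
#'
#' Reads the per-residue block of a standard DSSP output file. The `ACC`
#' column is taken as the absolute accessible surface area; relative ASA is
#' `min(1, ACC / maxASA)` with the per-residue maximum from [MAX_ASA]
#' (configurable). The 8-state secondary structure is collapsed to 3 states:
#' H, G, I to `"H"`; E, B to `"E"`; everything else to `"C"`.
#'
#' @param path Path to a DSSP output file.
#' @param max_asa Named numeric vector of per-residue maximum ASA values.
#' @return Data frame with columns `chain`, `resno`, `aa`, `ss3`,
#'   `asa_abs`, `asa_rel`.
#' @export
read_dssp <- function(path, max_asa = MAX_ASA) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("DSSP header line ('  #  RESIDUE ...') not found in ",
                         path, call. = FALSE)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 38L]
  aa <- substr(body, 14L, 14L)
  keep <- aa != "!"  # chain-break records
  body <- body[keep]; aa <- aa[keep]
  resno <- as.integer(substr(body, 6L, 10L))
  chain <- trimws(substr(body, 12L, 12L))
  ss8 <- substr(body, 17L, 17L)
  acc <- as.numeric(substr(body, 35L, 38L))
  ss3 <- ifelse(ss8 %in% c("H", "G", "I"), "H",
                ifelse(ss8 %in% c("E", "B"), "E", "C"))
  # lower-case letters in the AA column are half-cystines in SS-bonds
  aa <- ifelse(aa %in% letters, "C", aa)
  mx <- unname(max_asa[aa])
  rel <- ifelse(is.na(mx) | mx <= 0, NA_real_, pmin(1, acc / mx))
  data.frame(chain = chain, resno = resno, aa = aa, ss3 = ss3,
             asa_abs = acc, asa_rel = rel, stringsAsFactors = FALSE)
}

#' Read a precomputed per-residue annotation table
#'
#' TSV with columns `protein_id`, `position`, `asa_rel`, `ss3`; this format
#' stands in for the per-residue output of sequence-based ASA and secondary
#' structure predictors.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the four columns, validated (`asa_rel` in
#'   `[0, 1]`, `ss3` in H/E/C).
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "asa_rel", "ss3")
  if (!all(need %in% names(tab))) {
    stop("annotation table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tab$asa_rel < 0 | tab$asa_rel > 1, na.rm = TRUE)) {
    stop("asa_rel values outside [0, 1] in ", path, call. = FALSE)
  }
  if (any(!tab$ss3 %in% c("H", "E", "C"))) {
    stop("ss3 values outside {H, E, C} in ", path, call. = FALSE)
  }
  tab$position <- as.integer(tab$position)
  tab
}

#' Write a per-residue annotation table as TSV
#'
#' @param annotations Data frame as returned by [read_annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations[, c("protein_id", "position",
                                     "asa_rel", "ss3")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- site-to-structure mapping --------------------------------------------

#' Map a phosphosite onto a structure chain by sequence identity
#'
#' The site's sequence window is aligned without gaps against the derived
#' sequence of every chain. For each candidate placement, identity is the
#' fraction of matching letters among the window positions that are both
#' non-terminal and inside the chain; a placement qualifies when that
#' overlap covers at least `min_overlap` positions (capped at the number of
#' non-terminal window letters), identity is at least `min_identity`, and
#' the mapped residue type equals the site residue. The highest-identity
#' placement wins; ties go to the first chain in lexicographic order, then
#' to the leftmost placement.
#'
#' @param protein A [protein_record()].
#' @param site One-row site data frame (or list) with `position`, `residue`.
#' @param struct A `phos_structure`.
#' @param min_identity Minimum window identity (default 1.0 — exact).
#' @param min_overlap Minimum aligned window positions (default 13; capped
#'   at the available non-terminal letters).
#' @param flank Window flank (default 6).
#' @return A list with `protein_id`, `position`, `structure_id`, `chain_id`,
#'   `residue_number`, `identity`, or `NULL` when no placement qualifies.
#' @export
map_site_to_structure <- function(protein, site, struct,
                                  min_identity = 1.0, min_overlap = 13L,
                                  flank = 6L) {
  win <- extract_window(protein, site$position, flank = flank)
  wl <- seq_chars(win)
  w <- length(wl)
  n_real <- sum(wl != TERMINAL_SYMBOL)
  need <- min(min_overlap, n_real)
  best <- NULL
  for (ch in sort(unique(struct$atoms$chain))) {
    res <- chain_residues(struct, ch)
    cl <- res$aa
    n <- length(cl)
    for (centre in seq_len(n)) {
      if (cl[centre] != site$residue) next
      idx <- (centre - flank):(centre + flank)
      ok <- idx >= 1L & idx <= n & wl != TERMINAL_SYMBOL
      overlap <- sum(ok)
      if (overlap < need) next
      ident <- sum(wl[ok] == cl[idx[ok]]) / overlap
      if (ident < min_identity) next
      if (is.null(best) || ident > best$identity) {
        best <- list(protein_id = protein$id,
                     position = as.integer(site$position),
                     structure_id = struct$structure_id,
                     chain_id = ch,
                     residue_number = res$resno[centre],
                     identity = ident)
      }
    }
  }
  best
}
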