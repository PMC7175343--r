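#' Load a crystal structure into residue records
#'
#' Reads a PDB or mmCIF structure (file path or raw text) and returns one
#' record per residue of the chosen biological assembly, including bound
#' hetero ions. Residues listed in the sequence records (SEQRES) but absent
#' from the coordinates are included with `resolved = FALSE`; in typical
#' crystal structures of flexible proteins a large fraction of residues is
#' unresolved (about 35% for fibrinogen). Waters are dropped; other hetero
#' groups (e.g. glycans) are dropped with a message. Alternate locations:
#' the first altloc is kept.
#'
#' @param input Path to a `.pdb`/`.cif` file, or the file content as a
#'   single string.
#' @param assembly Biological assembly number. If the file carries
#'   REMARK 350 transformations, the corresponding assembly is generated
#'   (symmetry copies included); otherwise only assembly 1 (the deposited
#'   coordinates) is available.
#' @return An object of class `structure_records`: list with
#'   `residues` (data.frame: chain, resno, resid, resolved, is_ion,
#'   element), `atoms` (data.frame: chain, resno, resid, elety, element,
#'   x, y, z) and `source`.
#' @export
#' @examples
#' pdb_text <- make_toy_pdb()
#' rec <- load_structure(pdb_text)
#' table(rec$residues$resolved)
load_structure <- function(input, assembly = 1) {
  path <- .as_structure_file(input)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE) ||
    startsWith(trimws(readLines(path, n = 1L, warn = FALSE)), "data_")
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop(sprintf("failed to parse structure file: %s",
                                     conditionMessage(e)), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("failed to parse structure file: no atom records found",
         call. = FALSE)
  pdb <- .select_assembly(pdb, assembly)
  .records_from_pdb(pdb, basename(path))
}

.as_structure_file <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
    return(input)
  path <- tempfile(fileext = if (grepl("^data_", input[1])) ".cif" else ".pdb")
  writeLines(unlist(strsplit(input, "\n")), path)
  path
}

.select_assembly <- function(pdb, assembly) {
  biomat <- tryCatch(pdb$remark$biomat, error = function(e) NULL)
  n_avail <- if (is.null(biomat)) 1L else biomat$num
  if (is.null(biomat) || n_avail < 1) n_avail <- 1L
  if (!assembly %in% seq_len(n_avail))
    stop(sprintf("unknown assembly %s; available assemblies: %s",
                 assembly, paste(seq_len(n_avail), collapse = ", ")))
  if (is.null(biomat)) return(pdb)
  ## identity-only assemblies leave the coordinates untouched; biounit()
  ## applies the stored transformation matrices otherwise
  units <- tryCatch(suppressWarnings(bio3d::biounit(pdb)),
                    error = function(e) NULL)
  if (is.null(units) || length(units) < assembly) return(pdb)
  out <- units[[assembly]]
  out$seqres <- pdb$seqres
  out$remark <- pdb$remark
  out
}

.records_from_pdb <- function(pdb, source = "structure") {
  at <- pdb$atom
  at$element <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                      substr(trimws(at$elety), 1, 1),
                                      at$elesy)))
  at <- at[at$resid != "HOH", , drop = FALSE]

  is_ion_row <- at$type == "HETATM" & at$resid %in% .ion_table$resid
  is_prot <- at$type == "ATOM" & at$resid %in% names(.aa1)
  dropped <- unique(at$resid[!(is_ion_row | is_prot)])
  if (length(dropped))
    message("dropping hetero groups: ", paste(dropped, collapse = ", "))
  at <- at[is_ion_row | is_prot, , drop = FALSE]

  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety), element = at$element,
                      x = at$x, y = at$y, z = at$z,
                      is_ion = at$type == "HETATM" & at$resid %in% .ion_table$resid,
                      stringsAsFactors = FALSE)

  prot <- atoms[!atoms$is_ion, , drop = FALSE]
  key <- paste(prot$chain, prot$resno)
  first <- !duplicated(key)
  resolved <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                         resid = prot$resid[first], stringsAsFactors = FALSE)
  resolved <- resolved[order(resolved$chain, resolved$resno), , drop = FALSE]

  residues <- .merge_seqres(resolved, pdb$seqres)

  ions <- atoms[atoms$is_ion, , drop = FALSE]
  if (nrow(ions)) {
    residues <- rbind(residues, data.frame(
      chain = ions$chain, resno = ions$resno, resid = ions$resid,
      resolved = TRUE, is_ion = TRUE, element = ions$element,
      stringsAsFactors = FALSE))
  }
  rownames(residues) <- NULL
  out <- list(residues = residues, atoms = atoms, source = source)
  class(out) <- "structure_records"
  out
}

## Align per-chain SEQRES entries with the resolved residues to recover the
## unresolved ones. Greedy in-order name matching: adequate for structures
## whose resolved residues appear in SEQRES order (the PDB convention).
.merge_seqres <- function(resolved, seqres) {
  base <- data.frame(resolved, resolved = TRUE, is_ion = FALSE,
                     element = NA_character_, stringsAsFactors = FALSE)
  if (is.null(seqres) || !length(seqres)) return(base)
  out <- list()
  chains <- unique(c(unique(base$chain), unique(names(seqres))))
  for (ch in chains) {
    sq <- unname(seqres[names(seqres) == ch])
    rs <- base[base$chain == ch, , drop = FALSE]
    if (!length(sq)) { out[[ch]] <- rs; next }
    ri <- 1L
    match_idx <- integer(length(sq)) # resolved row matched by seqres pos (0 = none)
    for (si in seq_along(sq)) {
      if (ri <= nrow(rs) && rs$resid[ri] == sq[si] &&
          (nrow(rs) - ri) <= (length(sq) - si)) {
        match_idx[si] <- ri
        ri <- ri + 1L
      }
    }
    if (ri <= nrow(rs)) {
      ## alignment failed (names out of order); keep resolved records and
      ## count the unmatched seqres entries as unresolved without numbering
      warning(sprintf("chain %s: could not align SEQRES with coordinates", ch))
      extra <- table(sq)[setdiff(unique(sq), character(0))]
      unres <- sq[!seq_along(sq) %in% which(match_idx > 0)]
    } else {
      unres <- sq[match_idx == 0]
    }
    resno_un <- .interpolate_resno(match_idx, rs$resno)
    df_un <- if (length(unres)) data.frame(
      chain = ch, resno = resno_un, resid = unres,
      resolved = FALSE, is_ion = FALSE, element = NA_character_,
      stringsAsFactors = FALSE) else NULL
    chunk <- rbind(rs, df_un)
    chunk <- chunk[order(is.na(chunk$resno), chunk$resno), , drop = FALSE]
    out[[ch]] <- chunk
  }
  do.call(rbind, out)
}

## author residue numbers for unresolved seqres positions, extrapolated from
## the nearest matched neighbor
.interpolate_resno <- function(match_idx, resno_resolved) {
  n <- length(match_idx)
  resno <- ifelse(match_idx > 0, resno_resolved[pmax(match_idx, 1L)],
                  NA_real_)
  resno[match_idx == 0] <- NA_real_
  for (i in seq_len(n)) if (match_idx[i] == 0) {
    prev <- if (i > 1) resno[i - 1] else NA_real_
    resno[i] <- if (!is.na(prev)) prev + 1 else NA_real_
  }
  ## backward pass for a leading unresolved stretch
  for (i in rev(seq_len(n))) if (match_idx[i] == 0 && is.na(resno[i])) {
    nxt <- if (i < n) resno[i + 1] else NA_real_
    resno[i] <- if (!is.na(nxt)) nxt - 1 else NA_real_
  }
  resno[match_idx == 0]
}

#' @export
print.structure_records <- function(x, ...) {
  r <- x$residues
  cat(sprintf("Structure records from %s: %d residues (%d chains), %d ions\n",
              x$source, sum(!r$is_ion), length(unique(r$chain[!r$is_ion])),
              sum(r$is_ion)))
  cat(sprintf("  unresolved residues: %d (%.1f%%)\n", sum(!r$resolved),
              100 * mean(!r$resolved[!r$is_ion])))
  invisible(x)
}

#' Fraction of residues unresolved in the coordinates
#'
#' @param records A [load_structure()] result.
#' @return Fraction in `[0, 1]` (ions excluded from the denominator).
#' @export
unresolved_fraction <- function(records) {
  r <- records$residues[!records$residues$is_ion, , drop = FALSE]
  mean(!r$resolved)
}

#' Coarse-grain a crystal structure into a rigid bead model
#'
#' One bead per resolved residue, centered on the C-alpha atom; one bead per
#' bound ion at the ion position; and one extra bead per chain for each
#' *physically present* terminus (the backbone N atom of the first residue
#' and the carboxyl C atom of the last). A terminus whose flanking residues
#' are unresolved (a truncated chain, such as the fibrinogen A-alpha chains
#' whose C-terminal 410 residues are missing from the crystal structure)
#' gets no terminal bead, so its charge is absent from the model. Unresolved
#' residues produce no beads. Charges are all zero until [assign_charges()].
#'
#' @param records A [load_structure()] result.
#' @param bead_radius Bead radius in Angstrom (default 2.5).
#' @param exclude_chains Chain identifiers to drop (e.g. co-crystallized
#'   synthetic peptides).
#' @return A rigid [bead_model()].
#' @export
coarse_grain_rigid <- function(records, bead_radius = 2.5,
                               exclude_chains = NULL) {
  res <- records$residues
  res <- res[!res$chain %in% exclude_chains, , drop = FALSE]
  atoms <- records$atoms
  atoms <- atoms[!atoms$chain %in% exclude_chains, , drop = FALSE]
  if (!any(res$resolved & !res$is_ion))
    stop("no resolved residues to coarse-grain")

  pos <- NULL; lab <- chain <- character(0); mass <- numeric(0)
  add <- function(p, l, ch, m) {
    pos <<- rbind(pos, p); lab <<- c(lab, l); chain <<- c(chain, ch)
    mass <<- c(mass, m)
  }
  .atom_xyz <- function(ch, rn, names_try) {
    for (nm in names_try) {
      hit <- atoms$chain == ch & atoms$resno == rn & atoms$elety == nm
      if (any(hit)) return(as.numeric(atoms[which(hit)[1], c("x", "y", "z")]))
    }
    NULL
  }

  for (ch in unique(res$chain[!res$is_ion])) {
    rch <- res[res$chain == ch & !res$is_ion, , drop = FALSE]
    rch <- rch[order(is.na(rch$resno), rch$resno), , drop = FALSE]
    solved <- rch[rch$resolved, , drop = FALSE]
    if (!nrow(solved)) next
    for (k in seq_len(nrow(solved))) {
      ca <- .atom_xyz(ch, solved$resno[k], "CA")
      if (is.null(ca))
        stop(sprintf("residue %s %s%s has no C-alpha atom and is not an ion",
                     solved$resid[k], ch, solved$resno[k]))
      m <- .residue_mass[solved$resid[k]]
      if (is.na(m)) { warning("unknown residue mass for ", solved$resid[k])
        m <- mean(.residue_mass) }
      add(ca, solved$resid[k], ch, m)
    }
    ## terminal charge beads only where the terminus is physically present
    n_complete <- rch$resolved[1]
    c_complete <- rch$resolved[nrow(rch)]
    if (n_complete) {
      p <- .atom_xyz(ch, solved$resno[1], c("N", "CA"))
      add(p, "NTERM", ch, 16.023)
    }
    if (c_complete) {
      p <- .atom_xyz(ch, solved$resno[nrow(solved)], c("C", "CA"))
      add(p, "CTERM", ch, 45.017)
    }
  }

  ions <- res[res$is_ion, , drop = FALSE]
  for (k in seq_len(nrow(ions))) {
    hit <- atoms$is_ion & atoms$chain == ions$chain[k] &
      atoms$resno == ions$resno[k]
    p <- as.numeric(atoms[which(hit)[1], c("x", "y", "z")])
    m <- .ion_table$mass[match(ions$resid[k], .ion_table$resid)]
    add(p, ions$resid[k], ions$chain[k], m)
  }

  bead_model(pos, radius = bead_radius, charge = 0, mass = mass,
             label = lab, rigid = TRUE, chain = chain)
}

#' Assign point charges to a bead model
#'
#' Applies a [default_charge_rules()]-style table: titratable residues get
#' their integer charge at pH 7.4, terminal beads their +1/-1, ions their
#' formal charge; every other label gets zero. Unknown labels produce a
#' warning and zero charge. Re-applying the rules is idempotent.
#'
#' @param model A [bead_model()].
#' @param rules A `charge_rules` object.
#' @return The model with charges set.
#' @export
assign_charges <- function(model, rules = default_charge_rules()) {
  q <- numeric(n_beads(model))
  lab <- model$label
  known <- rep(FALSE, length(lab))
  hit <- lab %in% names(rules$residue)
  q[hit] <- rules$residue[lab[hit]]; known <- known | hit
  hit <- lab == "NTERM"; q[hit] <- rules$n_terminal; known <- known | hit
  hit <- lab == "CTERM"; q[hit] <- rules$c_terminal; known <- known | hit
  hit <- lab %in% names(rules$ions)
  q[hit] <- rules$ions[lab[hit]]; known <- known | hit
  if (any(!known))
    warning("unknown bead labels assigned charge 0: ",
            paste(unique(lab[!known]), collapse = ", "))
  model$charge <- q
  model
}

#' Charge carried by unresolved residues
#'
#' Sums the side-chain charges of the residues present in the sequence
#' records but missing from the coordinates, optionally adding one
#' C-terminal (and/or N-terminal) charge for every chain truncated at that
#' end. Adding this to [net_charge()] of the rigid model gives the net
#' charge of the full molecule (for fibrinogen: -8 for the main body,
#' -12 including the unresolved A-alpha parts).
#'
#' @param records A [load_structure()] result.
#' @param rules A `charge_rules` object.
#' @param include_cterm Count -1 for each chain with an unresolved
#'   C-terminal tail (default TRUE).
#' @param include_nterm Count +1 for each chain with an unresolved
#'   N-terminal stretch (default FALSE).
#' @param exclude_chains Chains to drop.
#' @return Signed total charge of the unresolved parts.
#' @export
unresolved_charge <- function(records, rules = default_charge_rules(),
                              include_cterm = TRUE, include_nterm = FALSE,
                              exclude_chains = NULL) {
  res <- records$residues
  res <- res[!res$is_ion & !res$chain %in% exclude_chains, , drop = FALSE]
  un <- res[!res$resolved, , drop = FALSE]
  q <- sum(rules$residue[un$resid], na.rm = TRUE)
  for (ch in unique(res$chain)) {
    rch <- res[res$chain == ch, , drop = FALSE]
    rch <- rch[order(is.na(rch$resno), rch$resno), , drop = FALSE]
    if (include_cterm && nrow(rch) && !rch$resolved[nrow(rch)])
      q <- q + rules$c_terminal
    if (include_nterm && nrow(rch) && !rch$resolved[1])
      q <- q + rules$n_terminal
  }
  q
}

#' Build a flexible chain model from a sequence
#'
#' One bead per residue plus two terminal charge beads, consecutive beads
#' bonded, initialized as a straight line along +z at the equilibrium bond
#' length. The smaller default radius (2.0 Angstrom vs 2.5 for the rigid
#' model) allows realistic center-to-center distances between bonded
#' residues. Charges are zero until [assign_charges()].
#'
#' @param sequence One-letter amino-acid string (e.g. residues 201-610 of
#'   the fibrinogen A-alpha chain for the alpha-C fragment).
#' @param bead_radius Bead radius in Angstrom (default 2.0).
#' @param bond_length Initial bond length in Angstrom (default 4.1, the
#'   harmonic equilibrium distance).
#' @return A flexible [bead_model()] with `length(sequence) + 2` beads.
#' @export
#' @examples
#' ch <- build_flexible_chain("AAA")
#' n_beads(ch) # 5
build_flexible_chain <- function(sequence, bead_radius = 2.0,
                                 bond_length = 4.1) {
  codes <- .seq_to_codes(sequence)
  n <- length(codes)
  if (n < 1) stop("sequence must be non-empty")
  lab <- c("NTERM", codes, "CTERM")
  mass <- c(16.023, unname(.residue_mass[codes]), 45.017)
  ntot <- n + 2L
  pos <- cbind(0, 0, bond_length * (seq_len(ntot) - 1))
  bonds <- cbind(seq_len(ntot - 1L), 2:ntot)
  bead_model(pos, radius = bead_radius, charge = 0, mass = mass,
             label = lab, bonds = bonds, rigid = FALSE)
}
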