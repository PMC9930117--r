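#' Molecular graphs and library input/output
#'
#' Molecules are carried in a tibble with one row per compound: an `id`
#' column, the canonical `smiles`, and a `graph` list-column holding the
#' perceived molecular graph (atoms with element, SYBYL atom type,
#' aromaticity, formal charge, implicit hydrogen count; bonds with order
#' tokens).  Structure perception (SMILES parsing, aromaticity, atom typing)
#' is delegated to Open Babel via ChemmineOB; everything downstream operates
#' on the plain graph.
#'
#' @name vsfuse-molecules
NULL

BOND_TOKEN <- c("1" = "-", "2" = "=", "3" = "#", "am" = "-", "ar" = ":",
                "du" = "-", "un" = "-", "nc" = "-")
BOND_ORDER <- c("1" = 1, "2" = 2, "3" = 3, "am" = 1, "ar" = 1.5,
                "du" = 1, "un" = 1, "nc" = 0)

ob_convert <- function(src, from, to, add_hydrogens = FALSE) {
  # "e" (continue after errors) keeps one bad record from ending the batch;
  # no coordinate generation: 2D layout is never needed for the graphs
  opts <- if (add_hydrogens) {
    data.frame(names = c("e", "h"), args = c("", ""))
  } else {
    data.frame(names = "e", args = "")
  }
  ChemmineOB::convertFormat(from, to, source = src, options = opts)
}

smiles_source <- function(smiles, token) {
  paste0(paste(smiles, token, collapse = "\n"), "\n")
}

# Open Babel molecule references for a vector of (valid) SMILES; the
# efficient entry point for property and SMARTS computations.
obmols_from_smiles <- function(smiles, ids = NULL) {
  src <- smiles_source(smiles, ids %||% paste0("M", seq_along(smiles)))
  refs <- ChemmineOB::forEachMol("SMILES", src, identity)
  names(refs) <- ids
  refs
}

# Canonicalise SMILES one batch at a time, falling back to per-record
# conversion for anything the batch pass dropped (the stream reader can
# skip the record following a malformed one, so stragglers get a second,
# isolated chance).  Returns a token -> canonical SMILES map.
canonical_smiles_map <- function(smiles, token) {
  batch <- tryCatch(
    suppressWarnings(ob_convert(smiles_source(smiles, token), "SMI", "CAN")),
    error = function(e) "")
  rows <- strsplit(trimws(strsplit(batch, "\n")[[1]]), "\\s+")
  rows <- rows[lengths(rows) == 2]
  can_map <- setNames(vapply(rows, `[[`, character(1), 1),
                      vapply(rows, `[[`, character(1), 2))
  can_map <- can_map[names(can_map) %in% token]
  missing <- setdiff(token, names(can_map))
  for (tk in missing) {
    smi <- smiles[match(tk, token)]
    out <- tryCatch(
      suppressWarnings(ob_convert(paste0(smi, " ", tk, "\n"), "SMI", "CAN")),
      error = function(e) "")
    f <- strsplit(trimws(out), "\\s+")[[1]]
    if (length(f) == 2 && identical(f[2], tk)) can_map[tk] <- f[1]
  }
  can_map
}

# Extract "M  CHG" overrides per molecule from raw SDF text; returns a list
# (by title) of named integer vectors atom_index -> formal charge.
sdf_chg_overrides <- function(sdf_text) {
  blocks <- strsplit(sdf_text, "\\$\\$\\$\\$\n?")[[1]]
  out <- list()
  for (b in blocks) {
    lines <- strsplit(b, "\n")[[1]]
    lines <- lines[nzchar(lines) | seq_along(lines) == 1]
    if (length(lines) < 4) next
    title <- trimws(lines[1])
    chg_lines <- grep("^M  CHG", lines, value = TRUE)
    if (length(chg_lines) == 0) next
    chg <- integer(0)
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
      npairs <- f[1]
      for (k in seq_len(npairs)) {
        chg[as.character(f[2 * k])] <- f[2 * k + 1]
      }
    }
    out[[title]] <- chg
  }
  out
}

# Formal charges per heavy atom, by internal token, from an SDF conversion.
# Reads the V2000 atom-block charge codes (field 6 of each atom line),
# overridden by "M  CHG" lines when present.  Only the charge/element fields
# are taken from the SDF text; all structure perception is done elsewhere.
charges_from_sdf <- function(smiles, token) {
  sdf_text <- ob_convert(smiles_source(smiles, token), "SMI", "SDF")
  overrides <- sdf_chg_overrides(sdf_text)
  code_map <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L,
                "5" = -1L, "6" = -2L, "7" = -3L)
  blocks <- strsplit(sdf_text, "\\$\\$\\$\\$\n?")[[1]]
  out <- list()
  for (b in blocks) {
    lines <- strsplit(b, "\n")[[1]]
    if (length(lines) && !nzchar(trimws(lines[1])) && length(lines) > 1 &&
        !nzchar(trimws(lines[2]))) lines <- lines[-1]
    if (length(lines) < 4) next
    title <- trimws(lines[1])
    natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
    if (is.na(natoms) || natoms < 1) next
    atom_lines <- lines[5:(4 + natoms)]
    fields <- strsplit(trimws(atom_lines), "\\s+")
    elem <- vapply(fields, `[[`, character(1), 4)
    chg <- unname(code_map[vapply(fields, `[[`, character(1), 6)])
    chg[is.na(chg)] <- 0L
    ov <- overrides[[title]]
    if (!is.null(ov)) {
      chg <- rep(0L, natoms)
      chg[as.integer(names(ov))] <- ov
    }
    out[[title]] <- list(element = elem, charge = as.integer(chg))
  }
  out
}

# Build a molecular graph from one bio3d mol2 record plus formal charges.
mol2_to_graph <- function(m2, charges) {
  at <- m2$atom
  bd <- m2$bond
  is_h <- toupper(at$elena) == "H"
  heavy_idx <- which(!is_h)
  map <- integer(nrow(at))
  map[heavy_idx] <- seq_along(heavy_idx)
  n <- length(heavy_idx)

  nh <- integer(n)
  bi <- integer(0); bj <- integer(0); btype <- character(0)
  if (!is.null(bd) && nrow(bd) > 0) {
    orig <- bd$origin; targ <- bd$target; type <- as.character(bd$type)
    ho <- is_h[orig]; ht <- is_h[targ]
    nh <- tabulate(c(map[targ[ho & !ht]], map[orig[ht & !ho]]), n)
    hh <- !ho & !ht
    bi <- map[orig[hh]]; bj <- map[targ[hh]]; btype <- type[hh]
  }
  token <- unname(BOND_TOKEN[btype])
  token[is.na(token)] <- "-"
  order_num <- unname(BOND_ORDER[btype])
  order_num[is.na(order_num)] <- 1

  degree <- tabulate(c(bi, bj), n)
  bsum <- numeric(n)
  if (length(bi)) {
    agg <- rowsum(c(order_num, order_num), group = c(bi, bj))
    bsum[as.integer(rownames(agg))] <- agg[, 1]
  }
  arom <- logical(n)
  arom[unique(c(bi[token == ":"], bj[token == ":"]))] <- TRUE
  element <- at$elena[heavy_idx]
  charge <- charges %||% rep(0L, n)
  valence <- as.integer(round(bsum)) + nh
  atoms <- tibble(
    element = element,
    sybyl = at$elety[heavy_idx],
    arom = arom,
    charge = as.integer(charge),
    nh = nh,
    degree = degree,
    valence = valence,
    x = at$x[heavy_idx], y = at$y[heavy_idx], z = at$z[heavy_idx]
  )
  atoms$daylight <- daylight_token(atoms)
  list(atoms = atoms,
       bonds = tibble(i = bi, j = bj, token = token, order = order_num))
}

# Daylight-style atom typing: atomic number, valence, formal charge, number
# of hydrogen connections and number of heavy-atom connections.
daylight_token <- function(atoms) {
  sprintf("%d,%d,%+d,%d,%d", atomic_number(atoms$element), atoms$valence,
          atoms$charge, atoms$nh, atoms$degree)
}

#' Parse SMILES into molecule records
#'
#' Builds the molecule tibble used throughout the package.  Unparseable
#' SMILES are skipped and reported through the `parse_failures` attribute
#' (a tibble of id and input string), mirroring how a screening library is
#' ingested: bad entries are logged, not fatal.
#'
#' @param smiles character vector of SMILES strings.
#' @param id compound identifiers; auto-generated (`REC<n>`) when `NULL`.
#' @param formal_charges read per-atom formal charges from an additional
#'   format conversion (default); disable for inputs known to be neutral
#'   (all charges are then 0), which skips one conversion pass.
#' @return a tibble with columns `id`, `smiles` (canonical form) and
#'   `graph` (list of molecular graphs), with attribute `parse_failures`.
#' @examples
#' mols <- parse_molecules(c("CCO", "c1ccccc1"), id = c("ethanol", "benzene"))
#' mols$smiles
#' @export
parse_molecules <- function(smiles, id = NULL, formal_charges = TRUE) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  if (is.null(id)) id <- paste0("REC", seq_along(smiles))
  id <- as.character(id)
  if (anyDuplicated(id)) abort("duplicate compound ids in input")
  token <- paste0("VSF", seq_along(smiles))

  can_map <- canonical_smiles_map(smiles, token)
  valid <- token %in% names(can_map)
  # structure perception runs once per unique canonical form, so graph
  # atom order always corresponds to the stored `smiles` column and
  # duplicated structures share one conversion
  uniq <- unique(unname(can_map[token[valid]]))
  utoken <- paste0("U", seq_along(uniq))

  m2 <- list()
  if (length(uniq)) {
    src <- smiles_source(uniq, utoken)
    mol2_text <- suppressWarnings(ob_convert(src, "SMI", "MOL2",
                                             add_hydrogens = TRUE))
    # parse record by record: multi-record parsing can coalesce
    # consecutive identical molecules into one multi-model entry
    chunks <- strsplit(mol2_text, "@<TRIPOS>MOLECULE\n", fixed = TRUE)[[1]]
    chunks <- chunks[nzchar(trimws(chunks))]
    tf <- tempfile(fileext = ".mol2")
    on.exit(unlink(tf))
    for (ch in chunks) {
      writeLines(paste0("@<TRIPOS>MOLECULE\n", ch), tf)
      rec <- tryCatch(bio3d::read.mol2(tf), error = function(e) NULL)
      if (!is.null(rec) && inherits(rec, "mol2")) m2[[rec$name]] <- rec
    }
  }

  umap <- setNames(utoken, uniq)
  have <- uniq[utoken %in% names(m2)]
  charges <- if (length(have) && formal_charges)
    charges_from_sdf(have, unname(umap[have])) else list()

  # one graph per unique structure
  ugraph <- list()
  for (u in have) {
    ut <- umap[[u]]
    chg <- charges[[ut]]
    n_heavy <- sum(toupper(m2[[ut]]$atom$elena) != "H")
    if (!is.null(chg) && length(chg$charge) != n_heavy) chg <- NULL
    g2 <- tryCatch(mol2_to_graph(m2[[ut]], chg$charge),
                   error = function(e) NULL)
    if (is.null(g2) ||
        (!is.null(chg) && !identical(toupper(g2$atoms$element),
                                     toupper(chg$element)))) {
      # format conversions disagree on the structure: treat as unparseable
      next
    }
    ugraph[[u]] <- g2
  }

  ok <- valid
  graphs <- vector("list", length(token))
  for (k in which(valid)) {
    g2 <- ugraph[[can_map[[token[k]]]]]
    if (is.null(g2)) ok[k] <- FALSE else graphs[[k]] <- g2
  }
  out <- tibble(id = id[ok], smiles = unname(can_map[token[ok]]),
                graph = graphs[ok])
  attr(out, "parse_failures") <- tibble(id = id[!ok], input = smiles[!ok])
  class(out) <- c("vs_mols", class(out))
  out
}

#' @export
print.vs_mols <- function(x, ...) {
  pf <- attr(x, "parse_failures")
  cat("# Molecule library: ", nrow(x), " compounds",
      if (!is.null(pf) && nrow(pf) > 0) paste0(" (", nrow(pf),
                                               " unparseable skipped)"),
      "\n", sep = "")
  NextMethod()
}

#' Read a compound library
#'
#' Reads a SMILES (`.smi`, whitespace-separated `SMILES id` per line) or an
#' SDF (V2000) file into a molecule tibble.  Entries that fail to parse are
#' skipped and counted in the `parse_failures` attribute.
#'
#' @param path input file.
#' @param format `"smiles"` or `"sdf"`; guessed from the extension when
#'   missing.
#' @return molecule tibble as from [parse_molecules()].
#' @export
read_library <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
              else "smiles"
  }
  if (format == "smiles") {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) abort("no records in SMILES file")
    parts <- strsplit(lines, "\\s+")
    smi <- vapply(parts, `[[`, character(1), 1)
    id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                 character(1))
    id[is.na(id)] <- paste0("REC", which(is.na(id)))
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    id <- ChemmineR::sdfid(sdfset)
    id[!nzchar(id) | is.na(id)] <- paste0("REC", which(!nzchar(id) | is.na(id)))
    smi_text <- suppressWarnings(
      ChemmineOB::convertFormat("SDF", "CAN",
                                source = paste(readLines(path),
                                               collapse = "\n")))
    rows <- strsplit(trimws(strsplit(smi_text, "\n")[[1]]), "\t")
    rows <- rows[lengths(rows) >= 1]
    smi <- vapply(rows, `[[`, character(1), 1)
    if (length(smi) != length(id)) {
      # fall back to per-record conversion so skipped entries stay aligned
      smi <- vapply(seq_along(sdfset), function(k) {
        txt <- paste(ChemmineR::sdf2str(sdfset[[k]]), collapse = "\n")
        out <- tryCatch(suppressWarnings(
          ChemmineOB::convertFormat("SDF", "CAN", source = txt)),
          error = function(e) "")
        s <- strsplit(trimws(out), "\\s+")[[1]]
        if (length(s) >= 1 && nzchar(s[1])) s[1] else NA_character_
      }, character(1))
      keep <- !is.na(smi)
      id <- id[keep]; smi <- smi[keep]
    }
  }
  out <- parse_molecules(smi, id)
  if (nrow(out) == 0) abort("no parseable records in library")
  out
}

#' Write a compound library as SMILES
#'
#' @param mols molecule tibble.
#' @param path output `.smi` path (lines of `SMILES id`).
#' @return `path`, invisibly.
#' @export
write_library <- function(mols, path) {
  stopifnot(all(c("id", "smiles") %in% names(mols)))
  writeLines(paste(mols$smiles, mols$id), path)
  invisible(path)
}

#' Permute the atom numbering of a molecular graph
#'
#' Relabels atoms by a permutation while preserving the molecule, which is
#' useful for checking that fingerprints are invariant under input atom
#' renumbering.
#'
#' @param graph a molecular graph (one element of the `graph` column).
#' @param perm permutation of `seq_len(nrow(graph$atoms))`; random if `NULL`.
#' @return the permuted graph.
#' @export
permute_molecule_graph <- function(graph, perm = NULL) {
  n <- nrow(graph$atoms)
  if (is.null(perm)) perm <- sample.int(n)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  atoms <- graph$atoms[perm, , drop = FALSE]
  bonds <- graph$bonds
  bonds$i <- inv[bonds$i]
  bonds$j <- inv[bonds$j]
  list(atoms = atoms, bonds = bonds)
}
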