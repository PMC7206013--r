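# Light-weight PDB coordinate model and the geometric checks used for
# structure QC: polymer chain counts, catalytic-site distances, and
# disordered-region (missing-residue) gaps.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE")

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records by their standard fixed columns.  Malformed
#' records (unreadable coordinates or occupancy) are skipped and reported
#' with their line numbers.  Alternate locations are resolved per
#' (chain, residue, atom) to the highest occupancy, ties going to the
#' alphabetically first alt-loc id.  Waters and other hetero compounds are
#' retained but flagged non-polymer.
#'
#' @param path PDB file.
#' @return object of class `"structure_model"`: list with `atoms` (a
#'   data.frame: chain, resno, resname, atom, altloc, x, y, z, occupancy,
#'   element, is_polymer), and `diagnostics` (data.frame line, message).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0) stop("no ATOM/HETATM records in ", path)
  ln <- lines[sel]
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ) & !is.na(x)] <- 1          # occupancy column may be blank
  resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  bad <- is.na(x) | is.na(y) | is.na(z) | is.na(resno)
  diagnostics <- data.frame(line = sel[bad],
                            message = rep("unparseable coordinate/residue field",
                                          sum(bad)))
  atoms <- data.frame(
    chain = substr(ln, 22, 22),
    resno = resno,
    resname = trimws(substr(ln, 18, 20)),
    atom = trimws(substr(ln, 13, 16)),
    altloc = substr(ln, 17, 17),
    x = x, y = y, z = z,
    occupancy = occ,
    element = trimws(substr(ln, 77, 78)))[!bad, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no parseable atoms in ", path)

  # alt-loc resolution: highest occupancy, tie -> first alphabetically
  keyv <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  o <- order(keyv, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[o, , drop = FALSE]
  atoms <- atoms[!duplicated(keyv[o]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$atom), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$is_polymer <- atoms$resname %in% .aa3

  structure(list(atoms = atoms, diagnostics = diagnostics),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure model: %d atoms, chains %s (%d polymer residues)\n",
              nrow(a), paste(unique(a$chain), collapse = ""),
              length(unique(paste(a$chain, a$resno)[a$is_polymer]))))
  if (nrow(x$diagnostics))
    cat(sprintf("%d malformed records skipped\n", nrow(x$diagnostics)))
  invisible(x)
}

#' Count polymer chains
#'
#' @param model a [read_pdb()] result.
#' @param min_residues minimum number of amino-acid residues for a chain
#'   to count as polymer (default 20; filters waters/ligand "chains").
#' @return integer chain count.
#' @export
count_polymer_chains <- function(model, min_residues = 20) {
  a <- model$atoms[model$atoms$is_polymer, , drop = FALSE]
  if (nrow(a) == 0) return(0L)
  nres <- tapply(a$resno, a$chain, function(r) length(unique(r)))
  sum(nres >= min_residues)
}

.resolve_atom <- function(model, sel) {
  a <- model$atoms
  hit <- a$chain == sel$chain & a$resno == sel$resno & a$atom == sel$atom
  if (sum(hit) == 0)
    stop("selection matches no atom: chain ", sel$chain, " residue ",
         sel$resno, " atom ", sel$atom)
  if (sum(hit) > 1)
    stop("selection is ambiguous: chain ", sel$chain, " residue ",
         sel$resno, " atom ", sel$atom)
  unlist(a[hit, c("x", "y", "z")])
}

#' Distance between two selected atoms
#'
#' @param model a [read_pdb()] result.
#' @param sel1,sel2 selections: `list(chain =, resno =, atom =)`; each
#'   must resolve to exactly one atom.
#' @return Euclidean distance in Angstrom.
#' @examples
#' # atoms at (0,0,0) and (3,4,0) are 5 A apart
#' @export
atom_distance <- function(model, sel1, sel2) {
  p1 <- .resolve_atom(model, sel1)
  p2 <- .resolve_atom(model, sel2)
  sqrt(sum((p1 - p2)^2))
}

#' Missing-residue gaps in a chain
#'
#' Maximal runs of residue numbers absent between the first and last
#' observed polymer residue of the chain; the standard way a disordered
#' region shows up in a deposited model.
#'
#' @param model a [read_pdb()] result.
#' @param chain chain id.
#' @return data.frame `(first_missing, last_missing)`, zero rows for a
#'   contiguous chain; ranges are disjoint and sorted.
#' @export
chain_gaps <- function(model, chain) {
  a <- model$atoms
  res <- sort(unique(a$resno[a$chain == chain & a$is_polymer]))
  if (length(res) == 0) stop("no polymer residues in chain ", chain)
  missing <- setdiff(seq(min(res), max(res)), res)
  if (length(missing) == 0)
    return(data.frame(first_missing = integer(0),
                      last_missing = integer(0)))
  runs <- cumsum(c(1L, diff(missing) != 1L))
  data.frame(first_missing = tapply(missing, runs, min),
             last_missing = tapply(missing, runs, max),
             row.names = NULL)
}

#' Catalytic dyad to scissile-carbonyl distances
#'
#' Reports the distances from the catalytic His imidazole nitrogens (NE2
#' and ND1) and from the catalytic residue's side-chain terminus (SG for a
#' cysteine, CB for its alanine mutant) to the main-chain carbonyl carbon
#' of the blocking/self-cleavage residue.  Which atom pair underlies a
#' quoted dyad distance is often unstated, so all candidates are returned,
#' the closest pair per side marked.
#'
#' @param model a [read_pdb()] result.
#' @param chain chain id.
#' @param his,cat_res,site residue numbers of the catalytic His, the
#'   catalytic Cys (or mutant), and the residue whose carbonyl is attacked
#'   (defaults 86, 139, 225).
#' @return data.frame `(role, atom, distance)` where `role` is
#'   `"his"` or `"nucleophile"`; attribute `"closest"` holds the minimum
#'   distance per role.
#' @export
dyad_distances <- function(model, chain, his = 86, cat_res = 139,
                           site = 225) {
  target <- list(chain = chain, resno = site, atom = "C")
  a <- model$atoms
  his_atoms <- intersect(c("NE2", "ND1"),
                         a$atom[a$chain == chain & a$resno == his])
  nuc_atoms <- intersect(c("SG", "CB"),
                         a$atom[a$chain == chain & a$resno == cat_res])
  if (length(his_atoms) == 0 || length(nuc_atoms) == 0)
    stop("catalytic residues lack the expected side-chain atoms")
  rows <- rbind(
    data.frame(role = "his", atom = his_atoms),
    data.frame(role = "nucleophile", atom = nuc_atoms))
  rows$resno <- ifelse(rows$role == "his", his, cat_res)
  rows$distance <- vapply(seq_len(nrow(rows)), function(i)
    atom_distance(model,
                  list(chain = chain, resno = rows$resno[i],
                       atom = rows$atom[i]), target), 0)
  closest <- tapply(rows$distance, rows$role, min)
  structure(rows[, c("role", "atom", "distance")], closest = closest)
}

#' Write a synthetic stand-in coordinate model
#'
#' The deposited crystal structures this package's geometry checks were
#' designed around are not redistributed here; this generator writes a
#' SYNTHETIC stand-in PDB with the same documented gross features: two
#' polymer chains (A and B) of a 418-residue protein with residues
#' 153-210 missing (the disordered linker region between observed
#' residues 152 and 211), a catalytic His86/Cys139 dyad whose NE2/SG atoms
#' both sit 3.2 Angstrom from the Lys225 main-chain carbonyl carbon, and
#' a handful of waters.  It exists so the geometry operations can be
#' exercised end-to-end without the deposited files; distances measured on
#' it validate the measurement code, not the deposited models.
#'
#' @param path output PDB path.
#' @param variant `"wild_type"` (Cys139 with SG) or `"c139a"` (Ala139,
#'   CB terminus).
#' @param dyad_distance the His-NE2/Cys-SG to carbonyl-carbon distance
#'   built into the active site (default 3.2 Angstrom).
#' @return `path`, invisibly.
#' @export
write_synthetic_model_pdb <- function(path, variant = c("wild_type",
                                                        "c139a"),
                                      dyad_distance = 3.2) {
  variant <- match.arg(variant)
  lines <- character(0)
  serial <- 0L
  emit <- function(chain, resno, resname, atom, xyz, occ = 1,
                   altloc = " ", het = FALSE) {
    serial <<- serial + 1L
    el <- substr(gsub("[0-9]", "", atom), 1, 1)
    lines[[length(lines) + 1L]] <<- sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (het) "HETATM" else "ATOM", serial,
      if (nchar(atom) < 4) paste0(" ", atom) else atom, altloc,
      resname, chain, resno, xyz[1], xyz[2], xyz[3], occ, 0, el)
  }
  for (ch in c("A", "B")) {
    off <- if (ch == "A") c(0, 0, 0) else c(60, 0, 0)
    # active-site geometry: K225 carbonyl C at local origin
    c225 <- off
    his_ne2 <- off + c(dyad_distance, 0, 0)
    # 3-4-5 proportions keep the distance exact at 3-decimal precision
    cys_sg <- off + c(-0.6 * dyad_distance, 0.8 * dyad_distance, 0)
    for (r in c(1:152, 211:418)) {
      # CA trace on a loose helix well away from the active-site atoms
      t <- r * 0.35
      ca <- off + c(10 + 2 * cos(t), 12 + 8 * sin(t), 15 + 0.8 * r / 4)
      resname <- if (r == 86) "HIS" else if (r == 139) {
        if (variant == "wild_type") "CYS" else "ALA"
      } else if (r == 225) "LYS" else "GLY"
      emit(ch, r, resname, "CA", ca)
      if (r == 86) {
        emit(ch, r, "HIS", "CB", (ca + his_ne2) / 2)
        emit(ch, r, "HIS", "ND1", his_ne2 + c(1.1, 1.0, 0.4))
        emit(ch, r, "HIS", "NE2", his_ne2)
      }
      if (r == 139) {
        if (variant == "wild_type") {
          emit(ch, r, "CYS", "CB", (ca + cys_sg) / 2)
          emit(ch, r, "CYS", "SG", cys_sg)
        } else {
          emit(ch, r, "ALA", "CB", cys_sg)
        }
      }
      if (r == 225) {
        emit(ch, r, "LYS", "N", c225 + c(-1.2, -0.8, 0))
        emit(ch, r, "LYS", "C", c225)
        emit(ch, r, "LYS", "O", c225 + c(0.6, -1.0, 0.3))
      }
    }
  }
  for (w in 1:5)
    emit("S", w, "HOH", "O", c(30 + 3 * w, -10, 5), het = TRUE)
  writeLines(c("REMARK   5 SYNTHETIC STAND-IN MODEL (NOT A DEPOSITED STRUCTURE)",
               lines, "END"), path)
  invisible(path)
}
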