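STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_NAMES <- c("HOH", "WAT", "DOD")

ELEMENTS <- c("H", "D", "C", "N", "O", "S", "P", "SE", "F", "CL", "BR", "I",
              "FE", "ZN", "MG", "MN", "CA", "NA", "K", "CU", "NI", "CO", "MO", "W")

#' Atomic model container
#'
#' A flat atom table with the chain/residue hierarchy encoded in key
#' columns, ordered as read. Columns: \code{chain}, \code{resno},
#' \code{ins} (insertion code, "" when absent), \code{resname},
#' \code{atom} (atom name), \code{element}, \code{x}, \code{y}, \code{z}
#' (Angstrom), \code{b} (B-factor, Angstrom^2), \code{occ} (occupancy),
#' \code{altloc} ("" when absent), \code{het} (non-polymer/water flag),
#' \code{hydrogen}.
#'
#' @param atoms data.frame with the columns above.
#' @return an object of class \code{atomic_model}.
#' @export
atomic_model <- function(atoms) {
  need <- c("chain", "resno", "ins", "resname", "atom", "element",
            "x", "y", "z", "b", "occ", "altloc", "het", "hydrogen")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  bad <- !(toupper(atoms$element) %in% ELEMENTS)
  if (any(bad))
    stop("unrecognised element(s): ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancies must lie in [0, 1]")
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<atomic_model: %d atoms, %d residues, %d chain(s)>\n",
              nrow(a), nrow(unique(a[, c("chain", "resno", "ins")])),
              length(unique(a$chain))))
  invisible(x)
}

# residue table in (chain, resno, ins) order, polymer residues only by default
model_residues <- function(model, polymer_only = TRUE) {
  a <- model$atoms
  if (polymer_only) a <- a[!a$het, , drop = FALSE]
  if (nrow(a) == 0) return(data.frame(chain = character(), resno = integer(),
                                      ins = character(), resname = character()))
  r <- unique(a[, c("chain", "resno", "ins", "resname")])
  r <- r[order(r$chain, r$resno, r$ins), , drop = FALSE]
  rownames(r) <- NULL
  r
}

residue_atoms <- function(model, chain, resno, ins = "") {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno & a$ins == ins, , drop = FALSE]
}

# reduce alternate conformers to the highest-occupancy one per atom
# (ties broken by first altloc id alphabetically)
select_conformer <- function(model) {
  a <- model$atoms
  if (!any(a$altloc != "")) return(model)
  key <- paste(a$chain, a$resno, a$ins, a$atom, sep = "\r")
  ord <- order(key, -a$occ, a$altloc)
  a2 <- a[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  a2 <- a2[keep, , drop = FALSE]
  # restore original relative order
  a2 <- a2[order(as.integer(rownames(a2))), , drop = FALSE]
  atomic_model(a2)
}

guess_element <- function(name, resname) {
  name <- toupper(trimws(name))
  if (grepl("^[0-9]*H", name)) return("H")
  two <- substr(name, 1, 2)
  if (two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "NA", "CU", "NI") &&
      !(resname %in% STANDARD_AA))
    return(two)
  substr(name, 1, 1)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Format detected from the extension (.pdb/.ent vs .cif/.mmcif), falling
#' back to content sniffing. Waters and non-polymer entities are retained
#' with \code{het = TRUE}; alternate conformers are retained with their
#' altloc ids.
#'
#' @param path input file.
#' @return an \code{\link{atomic_model}}.
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  is_cif <- ext %in% c("cif", "mmcif") ||
    (!(ext %in% c("pdb", "ent")) && any(grepl("^_atom_site\\.", lines)))
  m <- if (is_cif) parse_cif(lines) else parse_pdb(lines)
  if (nrow(m$atoms) == 0) stop("empty model: no atoms parsed from ", path)
  m
}

parse_pdb <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  ln <- lines[keep]
  if (!length(ln))
    return(structure(list(atoms = data.frame()), class = "atomic_model"))
  f <- function(a, b) trimws(substr(ln, a, b))
  name <- f(13, 16)
  resname <- f(18, 20)
  element <- f(77, 78)
  noelem <- element == ""
  if (any(noelem))
    element[noelem] <- mapply(guess_element, name[noelem], resname[noelem])
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(f(61, 66)))
  b[is.na(b)] <- 0
  atoms <- data.frame(
    chain = f(22, 22), resno = as.integer(f(23, 26)), ins = f(27, 27),
    resname = resname, atom = name, element = toupper(element),
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)), z = as.numeric(f(47, 54)),
    b = b, occ = occ, altloc = f(17, 17),
    het = substr(ln, 1, 6) == "HETATM" | resname %in% WATER_NAMES |
      !(resname %in% STANDARD_AA),
    stringsAsFactors = FALSE)
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  atomic_model(atoms)
}

# minimal mmCIF tokenizer for one line (handles 'quoted' and "quoted")
cif_tokens <- function(line) {
  out <- character()
  i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch %in% c("'", "\"")) {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1)); i <- j + 1
    } else {
      j <- i
      while (j <= n && !(substr(line, j, j) %in% c(" ", "\t"))) j <- j + 1
      out <- c(out, substr(line, i, j - 1)); i <- j
    }
  }
  out
}

parse_cif <- function(lines) {
  # locate the atom_site loop
  is_field <- grepl("^_atom_site\\.", lines)
  if (!any(is_field))
    return(structure(list(atoms = data.frame()), class = "atomic_model"))
  fi <- which(is_field)
  fields <- sub("^_atom_site\\.", "", trimws(lines[fi]))
  start <- max(fi) + 1
  rows <- list()
  for (i in start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || l == "#" || startsWith(l, "loop_") || startsWith(l, "_") ||
        startsWith(l, "data_")) break
    rows[[length(rows) + 1]] <- cif_tokens(l)
  }
  if (!length(rows))
    return(structure(list(atoms = data.frame()), class = "atomic_model"))
  mat <- do.call(rbind, rows)
  colnames(mat) <- fields
  gv <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% fields) return(mat[, nm])
    if (!is.null(alt) && alt %in% fields) return(mat[, alt])
    rep(default, nrow(mat))
  }
  dot_blank <- function(v) ifelse(v %in% c(".", "?"), "", v)
  resname <- gv("auth_comp_id", "label_comp_id")
  occ <- suppressWarnings(as.numeric(gv("occupancy", default = "1")))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(gv("B_iso_or_equiv", default = "0")))
  b[is.na(b)] <- 0
  element <- dot_blank(gv("type_symbol"))
  name <- gv("auth_atom_id", "label_atom_id")
  noelem <- is.na(element) | element == ""
  if (any(noelem))
    element[noelem] <- mapply(guess_element, name[noelem], resname[noelem])
  atoms <- data.frame(
    chain = gv("auth_asym_id", "label_asym_id"),
    resno = as.integer(gv("auth_seq_id", "label_seq_id")),
    ins = dot_blank(gv("pdbx_PDB_ins_code", default = ".")),
    resname = resname, atom = name, element = toupper(element),
    x = as.numeric(gv("Cartn_x")), y = as.numeric(gv("Cartn_y")),
    z = as.numeric(gv("Cartn_z")), b = b, occ = occ,
    altloc = dot_blank(gv("label_alt_id", default = ".")),
    het = gv("group_PDB", default = "ATOM") == "HETATM" |
      resname %in% WATER_NAMES | !(resname %in% STANDARD_AA),
    stringsAsFactors = FALSE)
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  atomic_model(atoms)
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB fixed-column layout when the extension is .pdb/.ent, otherwise
#' mmCIF. The PDB dialect is refused (with a pointer to mmCIF) for models
#' exceeding its fixed-field limits (chain ids longer than one character,
#' more than 99,999 atoms).
#'
#' @param model an \code{\link{atomic_model}}.
#' @param path output file; extension selects the dialect.
#' @return invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) write_pdb(model, path) else write_cif(model, path)
  invisible(path)
}

write_pdb <- function(model, path) {
  a <- model$atoms
  if (nrow(a) > 99999)
    stop("model has >99,999 atoms; the PDB dialect cannot hold it - write mmCIF (.cif) instead")
  if (any(nchar(a$chain) > 1))
    stop("chain id longer than one character; the PDB dialect cannot hold it - write mmCIF (.cif) instead")
  name <- ifelse(nchar(a$atom) < 4 & nchar(a$element) == 1,
                 sprintf(" %-3s", a$atom), sprintf("%-4s", a$atom))
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)) %% 100000, name, a$altloc, a$resname,
                   a$chain, a$resno, a$ins, a$x, a$y, a$z, a$occ, a$b,
                   sprintf("%2s", a$element))
  writeLines(c(lines, "END"), path)
}

write_cif <- function(model, path) {
  a <- model$atoms
  dotify <- function(v) ifelse(v == "", ".", v)
  lines <- c(
    "data_emval", "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                            "label_alt_id", "label_comp_id", "auth_asym_id",
                            "auth_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                            "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "auth_comp_id", "auth_atom_id")),
    sprintf("%s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.4f %.4f %s %s",
            ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
            a$atom, dotify(a$altloc), a$resname, a$chain, a$resno,
            dotify(a$ins), a$x, a$y, a$z, a$occ, a$b, a$resname, a$atom),
    "#")
  writeLines(lines, path)
}
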