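# Multi-model PDB coordinate container and fixed-column PDB I/O.
#
# Coordinates live in a plain data.frame (one row per atom) wrapped in the
# S3 class "nmr_structure"; author residue numbering is kept verbatim.

#' Construct an NMR structure object
#'
#' @param atoms data.frame with columns `model` (integer >= 1), `chain`
#'   (single character), `resno` (author residue number), `resname`
#'   (3-letter code), `atom` (PDB atom name) and `x`, `y`, `z` (Angstrom).
#' @param metadata free-text provenance string.
#' @param validate run the (O(n log n)) consistency checks; disable inside
#'   tight loops that build many structures from already-validated atoms.
#' @return object of class `nmr_structure`.
#' @export
nmr_structure <- function(atoms, metadata = "", validate = TRUE) {
  req <- c("model", "chain", "resno", "resname", "atom", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atoms data.frame must have columns: ", paste(req, collapse = ", "))
  }
  atoms <- atoms[req]
  atoms$model <- as.integer(atoms$model)
  atoms$resno <- as.integer(atoms$resno)
  s <- structure(list(atoms = atoms, metadata = metadata),
                 class = "nmr_structure")
  if (validate) validate_structure(s)
  s
}

validate_structure <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0L) stop("structure has no atoms")
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))) {
    stop("non-finite coordinates in structure")
  }
  key <- paste(a$model, a$chain, a$resno, a$atom)
  if (anyDuplicated(key)) {
    stop("duplicate (model, chain, residue, atom) records: ",
         key[anyDuplicated(key)])
  }
  # every model must carry the same (chain, residue, atom) set
  per_model <- split(paste(a$chain, a$resno, a$atom), a$model)
  if (length(per_model) > 1L) {
    ref <- sort(per_model[[1L]])
    for (m in seq_along(per_model)[-1L]) {
      if (!identical(sort(per_model[[m]]), ref)) {
        stop("models do not share an identical atom set (model ",
             names(per_model)[m], " differs)")
      }
    }
  }
  invisible(s)
}

#' @export
print.nmr_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<nmr_structure> %d model(s), %d chain(s), %d atoms/model\n",
              length(unique(a$model)), length(unique(a$chain)),
              sum(a$model == a$model[1L])))
  for (ch in unique(a$chain)) {
    r <- range(a$resno[a$chain == ch])
    cat(sprintf("  chain %s: residues %d-%d\n", ch, r[1], r[2]))
  }
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  invisible(x)
}

#' Model indices present in a structure
#' @param s an `nmr_structure`.
#' @return sorted integer vector of model indices.
#' @export
structure_models <- function(s) sort(unique(s$atoms$model))

#' Select atoms from a structure
#'
#' Convenience filter used throughout the package. All arguments are
#' optional; `NULL` means "no restriction".
#'
#' @param s an `nmr_structure`.
#' @param model integer model index (or vector).
#' @param chain chain identifier(s).
#' @param resno residue numbers to keep.
#' @param atoms atom names to keep.
#' @return data.frame of matching atom rows (same columns as `s$atoms`).
#' @export
atom_select <- function(s, model = NULL, chain = NULL, resno = NULL,
                        atoms = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(model)) keep <- keep & a$model %in% model
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(atoms)) keep <- keep & a$atom %in% atoms
  a[keep, , drop = FALSE]
}

# n x 3 coordinate matrix from an atom data.frame
coord_matrix <- function(a) as.matrix(a[, c("x", "y", "z")])

#' Read a (multi-model) PDB file
#'
#' Parses the coordinate subset of the PDB format: ATOM records inside
#' MODEL/ENDMDL blocks, or a single implicit model when no MODEL card is
#' present. HETATM records (waters, ligands) are excluded by default.
#' Author residue numbering is preserved.
#'
#' @param path path to a PDB-format text file.
#' @param model_selection `"all"` (default), `"first"`, or an integer model
#'   index.
#' @param include_hetatm also parse HETATM records.
#' @return an `nmr_structure`.
#' @export
read_pdb <- function(path, model_selection = "all", include_hetatm = FALSE) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  want <- rec == "ATOM  "
  if (include_hetatm) want <- want | rec == "HETATM"

  model_now <- 0L
  has_model_card <- any(rec == "MODEL ")
  model_of_line <- integer(length(lines))
  for (i in seq_along(lines)) {
    if (rec[i] == "MODEL ") {
      m <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      model_now <- if (is.na(m)) model_now + 1L else m
    }
    model_of_line[i] <- model_now
  }
  if (!has_model_card) model_of_line[] <- 1L
  model_of_line[model_of_line == 0L] <- 1L

  idx <- which(want)
  if (length(idx) == 0L) stop("no ATOM records found in ", path)
  al <- lines[idx]
  parse_num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1L]]
      stop(sprintf("unparsable ATOM line %d in %s (bad %s field)",
                   bad, path, what))
    }
    v
  }
  atoms <- data.frame(
    model = model_of_line[idx],
    chain = substr(al, 22, 22),
    resno = as.integer(parse_num(substr(al, 23, 26), "residue number")),
    resname = trimws(substr(al, 18, 20)),
    atom = trimws(substr(al, 13, 16)),
    x = parse_num(substr(al, 31, 38), "x"),
    y = parse_num(substr(al, 39, 46), "y"),
    z = parse_num(substr(al, 47, 54), "z"),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$resname != "HOH", , drop = FALSE]

  if (identical(model_selection, "first")) {
    atoms <- atoms[atoms$model == min(atoms$model), , drop = FALSE]
  } else if (is.numeric(model_selection)) {
    atoms <- atoms[atoms$model %in% as.integer(model_selection), , drop = FALSE]
  } else if (!identical(model_selection, "all")) {
    stop("model_selection must be 'all', 'first' or an integer index")
  }
  if (nrow(atoms) == 0L) stop("model selection yielded no atoms")
  nmr_structure(atoms, metadata = paste("read from", basename(path)))
}

#' Write a structure as a multi-model PDB file
#'
#' @param s an `nmr_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  models <- structure_models(s)
  multi <- length(models) > 1L
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- atom_select(s, model = m)
    a <- a[order(a$chain, a$resno, a$atom), , drop = FALSE]
    elem <- substr(gsub("[0-9]", "", a$atom), 1, 1)
    # atom names of 1-3 characters start in column 14 by PDB convention
    name_fmt <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                       sprintf("%-4s", a$atom))
    lines <- sprintf(
      "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), name_fmt, a$resname, a$chain, a$resno,
      a$x, a$y, a$z, elem)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# --- amino-acid code tables ---------------------------------------------

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA3 <- stats::setNames(names(AA1), AA1)

#' Convert between 1- and 3-letter amino-acid codes
#' @param x character vector of codes.
#' @return converted codes.
#' @export
aa_three <- function(x) {
  out <- AA1[toupper(x)]
  if (anyNA(out)) stop("invalid residue letter(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- AA3[toupper(x)]
  if (anyNA(out)) stop("invalid residue name(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}
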