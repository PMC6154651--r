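#' @importFrom methods as new is
#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

# ---- Molecule construction ---------------------------------------------------

# Internal constructor.  `atoms` is a data.frame(element, charge, nh, aromatic),
# `bonds` a data.frame(a1, a2, order).  Indices are 1-based into `atoms`.
new_molecule <- function(id, atoms, bonds, smiles = NA_character_,
                         source_text = NA_character_,
                         source_line = NA_integer_) {
  m <- structure(
    list(id = id, atoms = atoms, bonds = bonds, smiles = smiles,
         source_text = source_text, source_line = source_line),
    class = "Molecule"
  )
  validate_molecule(m)
  m
}

#' Validate a Molecule object
#'
#' Checks the structural invariants of the molecular-graph model: bond
#' endpoints are valid atom indices, there are no self-bonds, and implicit
#' hydrogen counts are non-negative.
#'
#' @param m A `Molecule`.
#' @return `m`, invisibly; an error is raised on violation.
#' @export
validate_molecule <- function(m) {
  stopifnot(inherits(m, "Molecule"))
  n <- nrow(m$atoms)
  b <- m$bonds
  if (nrow(b)) {
    if (any(b$a1 < 1 | b$a1 > n | b$a2 < 1 | b$a2 > n))
      stop("bond endpoint out of range in molecule ", m$id)
    if (any(b$a1 == b$a2))
      stop("self-bond in molecule ", m$id)
  }
  if (any(m$atoms$nh < 0))
    stop("negative implicit hydrogen count in molecule ", m$id)
  invisible(m)
}

#' @export
print.Molecule <- function(x, ...) {
  f <- format_formula(molecular_formula(x))
  cat("<Molecule ", x$id, "> ", f, ", ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds", sep = "")
  if (!is.na(x$smiles)) cat("  ", x$smiles, sep = "")
  cat("\n")
  invisible(x)
}

# number of connected components of the heavy-atom graph
n_fragments <- function(m) {
  n <- nrow(m$atoms)
  if (n == 0L) return(0L)
  adj <- adjacency_list(m)
  seen <- logical(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

adjacency_list <- function(m) {
  n <- nrow(m$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  b <- m$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
  }
  adj
}

heavy_degree <- function(m) {
  n <- nrow(m$atoms)
  d <- integer(n)
  if (nrow(m$bonds)) {
    t1 <- tabulate(m$bonds$a1, n)
    t2 <- tabulate(m$bonds$a2, n)
    d <- t1 + t2
  }
  d
}

# ---- Implicit hydrogens ------------------------------------------------------

# Default-valence model: the smallest allowed valence state that accommodates
# the bond-order sum is filled up with hydrogens.  Charge shifts the allowed
# valence for N/P/O/S/Se (protonation/deprotonation); carbanions/carbocations
# lose one bond per unit charge.
implicit_h <- function(element, charge, bondsum) {
  allowed <- .valences[[element]]
  if (is.null(allowed)) return(0L)
  if (element %in% c("N", "P", "O", "S", "Se")) {
    allowed <- allowed + charge
  } else if (element == "C") {
    allowed <- allowed - abs(charge)
  }
  allowed <- allowed[allowed >= bondsum]
  if (!length(allowed)) return(0L)
  as.integer(min(allowed) - bondsum)
}

# ---- ChemmineR bridge --------------------------------------------------------

# old-style MDL charge codes -> formal charge
.mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Build a Molecule from a single ChemmineR::SDF object (as produced by
# OpenBabel, i.e. kekulized, implicit hydrogens, old-style charge column).
molecule_from_sdf <- function(sdf, id, smiles = NA_character_,
                              source_text = NA_character_,
                              source_line = NA_integer_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  nat <- nrow(ab)
  chg_col <- if ("C6" %in% colnames(ab)) "C6" else 5L
  charge <- .mdl_charge[as.character(ab[, chg_col])]
  charge[is.na(charge)] <- 0L
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
  bonds <- if (nrow(bb)) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }

  # fold explicit hydrogens into neighbour counts
  extra_h <- integer(nat)
  is_h <- element == "H"
  if (any(is_h)) {
    keep_h <- rep(TRUE, nrow(bonds))
    for (i in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[i]; a2 <- bonds$a2[i]
      if (is_h[a1] && !is_h[a2]) { extra_h[a2] <- extra_h[a2] + 1L; keep_h[i] <- FALSE }
      if (is_h[a2] && !is_h[a1]) { extra_h[a1] <- extra_h[a1] + 1L; keep_h[i] <- FALSE }
      if (is_h[a1] && is_h[a2]) keep_h[i] <- FALSE   # H2: drop the bond
    }
    bonds <- bonds[keep_h, , drop = FALSE]
    newidx <- cumsum(!is_h)
    bonds$a1 <- newidx[bonds$a1]; bonds$a2 <- newidx[bonds$a2]
    charge <- charge[!is_h]; extra_h_kept <- extra_h[!is_h]
    element <- element[!is_h]
    extra_h <- extra_h_kept
    nat <- length(element)
  }

  bondsum <- numeric(nat)
  for (i in seq_len(nrow(bonds))) {
    bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + bonds$order[i]
    bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + bonds$order[i]
  }
  nh <- mapply(implicit_h, element, charge, bondsum) + extra_h

  atoms <- data.frame(element = element, charge = as.integer(charge),
                      nh = as.integer(nh), aromatic = FALSE,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  m <- new_molecule(id, atoms, bonds, smiles = smiles,
                    source_text = source_text, source_line = source_line)
  perceive_aromaticity(m)
}

# Parse one SMILES record through OpenBabel; returns a Molecule or signals
# a condition of class "esterlib_parse_error".
molecule_from_smiles <- function(smiles, id, source_line = NA_integer_) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != 1L)
    stop(errorCondition(paste0("unparseable SMILES record: ", smiles),
                        class = c("esterlib_parse_error", "error", "condition")))
  molecule_from_sdf(sdf[[1]], id = id, smiles = smiles,
                    source_text = smiles, source_line = source_line)
}

# ---- Public I/O --------------------------------------------------------------

#' Parse structures from SMILES or SDF text
#'
#' Reads a multi-record structure payload into `Molecule` objects.  SMILES
#' input is one record per line, with an optional identifier after
#' whitespace; SDF input is a V2000 multi-record block.  Records that
#' OpenBabel cannot interpret (or kekulize) are not dropped silently: they
#' are returned in a rejects table with their line or record number.
#'
#' @param text Character scalar (entire payload) or character vector of lines.
#' @param format `"smiles"` or `"sdf"`.
#' @return A list with elements `molecules` (list of `Molecule`) and
#'   `rejects` (data.frame with columns `line`, `id`, `reason`).
#' @examples
#' parse_structures("CCO ethanol\nOC(=O)c1ccccc1 benzoic", "smiles")
#' @export
parse_structures <- function(text, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (length(text) == 0L || !any(nzchar(trimws(text))))
    stop("empty structure payload")
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text

  molecules <- list()
  rejects <- data.frame(line = integer(0), id = character(0),
                        reason = character(0), stringsAsFactors = FALSE)

  if (format == "smiles") {
    for (i in seq_along(lines)) {
      ln <- trimws(lines[[i]])
      if (!nzchar(ln) || startsWith(ln, "#")) next
      parts <- strsplit(ln, "[[:space:]]+")[[1]]
      smi <- parts[[1]]
      id <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else paste0("L", i)
      m <- tryCatch(molecule_from_smiles(smi, id, source_line = i),
                    esterlib_parse_error = function(e) e)
      if (inherits(m, "condition")) {
        rejects <- rbind(rejects, data.frame(line = i, id = id,
                                             reason = "unparseable_smiles"))
      } else {
        molecules[[length(molecules) + 1L]] <- m
      }
    }
  } else {
    recs <- split_sdf_records(lines)
    for (k in seq_along(recs)) {
      rec <- recs[[k]]
      id <- trimws(rec$lines[[1]])
      if (!nzchar(id)) id <- paste0("R", k)
      m <- tryCatch({
        sdfset <- as(new("SDFstr", a = list(rec$lines)), "SDFset")
        smi <- tryCatch(as.character(ChemmineR::sdf2smiles(sdfset))[[1]],
                        error = function(e) NA_character_)
        molecule_from_sdf(sdfset[[1]], id = id, smiles = smi,
                          source_text = paste(rec$lines, collapse = "\n"),
                          source_line = rec$first_line)
      }, error = function(e) e)
      if (inherits(m, "condition")) {
        rejects <- rbind(rejects, data.frame(line = rec$first_line, id = id,
                                             reason = "unparseable_sdf_record"))
      } else {
        molecules[[length(molecules) + 1L]] <- m
      }
    }
  }
  list(molecules = molecules, rejects = rejects)
}

split_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  for (j in seq_along(ends)) {
    rng <- starts[j]:ends[j]
    body <- lines[rng]
    body <- body[trimws(body) != "$$$$"]
    if (!any(nzchar(trimws(body)))) next
    recs[[length(recs) + 1L]] <- list(lines = body, first_line = starts[j])
  }
  recs
}

#' Read structures from a file
#'
#' Convenience wrapper around [parse_structures()]; the format is taken
#' from the file extension (`.smi`/`.smiles` or `.sdf`) unless given.
#'
#' @param path File path.
#' @param format Optional format override.
#' @inherit parse_structures return
#' @export
read_structures <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = , smiles = "smiles", sdf = "sdf",
                     stop("cannot infer structure format from extension: ", ext))
  }
  parse_structures(readLines(path, warn = FALSE), format)
}

# ---- Writers -----------------------------------------------------------------

# Emit a V2000 molfile block for a Molecule (2D coordinates zeroed; charges
# written as M CHG lines), used as the bridge back into OpenBabel.
mol_to_sdf_text <- function(m) {
  na <- nrow(m$atoms); nb <- nrow(m$bonds)
  header <- c(as.character(m$id), " esterlib", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atoms <- vapply(seq_len(na), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, m$atoms$element[i])
  }, character(1))
  bonds <- vapply(seq_len(nb), function(i) {
    sprintf("%3d%3d%3d  0  0  0  0", m$bonds$a1[i], m$bonds$a2[i],
            m$bonds$order[i])
  }, character(1))
  chg <- which(m$atoms$charge != 0L)
  chg_lines <- if (length(chg)) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(idx) {
      paste0("M  CHG", sprintf("%3d", length(idx)),
             paste0(sprintf("%4d%4d", idx, m$atoms$charge[idx]), collapse = ""))
    }, character(1))
  } else character(0)
  paste(c(header, counts, atoms, bonds, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

#' Canonical SMILES for a Molecule
#'
#' Renders the molecular graph back through OpenBabel to obtain a canonical
#' SMILES string (stereochemistry-free, matching the 2D pipeline).
#'
#' @param m A `Molecule`.
#' @return Character scalar.
#' @export
mol_to_smiles <- function(m) {
  txt <- mol_to_sdf_text(m)
  out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt))
  smi <- strsplit(trimws(out), "[[:space:]]+")[[1]][1]
  if (!length(smi) || is.na(smi) || !nzchar(smi))
    stop("could not render SMILES for molecule ", m$id)
  smi
}

#' Write molecules as SMILES + id TSV
#'
#' @param molecules List of `Molecule` objects.
#' @param path Output file path.
#' @param canonical Re-canonicalize through OpenBabel (default `TRUE`);
#'   otherwise the stored source SMILES is used where available.
#' @return `path`, invisibly.
#' @export
write_structures <- function(molecules, path, canonical = TRUE) {
  smi <- vapply(molecules, function(m) {
    if (!canonical && !is.na(m$smiles)) m$smiles else mol_to_smiles(m)
  }, character(1))
  ids <- vapply(molecules, function(m) as.character(m$id), character(1))
  writeLines(paste(smi, ids, sep = "\t"), path)
  invisible(path)
}
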