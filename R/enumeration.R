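# ---- Scaffold site and combinatorial 3-O-esterification ----------------------

#' Locate the esterifiable hydroxyl of a scaffold
#'
#' Finds the oxygen atoms carrying exactly one hydrogen and a single bond
#' to a carbon that bears no carbonyl (so carboxylic OH groups are
#' excluded).  For the oleanolic-acid scaffold this identifies the 3-beta
#' hydroxyl uniquely.
#'
#' @param m A `Molecule`.
#' @return Integer vector of candidate atom indices.
#' @export
find_hydroxyl_site <- function(m) {
  el <- m$atoms$element
  b <- m$bonds
  out <- integer(0)
  for (o in which(el == "O" & m$atoms$nh == 1L & m$atoms$charge == 0L)) {
    nb <- c(b$a2[b$a1 == o & b$order == 1L], b$a1[b$a2 == o & b$order == 1L])
    deg_o <- sum(b$a1 == o | b$a2 == o)
    if (deg_o != 1L || length(nb) != 1L || el[nb] != "C") next
    cc <- nb[[1]]
    carbonyl <- any((b$a1 == cc & b$order == 2L & el[b$a2] == "O") |
                    (b$a2 == cc & b$order == 2L & el[b$a1] == "O"))
    if (!carbonyl) out <- c(out, o)
  }
  out
}

#' Declare the esterification site on a scaffold
#'
#' @param scaffold A `Molecule` (e.g. oleanolic acid).
#' @param site Optional atom index of the hydroxyl oxygen; when `NULL` the
#'   unique non-carboxyl hydroxyl found by [find_hydroxyl_site()] is used.
#' @return A `scaffold_site` (list with `scaffold` and `site`).
#' @export
scaffold_site <- function(scaffold, site = NULL) {
  if (is.null(site)) {
    cand <- find_hydroxyl_site(scaffold)
    if (length(cand) != 1L)
      stop("scaffold has ", length(cand),
           " candidate hydroxyl sites; declare one explicitly")
    site <- cand[[1]]
  }
  site <- as.integer(site)
  el <- scaffold$atoms$element
  b <- scaffold$bonds
  nb <- c(b$a2[b$a1 == site & b$order == 1L], b$a1[b$a2 == site & b$order == 1L])
  if (el[site] != "O" || scaffold$atoms$nh[site] != 1L ||
      length(nb) != 1L || el[nb] != "C")
    stop("declared site is not an O bearing one H and one single bond to carbon")
  structure(list(scaffold = scaffold, site = site), class = "scaffold_site")
}

#' Load the bundled oleanolic-acid scaffold
#'
#' Parses the shipped oleanolic acid structure (C30H48O3) and declares its
#' 3-beta hydroxyl as the esterification site.
#'
#' @return A `scaffold_site`.
#' @export
oa_scaffold <- function() {
  path <- system.file("extdata", "oleanolic_acid.smi", package = "esterlib")
  p <- read_structures(path)
  if (length(p$molecules) != 1L) stop("scaffold fixture did not parse")
  scaffold_site(p$molecules[[1]])
}

#' Condense an acid onto the scaffold hydroxyl (Fischer-type ester)
#'
#' Forms the ester by bonding the site oxygen to the acid's carboxyl
#' carbon and removing one water: the acid must contain exactly one
#' eligible carboxylic-acid group.  Element-wise,
#' `formula(product) = formula(scaffold) + formula(acid) - H2O`, and the
#' monoisotopic mass is conserved to 1e-6 u; both are recomputed from the
#' product graph, not assumed.
#'
#' @param site A [scaffold_site()].
#' @param acid A `Molecule` with exactly one COOH.
#' @return An `ester_product`: list with `product` (Molecule),
#'   `scaffold_id`, `acid_id`, `formula`, `mw_average`, `mw_monoisotopic`
#'   and `adducts` (data.frame label, mz).
#' @export
esterify <- function(site, acid) {
  stopifnot(inherits(site, "scaffold_site"))
  cx <- cooh_carbons(acid)
  if (length(cx) != 1L)
    stop("acid ", acid$id, " has ", length(cx),
         " eligible carboxylic-acid groups (need exactly 1)")
  cx <- cx[[1]]
  b <- acid$bonds
  el <- acid$atoms$element
  hydroxyl <- c(b$a2[b$a1 == cx & b$order == 1L],
                b$a1[b$a2 == cx & b$order == 1L])
  hydroxyl <- hydroxyl[el[hydroxyl] == "O" & acid$atoms$nh[hydroxyl] == 1L &
                       acid$atoms$charge[hydroxyl] == 0L][[1]]

  scaf <- site$scaffold
  n_s <- nrow(scaf$atoms)

  acid_atoms <- acid$atoms
  acid_bonds <- acid$bonds
  keep <- setdiff(seq_len(nrow(acid_atoms)), hydroxyl)
  remap <- integer(nrow(acid_atoms))
  remap[keep] <- seq_along(keep)
  keep_bond <- acid_bonds$a1 != hydroxyl & acid_bonds$a2 != hydroxyl
  acid_bonds <- acid_bonds[keep_bond, , drop = FALSE]
  acid_bonds$a1 <- remap[acid_bonds$a1] + n_s
  acid_bonds$a2 <- remap[acid_bonds$a2] + n_s
  acid_atoms <- acid_atoms[keep, , drop = FALSE]

  atoms <- rbind(scaf$atoms, acid_atoms)
  rownames(atoms) <- NULL
  atoms$nh[site$site] <- 0L                      # O-H becomes the ester O
  new_bond <- data.frame(a1 = site$site, a2 = remap[cx] + n_s, order = 1L)
  bonds <- rbind(scaf$bonds, acid_bonds, new_bond)
  rownames(bonds) <- NULL

  prod <- new_molecule(paste0(scaf$id, "_O_", acid$id), atoms, bonds)
  prod <- perceive_aromaticity(prod)
  if (n_fragments(prod) != 1L)
    stop("ester product is not connected for acid ", acid$id)

  f <- molecular_formula(prod)
  mono <- monoisotopic_mass(f)
  specs <- adduct_specs()
  structure(list(
    product = prod,
    scaffold_id = scaf$id, acid_id = acid$id,
    formula = f,
    mw_average = average_mass(f),
    mw_monoisotopic = mono,
    adducts = data.frame(label = specs$label, mz = mono + specs$delta,
                         stringsAsFactors = FALSE)
  ), class = "ester_product")
}

#' @export
print.ester_product <- function(x, ...) {
  cat(sprintf("<ester_product %s> %s  MW %.2f (mono %.4f)\n",
              x$product$id, format_formula(x$formula), x$mw_average,
              x$mw_monoisotopic))
  for (i in seq_len(nrow(x$adducts)))
    cat(sprintf("   %-8s m/z %.4f\n", x$adducts$label[i], x$adducts$mz[i]))
  invisible(x)
}

#' Predicted ESI m/z of an adduct
#'
#' `m/z = monoisotopic mass + adduct delta` (singly charged species).
#'
#' @param p An `ester_product` (or any object with `mw_monoisotopic`), or a
#'   bare monoisotopic mass.
#' @param label Adduct label: `"[M-H]-"`, `"[M+H]+"` or `"[M+Na]+"`.
#' @return m/z in u.
#' @examples
#' predict_adduct_mz(456.3603, "[M-H]-")   # oleanolic acid anion
#' @export
predict_adduct_mz <- function(p, label) {
  mono <- if (is.numeric(p)) p else p$mw_monoisotopic
  specs <- adduct_specs()
  hit <- match(label, specs$label)
  if (is.na(hit)) stop("unknown adduct label: ", label)
  mono + specs$delta[hit]
}

#' Enumerate the full ester library
#'
#' One condensation per acid, input order preserved; acids that cannot be
#' esterified (zero or several carboxyl groups) are routed to a rejects
#' report rather than raised.
#'
#' @param site A [scaffold_site()].
#' @param acids List of `Molecule` acids.
#' @return list with `products` (list of `ester_product`) and `rejects`
#'   (data.frame id, reason).
#' @export
enumerate_library <- function(site, acids) {
  products <- list()
  rej_id <- character(0); rej_reason <- character(0)
  for (a in acids) {
    p <- tryCatch(esterify(site, a), error = function(e) e)
    if (inherits(p, "error")) {
      rej_id <- c(rej_id, as.character(a$id))
      rej_reason <- c(rej_reason, conditionMessage(p))
    } else {
      products[[length(products) + 1L]] <- p
    }
  }
  list(products = products,
       rejects = data.frame(id = rej_id, reason = rej_reason,
                            stringsAsFactors = FALSE))
}

#' Product table for an enumerated library
#'
#' @param products List of `ester_product` objects.
#' @return data.frame: acid id, product id, formula, masses, and one m/z
#'   column per supported adduct.
#' @export
product_table <- function(products) {
  rows <- lapply(products, function(p) {
    adds <- stats::setNames(p$adducts$mz, p$adducts$label)
    cbind(data.frame(acid_id = p$acid_id, product_id = p$product$id,
                     formula = format_formula(p$formula),
                     mw_average = p$mw_average,
                     mw_monoisotopic = p$mw_monoisotopic,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(adds), check.names = FALSE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write the enumerated library
#'
#' Writes a product CSV (formula, masses, adduct m/z) and a SMILES + id TSV.
#'
#' @param products List of `ester_product`.
#' @param csv_path,smi_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_products <- function(products, csv_path = NULL, smi_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(product_table(products), csv_path, row.names = FALSE)
  if (!is.null(smi_path))
    write_structures(lapply(products, `[[`, "product"), smi_path)
  invisible(list(csv = csv_path, smi = smi_path))
}
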