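# ---- Drug-likeness criteria --------------------------------------------------

#' Filter criteria for the acid library funnel
#'
#' Defaults are the customized Rule-of-5 thresholds used to trim a
#' carboxylic-acid building-block library before diversity selection:
#' MW at most 200 u, at most 4 H-bond donors, 8 acceptors, 7 rotatable
#' bonds, 2 rings and 2 aromatic rings.
#'
#' @param mw_max Upper bound on average molecular weight (u).
#' @param hbd_max,hba_max,rotatable_max,ring_max,aromatic_ring_max Count bounds.
#' @return A `filter_criteria` object.
#' @export
filter_criteria <- function(mw_max = 200, hbd_max = 4, hba_max = 8,
                            rotatable_max = 7, ring_max = 2,
                            aromatic_ring_max = 2) {
  vals <- c(mw_max = mw_max, hbd_max = hbd_max, hba_max = hba_max,
            rotatable_max = rotatable_max, ring_max = ring_max,
            aromatic_ring_max = aromatic_ring_max)
  if (any(vals < 0)) stop("filter thresholds must be non-negative")
  structure(as.list(vals), class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat(sprintf(
    "<filter_criteria> MW<=%g  HBD<=%g  HBA<=%g  rot<=%g  rings<=%g  aromatic<=%g\n",
    x$mw_max, x$hbd_max, x$hba_max, x$rotatable_max, x$ring_max,
    x$aromatic_ring_max))
  invisible(x)
}

# ---- Carboxylic-acid validation / salt stripping -----------------------------

# carboxyl carbons: C with a double bond to O and a single bond to O-H
cooh_carbons <- function(m) {
  el <- m$atoms$element
  b <- m$bonds
  out <- integer(0)
  for (c_idx in which(el == "C")) {
    nb1 <- c(b$a2[b$a1 == c_idx & b$order == 2L], b$a1[b$a2 == c_idx & b$order == 2L])
    nb2 <- c(b$a2[b$a1 == c_idx & b$order == 1L], b$a1[b$a2 == c_idx & b$order == 1L])
    has_carbonyl <- any(el[nb1] == "O")
    hydroxyl <- nb2[el[nb2] == "O" & m$atoms$nh[nb2] == 1L &
                    m$atoms$charge[nb2] == 0L]
    if (has_carbonyl && length(hydroxyl)) out <- c(out, c_idx)
  }
  out
}

#' Number of carboxylic-acid groups in a molecule
#'
#' @param m A `Molecule`.
#' @return Integer count of protonated C(=O)OH groups.
#' @export
count_cooh <- function(m) length(cooh_carbons(m))

#' Validate a parsed record as a single-fragment carboxylic acid
#'
#' Mirrors the salt-removal step of the funnel: multi-fragment records
#' (salts, mixtures) are rejected whole rather than desalted, and survivors
#' must contain at least one protonated carboxylic-acid group.
#'
#' @param m A `Molecule`.
#' @return The molecule itself when valid, otherwise an `acid_rejection`
#'   (list with `id` and `reason` of `"salt"` or `"not_carboxylic_acid"`).
#'   Rejections are data, not errors.
#' @export
strip_and_validate_acid <- function(m) {
  if (n_fragments(m) > 1L)
    return(structure(list(id = m$id, reason = "salt"),
                     class = "acid_rejection"))
  if (count_cooh(m) == 0L)
    return(structure(list(id = m$id, reason = "not_carboxylic_acid"),
                     class = "acid_rejection"))
  m
}

# ---- Funnel report -----------------------------------------------------------

new_funnel_report <- function() structure(list(stages = list()),
                                          class = "funnel_report")

add_funnel_stage <- function(report, stage, n_in, n_out, tallies = integer(0)) {
  if (n_out > n_in) stop("funnel stage cannot gain records")
  report$stages[[stage]] <- list(stage = stage, n_in = as.integer(n_in),
                                 n_out = as.integer(n_out),
                                 tallies = tallies)
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (s in x$stages) {
    cat(sprintf("  %-22s %6d -> %6d\n", s$stage, s$n_in, s$n_out))
    if (length(s$tallies)) {
      for (nm in names(s$tallies))
        cat(sprintf("      %-24s %d\n", nm, s$tallies[[nm]]))
    }
  }
  invisible(x)
}

#' Funnel report as a long-format data frame
#'
#' One row per stage for the counts plus one row per per-rule rejection
#' tally; suitable for TSV export.
#'
#' @param report A `funnel_report`.
#' @return data.frame with columns `stage`, `n_in`, `n_out`, `rule`, `count`.
#' @export
funnel_as_data_frame <- function(report) {
  rows <- lapply(report$stages, function(s) {
    base <- data.frame(stage = s$stage, n_in = s$n_in, n_out = s$n_out,
                       rule = ".total_rejected", count = s$n_in - s$n_out,
                       stringsAsFactors = FALSE)
    if (length(s$tallies)) {
      tl <- s$tallies[order(names(s$tallies))]
      base <- rbind(base, data.frame(stage = s$stage, n_in = s$n_in,
                                     n_out = s$n_out, rule = names(tl),
                                     count = as.integer(tl),
                                     stringsAsFactors = FALSE))
    }
    base
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# ---- Stage 1: salt strip (batch) ---------------------------------------------

#' Batch salt stripping and acid validation
#'
#' @param molecules List of `Molecule` objects.
#' @return list with `survivors`, `rejects` (data.frame id, reason) and
#'   `stage` (funnel entry fields).
#' @export
strip_acids <- function(molecules) {
  survivors <- list()
  rej_id <- character(0); rej_reason <- character(0)
  for (m in molecules) {
    r <- strip_and_validate_acid(m)
    if (inherits(r, "acid_rejection")) {
      rej_id <- c(rej_id, r$id); rej_reason <- c(rej_reason, r$reason)
    } else {
      survivors[[length(survivors) + 1L]] <- r
    }
  }
  tallies <- if (length(rej_reason)) table(rej_reason) else integer(0)
  list(survivors = survivors,
       rejects = data.frame(id = rej_id, reason = rej_reason,
                            stringsAsFactors = FALSE),
       stage = list(stage = "strip_salts", n_in = length(molecules),
                    n_out = length(survivors),
                    tallies = stats::setNames(as.integer(tallies),
                                              names(tallies))))
}

# ---- Stage 2: drug-likeness filter -------------------------------------------

#' Apply the six-descriptor drug-likeness filter
#'
#' A molecule survives iff all six descriptors are at or below their
#' thresholds.  A record violating several rules is removed once but
#' tallied under every violated rule, so the tallies are diagnostic.
#'
#' @param molecules List of `Molecule` objects.
#' @param criteria A [filter_criteria()] object.
#' @return list with `survivors`, `rejects` (data.frame id, rules), `stage`
#'   (funnel entry) and `profiles` (the computed property table).
#' @export
apply_druglike_filter <- function(molecules, criteria = filter_criteria()) {
  props <- property_table(molecules)
  keep <- logical(length(molecules))
  rules <- character(length(molecules))
  tallies <- c(mw_max = 0L, hbd_max = 0L, hba_max = 0L, rotatable_max = 0L,
               ring_max = 0L, aromatic_ring_max = 0L)
  for (i in seq_along(molecules)) {
    p <- props[i, ]
    viol <- c(
      mw_max = p$mw_average > criteria$mw_max,
      hbd_max = p$hbd > criteria$hbd_max,
      hba_max = p$hba > criteria$hba_max,
      rotatable_max = p$rotatable_bonds > criteria$rotatable_max,
      ring_max = p$ring_count > criteria$ring_max,
      aromatic_ring_max = p$aromatic_ring_count > criteria$aromatic_ring_max
    )
    keep[i] <- !any(viol)
    rules[i] <- paste(names(viol)[viol], collapse = ",")
    tallies[viol] <- tallies[viol] + 1L
  }
  list(
    survivors = molecules[keep],
    rejects = data.frame(id = props$id[!keep], rules = rules[!keep],
                         stringsAsFactors = FALSE),
    stage = list(stage = "druglike_filter", n_in = length(molecules),
                 n_out = sum(keep), tallies = tallies[tallies > 0L]),
    profiles = props
  )
}

# ---- Stage 3: structural alerts ----------------------------------------------

#' Load the structural-alert catalogue
#'
#' The catalogue is a TSV with columns `name`, `category`
#' (`reactive`/`non_druglike`), `kind` and `pattern`.  Kind `smarts` rows
#' are SMARTS substructure queries matched through OpenBabel; kind
#' `element` rows reject molecules containing any of the listed element
#' symbols; kind `chain` rows invoke the built-in long-chain fatty-acid
#' rule (an unbranched sp3 carbon chain of at least `pattern` carbons
#' attached to the carboxyl group and ending in a methyl).
#'
#' @param path Catalogue path; defaults to the catalogue shipped with the
#'   package.
#' @return data.frame of alerts.
#' @export
load_alerts <- function(path = system.file("extdata", "structural_alerts.tsv",
                                           package = "esterlib")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]   # '#' is SMARTS syntax,
  al <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE) # so only full-line comments
  stopifnot(all(c("name", "category", "kind", "pattern") %in% names(al)))
  if (anyDuplicated(al$name)) stop("duplicate alert names in catalogue")
  al
}

# longest unbranched sp3 carbon chain hanging off a carboxyl carbon;
# returns TRUE when some chain of >= min_len carbons ends in a terminal CH3
is_long_chain_fatty_acid <- function(m, min_len = 8L) {
  deg <- heavy_degree(m)
  el <- m$atoms$element
  b <- m$bonds
  ring_atoms <- unique(unlist(sssr(m)))
  plain_sp3_c <- function(a) {
    el[a] == "C" && !(a %in% ring_atoms) && m$atoms$charge[a] == 0L &&
      all(b$order[b$a1 == a | b$a2 == a] == 1L)
  }
  neighbors <- function(a) c(b$a2[b$a1 == a], b$a1[b$a2 == a])
  for (cx in cooh_carbons(m)) {
    alpha <- setdiff(neighbors(cx), which(el == "O"))
    if (length(alpha) != 1L) next
    prev <- cx; cur <- alpha; len <- 0L
    repeat {
      if (!plain_sp3_c(cur) || deg[cur] > 2L) break
      len <- len + 1L
      if (deg[cur] == 1L) {                      # terminal methyl
        if (len >= min_len) return(TRUE)
        break
      }
      nxt <- setdiff(neighbors(cur), prev)
      if (length(nxt) != 1L) break
      prev <- cur; cur <- nxt
    }
  }
  FALSE
}

# evaluate the catalogue against a molecule list; returns a logical matrix
# (molecules x alerts)
match_alerts <- function(molecules, alerts) {
  n <- length(molecules)
  hits <- matrix(FALSE, n, nrow(alerts),
                 dimnames = list(NULL, alerts$name))
  if (!n) return(hits)
  smarts_rows <- which(alerts$kind == "smarts")
  if (length(smarts_rows)) {
    smi <- vapply(molecules, function(m) {
      if (!is.na(m$smiles)) m$smiles else mol_to_smiles(m)
    }, character(1))
    payload <- paste(smi, seq_along(smi), collapse = "\n")
    pats <- alerts$pattern[smarts_rows]
    res <- suppressWarnings(ChemmineOB::forEachMol("SMILES", payload,
      function(mol) {
        vapply(pats, function(p)
          ChemmineOB::smartsSearch_OB(list(mol), p), numeric(1))
      }))
    if (length(res) != n)
      stop("alert matching lost records (OpenBabel rejected a survivor)")
    mat <- do.call(rbind, res) > 0
    hits[, smarts_rows] <- mat
  }
  for (j in which(alerts$kind == "element")) {
    els <- strsplit(alerts$pattern[j], ",", fixed = TRUE)[[1]]
    hits[, j] <- vapply(molecules, function(m) any(m$atoms$element %in% els),
                        logical(1))
  }
  for (j in which(alerts$kind == "chain")) {
    min_len <- as.integer(alerts$pattern[j])
    hits[, j] <- vapply(molecules, is_long_chain_fatty_acid, logical(1),
                        min_len = min_len)
  }
  hits
}

#' Apply the structural-alert pass
#'
#' A molecule survives iff it matches no alert; the names of matched
#' alerts are recorded per rejection and tallied per rule.
#'
#' @param molecules List of `Molecule` objects.
#' @param alerts Alert catalogue from [load_alerts()].
#' @return list with `survivors`, `rejects` (data.frame id, alerts) and
#'   `stage` (funnel entry).
#' @export
apply_alerts <- function(molecules, alerts = load_alerts()) {
  hits <- match_alerts(molecules, alerts)
  hit_any <- rowSums(hits) > 0
  ids <- vapply(molecules, function(m) as.character(m$id), character(1))
  matched <- vapply(seq_along(molecules), function(i)
    paste(colnames(hits)[hits[i, ]], collapse = ","), character(1))
  tallies <- colSums(hits)
  list(
    survivors = molecules[!hit_any],
    rejects = data.frame(id = ids[hit_any], alerts = matched[hit_any],
                         stringsAsFactors = FALSE),
    stage = list(stage = "structural_alerts", n_in = length(molecules),
                 n_out = sum(!hit_any),
                 tallies = stats::setNames(as.integer(tallies[tallies > 0]),
                                           names(tallies)[tallies > 0]))
  )
}

# ---- Full curation pass ------------------------------------------------------

#' Run the full curation funnel on parsed molecules
#'
#' Salt strip + acid validation, six-descriptor filter, structural alerts;
#' returns the survivors and the per-stage [funnel report][funnel_as_data_frame].
#'
#' @param molecules List of `Molecule` objects.
#' @param criteria [filter_criteria()].
#' @param alerts Alert catalogue.
#' @return list with `survivors`, `report` (funnel_report) and `rejects`
#'   (list of per-stage reject tables).
#' @export
curate_acids <- function(molecules, criteria = filter_criteria(),
                         alerts = load_alerts()) {
  report <- new_funnel_report()
  s1 <- strip_acids(molecules)
  report <- add_funnel_stage(report, s1$stage$stage, s1$stage$n_in,
                             s1$stage$n_out, s1$stage$tallies)
  s2 <- apply_druglike_filter(s1$survivors, criteria)
  report <- add_funnel_stage(report, s2$stage$stage, s2$stage$n_in,
                             s2$stage$n_out, s2$stage$tallies)
  s3 <- apply_alerts(s2$survivors, alerts)
  report <- add_funnel_stage(report, s3$stage$stage, s3$stage$n_in,
                             s3$stage$n_out, s3$stage$tallies)
  list(survivors = s3$survivors, report = report,
       rejects = list(strip = s1$rejects, druglike = s2$rejects,
                      alerts = s3$rejects))
}
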