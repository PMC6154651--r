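# ---- Docking-score ingestion and ranking -------------------------------------

#' Record an external docking configuration
#'
#' The docking engine itself is external to this package; its configuration
#' is recorded verbatim for provenance (receptor, grid, runs per ligand,
#' engine label) and never interpreted numerically beyond validation.
#'
#' @param receptor Receptor label (e.g. a PDB code such as `"1OSH"`).
#' @param grid Integer vector of grid points per axis.
#' @param runs Runs per ligand (e.g. 10 for screening, 100 for refinement).
#' @param engine Engine label (e.g. `"AutoDock 4.2"`).
#' @return A `docking_config` list.
#' @export
docking_config <- function(receptor = "1OSH", grid = c(60L, 60L, 60L),
                           runs = 10L, engine = "AutoDock 4.2") {
  if (length(grid) != 3L || any(grid <= 0)) stop("grid must be 3 positive values")
  if (runs <= 0) stop("runs must be positive")
  structure(list(receptor = receptor, grid = as.integer(grid),
                 runs = as.integer(runs), engine = engine),
            class = "docking_config")
}

#' Load a docking score table
#'
#' Expects a CSV with header `ligand_id, pki, is_control`.  Duplicated
#' ligand ids are an error (listing the ids); non-numeric or non-finite
#' scores are an error reporting the offending row numbers.
#'
#' @param table Path to a CSV file, or the CSV payload as a character
#'   scalar/vector of lines.
#' @return data.frame with columns `ligand_id` (character), `pki`
#'   (numeric) and `is_control` (logical).
#' @export
load_scores <- function(table) {
  con <- if (length(table) == 1L && file.exists(table)) table
         else textConnection(paste(table, collapse = "\n"))
  df <- utils::read.csv(con, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("ligand_id", "pki", "is_control")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  pki <- suppressWarnings(as.numeric(df$pki))
  bad <- which(is.na(pki) | !is.finite(pki))
  if (length(bad))
    stop("non-numeric pKi at row(s): ", paste(bad, collapse = ", "))
  dup <- unique(df$ligand_id[duplicated(df$ligand_id)])
  if (length(dup))
    stop("duplicate ligand_id(s): ", paste(dup, collapse = ", "))
  data.frame(ligand_id = df$ligand_id, pki = pki,
             is_control = as.logical(df$is_control) %in% TRUE,
             stringsAsFactors = FALSE)
}

#' Rank docked ligands by score
#'
#' Descending pKi; ties broken by ligand id (lexicographic); controls are
#' ranked alongside library compounds but remain flagged.  Truncation to
#' `top_n` happens after ranking.
#'
#' @param scores data.frame from [load_scores()].
#' @param top_n Optional truncation; must be positive when given.
#' @return data.frame with columns `rank`, `ligand_id`, `pki`, `is_control`.
#' @export
rank_ligands <- function(scores, top_n = NULL) {
  if (nrow(scores) < 1L) stop("need at least one score record")
  if (!is.null(top_n) && top_n <= 0) stop("top_n must be positive")
  ord <- order(-scores$pki, scores$ligand_id)
  out <- scores[ord, , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  out
}

#' Validate the positive control against the ranking
#'
#' Mirrors the screening validation logic: the docking setup is considered
#' validated when every flagged control outranks every library compound.
#' Anything else produces a warning status, not an error.
#'
#' @param scores data.frame from [load_scores()].
#' @return A `control_check` list with `status` (`"pass"`/`"warn"`) and
#'   `message`.
#' @export
control_check <- function(scores) {
  ranked <- rank_ligands(scores)
  if (!any(ranked$is_control)) {
    return(structure(list(status = "warn",
                          message = "no control present in score table"),
                     class = "control_check"))
  }
  worst_control <- max(ranked$rank[ranked$is_control])
  best_library <- if (any(!ranked$is_control))
    min(ranked$rank[!ranked$is_control]) else Inf
  if (worst_control < best_library) {
    structure(list(status = "pass",
                   message = "every control outranks the library compounds"),
              class = "control_check")
  } else {
    structure(list(status = "warn",
                   message = sprintf(
                     "control ranked %d but best library compound ranked %d",
                     worst_control, best_library)),
              class = "control_check")
  }
}

#' @export
print.control_check <- function(x, ...) {
  cat(sprintf("<control_check> %s: %s\n", toupper(x$status), x$message))
  invisible(x)
}
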