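# ---- Synthetic carboxylic-acid library generator -----------------------------
#
# Stands in for a commercial acid catalogue: every record is built from a
# fragment grammar (COOH head + ring/chain/heteroatom bodies), so its
# descriptor labels are known exactly at construction time from frozen
# per-fragment constants.  The generator never calls the descriptor or
# filter code: label agreement with the pipeline is an end-to-end test,
# not a tautology.

# formula helpers (named integer vectors)
.fadd <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  els <- unique(unlist(lapply(parts, names)))
  v <- vapply(els, function(e)
    sum(vapply(parts, function(p) if (e %in% names(p)) p[[e]] else 0L,
               integer(1))), integer(1))
  v[v != 0L]
}
.fH <- function(n) c(H = as.integer(n))

.favg <- function(f) sum(.atomic_weight[names(f)] * as.numeric(f))
.fmono <- function(f) sum(.monoisotopic[names(f)] * as.numeric(f))

# one labelled record
.rec <- function(smiles, formula, hbd, hba, rot, rings, aromrings,
                 alerts = "", is_salt = FALSE, n_cooh = 1L) {
  data.frame(smiles = smiles,
             is_salt = is_salt, n_cooh = as.integer(n_cooh),
             alerts = alerts,
             mw_average = if (is_salt) NA_real_ else .favg(formula),
             mw_monoisotopic = if (is_salt) NA_real_ else .fmono(formula),
             hbd = if (is_salt) NA_integer_ else as.integer(hbd),
             hba = if (is_salt) NA_integer_ else as.integer(hba),
             rotatable_bonds = if (is_salt) NA_integer_ else as.integer(rot),
             ring_count = if (is_salt) NA_integer_ else as.integer(rings),
             aromatic_ring_count = if (is_salt) NA_integer_ else as.integer(aromrings),
             stringsAsFactors = FALSE)
}

# ---- frozen fragment constants ----------------------------------------------

# aromatic/aliphatic ring cores: atoms in ring order (attachment at 1),
# ring formula with attachment H already removed
.cores <- list(
  benzene     = list(atoms = c("c", "c", "c", "c", "c", "c"),
                     formula = c(C = 6L, H = 5L), hba = 0L, arom = 1L),
  pyridine    = list(atoms = c("c", "c", "n", "c", "c", "c"),
                     formula = c(C = 5L, H = 4L, N = 1L), hba = 1L, arom = 1L),
  furan       = list(atoms = c("c", "c", "c", "c", "o"),
                     formula = c(C = 4L, H = 3L, O = 1L), hba = 1L, arom = 1L),
  thiophene   = list(atoms = c("c", "c", "c", "c", "s"),
                     formula = c(C = 4L, H = 3L, S = 1L), hba = 0L, arom = 1L),
  cyclohexane = list(atoms = c("C", "C", "C", "C", "C", "C"),
                     formula = c(C = 6L, H = 11L), hba = 0L, arom = 0L),
  cyclopentane = list(atoms = c("C", "C", "C", "C", "C"),
                     formula = c(C = 5L, H = 9L), hba = 0L, arom = 0L)
)

# substituent groups (group formula includes the group's own hydrogens; a
# substitution replaces one ring hydrogen).  rot is the contribution of the
# attachment plus internal single bonds between non-terminal heavy atoms.
.subs <- data.frame(
  name = c("F", "Cl", "Me", "Et", "OMe", "OH", "NH2", "CN", "CF3", "Ac"),
  frag = c("F", "Cl", "C", "CC", "OC", "O", "N", "C#N", "C(F)(F)F", "C(C)=O"),
  hbd = c(0L, 0L, 0L, 0L, 0L, 1L, 2L, 0L, 0L, 0L),
  hba = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 1L),
  rot = c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L, 1L),
  stringsAsFactors = FALSE
)
.sub_formula <- list(
  F = c(F = 1L), Cl = c(Cl = 1L), Me = c(C = 1L, H = 3L),
  Et = c(C = 2L, H = 5L), OMe = c(C = 1L, H = 3L, O = 1L),
  OH = c(O = 1L, H = 1L), NH2 = c(N = 1L, H = 2L), CN = c(C = 1L, N = 1L),
  CF3 = c(C = 1L, F = 3L), Ac = c(C = 2L, H = 3L, O = 1L)
)
.aliphatic_subs <- c("F", "Cl", "Me", "OH")

.cooh_formula <- c(C = 1L, H = 1L, O = 2L)   # -C(=O)OH as a group

# build the ring SMILES with an attachment string and position -> fragment subs
ring_smiles <- function(atoms, attach, subs = list()) {
  out <- character(length(atoms))
  for (i in seq_along(atoms)) {
    a <- atoms[[i]]
    dec <- ""
    if (i == 1L) dec <- paste0("1(", attach, ")")
    else if (!is.null(subs[[as.character(i)]]))
      dec <- paste0("(", subs[[as.character(i)]], ")")
    if (i == length(atoms)) dec <- paste0(dec, "1")
    out[i] <- paste0(a, dec)
  }
  paste(out, collapse = "")
}

# clean in-range pool: one random core/chain acid with exact labels
sample_clean_acid <- function() {
  repeat {
    fam <- sample(c(names(.cores), "chain", "branched"), 1L,
                  prob = c(30, 14, 7, 7, 5, 4, 8, 3) / 78)
    if (fam == "chain") {
      m <- sample(0:5, 1L)
      smiles <- paste0(strrep("C", m + 1L), "C(=O)O")
      rec <- .rec(smiles,
                  c(C = m + 2L, H = 2L * m + 4L, O = 2L),
                  hbd = 1L, hba = 2L, rot = m, rings = 0L, aromrings = 0L)
    } else if (fam == "branched") {
      pick <- sample(3L, 1L)
      rec <- switch(pick,
        .rec("CC(C)C(=O)O", c(C = 4L, H = 8L, O = 2L), 1L, 2L, 1L, 0L, 0L),
        .rec("CC(C)(C)C(=O)O", c(C = 5L, H = 10L, O = 2L), 1L, 2L, 1L, 0L, 0L),
        .rec("CC(C)CC(=O)O", c(C = 5L, H = 10L, O = 2L), 1L, 2L, 2L, 0L, 0L))
    } else {
      core <- .cores[[fam]]
      aromatic <- core$arom == 1L
      s <- sample(0:2, 1L, prob = c(0.5, 0.3, 0.2))
      attach <- paste0(strrep("C", s), "C(=O)O")
      sub_pool <- if (aromatic) .subs$name else .aliphatic_subs
      open <- which(core$atoms %in% c("c", "C"))[-1L]
      n_sub <- sample(0:2, 1L, prob = c(0.35, 0.4, 0.25))
      n_sub <- min(n_sub, length(open))
      pos <- if (n_sub) sort(sample(open, n_sub)) else integer(0)
      chosen <- if (n_sub) sample(sub_pool, n_sub, replace = TRUE) else character(0)
      subs <- stats::setNames(
        as.list(.subs$frag[match(chosen, .subs$name)]),
        as.character(pos))
      smiles <- ring_smiles(core$atoms, attach, subs)
      linker <- if (s > 0L) c(C = s, H = 2L * s) else NULL
      f <- .fadd(core$formula, linker, .cooh_formula)
      hbd <- 1L; hba <- 2L + core$hba
      rot <- s + 1L
      for (nm in chosen) {
        f <- .fadd(f, .sub_formula[[nm]], .fH(-1L))
        i <- match(nm, .subs$name)
        hbd <- hbd + .subs$hbd[i]; hba <- hba + .subs$hba[i]
        rot <- rot + .subs$rot[i]
      }
      rec <- .rec(smiles, f, hbd, hba, rot, rings = 1L,
                  aromrings = core$arom)
    }
    ok <- rec$mw_average <= 200 && rec$hbd <= 4 && rec$hba <= 8 &&
      rec$rotatable_bonds <= 7 && rec$ring_count <= 2 &&
      rec$aromatic_ring_count <= 2
    if (ok) return(rec)
  }
}

# fixed out-of-range pool (property violators; no structural alerts)
.violators <- function() rbind(
  .rec("COc1ccc2cc(C(=O)O)ccc2c1", c(C = 12L, H = 10L, O = 3L),
       1L, 3L, 2L, 2L, 2L),                                  # MW > 200
  .rec("OC(=O)c1ccc(-c2ccc(Cl)cc2)cc1", c(C = 13L, H = 9L, Cl = 1L, O = 2L),
       1L, 2L, 2L, 2L, 2L),                                  # MW > 200
  .rec("OC(=O)c1ccc2cc3ccccc3cc2c1", c(C = 15L, H = 10L, O = 2L),
       1L, 2L, 1L, 3L, 3L),                                  # MW, rings, aromatic
  .rec("OCC(O)C(O)C(O)C(O)C(=O)O", c(C = 6L, H = 12L, O = 7L),
       6L, 7L, 5L, 0L, 0L),                                  # HBD > 4
  .rec("OC(=O)C12CC3CC(C1)CC(C2)C3", c(C = 11L, H = 16L, O = 2L),
       1L, 2L, 1L, 3L, 0L),                                  # rings > 2
  .rec("COCCCCCCCC(=O)O", c(C = 9L, H = 18L, O = 3L),
       1L, 3L, 8L, 0L, 0L),                                  # rotatable > 7
  .rec("COCCOCCOCCOCCOCCOCCOCC(=O)O", c(C = 15L, H = 30L, O = 9L),
       1L, 9L, 20L, 0L, 0L)                                  # MW, HBA, rotatable
)

# fixed spiked motifs (reactive / non-druglike), one table per alert name
.spikes <- function() list(
  aminonitrile = .rec("NC(C#N)C(=O)O", c(C = 3L, H = 4L, N = 2L, O = 2L),
                      3L, 4L, 2L, 0L, 0L, alerts = "aminonitrile"),
  thionitrile = .rec("OC(=O)CSC#N", c(C = 3L, H = 3L, N = 1L, O = 2L, S = 1L),
                     1L, 3L, 3L, 0L, 0L, alerts = "thionitrile"),
  epoxide = .rec("OC(=O)C1CO1", c(C = 3L, H = 4L, O = 3L),
                 1L, 3L, 1L, 1L, 0L, alerts = "epoxide"),
  aziridine = .rec("OC(=O)C1CN1", c(C = 3L, H = 5L, N = 1L, O = 2L),
                   2L, 3L, 1L, 1L, 0L, alerts = "aziridine"),
  disulfide = .rec("OC(=O)CSSC", c(C = 3L, H = 6L, O = 2L, S = 2L),
                   1L, 2L, 3L, 0L, 0L, alerts = "disulfide"),
  nitrogen_oxide = .rec("OC(=O)c1ccc[n+]([O-])c1", c(C = 6L, H = 5L, N = 1L, O = 3L),
                        1L, 4L, 1L, 1L, 1L, alerts = "nitrogen_oxide"),
  azo = .rec("OC(=O)CN=Nc1ccccc1", c(C = 8L, H = 8L, N = 2L, O = 2L),
             1L, 4L, 3L, 1L, 1L, alerts = "azo"),
  beta_lactam = .rec("OC(=O)C1CC(=O)N1", c(C = 4L, H = 5L, N = 1L, O = 3L),
                     2L, 4L, 1L, 1L, 0L, alerts = "beta_lactam"),
  gem_dicarboxylic = .rec("OC(=O)C(C)C(=O)O", c(C = 4L, H = 6L, O = 4L),
                          2L, 4L, 2L, 0L, 0L,
                          alerts = "gem_dicarboxylic", n_cooh = 2L),
  long_chain_fatty_acid = .rec("CCCCCCCCC(=O)O", c(C = 9L, H = 18L, O = 2L),
                               1L, 2L, 7L, 0L, 0L,
                               alerts = "long_chain_fatty_acid"),
  quaternary_ammonium = .rec("OC(=O)C[N+](C)(C)C", c(C = 5L, H = 12L, N = 1L, O = 2L),
                             1L, 3L, 2L, 0L, 0L,
                             alerts = "quaternary_ammonium"),
  boron_selenium_silicon = .rec("OC(=O)C[Si](C)(C)C", c(C = 5L, H = 12L, O = 2L, Si = 1L),
                                1L, 2L, 2L, 0L, 0L,
                                alerts = "boron_selenium_silicon")
)

.salts <- function() rbind(
  .rec("[Na+].[O-]C(=O)c1ccccc1", NULL, NA, NA, NA, NA, NA,
       is_salt = TRUE, n_cooh = 0L),
  .rec("[K+].[O-]C(=O)C", NULL, NA, NA, NA, NA, NA,
       is_salt = TRUE, n_cooh = 0L),
  .rec("[Na+].[O-]C(=O)CC", NULL, NA, NA, NA, NA, NA,
       is_salt = TRUE, n_cooh = 0L)
)

.diacids <- function() rbind(
  .rec("OC(=O)CCC(=O)O", c(C = 4L, H = 6L, O = 4L), 2L, 4L, 3L, 0L, 0L,
       n_cooh = 2L),
  .rec("OC(=O)CCCC(=O)O", c(C = 5L, H = 8L, O = 4L), 2L, 4L, 4L, 0L, 0L,
       n_cooh = 2L),
  .rec("OC(=O)c1ccc(C(=O)O)cc1", c(C = 8L, H = 6L, O = 4L), 2L, 4L, 2L, 1L, 1L,
       n_cooh = 2L)
)

# ---- public API --------------------------------------------------------------

#' Specification for a synthetic acid library
#'
#' @param n Library size (records).
#' @param seed Integer seed; all draws flow from one seeded stream.
#' @param fraction_property_pass Target share of the clean (non-spiked)
#'   records that satisfy the default [filter_criteria()]; realized as an
#'   exact count `round(fraction * n_clean)`.
#' @param alert_rates Named numeric vector of spike rates per alert name
#'   (see [load_alerts()]); each realizes exactly `round(rate * n)` records.
#' @param salt_rate,diacid_rate Spike rates for multi-fragment salt records
#'   and for non-gem dicarboxylic acids.
#' @return A `library_spec`.
#' @export
library_spec <- function(n, seed = 1L, fraction_property_pass = 0.7,
                         alert_rates = NULL, salt_rate = 0.02,
                         diacid_rate = 0.02) {
  if (n < 1L) stop("n must be >= 1")
  if (fraction_property_pass < 0 || fraction_property_pass > 1)
    stop("fraction_property_pass must be in [0, 1]")
  known <- names(.spikes())
  if (is.null(alert_rates))
    alert_rates <- stats::setNames(rep(0.01, length(known)), known)
  if (length(alert_rates) == 1L && is.null(names(alert_rates)))
    alert_rates <- stats::setNames(rep(alert_rates, length(known)), known)
  if (is.null(names(alert_rates)) || !all(names(alert_rates) %in% known))
    stop("alert_rates names must be a subset of: ", paste(known, collapse = ", "))
  if (any(alert_rates < 0 | alert_rates > 1) || salt_rate < 0 || salt_rate > 1 ||
      diacid_rate < 0 || diacid_rate > 1)
    stop("rates must be in [0, 1]")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 fraction_property_pass = fraction_property_pass,
                 alert_rates = alert_rates, salt_rate = salt_rate,
                 diacid_rate = diacid_rate),
            class = "library_spec")
}

#' Generate a labelled synthetic acid library
#'
#' Produces exactly `spec$n` SMILES records with ground-truth labels:
#' descriptor values, structural-alert names, salt flag and carboxyl
#' count, all derived from the construction grammar rather than from the
#' pipeline's own calculators.  Spiked motif counts are exact
#' (`round(rate * n)`), and output is deterministic for a fixed seed.
#'
#' @param spec A [library_spec()].
#' @return data.frame with columns `id`, `smiles`, `is_salt`, `n_cooh`,
#'   `alerts` (comma-separated names, `""` for none), `mw_average`,
#'   `mw_monoisotopic`, `hbd`, `hba`, `rotatable_bonds`, `ring_count`,
#'   `aromatic_ring_count`.  Descriptor labels are `NA` for salt records
#'   (they leave the funnel before properties are computed).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  n <- spec$n
  spikes <- .spikes()
  n_alert <- vapply(spec$alert_rates, function(r) as.integer(round(r * n)),
                    integer(1))
  n_salt <- as.integer(round(spec$salt_rate * n))
  n_diacid <- as.integer(round(spec$diacid_rate * n))
  n_spike <- sum(n_alert) + n_salt + n_diacid
  if (n_spike > n)
    stop("spike rates demand ", n_spike, " records but n = ", n)
  n_clean <- n - n_spike
  n_pass <- as.integer(round(spec$fraction_property_pass * n_clean))
  n_fail <- n_clean - n_pass

  with_local_seed(spec$seed, {
    rows <- list()
    for (nm in names(n_alert)) {
      if (n_alert[[nm]] == 0L) next
      tab <- spikes[[nm]]
      idx <- sample.int(nrow(tab), n_alert[[nm]], replace = TRUE)
      rows[[length(rows) + 1L]] <- tab[idx, , drop = FALSE]
    }
    if (n_salt > 0L) {
      tab <- .salts()
      rows[[length(rows) + 1L]] <-
        tab[sample.int(nrow(tab), n_salt, replace = TRUE), , drop = FALSE]
    }
    if (n_diacid > 0L) {
      tab <- .diacids()
      rows[[length(rows) + 1L]] <-
        tab[sample.int(nrow(tab), n_diacid, replace = TRUE), , drop = FALSE]
    }
    if (n_fail > 0L) {
      tab <- .violators()
      rows[[length(rows) + 1L]] <-
        tab[sample.int(nrow(tab), n_fail, replace = TRUE), , drop = FALSE]
    }
    if (n_pass > 0L) {
      rows[[length(rows) + 1L]] <-
        do.call(rbind, replicate(n_pass, sample_clean_acid(), simplify = FALSE))
    }
    out <- do.call(rbind, rows)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    data.frame(id = sprintf("ACID%05d", seq_len(n)), out,
               stringsAsFactors = FALSE)
  })
}

#' Expected funnel report from generator labels alone
#'
#' Recomputes, from the ground-truth labels, the survivor counts and
#' per-rule tallies that the curation funnel should realize on the same
#' records; used to validate the pipeline end to end.
#'
#' @param records Output of [generate_library()].
#' @param criteria A [filter_criteria()].
#' @param alert_names Alert names in force (defaults to the shipped
#'   catalogue).
#' @return A `funnel_report` (same shape as [curate_acids()] produces).
#' @export
funnel_truth <- function(records, criteria = filter_criteria(),
                         alert_names = load_alerts()$name) {
  report <- new_funnel_report()

  ok1 <- !records$is_salt & records$n_cooh >= 1L
  t1 <- c(salt = sum(records$is_salt),
          not_carboxylic_acid = sum(!records$is_salt & records$n_cooh < 1L))
  report <- add_funnel_stage(report, "strip_salts", nrow(records), sum(ok1),
                             t1[t1 > 0L])

  r2 <- records[ok1, , drop = FALSE]
  viol <- cbind(
    mw_max = r2$mw_average > criteria$mw_max,
    hbd_max = r2$hbd > criteria$hbd_max,
    hba_max = r2$hba > criteria$hba_max,
    rotatable_max = r2$rotatable_bonds > criteria$rotatable_max,
    ring_max = r2$ring_count > criteria$ring_max,
    aromatic_ring_max = r2$aromatic_ring_count > criteria$aromatic_ring_max
  )
  ok2 <- rowSums(viol) == 0L
  t2 <- colSums(viol)
  report <- add_funnel_stage(report, "druglike_filter", nrow(r2), sum(ok2),
                             stats::setNames(as.integer(t2[t2 > 0L]),
                                             names(t2)[t2 > 0L]))

  r3 <- r2[ok2, , drop = FALSE]
  lab_alerts <- lapply(strsplit(r3$alerts, ",", fixed = TRUE),
                       intersect, x = alert_names)
  hit <- lengths(lab_alerts) > 0L
  t3 <- table(unlist(lab_alerts))
  report <- add_funnel_stage(report, "structural_alerts", nrow(r3), sum(!hit),
                             stats::setNames(as.integer(t3), names(t3)))
  report
}

#' Write a generated library as .smi plus a labels sidecar
#'
#' @param records Output of [generate_library()].
#' @param smi_path SMILES file (smiles, id).
#' @param labels_path Labels TSV.
#' @return Invisible list of paths.
#' @export
write_library <- function(records, smi_path, labels_path) {
  writeLines(paste(records$smiles, records$id, sep = "\t"), smi_path)
  utils::write.table(records, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(smi = smi_path, labels = labels_path))
}
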